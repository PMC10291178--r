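#' Read a mothur .shared OTU table
#'
#' The `.shared` dialect is tab-delimited with header
#' `label<TAB>Group<TAB>numOtus<TAB>Otu0001<TAB>...` and one row per
#' sample; the `Group` column carries sample identifiers and the remaining
#' columns carry integer OTU counts.
#'
#' @param path path to a `.shared` file.
#' @return an `otu_table` (OTUs in rows, in file column order; samples in
#'   file row order).
#' @export
read_shared <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("shared file has no sample rows: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 4L ||
      !identical(tolower(header[1:3]), c("label", "group", "numotus"))) {
    stop("malformed shared header (expected 'label\\tGroup\\tnumOtus\\t...'): ",
         paste(utils::head(header, 4L), collapse = " "), call. = FALSE)
  }
  ids <- header[-(1:3)]
  n_otus <- length(ids)
  rows <- fields[-1L]
  groups <- character(length(rows))
  counts <- matrix(0, nrow = n_otus, ncol = length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_otus + 3L) {
      stop(sprintf("row %d has %d fields, expected %d", i + 1L,
                   length(f), n_otus + 3L), call. = FALSE)
    }
    declared <- suppressWarnings(as.integer(f[3L]))
    if (is.na(declared) || declared != n_otus) {
      stop(sprintf("row %d: numOtus '%s' does not match the %d OTU columns",
                   i + 1L, f[3L], n_otus), call. = FALSE)
    }
    groups[i] <- f[2L]
    v <- suppressWarnings(as.numeric(f[-(1:3)]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("row %d (Group '%s'): non-integer count '%s' in column %s",
                   i + 1L, f[2L], f[3L + bad[1L]], ids[bad[1L]]),
           call. = FALSE)
    }
    counts[, i] <- v
  }
  if (anyDuplicated(groups)) {
    stop("duplicate Group in shared file: ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(counts) <- list(ids, groups)
  otu_table(counts)
}

#' Write an OTU table as a mothur .shared file
#'
#' @param table an `otu_table`.
#' @param path output path.
#' @param label value for the `label` column (mothur's OTU-clustering
#'   label; cosmetic here).
#' @return `path`, invisibly.
#' @export
write_shared <- function(table, path, label = "0.03") {
  m <- as_otu_table(table)
  header <- paste(c("label", "Group", "numOtus", rownames(m)), collapse = "\t")
  body <- vapply(seq_len(ncol(m)), function(j) {
    paste(c(label, colnames(m)[j], nrow(m), unclass(m)[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a generic TSV count matrix
#'
#' A rectangular tab-delimited matrix whose first column holds row
#' identifiers and whose header row holds column identifiers. The
#' `orientation` flag says whether rows are OTUs or samples; the returned
#' table always has OTUs in rows.
#'
#' @param path path to the TSV file.
#' @param orientation `"otus_in_rows"` (default) or `"samples_in_rows"`.
#' @return an `otu_table`.
#' @export
read_tsv_table <- function(path,
                           orientation = c("otus_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty or header-only TSV: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header) - 1L
  if (n_col < 1L) stop("TSV has no data columns: ", path, call. = FALSE)
  col_ids <- header[-1L]
  rows <- fields[-1L]
  row_ids <- character(length(rows))
  counts <- matrix(0, nrow = length(rows), ncol = n_col)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_col + 1L) {
      stop(sprintf("ragged TSV: row %d has %d fields, expected %d",
                   i + 1L, length(f), n_col + 1L), call. = FALSE)
    }
    row_ids[i] <- f[1L]
    counts[i, ] <- suppressWarnings(as.numeric(f[-1L]))
  }
  dimnames(counts) <- list(row_ids, col_ids)
  if (orientation == "samples_in_rows") counts <- t(counts)
  otu_table(counts)
}

#' @rdname read_tsv_table
#' @param table an `otu_table` to write.
#' @export
write_tsv_table <- function(table, path,
                            orientation = c("otus_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(as_otu_table(table))
  if (orientation == "samples_in_rows") m <- t(m)
  id_col <- if (orientation == "otus_in_rows") "otu_id" else "sample_id"
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a replicate-design TSV
#'
#' Two tab-separated columns, `sample_id` and `specimen_id`, with header.
#'
#' @param path file path.
#' @return `read_design` returns a `replicate_design`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  replicate_design(d)
}

#' @rdname read_design
#' @param design a `replicate_design` to write.
#' @export
write_design <- function(design, path) {
  design <- replicate_design(design)
  utils::write.table(as.data.frame(unclass(design)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a taxonomy TSV
#'
#' Accepts either the two-column form `otu_id<TAB>lineage` with
#' greengenes-style lineage strings (`k__Bacteria;p__Firmicutes;...`), or
#' a table with explicit rank columns (`otu_id`, `kingdom`, `phylum`, ...).
#'
#' @param path file path.
#' @return `read_taxonomy` returns a `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  if (!"otu_id" %in% names(d)) names(d)[1L] <- "otu_id"
  if ("lineage" %in% names(d) ||
      (ncol(d) == 2L && !"phylum" %in% names(d))) {
    lin <- if ("lineage" %in% names(d)) d$lineage else d[[2L]]
    parsed <- t(vapply(lin, parse_lineage, character(6)))
    d <- data.frame(otu_id = d$otu_id, parsed,
                    stringsAsFactors = FALSE, row.names = NULL)
  }
  taxonomy_table(d)
}

#' @rdname read_taxonomy
#' @param taxonomy a `taxonomy_table` to write (rank-column form).
#' @export
write_taxonomy <- function(taxonomy, path) {
  if (!inherits(taxonomy, "taxonomy_table")) taxonomy <- taxonomy_table(taxonomy)
  utils::write.table(as.data.frame(unclass(taxonomy)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
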
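#' Construct an OTU count table
#'
#' An `otu_table` is an integer matrix of read (copy) counts with OTUs as
#' rows and samples as columns. Row names are OTU identifiers and column
#' names are sample identifiers; both must be unique. Counts are stored as
#' exact integers; relative abundances are always derived on demand so that
#' filtering operates on copies.
#'
#' An OTU is considered *detected* ("present") in a sample when its count
#' is at least 1.
#'
#' @param counts a numeric matrix (or object coercible to one) of
#'   non-negative, integer-valued read counts, OTUs in rows and samples in
#'   columns. If dimnames are missing, identifiers `Otu0001`, ... and
#'   `S01`, ... are generated.
#' @return an `otu_table` object (an integer matrix with class
#'   `"otu_table"`).
#' @examples
#' tab <- otu_table(matrix(c(5, 1, 0, 0, 2, 7), nrow = 3,
#'                         dimnames = list(c("OtuA", "OtuB", "OtuC"),
#'                                         c("S1", "S2"))))
#' total_reads(tab)
#' @export
otu_table <- function(counts) {
  m <- as.matrix(counts)
  if (length(m) && !is.numeric(m)) {
    stop("counts must be numeric", call. = FALSE)
  }
  if (anyNA(m)) stop("counts contain missing values", call. = FALSE)
  if (length(m)) {
    if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(m != round(m))) {
      stop("counts must be integer-valued read counts", call. = FALSE)
    }
  }
  if (is.null(rownames(m)) && nrow(m) > 0) {
    rownames(m) <- sprintf("Otu%04d", seq_len(nrow(m)))
  }
  if (is.null(colnames(m)) && ncol(m) > 0) {
    colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate OTU identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  class(m) <- c("otu_table", class(matrix()))
  m
}

#' Coerce to an OTU table
#'
#' @param x an `otu_table`, or a matrix-like object of counts.
#' @return an `otu_table`.
#' @export
as_otu_table <- function(x) {
  if (inherits(x, "otu_table")) x else otu_table(x)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' OTU and sample identifiers
#'
#' @param x an `otu_table`.
#' @return character vector of identifiers.
#' @export
otu_ids <- function(x) rownames(as_otu_table(x))

#' @rdname otu_ids
#' @export
sample_ids <- function(x) colnames(as_otu_table(x))

#' Per-sample and pooled read totals
#'
#' Column sums of the count matrix (reads per sample), the pooled grand
#' total, and the mean reads per sample. `mean_per_sample` retains full
#' precision; use `trunc()` on it where an integer presentation is wanted.
#'
#' @param table an `otu_table`.
#' @return a list with components `per_sample` (named numeric vector),
#'   `grand_total`, and `mean_per_sample`.
#' @export
total_reads <- function(table) {
  m <- as_otu_table(table)
  per_sample <- colSums(matrix(as.numeric(m), nrow = nrow(m),
                               dimnames = dimnames(m)))
  grand <- sum(per_sample)
  list(per_sample = per_sample,
       grand_total = grand,
       mean_per_sample = if (ncol(m) > 0) grand / ncol(m) else NaN)
}

#' Drop OTU rows that are zero in every sample
#'
#' @param table an `otu_table`.
#' @return an `otu_table` restricted to OTUs detected in at least one
#'   sample.
#' @export
drop_empty_otus <- function(table) {
  m <- as_otu_table(table)
  keep <- rowSums(unclass(m) >= 1L) > 0L
  otu_table(unclass(m)[keep, , drop = FALSE])
}
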
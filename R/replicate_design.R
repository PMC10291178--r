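#' Replicate design: mapping of samples to specimens
#'
#' Records which specimen (replicate group) each sequenced sample belongs
#' to. In the triplicate design every specimen contributes exactly three
#' samples; operations that act on triplicates (replicate agreement, CV,
#' triplicate-scope filters) enforce a group size of three.
#'
#' @param x either a data frame with columns `sample_id` and `specimen_id`,
#'   or a named character vector mapping sample ids (names) to specimen
#'   ids (values).
#' @return a `replicate_design` object (a data frame with columns
#'   `sample_id`, `specimen_id`).
#' @examples
#' replicate_design(c(A_1 = "A", A_2 = "A", A_3 = "A"))
#' @export
replicate_design <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "specimen_id") %in% names(x))) {
      stop("design data frame needs columns sample_id and specimen_id",
           call. = FALSE)
    }
    d <- data.frame(sample_id = as.character(x$sample_id),
                    specimen_id = as.character(x$specimen_id),
                    stringsAsFactors = FALSE)
  } else {
    if (is.null(names(x))) {
      stop("a design vector must be named by sample id", call. = FALSE)
    }
    d <- data.frame(sample_id = names(x),
                    specimen_id = as.character(x),
                    stringsAsFactors = FALSE)
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample ids in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(d) || any(d == "")) {
    stop("design contains empty or missing identifiers", call. = FALSE)
  }
  class(d) <- c("replicate_design", "data.frame")
  d
}

#' @export
print.replicate_design <- function(x, ...) {
  cat(sprintf("Replicate design: %d samples over %d specimens\n",
              nrow(x), length(unique(x$specimen_id))))
  invisible(x)
}

#' Samples of each specimen
#'
#' @param design a `replicate_design`.
#' @return a named list, specimen id -> character vector of its sample ids.
#' @export
specimen_samples <- function(design) {
  design <- replicate_design(design)
  split(design$sample_id, design$specimen_id)
}

# Validate that a table's samples are fully covered by the design; samples
# missing from the design are a hard error, never a silent exclusion.
check_design <- function(table, design, require_triplicates = FALSE) {
  m <- as_otu_table(table)
  design <- replicate_design(design)
  missing <- setdiff(colnames(m), design$sample_id)
  if (length(missing)) {
    stop("samples absent from the replicate design: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- specimen_samples(design)
  groups <- lapply(groups, intersect, colnames(m))
  groups <- groups[vapply(groups, length, 0L) > 0L]
  sizes <- vapply(groups, length, 0L)
  if (require_triplicates && any(sizes != 3L)) {
    bad <- names(groups)[sizes != 3L]
    stop("specimens without exactly 3 replicates in the table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(sizes < 2L)) {
    stop("specimens need at least 2 replicate samples: ",
         paste(names(groups)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  groups
}
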
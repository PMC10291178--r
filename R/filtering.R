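#' @name filters
#' @title Low-abundance OTU filtering methods
#'
#' @description
#' Six strategies for removing low-abundance OTUs from a count table,
#' differing in the scope at which the criterion is evaluated:
#'
#' * **dataset scope** (`filter_dataset_relative`,
#'   `filter_dataset_max_copies`): the criterion is evaluated on counts
#'   pooled over all samples and a failing OTU is removed from *every*
#'   sample;
#' * **sample scope** (`filter_sample_singleton`,
#'   `filter_sample_min_copies`): the criterion is evaluated per cell and
#'   the OTU is zeroed only in the samples where it holds;
#' * **triplicate scope** (`filter_triplicate_max_copies`,
#'   `filter_triplicate_intersection`): the criterion is evaluated within
#'   each specimen's three replicates and a failing OTU is zeroed in all
#'   three; decisions are independent across specimens.
#'
#' `filter_none` is the identity baseline. All filters drop OTU rows that
#' end up zero in every sample, never increase any count, and account for
#' every removed read, so for each sample
#' `pre-filter total = post-filter total + reads_removed`.
#'
#' Threshold semantics follow the wording of the method labels exactly:
#' the dataset-relative rule removes an OTU whose pooled share is
#' strictly below `fraction` (a tie at the threshold is kept); the
#' dataset max-copies rule keeps an OTU only if some sample count is
#' strictly greater than `min_exceed`; the sample-scope rule zeroes
#' counts strictly below `min_copies`; the triplicate max-copies rule
#' keeps an OTU in a specimen when some replicate count is `>=
#' min_copies` (non-strict).
#'
#' @param table an [otu_table()].
#' @param design a [replicate_design()]; required by the triplicate-scope
#'   filters, which insist on exactly three replicates per specimen.
#' @param fraction dataset-relative abundance threshold (default 0.001,
#'   i.e. 0.1%).
#' @param min_exceed copy count that must be strictly exceeded in at
#'   least one sample (default 10).
#' @param min_copies copy threshold (default 10).
#' @return a [filter_result()].
NULL

# row maxima, safe for zero-row matrices
row_max <- function(x) {
  if (nrow(x) == 0L) return(numeric(0))
  apply(x, 1, max)
}

#' Filtering result with read accounting
#'
#' Wraps a filtered [otu_table()] together with per-sample accounting:
#' `reads_removed` (named integer vector) and `otus_zeroed` (named list of
#' the OTU ids whose count went from detected to zero in that sample), and
#' the `method` label.
#'
#' @param post filtered count matrix (same samples as `baseline`, rows a
#'   subset of the baseline's rows; all-zero rows are dropped).
#' @param baseline the pre-filter `otu_table`.
#' @param method method label.
#' @return a `filter_result` object.
#' @export
filter_result <- function(post, baseline, method) {
  base <- as_otu_table(baseline)
  bm <- unclass(base)
  pm <- matrix(0L, nrow = nrow(bm), ncol = ncol(bm), dimnames = dimnames(bm))
  if (nrow(post)) pm[rownames(post), ] <- as.integer(unclass(post))
  if (any(pm > bm)) {
    stop("post-filter counts exceed pre-filter counts", call. = FALSE)
  }
  removed <- colSums(bm) - colSums(pm)
  zeroed <- lapply(seq_len(ncol(bm)), function(j) {
    rownames(bm)[bm[, j] >= 1L & pm[, j] == 0L]
  })
  names(zeroed) <- colnames(bm)
  keep <- rowSums(pm >= 1L) > 0L
  structure(list(table = otu_table(pm[keep, , drop = FALSE]),
                 reads_removed = stats::setNames(as.integer(removed),
                                                 colnames(bm)),
                 otus_zeroed = zeroed,
                 method = method),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("Filter '%s': %d OTUs retained, %s reads removed\n",
              x$method, nrow(x$table),
              format(sum(x$reads_removed), big.mark = ",")))
  invisible(x)
}

#' @rdname filters
#' @export
filter_none <- function(table) {
  m <- as_otu_table(table)
  filter_result(unclass(m), m, "none")
}

#' Copy threshold implied by a dataset-relative abundance cutoff
#'
#' An OTU whose pooled count across all samples is strictly below
#' `fraction * grand_total` fails the dataset-relative rule, so the
#' implied copy threshold scales with the dataset: 10,000 copies for a
#' 10,000,000-read dataset at 0.1%, but only 1,000 copies at
#' 1,000,000 reads.
#'
#' @param grand_total pooled read count of the dataset.
#' @param fraction relative-abundance cutoff (default 0.001).
#' @return the copy threshold `fraction * grand_total`.
#' @export
dataset_relative_threshold <- function(grand_total, fraction = 0.001) {
  if (grand_total <= 0) stop("grand total must be positive", call. = FALSE)
  fraction * grand_total
}

#' @rdname filters
#' @export
filter_dataset_relative <- function(table, fraction = 0.001) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  m <- as_otu_table(table)
  bm <- unclass(m)
  pooled <- rowSums(bm)
  thr <- dataset_relative_threshold(sum(pooled), fraction)
  post <- bm
  post[pooled < thr, ] <- 0L
  filter_result(post, m, "dataset_relative")
}

#' @rdname filters
#' @export
filter_dataset_max_copies <- function(table, min_exceed = 10) {
  if (min_exceed < 0) stop("min_exceed must be >= 0", call. = FALSE)
  m <- as_otu_table(table)
  bm <- unclass(m)
  post <- bm
  post[row_max(bm) <= min_exceed, ] <- 0L
  filter_result(post, m, "dataset_max_copies")
}

#' @rdname filters
#' @export
filter_sample_singleton <- function(table) {
  m <- as_otu_table(table)
  post <- unclass(m)
  post[post == 1L] <- 0L
  filter_result(post, m, "sample_singleton")
}

#' @rdname filters
#' @export
filter_sample_min_copies <- function(table, min_copies = 10) {
  if (min_copies < 1) stop("min_copies must be >= 1", call. = FALSE)
  m <- as_otu_table(table)
  post <- unclass(m)
  post[post >= 1L & post < min_copies] <- 0L
  filter_result(post, m, "sample_min_copies")
}

#' @rdname filters
#' @export
filter_triplicate_max_copies <- function(table, design, min_copies = 10) {
  if (min_copies < 1) stop("min_copies must be >= 1", call. = FALSE)
  m <- as_otu_table(table)
  groups <- check_design(m, design, require_triplicates = TRUE)
  post <- unclass(m)
  for (samples in groups) {
    sub <- post[, samples, drop = FALSE]
    fail <- row_max(sub) < min_copies
    post[fail, samples] <- 0L
  }
  filter_result(post, m, "triplicate_max_copies")
}

#' @rdname filters
#' @export
filter_triplicate_intersection <- function(table, design) {
  m <- as_otu_table(table)
  groups <- check_design(m, design, require_triplicates = TRUE)
  post <- unclass(m)
  for (samples in groups) {
    sub <- post[, samples, drop = FALSE]
    fail <- rowSums(sub >= 1L) < length(samples)
    post[fail, samples] <- 0L
  }
  filter_result(post, m, "triplicate_intersection")
}

#' The seven filtering method labels
#'
#' @return character vector of method labels accepted by [apply_filter()],
#'   baseline first.
#' @export
filter_methods <- function() {
  c("none", "dataset_relative", "dataset_max_copies", "sample_singleton",
    "sample_min_copies", "triplicate_max_copies", "triplicate_intersection")
}

#' Apply a filtering method by label
#'
#' @param table an [otu_table()].
#' @param method one of [filter_methods()].
#' @param design a [replicate_design()]; required by triplicate-scope
#'   methods.
#' @param fraction,min_exceed,min_copies thresholds passed through to the
#'   respective filters.
#' @return a [filter_result()].
#' @export
apply_filter <- function(table, method, design = NULL, fraction = 0.001,
                         min_exceed = 10, min_copies = 10) {
  method <- match.arg(method, filter_methods())
  needs_design <- method %in% c("triplicate_max_copies",
                                "triplicate_intersection")
  if (needs_design && is.null(design)) {
    stop("method '", method, "' requires a replicate design", call. = FALSE)
  }
  switch(method,
    none = filter_none(table),
    dataset_relative = filter_dataset_relative(table, fraction),
    dataset_max_copies = filter_dataset_max_copies(table, min_exceed),
    sample_singleton = filter_sample_singleton(table),
    sample_min_copies = filter_sample_min_copies(table, min_copies),
    triplicate_max_copies = filter_triplicate_max_copies(table, design,
                                                         min_copies),
    triplicate_intersection = filter_triplicate_intersection(table, design))
}
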
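#' Abundance bin scheme for reliability and CV summaries
#'
#' Two descending edge sets: relative-abundance edges for binning OTUs by
#' within-sample (or within-specimen mean) relative abundance, and
#' copy-count edges for binning triplicate units by mean copies. The
#' defaults give the bins `>1%`, `0.1-1%`, `0.01-0.1%`, `<0.01%` and
#' `>1000`, `100-1000`, `10-100`, `1-10` plus a `sporadic` class.
#'
#' Bins are half-open from above: a value lands in the highest bin whose
#' upper edge it exceeds, so a value exactly on an edge belongs to the bin
#' *below* it (exactly 1% falls in `0.1-1%`). The `sporadic` class holds
#' units detected in at most two of the three replicates with every
#' nonzero count below the smallest copy edge.
#'
#' @param rel_edges strictly decreasing relative-abundance edges in (0, 1).
#' @param copy_edges strictly decreasing positive copy-count edges; the
#'   last edge doubles as the sporadic copy threshold.
#' @return a `bin_scheme` object.
#' @export
abundance_bins <- function(rel_edges = c(0.01, 0.001, 1e-4),
                           copy_edges = c(1000, 100, 10)) {
  if (any(diff(rel_edges) >= 0) || any(rel_edges <= 0) || any(rel_edges >= 1)) {
    stop("rel_edges must be strictly decreasing within (0, 1)", call. = FALSE)
  }
  if (any(diff(copy_edges) >= 0) || any(copy_edges <= 0)) {
    stop("copy_edges must be strictly decreasing and positive", call. = FALSE)
  }
  pct <- function(x) {
    y <- x * 100
    ifelse(y == round(y), sprintf("%g%%", y), sprintf("%g%%", y))
  }
  rel_labels <- c(sprintf(">%s", pct(rel_edges[1])),
                  if (length(rel_edges) > 1)
                    sprintf("%s-%s", pct(rel_edges[-1]),
                            pct(rel_edges[-length(rel_edges)])),
                  sprintf("<%s", pct(rel_edges[length(rel_edges)])))
  copy_labels <- c(sprintf(">%g", copy_edges[1]),
                   if (length(copy_edges) > 1)
                     sprintf("%g-%g", copy_edges[-1],
                             copy_edges[-length(copy_edges)]),
                   sprintf("1-%g", copy_edges[length(copy_edges)]))
  structure(list(rel_edges = rel_edges, rel_labels = rel_labels,
                 copy_edges = copy_edges, copy_labels = copy_labels,
                 sporadic_threshold = copy_edges[length(copy_edges)]),
            class = "bin_scheme")
}

# Descending half-open binning: index 1 for v > edges[1], index i+1 for
# edges[i] >= v > edges[i+1], last index for v <= min(edges).
bin_index <- function(v, edges) {
  idx <- rep(1L, length(v))
  for (e in edges) idx <- idx + (v <= e)
  idx
}

standard_error <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  stats::sd(x) / sqrt(n)
}

#' Replicate agreement (reliability) of OTU detection
#'
#' For each specimen, the unit set is the OTUs detected (count >= 1) in at
#' least one of its three replicates; each unit is classified by the
#' number of replicates in which it is detected (3, 2, or 1) and the
#' three classes are expressed as percentages of the unit set. The
#' aggregate is the mean and standard error of each class across
#' specimens. The `% in 3 replicates` class is what is reported as the
#' *reliability* of detection.
#'
#' @param table an [otu_table()].
#' @param design a [replicate_design()] with complete triplicates.
#' @return a `reliability_report`: list with `per_specimen` (data frame:
#'   `specimen`, `n_union`, `pct_in_3`, `pct_in_2`, `pct_in_1`) and
#'   `summary` (data frame: `class`, `mean`, `se`, with `n` the number of
#'   contributing specimens). Specimens with an empty unit set are
#'   excluded from the aggregate and listed in `empty_specimens` with a
#'   warning.
#' @export
replicate_agreement <- function(table, design) {
  m <- as_otu_table(table)
  groups <- check_design(m, design, require_triplicates = TRUE)
  bm <- unclass(m)
  rows <- lapply(names(groups), function(sp) {
    det <- bm[, groups[[sp]], drop = FALSE] >= 1L
    nrep <- rowSums(det)
    unit <- nrep >= 1L
    n <- sum(unit)
    if (n == 0L) {
      return(data.frame(specimen = sp, n_union = 0L, pct_in_3 = NA_real_,
                        pct_in_2 = NA_real_, pct_in_1 = NA_real_))
    }
    data.frame(specimen = sp, n_union = n,
               pct_in_3 = 100 * sum(nrep == 3L) / n,
               pct_in_2 = 100 * sum(nrep == 2L) / n,
               pct_in_1 = 100 * sum(nrep == 1L) / n)
  })
  per_specimen <- do.call(rbind, rows)
  empty <- per_specimen$specimen[per_specimen$n_union == 0L]
  if (length(empty)) {
    warning("specimens with no detected OTUs: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  ok <- per_specimen[per_specimen$n_union > 0L, , drop = FALSE]
  summary <- data.frame(
    class = c("in_3", "in_2", "in_1"),
    mean = c(mean(ok$pct_in_3), mean(ok$pct_in_2), mean(ok$pct_in_1)),
    se = c(standard_error(ok$pct_in_3), standard_error(ok$pct_in_2),
           standard_error(ok$pct_in_1)),
    n = nrow(ok))
  structure(list(per_specimen = per_specimen, summary = summary,
                 empty_specimens = empty),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Reliability over %d specimens: %.1f%% (SE %.1f) in 3, ",
                     "%.1f%% in 2, %.1f%% in 1 replicate(s)\n"),
              s$n[1], s$mean[1], s$se[1], s$mean[2], s$mean[3]))
  invisible(x)
}

#' Percentage of reads removed by a filter
#'
#' Per sample, `100 * reads_removed / baseline_total`; aggregated as mean
#' and standard error across samples.
#'
#' @param fr a [filter_result()].
#' @param baseline the pre-filter [otu_table()] the filter was applied to.
#' @return list with `per_sample` (named numeric vector of percentages),
#'   `mean`, and `se`.
#' @export
percent_reads_removed <- function(fr, baseline) {
  if (!inherits(fr, "filter_result")) {
    stop("fr must be a filter_result", call. = FALSE)
  }
  base <- as_otu_table(baseline)
  if (!setequal(colnames(base), names(fr$reads_removed)) ||
      !ncol(base) == length(fr$reads_removed)) {
    stop("filter result and baseline cover different samples", call. = FALSE)
  }
  totals <- colSums(unclass(base))
  if (any(totals == 0)) {
    stop("baseline samples with zero reads: ",
         paste(colnames(base)[totals == 0], collapse = ", "), call. = FALSE)
  }
  pct <- 100 * fr$reads_removed[colnames(base)] / totals
  list(per_sample = pct, mean = mean(pct), se = standard_error(pct))
}

#' Coefficient of variation of one OTU within a specimen's triplicate
#'
#' CV = standard deviation / mean over the specimen's three copy counts;
#' replicates in which the OTU is absent contribute zeros. `ddof = 1`
#' (default) uses the sample standard deviation (n - 1 denominator),
#' `ddof = 0` the population form.
#'
#' @param table an [otu_table()].
#' @param design a [replicate_design()].
#' @param specimen specimen identifier.
#' @param otu OTU identifier; must be detected in at least one replicate
#'   of the specimen.
#' @param ddof 0 or 1.
#' @return the coefficient of variation (dimensionless).
#' @export
otu_cv <- function(table, design, specimen, otu, ddof = 1) {
  m <- as_otu_table(table)
  groups <- check_design(m, design, require_triplicates = TRUE)
  if (!specimen %in% names(groups)) {
    stop("unknown specimen: ", specimen, call. = FALSE)
  }
  if (!otu %in% rownames(m)) stop("unknown OTU: ", otu, call. = FALSE)
  x <- as.numeric(unclass(m)[otu, groups[[specimen]]])
  if (mean(x) == 0) {
    stop("OTU ", otu, " is absent from every replicate of ", specimen,
         call. = FALSE)
  }
  cv_vector(x, ddof)
}

cv_vector <- function(x, ddof = 1) {
  if (!ddof %in% c(0, 1)) stop("ddof must be 0 or 1", call. = FALSE)
  sdv <- sqrt(sum((x - mean(x))^2) / (length(x) - ddof))
  sdv / mean(x)
}

# Per-(specimen, OTU) unit table: mean copies, replicate detections, max
# count, CV, and mean within-sample relative abundance.
triplicate_units <- function(m, groups, ddof = 1) {
  bm <- unclass(m)
  totals <- colSums(bm)
  out <- lapply(names(groups), function(sp) {
    sub <- bm[, groups[[sp]], drop = FALSE]
    nrep <- rowSums(sub >= 1L)
    unit <- nrep >= 1L
    if (!any(unit)) return(NULL)
    sub <- sub[unit, , drop = FALSE]
    k <- ncol(sub)
    rm_ <- rowMeans(sub)
    ss <- rowSums((sub - rm_)^2)
    rel <- sweep(sub, 2, totals[groups[[sp]]], "/")
    data.frame(specimen = sp, otu = rownames(sub),
               n_detected = nrep[unit],
               mean_copies = rm_,
               max_copies = row_max(sub),
               cv = sqrt(ss / (k - ddof)) / rm_,
               mean_rel = rowMeans(rel),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Mean CV per copy-count abundance bin
#'
#' Each (specimen, OTU) unit detected in at least one replicate is
#' assigned to a copy-count bin by its mean copies over the triplicate,
#' except that units detected in at most two replicates with all counts
#' below the sporadic threshold form the `sporadic` class. Reported is
#' the mean CV per bin over all units, pooled across specimens.
#'
#' @inheritParams otu_cv
#' @param scheme an [abundance_bins()] scheme.
#' @return data frame with `bin`, `mean_cv`, `n_units`, ordered from the
#'   most abundant bin to `sporadic`; empty bins are absent.
#' @export
cv_by_abundance_bin <- function(table, design, scheme = abundance_bins(),
                                ddof = 1) {
  m <- as_otu_table(table)
  groups <- check_design(m, design, require_triplicates = TRUE)
  units <- triplicate_units(m, groups, ddof)
  labels <- c(scheme$copy_labels, "sporadic")
  bin <- labels[bin_index(units$mean_copies, scheme$copy_edges)]
  sporadic <- units$n_detected <= 2L &
    units$max_copies < scheme$sporadic_threshold
  bin[sporadic] <- "sporadic"
  bin <- factor(bin, levels = labels)
  counts <- tabulate(bin, nbins = length(labels))
  agg <- stats::aggregate(units$cv, list(bin = bin), mean, drop = TRUE)
  out <- data.frame(bin = as.character(agg$bin), mean_cv = agg$x,
                    n_units = counts[match(as.character(agg$bin), labels)])
  out[order(match(out$bin, labels)), , drop = FALSE]
}

#' Detection reliability per relative-abundance bin
#'
#' Units are (specimen, OTU) pairs detected in at least one replicate,
#' binned by the OTU's mean within-sample relative abundance over the
#' specimen's triplicate; per bin, the percentage of units detected in
#' all three replicates is reported, pooled across specimens.
#'
#' @inheritParams cv_by_abundance_bin
#' @return data frame with `bin`, `pct_in_three`, `n_units`, from the most
#'   abundant bin downward; empty bins are absent.
#' @export
reliability_by_abundance_bin <- function(table, design,
                                         scheme = abundance_bins()) {
  m <- as_otu_table(table)
  groups <- check_design(m, design, require_triplicates = TRUE)
  units <- triplicate_units(m, groups)
  bin <- factor(scheme$rel_labels[bin_index(units$mean_rel, scheme$rel_edges)],
                levels = scheme$rel_labels)
  in3 <- units$n_detected == 3L
  counts <- tabulate(bin, nbins = length(scheme$rel_labels))
  agg <- stats::aggregate(in3, list(bin = bin), function(z) 100 * mean(z),
                          drop = TRUE)
  out <- data.frame(bin = as.character(agg$bin), pct_in_three = agg$x,
                    n_units = counts[match(as.character(agg$bin),
                                           scheme$rel_labels)])
  out[order(match(out$bin, scheme$rel_labels)), , drop = FALSE]
}

#' Distribution of OTUs over relative-abundance bins
#'
#' Per sample, detected OTUs are binned by within-sample relative
#' abundance; the number of OTUs and the share of reads per bin are then
#' averaged over samples. Within each sample the bin OTU counts sum to
#' the number of detected OTUs and the read shares to 100%.
#'
#' @param table an [otu_table()].
#' @param scheme an [abundance_bins()] scheme.
#' @return data frame with `bin`, `mean_n_otus`, `mean_pct_reads`, one
#'   row per relative-abundance bin.
#' @export
abundance_bin_summary <- function(table, scheme = abundance_bins()) {
  m <- as_otu_table(table)
  bm <- unclass(m)
  totals <- colSums(bm)
  if (any(totals == 0)) {
    stop("samples with zero reads: ",
         paste(colnames(bm)[totals == 0], collapse = ", "), call. = FALSE)
  }
  nb <- length(scheme$rel_labels)
  n_mat <- matrix(0, nb, ncol(bm))
  s_mat <- matrix(0, nb, ncol(bm))
  for (j in seq_len(ncol(bm))) {
    det <- bm[, j] >= 1L
    rel <- bm[det, j] / totals[j]
    idx <- bin_index(rel, scheme$rel_edges)
    n_mat[, j] <- tabulate(idx, nb)
    s_mat[, j] <- vapply(seq_len(nb),
                         function(b) 100 * sum(rel[idx == b]), 0)
  }
  data.frame(bin = scheme$rel_labels,
             mean_n_otus = rowMeans(n_mat),
             mean_pct_reads = rowMeans(s_mat))
}
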
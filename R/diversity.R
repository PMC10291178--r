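#' Alpha-diversity estimators for a count vector
#'
#' @description
#' * `observed_otus`: number of OTUs with count >= 1.
#' * `chao1`: bias-corrected Chao1 richness,
#'   `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))` with `f1` the number of
#'   singletons and `f2` the number of doubletons; defined for `f2 = 0`.
#'   With `bias_corrected = FALSE` the classic form
#'   `S_obs + f1^2 / (2 * f2)` is used (infinite when `f1 > 0, f2 = 0`).
#' * `shannon`: `-sum(p * log(p))` over detected OTUs, natural log by
#'   default (`base` configurable).
#' * `inverse_simpson`: `1 / sum(p^2)`.
#'
#' @param counts non-negative integer vector of OTU read counts for one
#'   sample.
#' @param bias_corrected use the bias-corrected Chao1 form (default TRUE).
#' @param base logarithm base for Shannon (default `exp(1)`).
#' @return a single numeric value.
#' @examples
#' x <- c(5, 0, 1, 2)
#' observed_otus(x)  # 3
#' chao1(c(1, 1, 2, 2, 5))  # 5 + 2*1/6
#' shannon(rep(1, 4))  # log(4)
#' inverse_simpson(c(3, 1))  # 1.6
#' @export
observed_otus <- function(counts) {
  counts <- check_counts(counts)
  sum(counts >= 1)
}

#' @rdname observed_otus
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_counts(counts)
  s_obs <- sum(counts >= 1)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + if (f1 > 0) f1^2 / (2 * f2) else 0
  }
}

#' @rdname observed_otus
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  if (sum(counts) <= 0) stop("sample has no reads", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(base)
}

#' @rdname observed_otus
#' @export
inverse_simpson <- function(counts) {
  counts <- check_counts(counts)
  if (sum(counts) <= 0) stop("sample has no reads", call. = FALSE)
  p <- counts / sum(counts)
  1 / sum(p^2)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  counts
}

#' Per-sample alpha diversity of an OTU table
#'
#' Computed on raw counts without rarefaction.
#'
#' @param table an [otu_table()].
#' @param base logarithm base for Shannon.
#' @return data frame with one row per sample: `sample_id`,
#'   `observed_otus`, `chao1`, `shannon`, `inverse_simpson`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- unclass(as_otu_table(table))
  data.frame(
    sample_id = colnames(m),
    observed_otus = apply(m, 2, observed_otus),
    chao1 = apply(m, 2, chao1),
    shannon = apply(m, 2, shannon, base = base),
    inverse_simpson = apply(m, 2, inverse_simpson),
    row.names = NULL)
}

# mean (SE) of each alpha metric over samples
alpha_summary <- function(alpha) {
  metrics <- c("observed_otus", "chao1", "shannon", "inverse_simpson")
  data.frame(metric = metrics,
             mean = vapply(alpha[metrics], mean, 0),
             se = vapply(alpha[metrics], standard_error, 0),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`, computed on raw
#' counts by default (set `relative = TRUE` to first convert each sample
#' to relative abundances).
#'
#' @param table an [otu_table()] with at least two samples.
#' @param relative compute on per-sample relative abundances instead of
#'   raw counts.
#' @return a [stats::dist] object over samples.
#' @export
bray_curtis <- function(table, relative = FALSE) {
  m <- unclass(as_otu_table(table))
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  totals <- colSums(m)
  if (sum(totals == 0) >= 2L) {
    stop("Bray-Curtis is undefined between all-zero samples: ",
         paste(colnames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  x <- t(m)
  if (relative) x <- x / totals
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical (Torgerson) scaling: the squared dissimilarities are
#' double-centered and eigendecomposed; coordinates are the eigenvectors
#' scaled by the square roots of the positive eigenvalues, axes ordered
#' by eigenvalue. Negative eigenvalues (possible because Bray-Curtis is
#' not Euclidean) are reported unchanged so the distortion can be
#' assessed; no Cailliez/Lingoes correction is applied.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @return list with `coordinates` (samples x positive axes, columns
#'   `PCo1`, `PCo2`, ...) and `eigenvalues` (all of them, decreasing).
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = max(n - 1L, 1L), eig = TRUE))
  pts <- fit$points
  if (!is.null(pts) && ncol(pts) > 0) {
    colnames(pts) <- sprintf("PCo%d", seq_len(ncol(pts)))
  }
  list(coordinates = pts, eigenvalues = fit$eig)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a dissimilarity matrix. With `n` samples in `a`
#' groups, `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` sums
#' `sum_{i<j in g} d_ij^2 / n_g` over groups, `SS_between = SS_total -
#' SS_within`, `R^2 = SS_between / SS_total`, and `pseudo-F =
#' (SS_between / (a - 1)) / (SS_within / (n - a))`. The p-value permutes
#' group labels without restriction and applies the +1 correction:
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_permutations)`.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param grouping factor (or vector) of group labels, one per sample, in
#'   the order of the dissimilarity matrix; at least two groups, and
#'   fewer groups than samples.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return a `permanova_result`: list with `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, grouping, n_permutations = 999, seed = NULL) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) {
    stop("grouping length must match the distance matrix", call. = FALSE)
  }
  grouping <- droplevels(grouping)
  a <- nlevels(grouping)
  if (a < 2L) stop("need at least 2 groups", call. = FALSE)
  if (a >= n) stop("no residual degrees of freedom (a = n)", call. = FALSE)
  d2 <- dm^2
  obs <- permanova_stat(d2, grouping)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (i in seq_len(n_permutations)) {
    f <- permanova_stat(d2, sample(grouping))["pseudo_f"]
    if (f >= obs[["pseudo_f"]]) count <- count + 1L
  }
  structure(list(r_squared = obs[["r_squared"]],
                 pseudo_f = obs[["pseudo_f"]],
                 p_value = (1 + count) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 seed = seed),
            class = "permanova_result")
}

# R^2 and pseudo-F for one labelling; d2 is the squared distance matrix.
permanova_stat <- function(d2, grouping) {
  n <- nrow(d2)
  a <- nlevels(grouping)
  upper <- upper.tri(d2)
  ss_total <- sum(d2[upper]) / n
  ss_within <- 0
  for (g in levels(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  c(r_squared = ss_between / ss_total,
    pseudo_f = (ss_between / (a - 1)) / (ss_within / (n - a)))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.3f, pseudo-F = %.2f, p = %.4g (%d permutations)\n",
              x$r_squared, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}

#' Relative abundance of taxa at a given rank
#'
#' Aggregates OTU counts by taxon (phylum by default), converts to
#' percentages of each sample's post-filter total, and summarizes as
#' mean and standard error over samples.
#'
#' @param table an [otu_table()]; every OTU must have a taxonomy entry.
#' @param taxonomy a [taxonomy_table()].
#' @param rank taxonomic rank to aggregate at (default `"phylum"`).
#' @return list with `per_sample` (taxa x samples matrix of percentages)
#'   and `summary` (data frame `taxon`, `mean_pct`, `se`, ordered by
#'   decreasing mean).
#' @export
phylum_relative_abundance <- function(table, taxonomy, rank = "phylum") {
  m <- unclass(as_otu_table(table))
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("samples with zero reads: ",
         paste(colnames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  labels <- taxon_of(taxonomy, rownames(m), rank)
  agg <- rowsum(m, labels)
  pct <- sweep(agg, 2, totals, "/") * 100
  summary <- data.frame(taxon = rownames(pct),
                        mean_pct = rowMeans(pct),
                        se = apply(pct, 1, standard_error),
                        row.names = NULL)
  summary <- summary[order(summary$mean_pct, decreasing = TRUE), , drop = FALSE]
  rownames(summary) <- NULL
  list(per_sample = pct, summary = summary)
}
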
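#' Run the full filtering-method comparison grid
#'
#' Applies each requested filtering method independently to the same
#' baseline table and computes, per method: replicate agreement, the
#' percentage of reads removed, per-sample alpha diversity (with
#' significance of each metric against the unfiltered baseline),
#' taxon-level relative abundance (if a taxonomy is given), the
#' Bray-Curtis matrix with its principal-coordinates ordination, and a
#' seeded PERMANOVA of sample-to-specimen grouping. Deterministic given
#' `seed`.
#'
#' @param table baseline [otu_table()].
#' @param design a [replicate_design()] with complete triplicates.
#' @param taxonomy optional [taxonomy_table()].
#' @param methods character vector of [filter_methods()] labels, or
#'   `"all"`; the `"none"` baseline is always included.
#' @param seed integer seed controlling the PERMANOVA permutations.
#' @param n_permutations permutations per PERMANOVA (default 999).
#' @param rank taxonomic rank for the composition summary.
#' @return a `method_grid` object: list with `methods` (named list of
#'   per-method results), `baseline_alpha`, `seed`.
#' @export
run_grid <- function(table, design, taxonomy = NULL, methods = "all",
                     seed = 1L, n_permutations = 999, rank = "phylum") {
  m <- as_otu_table(table)
  design <- replicate_design(design)
  if (identical(methods, "all")) methods <- filter_methods()
  methods <- union("none", match.arg(methods, filter_methods(),
                                     several.ok = TRUE))
  spec_of <- stats::setNames(design$specimen_id, design$sample_id)
  baseline_alpha <- alpha_diversity(filter_none(m)$table)

  results <- list()
  for (i in seq_along(methods)) {
    method <- methods[[i]]
    fr <- apply_filter(m, method, design = design)
    alpha <- alpha_diversity(fr$table)
    vs_baseline <- if (method == "none") NULL else {
      out <- lapply(c("observed_otus", "chao1", "shannon", "inverse_simpson"),
                    function(metric) {
                      cmp <- compare_alpha(baseline_alpha[[metric]],
                                           alpha[[metric]])
                      data.frame(metric = metric, t_statistic = cmp$t_statistic,
                                 t_p = cmp$t_p, u_statistic = cmp$u_statistic,
                                 u_p = cmp$u_p, significance = cmp$significance)
                    })
      do.call(rbind, out)
    }
    bc <- bray_curtis(fr$table)
    grouping <- spec_of[labels(bc)]
    results[[method]] <- list(
      method = method,
      filter = fr,
      reliability = replicate_agreement(fr$table, design),
      reads_removed = percent_reads_removed(fr, m),
      alpha = alpha,
      alpha_summary = alpha_summary(alpha),
      alpha_vs_baseline = vs_baseline,
      taxa = if (!is.null(taxonomy))
        phylum_relative_abundance(fr$table, taxonomy, rank),
      bray_curtis = bc,
      pcoa = pcoa(bc),
      permanova = permanova(bc, grouping, n_permutations = n_permutations,
                            seed = seed + i))
  }
  structure(list(methods = results, baseline_alpha = baseline_alpha,
                 seed = seed), class = "method_grid")
}

#' @export
print.method_grid <- function(x, ...) {
  cat(sprintf("Filtering-method grid: %d methods (seed %d)\n",
              length(x$methods), x$seed))
  for (r in x$methods) {
    cat(sprintf("  %-24s reliability %.1f%%, reads removed %.2f%%, R2 %.3f\n",
                r$method, r$reliability$summary$mean[1],
                r$reads_removed$mean, r$permanova$r_squared))
  }
  invisible(x)
}

#' Compare an alpha-diversity metric between baseline and filtered samples
#'
#' Two-sided two-sample t test (Welch by default) followed by a
#' Mann-Whitney rank-sum test with normal approximation and tie
#' correction. Significance flags use the t-test p-value at the two-level
#' convention `*` (p < 0.05) and `**` (p < 0.001). Samples are treated as
#' unpaired by default; `paired = TRUE` switches to a paired t test and a
#' Wilcoxon signed-rank test.
#'
#' @param baseline_values,filtered_values equal-length numeric vectors of
#'   per-sample metric values (n >= 3).
#' @param paired treat the vectors as paired.
#' @param var_equal pooled-variance t test instead of Welch.
#' @return list with `t_statistic`, `t_p`, `u_statistic`, `u_p`,
#'   `significance` (`""`, `"*"`, or `"**"`).
#' @export
compare_alpha <- function(baseline_values, filtered_values, paired = FALSE,
                          var_equal = FALSE) {
  x <- as.numeric(baseline_values)
  y <- as.numeric(filtered_values)
  if (length(x) != length(y)) {
    stop("per-sample vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x) + stats::var(y), 0)) &&
      isTRUE(all.equal(mean(x), mean(y)))) {
    # both constant and identical: no dispersion, no difference
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(x, y, paired = paired, var.equal = var_equal)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = FALSE, correct = TRUE))
  t_p <- tt$p.value
  list(t_statistic = unname(tt$statistic),
       t_p = t_p,
       u_statistic = unname(wt$statistic),
       u_p = wt$p.value,
       significance = if (t_p < 0.001) "**" else if (t_p < 0.05) "*" else "")
}

#' Write the grid result as tab-separated tables and one JSON report
#'
#' Emits `reliability.tsv` (per-method reliability classes and reads
#' removed), `alpha_diversity.tsv` (per-method metric means, SEs, and
#' significance vs baseline), `taxa.tsv` (per-method taxon percentages,
#' when taxonomy was supplied), one `pcoa_<method>.tsv` of ordination
#' coordinates per method, and `grid.json` holding all numbers.
#' Re-running on the same result overwrites byte-identically.
#'
#' @param grid a `method_grid` from [run_grid()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_grid_report <- function(grid, dir) {
  if (!inherits(grid, "method_grid")) {
    stop("grid must come from run_grid()", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  rel <- do.call(rbind, lapply(grid$methods, function(r) {
    s <- r$reliability$summary
    data.frame(method = r$method,
               pct_in_3 = s$mean[1], se_in_3 = s$se[1],
               pct_in_2 = s$mean[2], se_in_2 = s$se[2],
               pct_in_1 = s$mean[3], se_in_1 = s$se[3],
               pct_reads_removed = r$reads_removed$mean,
               se_reads_removed = r$reads_removed$se)
  }))
  wt(rel, "reliability.tsv")

  alpha <- do.call(rbind, lapply(grid$methods, function(r) {
    s <- r$alpha_summary
    sig <- if (is.null(r$alpha_vs_baseline)) rep("", nrow(s)) else
      r$alpha_vs_baseline$significance[match(s$metric,
                                             r$alpha_vs_baseline$metric)]
    data.frame(method = r$method, metric = s$metric, mean = s$mean,
               se = s$se, significance = sig)
  }))
  wt(alpha, "alpha_diversity.tsv")

  taxa <- do.call(rbind, lapply(grid$methods, function(r) {
    if (is.null(r$taxa)) return(NULL)
    s <- r$taxa$summary
    data.frame(method = r$method, taxon = s$taxon, mean_pct = s$mean_pct,
               se = s$se)
  }))
  if (!is.null(taxa)) wt(taxa, "taxa.tsv")

  for (r in grid$methods) {
    co <- r$pcoa$coordinates
    wt(data.frame(sample_id = rownames(co), co, check.names = FALSE),
       sprintf("pcoa_%s.tsv", r$method))
  }

  json <- lapply(grid$methods, function(r) {
    list(reliability = list(
           per_specimen = r$reliability$per_specimen,
           summary = r$reliability$summary),
         reads_removed = list(mean = r$reads_removed$mean,
                              se = r$reads_removed$se),
         alpha_summary = r$alpha_summary,
         alpha_vs_baseline = r$alpha_vs_baseline,
         taxa = if (!is.null(r$taxa)) r$taxa$summary,
         permanova = list(r_squared = r$permanova$r_squared,
                          pseudo_f = r$permanova$pseudo_f,
                          p_value = r$permanova$p_value,
                          n_permutations = r$permanova$n_permutations))
  })
  jsonlite::write_json(json, file.path(dir, "grid.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_grid_report
#' @param path path to a `grid.json` written by `write_grid_report`.
#' @return `read_grid_report` returns the parsed report list.
#' @export
read_grid_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
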
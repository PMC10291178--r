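# Fixture builders and independent brute-force oracles shared by the suite.

# Random sparse count table with the given shape.
random_table <- function(n_otus, n_samples, max_count = 30, zero_prob = 0.4) {
  m <- matrix(
    ifelse(stats::runif(n_otus * n_samples) < zero_prob, 0L,
           sample.int(max_count, n_otus * n_samples, replace = TRUE)),
    nrow = n_otus,
    dimnames = list(sprintf("Otu%03d", seq_len(n_otus)),
                    sprintf("S%02d", seq_len(n_samples))))
  otu_table(m)
}

# Triplicate design over n_spec specimens; sample ids Sp<k>_R<r>.
triplicate_design <- function(n_spec) {
  spec <- sprintf("Sp%02d", seq_len(n_spec))
  sam <- as.vector(vapply(spec, function(s) paste0(s, "_R", 1:3), character(3)))
  replicate_design(stats::setNames(rep(spec, each = 3), sam))
}

# Random table whose samples match triplicate_design(n_spec).
random_triplicate_table <- function(n_spec, n_otus, max_count = 30,
                                    zero_prob = 0.4) {
  tab <- random_table(n_otus, 3 * n_spec, max_count, zero_prob)
  d <- triplicate_design(n_spec)
  colnames(tab) <- d$sample_id
  otu_table(unclass(tab))
}

# Table from a per-OTU list of count vectors (one triplicate specimen).
otu_rows <- function(rows, sample_ids = c("Sp01_R1", "Sp01_R2", "Sp01_R3")) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), sample_ids)
  otu_table(m)
}

# Brute-force replicate agreement: explicit per-OTU pattern enumeration.
bf_agreement <- function(table, design) {
  m <- unclass(as_otu_table(table))
  groups <- split(design$sample_id, design$specimen_id)
  out <- list()
  for (sp in names(groups)) {
    n3 <- n2 <- n1 <- 0L
    for (otu in rownames(m)) {
      hits <- 0L
      for (s in groups[[sp]]) if (m[otu, s] >= 1) hits <- hits + 1L
      if (hits == 3L) n3 <- n3 + 1L
      if (hits == 2L) n2 <- n2 + 1L
      if (hits == 1L) n1 <- n1 + 1L
    }
    tot <- n3 + n2 + n1
    out[[sp]] <- if (tot == 0) c(NA, NA, NA) else 100 * c(n3, n2, n1) / tot
  }
  out
}

# Brute-force alpha diversity formulas, written from their definitions.
bf_observed <- function(x) {
  n <- 0L
  for (v in x) if (v >= 1) n <- n + 1L
  n
}
bf_chao1 <- function(x) {
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  bf_observed(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}
bf_shannon <- function(x) {
  tot <- sum(x)
  h <- 0
  for (v in x) if (v > 0) h <- h - (v / tot) * log(v / tot)
  h
}
bf_inverse_simpson <- function(x) {
  tot <- sum(x)
  s <- 0
  for (v in x) s <- s + (v / tot)^2
  1 / s
}
bf_bray_curtis <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  unname(num / den)
}

# All permutations of seq_len(n), for exhaustive PERMANOVA enumeration.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}
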
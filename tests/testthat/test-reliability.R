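test_that("replicate agreement classifies detection patterns over the union", {
  d <- triplicate_design(1)
  tab <- otu_rows(list(A = c(1, 1, 1), B = c(1, 1, 0), C = c(1, 0, 0)))
  rep <- replicate_agreement(tab, d)
  expect_equal(rep$per_specimen$pct_in_3, 100 / 3)
  expect_equal(rep$per_specimen$pct_in_2, 100 / 3)
  expect_equal(rep$per_specimen$pct_in_1, 100 / 3)
  expect_equal(rep$summary$n[1], 1)

  all3 <- otu_rows(list(A = c(2, 1, 9), B = c(1, 1, 1)))
  expect_equal(replicate_agreement(all3, d)$summary$mean, c(100, 0, 0))
})

test_that("agreement percentages match brute-force enumeration and sum to 100", {
  withr::local_seed(41)
  d <- triplicate_design(3)
  for (i in 1:8) {
    tab <- random_triplicate_table(3, 15, max_count = 3, zero_prob = 0.6)
    rep <- replicate_agreement(tab, d)
    oracle <- bf_agreement(tab, d)
    for (k in seq_len(nrow(rep$per_specimen))) {
      row <- rep$per_specimen[k, ]
      expect_equal(unlist(row[c("pct_in_3", "pct_in_2", "pct_in_1")],
                          use.names = FALSE),
                   oracle[[row$specimen]])
      expect_equal(row$pct_in_3 + row$pct_in_2 + row$pct_in_1, 100)
    }
  }
})

test_that("specimens with no detected OTUs are flagged and excluded", {
  d <- triplicate_design(2)
  m <- rbind(A = c(1L, 1L, 1L, 0L, 0L, 0L))
  colnames(m) <- d$sample_id
  expect_warning(rep <- replicate_agreement(otu_table(m), d),
                 "no detected OTUs.*Sp02")
  expect_equal(rep$summary$n[1], 1)
  expect_equal(rep$summary$mean[1], 100)
})

test_that("percent reads removed aggregates per-sample removal", {
  d <- triplicate_design(1)
  tab <- otu_rows(list(A = c(99, 99, 99), B = c(1, 1, 1)))
  fr <- filter_sample_singleton(tab)
  prr <- percent_reads_removed(fr, tab)
  expect_equal(unname(prr$per_sample), rep(1, 3))
  expect_equal(prr$mean, 1)
  expect_equal(prr$se, 0)  # SE of a constant vector

  zero <- otu_rows(list(A = c(0, 5, 5)))
  expect_error(percent_reads_removed(filter_none(zero), zero), "zero reads")
})

test_that("otu_cv matches closed forms and is scale invariant", {
  d <- triplicate_design(1)
  tab <- otu_rows(list(A = c(7, 7, 7), B = c(10, 0, 0), C = c(10, 10, 0),
                       D = c(0, 0, 0), E = c(30, 0, 0)))
  expect_equal(otu_cv(tab, d, "Sp01", "A"), 0)
  expect_equal(otu_cv(tab, d, "Sp01", "B"), sqrt(3))
  expect_equal(otu_cv(tab, d, "Sp01", "B", ddof = 0), sqrt(2))
  expect_equal(otu_cv(tab, d, "Sp01", "C"), sqrt(3) / 2)
  expect_error(otu_cv(tab, d, "Sp01", "D"), "absent")
  # CV(c * x) = CV(x): B scaled by 3 is E
  expect_equal(otu_cv(tab, d, "Sp01", "E"), otu_cv(tab, d, "Sp01", "B"))
})

test_that("copy-count bins assign by mean copies with a sporadic class", {
  d <- triplicate_design(1)
  tab <- otu_rows(list(A = c(2000, 2000, 2000), B = c(3, 0, 0),
                       C = c(150, 150, 150), D = c(0, 12, 12)))
  cv <- cv_by_abundance_bin(tab, d)
  expect_equal(cv$mean_cv[cv$bin == ">1000"], 0)
  expect_true("B" %in% rownames(unclass(tab)))
  expect_equal(cv$n_units[cv$bin == "sporadic"], 1L)  # only B
  # D is detected twice but with >=10 copies, so it bins by mean copies (8 -> 1-10)
  expect_equal(cv$n_units[cv$bin == "1-10"], 1L)
  expect_equal(cv$n_units[cv$bin == "100-1000"], 1L)
})

test_that("no unit is sporadic after the 10-copy sample filter", {
  withr::local_seed(13)
  d <- triplicate_design(3)
  for (i in 1:5) {
    tab <- random_triplicate_table(3, 40, max_count = 40, zero_prob = 0.5)
    fr <- filter_sample_min_copies(tab, 10)
    cv <- cv_by_abundance_bin(fr$table, d)
    expect_false("sporadic" %in% cv$bin)
  }
})

test_that("reliability by relative-abundance bin reports detected bins only", {
  d <- triplicate_design(1)
  # A ~91%, B ~9%: both triple-detected; low bins are empty and absent
  tab <- otu_rows(list(A = c(1000, 1000, 1000), B = c(100, 100, 100)))
  rel <- reliability_by_abundance_bin(tab, d)
  expect_equal(rel$bin, c(">1%", "0.1%-1%")[c(1)])
  expect_equal(rel$pct_in_three, 100)

  # a value exactly on an edge falls in the bin below it
  tab2 <- otu_rows(list(A = c(99, 99, 99), B = c(1, 1, 1)))
  rel2 <- reliability_by_abundance_bin(tab2, d)
  expect_setequal(rel2$bin, c(">1%", "0.1%-1%"))
})

test_that("abundance-bin summary partitions detected OTUs and read shares", {
  tab <- otu_table(matrix(c(80L, 15L, 4L, 1L), ncol = 1,
                          dimnames = list(LETTERS[1:4], "S1")))
  s <- abundance_bin_summary(tab)
  expect_equal(s$mean_n_otus[s$bin == ">1%"], 3)   # 80%, 15%, 4%
  expect_equal(s$mean_n_otus[s$bin == "0.1%-1%"], 1)  # exactly 1%
  expect_equal(s$mean_pct_reads[s$bin == ">1%"], 99)
  expect_equal(sum(s$mean_pct_reads), 100)

  withr::local_seed(19)
  tab2 <- random_table(30, 4, zero_prob = 0.2)
  s2 <- abundance_bin_summary(tab2)
  expect_equal(sum(s2$mean_n_otus), mean(colSums(unclass(tab2) >= 1)))
  expect_equal(sum(s2$mean_pct_reads), 100)

  single <- otu_table(matrix(5L, 1, 1, dimnames = list("A", "S1")))
  ss <- abundance_bin_summary(single)
  expect_equal(ss$mean_pct_reads[ss$bin == ">1%"], 100)
})
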
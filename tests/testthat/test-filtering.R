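test_that("filter_none is the identity with zero removal accounting", {
  tab <- random_table(15, 4)
  fr <- filter_none(tab)
  expect_identical(unclass(drop_empty_otus(tab)), unclass(fr$table))
  expect_true(all(fr$reads_removed == 0))
  expect_equal(percent_reads_removed(fr, tab)$mean, 0)
  empty <- otu_table(matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("S1", "S2"))))
  expect_equal(nrow(filter_none(empty)$table), 0)
})

test_that("dataset-relative filter uses a strict pooled-share threshold", {
  # total 10,000 at 0.1% => threshold 10 copies; a pooled count of exactly
  # 10 is kept, 9 is removed
  tab <- otu_rows(list(A = c(9990, 0, 0), B = c(10, 0, 0)))
  fr <- filter_dataset_relative(tab)
  expect_true(all(c("A", "B") %in% rownames(fr$table)))
  expect_equal(sum(fr$reads_removed), 0)

  tab2 <- otu_rows(list(A = c(9991, 0, 0), B = c(9, 0, 0)))
  fr2 <- filter_dataset_relative(tab2)
  expect_false("B" %in% rownames(fr2$table))
  expect_equal(unname(fr2$reads_removed["Sp01_R1"]), 9L)

  expect_error(filter_dataset_relative(tab, fraction = 0), "fraction")
  expect_error(filter_dataset_relative(otu_table(matrix(0L, 2, 2))),
               "grand total")
})

test_that("dataset max-copies filter keeps an OTU only if some count strictly exceeds the threshold", {
  tab <- otu_rows(list(A = c(10, 10, 10), B = c(11, 0, 0), C = c(0, 0, 0)))
  fr <- filter_dataset_max_copies(tab, min_exceed = 10)
  expect_false("A" %in% rownames(fr$table))
  # dataset scope: B kept everywhere, including its zero-count samples
  expect_equal(unname(unclass(fr$table)["B", ]), c(11L, 0L, 0L))
  empty <- otu_table(matrix(integer(0), 0, 1, dimnames = list(NULL, "S1")))
  expect_equal(nrow(filter_dataset_max_copies(empty)$table), 0)
})

test_that("sample-scope filters zero cells below the copy threshold", {
  tab <- otu_rows(list(A = c(1, 2, 1), B = c(9, 10, 3), C = c(1, 1, 1)))
  fs <- filter_sample_singleton(tab)
  expect_equal(unname(unclass(fs$table)["A", ]), c(0L, 2L, 0L))
  expect_false("C" %in% rownames(fs$table))  # all-zero row dropped

  fm <- filter_sample_min_copies(tab, min_copies = 10)
  expect_equal(unname(unclass(fm$table)["B", ]), c(0L, 10L, 0L))

  # after the singleton filter every remaining count is 0 or >= 2
  withr::local_seed(8)
  for (i in 1:10) {
    rt <- random_table(20, 5, max_count = 4)
    post <- unclass(filter_sample_singleton(rt)$table)
    expect_true(all(post == 0L | post >= 2L))
    # min_copies = 2 is the singleton filter; min_copies = 1 the identity
    expect_identical(unclass(filter_sample_min_copies(rt, 2)$table), post)
    expect_identical(unclass(filter_sample_min_copies(rt, 1)$table),
                     unclass(drop_empty_otus(rt)))
  }
})

test_that("triplicate max-copies filter is non-strict and specimen-scoped", {
  d <- triplicate_design(2)
  m <- rbind(A = c(9, 9, 9, 10, 0, 0),
             B = c(10, 0, 0, 9, 9, 9))
  colnames(m) <- d$sample_id
  fr <- filter_triplicate_max_copies(otu_table(m), d, min_copies = 10)
  post <- unclass(fr$table)
  # A fails in Sp01 (max 9 < 10) but passes in Sp02 (max 10 >= 10)
  expect_equal(unname(post["A", ]), c(0L, 0L, 0L, 10L, 0L, 0L))
  expect_equal(unname(post["B", ]), c(10L, 0L, 0L, 0L, 0L, 0L))

  bad <- replicate_design(c(S1 = "X", S2 = "X"))
  expect_error(
    filter_triplicate_max_copies(
      otu_table(matrix(1L, 1, 2, dimnames = list("A", c("S1", "S2")))), bad),
    "exactly 3")
})

test_that("triplicate intersection filter removes OTUs missing from any replicate", {
  d <- triplicate_design(1)
  tab <- otu_rows(list(A = c(1, 1, 1), B = c(5, 5, 0)))
  fr <- filter_triplicate_intersection(tab, d)
  expect_equal(rownames(fr$table), "A")
  expect_equal(unname(fr$reads_removed), c(5L, 5L, 0L))
})

test_that("all filters conserve reads and are idempotent", {
  withr::local_seed(31)
  d <- triplicate_design(3)
  for (i in 1:8) {
    tab <- random_triplicate_table(3, 25, max_count = 25, zero_prob = 0.5)
    base_totals <- total_reads(tab)$per_sample
    for (method in filter_methods()) {
      fr <- apply_filter(tab, method, design = d)
      post_totals <- total_reads(fr$table)$per_sample
      # read conservation per sample
      expect_equal(post_totals + fr$reads_removed, base_totals)
      # post-filter counts never exceed pre-filter counts
      pre <- unclass(tab)[rownames(fr$table), , drop = FALSE]
      expect_true(all(unclass(fr$table) <= pre))
      # idempotence
      fr2 <- apply_filter(fr$table, method, design = d)
      expect_identical(unclass(fr2$table), unclass(fr$table))
      expect_true(all(fr2$reads_removed == 0L))
    }
  }
})

test_that("the 10-copy sample filter removes at least as many reads as the singleton filter", {
  withr::local_seed(17)
  for (i in 1:10) {
    tab <- random_table(30, 6, max_count = 15, zero_prob = 0.3)
    r1 <- sum(filter_sample_singleton(tab)$reads_removed)
    r10 <- sum(filter_sample_min_copies(tab, 10)$reads_removed)
    expect_gte(r10, r1)
  }
})

test_that("dataset-scope removal implies triplicate-scope removal where the specimen max is below threshold", {
  withr::local_seed(23)
  d <- triplicate_design(3)
  for (i in 1:5) {
    tab <- random_triplicate_table(3, 20, max_count = 20, zero_prob = 0.5)
    m <- unclass(tab)
    removed_ds <- setdiff(rownames(m),
                          rownames(filter_dataset_max_copies(tab, 10)$table))
    post_tri <- filter_triplicate_max_copies(tab, d, 10)
    groups <- specimen_samples(d)
    for (otu in removed_ds) {
      for (sp in names(groups)) {
        cols <- groups[[sp]]
        if (max(m[otu, cols]) < 10) {
          # brute-force expectation: zeroed in this specimen too
          post <- unclass(post_tri$table)
          vals <- if (otu %in% rownames(post)) post[otu, cols] else rep(0L, 3)
          expect_true(all(vals == 0L))
        }
      }
    }
  }
})
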
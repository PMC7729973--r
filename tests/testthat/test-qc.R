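test_that("length filter is strict at the boundary and preserves order", {
  m <- matrix(1:9, 3, 3,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  tab <- sv_table(m, c(a = 374L, b = 375L, c = 400L))
  res <- filter_by_length(tab, min_len = 375)
  expect_equal(colnames(res$table$counts), c("b", "c"))  # 374 gone, 375 kept
  expect_equal(res$report$n_sv_in, 3L)
  expect_equal(res$report$n_sv_out, 2L)
  expect_equal(res$report$removed$id, "a")

  # min_len = 0 is the identity
  expect_equal(filter_by_length(tab, 0)$table$counts, tab$counts)
})

test_that("depth and support thresholds are strict ('fewer than')", {
  m <- rbind(s1 = c(1000, 999, 0), s2 = c(1000, 999, 1),
             s3 = c(4000, 999, 1))
  colnames(m) <- c("a", "b", "c")
  tab <- sv_table(m, c(a = 400L, b = 400L, c = 400L))
  res <- filter_low_support(tab, min_sample_reads = 2000, min_sv_reads = 10)
  # s1 has 1999 reads -> removed; s2 exactly 2000 -> retained
  expect_setequal(rownames(res$table$counts), c("s2", "s3"))
  # SV c has 2 reads on survivors -> removed; b has 1998 -> retained
  expect_setequal(colnames(res$table$counts), c("a", "b"))

  # an SV with exactly 10 reads is retained, 9 is removed
  m2 <- rbind(s1 = c(3000, 10, 9))
  colnames(m2) <- c("a", "b", "c")
  tab2 <- sv_table(m2, c(a = 400L, b = 400L, c = 400L))
  res2 <- filter_low_support(tab2)
  expect_setequal(colnames(res2$table$counts), c("a", "b"))
})

test_that("samples are filtered before SVs (order is load-bearing)", {
  # SV 'b' has 10 reads in total but only 9 once the shallow sample is gone;
  # brute-force comparison of both orders shows they disagree, and the
  # implementation must match the sample-first result
  m <- rbind(s1 = c(1000, 1, 500), s2 = c(3000, 5, 0), s3 = c(4000, 4, 0))
  colnames(m) <- c("a", "b", "c")
  tab <- sv_table(m, c(a = 400L, b = 400L, c = 400L))

  # oracle, order 1: samples first then SVs
  keep_s <- rownames(m)[rowSums(m) >= 2000]
  m1 <- m[keep_s, , drop = FALSE]
  keep_sv1 <- colnames(m1)[colSums(m1) >= 10]
  # oracle, order 2: SVs first then samples
  keep_sv2 <- colnames(m)[colSums(m) >= 10]
  expect_false(setequal(keep_sv1, keep_sv2))  # the orders genuinely differ

  res <- filter_low_support(tab)
  expect_setequal(colnames(res$table$counts), keep_sv1)
  expect_false("b" %in% colnames(res$table$counts))
})

test_that("control rules remove exactly the constructed contaminants", {
  fx <- make_qc_fixture()
  chain <- qc_chain(fx$table, fx$metadata, fx$tax)
  got <- chain$table

  # rule (a): spill-in SVs of a non-mock genus seen in the positive control
  expect_false(any(fx$spill_ids %in% colnames(got$counts)))
  # rule (b): SVs prevalent and enriched in negative controls
  expect_false(any(fx$cont_ids %in% colnames(got$counts)))
  # short SVs and shallow samples are gone
  expect_false(any(fx$short_ids %in% colnames(got$counts)))
  expect_false(any(fx$shallow %in% rownames(got$counts)))
  # mock-genus SVs were NOT removed by the positive-control rule
  rm_a <- chain$report$removed
  rm_a <- rm_a$id[rm_a$rule == "positive_control_non_mock"]
  expect_setequal(rm_a, fx$spill_ids)
  rm_b <- chain$report$removed
  expect_setequal(rm_b$id[rm_b$rule == "negative_control_prevalent"],
                  fx$cont_ids)

  # explicit rule calls error without the required controls
  no_ctrl <- fx$metadata[fx$metadata$role == "specimen", ]
  expect_error(control_filter(fx$table, no_ctrl, tax = fx$tax),
               "no positive_control")
})

test_that("the QC chain is idempotent and its accounting balances", {
  fx <- make_qc_fixture()
  once <- qc_chain(fx$table, fx$metadata, fx$tax)
  twice <- qc_chain(once$table, fx$metadata, fx$tax)
  expect_equal(twice$table$counts, once$table$counts)
  expect_equal(nrow(twice$report$removed), 0L)

  rep1 <- once$report
  rm_sv <- sum(rep1$removed$entity == "sv")
  rm_s <- sum(rep1$removed$entity == "sample")
  expect_equal(rep1$n_sv_out + rm_sv, rep1$n_sv_in)
  expect_equal(rep1$n_samples_out + rm_s, rep1$n_samples_in)
  expect_equal(rep1$reads_removed_pct,
               100 * (sum(fx$table$counts) - sum(once$table$counts)) /
                 sum(fx$table$counts))
})

test_that("depth summary uses exact integer arithmetic", {
  m <- rbind(s1 = c(50, 50), s2 = c(100, 100), s3 = c(300, 300))
  colnames(m) <- c("a", "b")
  tab <- sv_table(m, c(a = 400L, b = 400L))
  ds <- depth_summary(tab)
  expect_equal(ds, list(mean = 300, median = 200, min = 100, max = 600))

  one <- sv_table(m[1, , drop = FALSE], tab$sv_length)
  ds1 <- depth_summary(one)
  expect_true(all(unlist(ds1) == 100))

  # permutation invariance
  perm <- sv_table(m[c(3, 1, 2), ], tab$sv_length)
  expect_equal(depth_summary(perm), ds)
})
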
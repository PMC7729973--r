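test_that("the dominance rule fires only strictly past both thresholds", {
  # clear dominance in LF
  q <- quarters_with_family_shares(c(LF = 0.70, LR = 0.05, RF = 0.05,
                                     RR = 0.10))
  res <- call_dysbiotic_quarters(make_quarter_set(q))
  expect_true(res$evaluated)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$quarter, "LF")
  expect_equal(res$calls$family, "Staphylococcaceae")
  expect_equal(res$calls$dominant_fraction, 0.70)
  expect_equal(res$calls$max_other_fraction, 0.10)
  expect_equal(res$calls$n_quarters_evaluated, 4L)

  # exactly 60% dominant: no call (strict >)
  q2 <- quarters_with_family_shares(c(LF = 0.60, LR = 0.05, RF = 0.05,
                                      RR = 0.05))
  expect_equal(nrow(call_dysbiotic_quarters(make_quarter_set(q2))$calls), 0L)

  # one sibling at exactly 20%: no call (strict <)
  q3 <- quarters_with_family_shares(c(LF = 0.70, LR = 0.20, RF = 0.05,
                                      RR = 0.05))
  expect_equal(nrow(call_dysbiotic_quarters(make_quarter_set(q3))$calls), 0L)

  # a second elevated quarter blocks the call for that family
  q4 <- quarters_with_family_shares(c(LF = 0.70, LR = 0.65, RF = 0.02))
  expect_equal(nrow(call_dysbiotic_quarters(make_quarter_set(q4))$calls), 0L)
})

test_that("fewer than 3 quarters means 'not evaluated', not 'no call'", {
  q <- quarters_with_family_shares(c(LF = 0.70, RR = 0.05))
  res <- call_dysbiotic_quarters(make_quarter_set(q))
  expect_false(res$evaluated)
  expect_equal(nrow(res$calls), 0L)
  # 3 quarters are evaluated
  q3 <- quarters_with_family_shares(c(LF = 0.70, LR = 0.05, RR = 0.05))
  res3 <- call_dysbiotic_quarters(make_quarter_set(q3))
  expect_true(res3$evaluated)
  expect_equal(res3$calls$n_quarters_evaluated, 3L)
})

test_that("invalid proportion vectors are rejected", {
  q <- quarters_with_family_shares(c(LF = 0.70, LR = 0.05, RF = 0.05))
  q[1, 1] <- q[1, 1] + 0.1
  expect_error(call_dysbiotic_quarters(make_quarter_set(q)),
               "sum to 1")
})

test_that("multiple families can each produce a call in one cow-period", {
  # family A dominates LF, family B dominates RR
  m <- matrix(c(
    0.70, 0.10, 0.20,
    0.10, 0.15, 0.75,
    0.10, 0.72, 0.18), 3, 3, byrow = TRUE,
    dimnames = list(c("LF", "LR", "RF"),
                    c("Staphylococcaceae", "Corynebacteriaceae",
                      "Streptococcaceae")))
  res <- call_dysbiotic_quarters(make_quarter_set(m))
  expect_equal(nrow(res$calls), 2L)
  expect_setequal(res$calls$family,
                  c("Staphylococcaceae", "Corynebacteriaceae"))
})

test_that("calling is invariant to SV-level representation", {
  set.seed(17)
  d <- generate_dataset(small_config(seed = 17))
  md <- d$metadata[d$metadata$role == "specimen", ]
  fam <- aggregate_to_family(d$table, d$taxonomy)
  relab_after <- relative_abundance(fam[md$sample_id, ])

  # family shares computed directly from SV counts without aggregation
  tax_fam <- setNames(d$taxonomy$family, d$taxonomy$sv_id)
  m <- d$table$counts[md$sample_id, !is.na(tax_fam[colnames(d$table$counts)])]
  fams <- tax_fam[colnames(m)]
  manual <- sapply(sort(unique(fams)), function(f)
    rowSums(m[, fams == f, drop = FALSE]))
  relab_before <- relative_abundance(manual)

  c1 <- call_dysbiosis(relab_after, md)$calls
  c2 <- call_dysbiosis(relab_before[, colnames(relab_after)], md)$calls
  expect_equal(c1, c2)
})

test_that("dysbiosis summary counts conserve and split by family", {
  d <- generate_dataset(small_config(seed = 18))
  md <- d$metadata[d$metadata$role == "specimen", ]
  relab <- relative_abundance(
    aggregate_to_family(d$table, d$taxonomy)[md$sample_id, ])
  res <- call_dysbiosis(relab, md)
  s <- dysbiosis_summary(res)
  expect_equal(sum(s$per_family), s$n_dysbiotic)
  expect_equal(s$n_dysbiotic, nrow(res$calls))
  cp <- unique(paste(md$cow_id, md$period))
  expect_equal(res$n_evaluated + res$n_not_evaluated, length(cp))
})
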
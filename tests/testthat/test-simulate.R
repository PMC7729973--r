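test_that("generator is deterministic given a seed, distinct across seeds", {
  d1 <- generate_dataset(small_config(seed = 7))
  d2 <- generate_dataset(small_config(seed = 7))
  expect_identical(d1$table$counts, d2$table$counts)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$isolates, d2$isolates)

  d3 <- generate_dataset(small_config(seed = 8))
  expect_false(identical(d1$table$counts, d3$table$counts))
})

test_that("config invariants are checked before sampling", {
  expect_error(generator_config(dominant_range = c(0.55, 0.9)),
               "exceed 0.60")
  expect_error(generator_config(sibling_cap = 0.25), "below 0.20")
  expect_error(generator_config(core_coupling = 0.3), "<= 0")
  expect_error(generator_config(dysbiosis_rate = 1.5), "probabilities")
  bad_base <- default_family_baseline()
  bad_base[, 1] <- bad_base[, 1] * 3
  expect_error(generator_config(family_baseline = bad_base), "<= 1")
})

test_that("dysbiosis_rate = 0 yields an empty truth log", {
  d <- generate_dataset(small_config(seed = 9, dysbiosis_rate = 0))
  expect_equal(nrow(d$truth$dysbiosis_events), 0L)
})

test_that("inject_dysbiosis renormalizes rows and clamps siblings", {
  q <- matrix(c(0.30, 0.50, 0.20,
                0.25, 0.55, 0.20,
                0.40, 0.40, 0.20,
                0.10, 0.70, 0.20), 4, 3, byrow = TRUE,
              dimnames = list(c("LF", "LR", "RF", "RR"),
                              c("Staphylococcaceae", "Corynebacteriaceae",
                                "Aerococcaceae")))
  out <- inject_dysbiosis(q, "LF", "Staphylococcaceae", 0.70,
                          sibling_cap = 0.15)
  expect_equal(rowSums(out), rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(out["LF", "Staphylococcaceae"], 0.70)
  expect_true(all(out[c("LR", "RF", "RR"), "Staphylococcaceae"] <= 0.15))
  # untouched sibling ratios preserved
  expect_equal(out["LR", "Corynebacteriaceae"] / out["LR", "Aerococcaceae"],
               q["LR", "Corynebacteriaceae"] / q["LR", "Aerococcaceae"])

  # boundary-inside: injection at 0.61 with cap 0.19 still satisfies the rule
  out2 <- inject_dysbiosis(q, "LF", "Staphylococcaceae", 0.61,
                           sibling_cap = 0.19)
  qs <- make_quarter_set(out2)
  calls <- call_dysbiotic_quarters(qs)$calls
  expect_equal(calls$quarter, "LF")

  expect_error(inject_dysbiosis(q, "LF", "Staphylococcaceae", 0.55),
               "exceed 0.60")
  one_fam <- matrix(1, 3, 1, dimnames = list(c("LF", "LR", "RF"), "OnlyFam"))
  expect_error(inject_dysbiosis(one_fam, "LF", "OnlyFam", 0.7),
               "no mass outside")
})

test_that("every truth event satisfies the caller's rule on emitted counts", {
  d <- generate_dataset(small_config(seed = 10))
  fam <- aggregate_to_family(d$table, d$taxonomy)
  md <- d$metadata[d$metadata$role == "specimen", ]
  relab <- relative_abundance(fam[md$sample_id, ])
  res <- call_dysbiosis(relab, md)
  ev <- d$truth$dysbiosis_events
  expect_gt(nrow(ev), 0)
  key <- paste(res$calls$cow_id, res$calls$period, res$calls$quarter,
               res$calls$family)
  expect_true(all(paste(ev$cow_id, ev$period, ev$quarter, ev$family) %in%
                    key))
})

test_that("controls carry contaminants and mock plus spill-in only", {
  d <- generate_dataset(small_config(seed = 12))
  md <- d$metadata
  neg <- md$sample_id[md$role == "negative_control"]
  pos <- md$sample_id[md$role == "positive_control"]
  negm <- d$table$counts[neg, , drop = FALSE]
  expect_true(all(colnames(negm)[colSums(negm) > 0] %in%
                    d$truth$contaminant_svs))
  posm <- d$table$counts[pos, , drop = FALSE]
  pos_sv <- colnames(posm)[colSums(posm) > 0]
  mock_sv <- grep("^SV_M", colnames(posm), value = TRUE)
  expect_true(all(pos_sv %in% c(mock_sv, d$truth$pos_spill_svs)))
  # mock SVs dominate the positive control
  expect_gt(sum(posm[, mock_sv]) / sum(posm), 0.9)
})

test_that("generated depths follow the configured distribution", {
  d <- generate_dataset(generator_config(n_cows_per_farm = 20, seed = 13))
  md <- d$metadata[d$metadata$role == "specimen", ]
  dep <- sample_depths(d$table)[md$sample_id]
  # median within 20% of the ~5988-read target (dysbiotic boosts shift it
  # only slightly)
  expect_lt(abs(median(dep) - 5988) / 5988, 0.2)
})

test_that("colony truth: dysbiotic quarters are always culture-infected", {
  d <- generate_dataset(small_config(seed = 14))
  imi <- classify_imi(d$colony, sample_ids = d$truth$infected_samples)
  known <- imi$status[imi$status != "unknown"]
  expect_true(all(known == "infected"))
  ev <- d$truth$dysbiosis_events
  expect_true(all(ev$sample_id %in% d$truth$infected_samples))
})
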
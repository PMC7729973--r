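make_profile_fixture <- function() {
  # 8 specimens over 2 farms x 2 cows x 2 quarters, 4 SVs in 3 families;
  # sv4 (familyless) exercises the aggregation drop
  ids <- sprintf("q%d", 1:8)
  m <- matrix(10, 8, 4, dimnames = list(ids, c("sv1", "sv2", "sv3", "sv4")))
  m[, "sv2"] <- c(5, 5, 5, 5, 0, 0, 0, 0)   # Streptococcaceae absent on K
  m[1, "sv3"] <- 0                          # Corynebacteriaceae 7/8 samples
  tab <- sv_table(m, c(sv1 = 400L, sv2 = 400L, sv3 = 400L, sv4 = 400L))
  md <- sample_metadata(data.frame(
    sample_id = ids,
    cow_id = rep(c("c1", "c2", "c3", "c4"), each = 2),
    farm = rep(c("A", "K"), each = 4),
    quarter = rep(c("LF", "LR"), 4),
    period = 1L,
    role = "specimen", stringsAsFactors = FALSE))
  list(table = tab, tax = make_tax_fixture(), md = md)
}

test_that("family profiles report prevalence and read shares correctly", {
  fx <- make_profile_fixture()
  prof <- family_profiles(fx$table, fx$tax, fx$md, min_pct = 0.5)

  staph <- prof[prof$family == "Staphylococcaceae", ]
  # present in every sample of both farms and every cow
  expect_equal(staph$pct_quarters_farm_A, 100)
  expect_equal(staph$pct_quarters_farm_K, 100)
  expect_equal(staph$pct_cows_any, 100)
  expect_equal(staph$pct_cows_all_periods, 100)

  strep <- prof[prof$family == "Streptococcaceae", ]
  expect_equal(strep$pct_quarters_farm_A, 100)
  expect_equal(strep$pct_quarters_farm_K, 0)
  expect_equal(strep$pct_cows_any, 50)

  cory <- prof[prof$family == "Corynebacteriaceae", ]
  expect_equal(cory$pct_quarters_farm_A, 75)  # 3 of 4 farm-A samples

  # read shares: computed over family-assigned reads only, sum to 100
  expect_equal(sum(prof$pct_reads_total), 100)
  # per-farm mean relative abundances lie in [0, 100]
  mean_cols <- grep("^mean_pct_reads", names(prof), value = TRUE)
  expect_true(all(prof[, mean_cols] >= 0 & prof[, mean_cols] <= 100))
})

test_that("profiles pool sub-threshold families into 'other'", {
  fx <- make_profile_fixture()
  # Streptococcaceae carries 20/180 of family-assigned reads (~11%); raise
  # the bar above it
  prof <- family_profiles(fx$table, fx$tax, fx$md, min_pct = 20)
  expect_true("other" %in% prof$family)
  expect_false("Streptococcaceae" %in% prof$family)
  expect_equal(sum(prof$pct_reads_total), 100)  # 'other' absorbs remainder
  expect_equal(prof$n_sv[prof$family == "other"], 1L)
})

test_that("profiles are invariant to sample order", {
  fx <- make_profile_fixture()
  p1 <- family_profiles(fx$table, fx$tax, fx$md)
  perm <- sample(rownames(fx$table$counts))
  tab2 <- sv_table(fx$table$counts[perm, ], fx$table$sv_length)
  p2 <- family_profiles(tab2, fx$tax, fx$md)
  expect_equal(p1, p2)
})

test_that("the stricter cow-prevalence variant requires every period", {
  ids <- sprintf("q%d", 1:4)
  m <- matrix(c(10, 10, 10, 10,
                10, 0, 10, 10), 4, 2,
              dimnames = list(ids, c("sv1", "sv3")))
  tab <- sv_table(m, c(sv1 = 400L, sv3 = 400L))
  md <- sample_metadata(data.frame(
    sample_id = ids, cow_id = "c1", farm = "A",
    quarter = c("LF", "LF", "LR", "LR"),
    period = c(1L, 2L, 1L, 2L), role = "specimen",
    stringsAsFactors = FALSE))
  prof <- family_profiles(tab, make_tax_fixture(), md, min_pct = 0)
  cory <- prof[prof$family == "Corynebacteriaceae", ]
  # detected in period 1 (q1) and period 2 (q4): both variants positive
  expect_equal(cory$pct_cows_any, 100)
  expect_equal(cory$pct_cows_all_periods, 100)

  m2 <- m; m2[c(2, 4), "sv3"] <- 0  # absent in period 2 entirely
  tab2 <- sv_table(m2, tab$sv_length)
  prof2 <- family_profiles(tab2, make_tax_fixture(), md, min_pct = 0)
  cory2 <- prof2[prof2$family == "Corynebacteriaceae", ]
  expect_equal(cory2$pct_cows_any, 100)
  expect_equal(cory2$pct_cows_all_periods, 0)
})
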
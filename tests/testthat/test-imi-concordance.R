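test_that("infection classification applies the >10-colonies rule", {
  cr <- colony_records(data.frame(
    sample_id = c("s1", "s1", "s2", "s2", "s3"),
    condition = c("aerobic", "anaerobic", "aerobic", "anaerobic",
                  "aerobic"),
    colony_class = c("c1_lt10", "c1_lt10", "zero", "gt1000", "c10_lt100"),
    stringsAsFactors = FALSE))
  imi <- classify_imi(cr, sample_ids = c("s1", "s2", "s3", "s4"))
  st <- setNames(imi$status, imi$sample_id)
  expect_equal(unname(st["s1"]), "not_infected")  # both below threshold
  expect_equal(unname(st["s2"]), "infected")      # one condition suffices
  expect_equal(unname(st["s3"]), "infected")      # boundary class infects
  expect_equal(unname(st["s4"]), "unknown")       # no colony data
  expect_equal(imi$triggering[imi$sample_id == "s2"], "anaerobic")
})

test_that("infection status is monotone in colony class", {
  classes <- c("zero", "c1_lt10", "c10_lt100", "c100_lt1000", "gt1000")
  status_rank <- function(cls) {
    cr <- colony_records(data.frame(sample_id = "s", condition = "aerobic",
                                    colony_class = cls,
                                    stringsAsFactors = FALSE))
    classify_imi(cr)$status == "infected"
  }
  inf <- vapply(classes, status_rank, logical(1))
  # once infected, raising the class never flips back
  expect_false(is.unsorted(inf))
  expect_equal(unname(inf), c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("microbiota-infection association behaves under null and signal", {
  set.seed(19)
  # null: infection independent of composition
  m <- matrix(rpois(20 * 12, 8) + 1, 20, 12,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:12)))
  d <- distance_matrix(m, "bray")
  imi <- data.frame(sample_id = rownames(m),
                    status = rep(c("infected", "not_infected"), 10),
                    stringsAsFactors = FALSE)
  res <- imi_microbiota_association(d, imi, n_perm = 199, seed = 20)
  expect_gt(res$p_value, 0.05)

  # signal: infected samples drawn from a shifted composition
  m2 <- m
  m2[1:10, 1:3] <- m2[1:10, 1:3] + 60
  d2 <- distance_matrix(m2, "bray")
  imi2 <- data.frame(sample_id = rownames(m2),
                     status = rep(c("infected", "not_infected"), each = 10),
                     stringsAsFactors = FALSE)
  res2 <- imi_microbiota_association(d2, imi2, n_perm = 199, seed = 20)
  expect_lt(res2$p_value, 0.05)

  # one-label grouping errors
  imi3 <- imi; imi3$status <- "infected"
  expect_error(imi_microbiota_association(d, imi3), "both infected")
})

test_that("concordance matches called families against isolate families", {
  md <- sample_metadata(data.frame(
    sample_id = c("s_rr", "s_lf", "s_rf"),
    cow_id = c("34", "11", "41"), farm = "A",
    quarter = c("RR", "LF", "RF"), period = 1L, role = "specimen",
    stringsAsFactors = FALSE))
  calls <- data.frame(
    cow_id = c("34", "11", "41"), period = 1L,
    quarter = c("RR", "LF", "RF"),
    family = c("Streptococcaceae", "Enterococcaceae", "Pseudonocardiaceae"),
    dominant_fraction = 0.8, max_other_fraction = 0.05,
    n_quarters_evaluated = 4L, stringsAsFactors = FALSE)
  isolates <- isolate_records(data.frame(
    sample_id = c("s_rr", "s_rr", "s_lf"),
    medium = "TSA_blood_aerobic",
    species = c("Aerococcus viridans", "Streptococcus uberis",
                "Enterococcus gallinarum"),
    score = 2.3, stringsAsFactors = FALSE))
  res <- concordance(calls, isolates, md)
  rec <- res$records
  expect_true(rec$concordant[rec$cow_id == "34"])   # Strep. uberis in RR
  expect_true(rec$concordant[rec$cow_id == "11"])   # E. gallinarum in LF
  expect_false(rec$concordant[rec$cow_id == "41"])  # nothing cultured
  expect_equal(rec$note[rec$cow_id == "41"], "no isolates")
  expect_equal(res$rate, 2 / 3)
})

test_that("unmapped isolate genera are reported, not fatal", {
  md <- sample_metadata(data.frame(
    sample_id = "s1", cow_id = "c1", farm = "A", quarter = "LF",
    period = 1L, role = "specimen", stringsAsFactors = FALSE))
  calls <- data.frame(cow_id = "c1", period = 1L, quarter = "LF",
                      family = "Staphylococcaceae",
                      dominant_fraction = 0.7, max_other_fraction = 0.1,
                      n_quarters_evaluated = 4L, stringsAsFactors = FALSE)
  isolates <- isolate_records(data.frame(
    sample_id = "s1", medium = "M17", species = "Exiguobacterium aurantiacum",
    score = 2.2, stringsAsFactors = FALSE))
  res <- concordance(calls, isolates, md)
  expect_equal(res$unmapped_genera, "Exiguobacterium")
  expect_false(res$records$concordant)
})
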
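# small programmatic fixtures shared across test files

make_sv_fixture <- function() {
  m <- matrix(c(5, 0, 2, 7,
                1, 3, 0, 9,
                0, 4, 6, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("sv1", "sv2", "sv3", "sv4")))
  sv_table(m, c(sv1 = 400L, sv2 = 380L, sv3 = 390L, sv4 = 410L))
}

make_tax_fixture <- function() {
  taxonomy_table(data.frame(
    sv_id = c("sv1", "sv2", "sv3", "sv4"),
    domain = "Bacteria",
    phylum = c("Firmicutes", "Firmicutes", "Actinobacteriota", "Firmicutes"),
    class = c("Bacilli", "Bacilli", "Actinobacteria", "Clostridia"),
    order = c("Staphylococcales", "Lactobacillales", "Corynebacteriales",
              "Clostridiales"),
    family = c("Staphylococcaceae", "Streptococcaceae", "Corynebacteriaceae",
               NA),
    genus = c("Staphylococcus", "Streptococcus", "Corynebacterium", NA),
    stringsAsFactors = FALSE))
}

# quarters x families proportion matrix builder
make_quarter_set <- function(shares, cow = "C1", period = 1L) {
  structure(list(cow_id = cow, period = period, quarters = shares,
                 sample_ids = stats::setNames(
                   paste(cow, period, rownames(shares), sep = "_"),
                   rownames(shares))),
            class = "quarter_set")
}

# shares for family F across quarters; remaining mass split over two filler
# families so every row sums to 1
quarters_with_family_shares <- function(f_shares,
                                        family = "Staphylococcaceae") {
  q <- names(f_shares)
  m <- cbind(f_shares, (1 - f_shares) * 0.6, (1 - f_shares) * 0.4)
  dimnames(m) <- list(q, c(family, "Corynebacteriaceae", "Aerococcaceae"))
  m
}

# deterministic 50-specimen QC fixture with known contaminants:
# 60 SVs incl. 3 short, 4 contaminant-only-in-negatives, 3 mock-spill,
# 2 shallow samples, plus 2 negative and 1 positive control
make_qc_fixture <- function(seed = 42) {
  set.seed(seed)
  n_spec <- 50
  fams <- c("Staphylococcaceae", "Corynebacteriaceae", "Streptococcaceae")
  genera <- c(Staphylococcaceae = "Staphylococcus",
              Corynebacteriaceae = "Corynebacterium",
              Streptococcaceae = "Streptococcus")
  core_ids <- sprintf("SV_%02d", 1:50)
  core_fam <- rep(fams, length.out = 50)
  short_ids <- c("SHORT_1", "SHORT_2", "SHORT_3")
  cont_ids <- c("CONT_1", "CONT_2", "CONT_3", "CONT_4")
  spill_ids <- c("SPILL_1", "SPILL_2", "SPILL_3")
  ids <- c(core_ids, short_ids, cont_ids, spill_ids)
  spec_ids <- sprintf("SP%02d", seq_len(n_spec))
  m <- matrix(0, n_spec + 3, length(ids),
              dimnames = list(c(spec_ids, "NEG1", "NEG2", "POS1"), ids))
  for (i in seq_len(n_spec)) {
    depth <- if (i <= 2) 1500 else sample(3000:9000, 1)
    pr <- c(rgamma(50, 2), rep(0.02, 3), rep(0.02, 4), rgamma(3, 0.5))
    m[i, ] <- rmultinom(1, depth, pr)[, 1]
  }
  m["NEG1", cont_ids] <- c(120, 80, 60, 40)
  m["NEG2", cont_ids] <- c(90, 70, 50, 30)
  m["POS1", ] <- 0
  mock_sv <- core_ids[core_fam == "Staphylococcaceae"][1:5]
  m["POS1", mock_sv] <- 2000
  m["POS1", spill_ids] <- c(50, 40, 30)
  lengths <- stats::setNames(rep(400L, length(ids)), ids)
  lengths[short_ids] <- c(374L, 300L, 220L)
  tab <- sv_table(m, lengths)
  tax <- taxonomy_table(data.frame(
    sv_id = ids, domain = "Bacteria", phylum = "Firmicutes",
    class = "Bacilli", order = "Bacillales",
    family = c(core_fam, rep(NA, 3), rep("Pseudomonadaceae", 4),
               rep("Prevotellaceae", 3)),
    genus = c(genera[core_fam], rep(NA, 3), rep("Pseudomonas", 4),
              rep("Prevotella", 3)),
    stringsAsFactors = FALSE))
  md <- sample_metadata(data.frame(
    sample_id = c(spec_ids, "NEG1", "NEG2", "POS1"),
    cow_id = c(paste0("C", rep(1:13, each = 4))[seq_len(n_spec)],
               NA, NA, NA),
    farm = c(rep(c("A", "K"), length.out = n_spec), NA, NA, NA),
    quarter = c(rep(c("LF", "LR", "RF", "RR"), length.out = n_spec),
                NA, NA, NA),
    period = c(rep(1L, n_spec), NA, NA, NA),
    role = c(rep("specimen", n_spec), "negative_control",
             "negative_control", "positive_control"),
    stringsAsFactors = FALSE))
  list(table = tab, tax = tax, metadata = md,
       short_ids = short_ids, cont_ids = cont_ids, spill_ids = spill_ids,
       shallow = spec_ids[1:2])
}

# small generator config for fast module tests
small_config <- function(seed = 11, ...) {
  generator_config(n_cows_per_farm = 8, seed = seed, ...)
}
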
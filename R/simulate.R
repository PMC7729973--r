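#' Synthetic quarter-milk microbiota generator
#'
#' Generates cow/quarter-structured SV datasets with known ground truth so
#' every downstream stage of the pipeline can be exercised offline. Family
#' compositions follow a logistic-normal model with farm-specific means, a
#' shared cow random effect, an independent quarter effect and a negative
#' latent coupling between the two core families (Corynebacteriaceae and
#' Staphylococcaceae); family mass is split over SVs by a Dirichlet draw and
#' counts are multinomial at log-normal per-sample depth. Dysbiosis events
#' are injected post-hoc by renormalization (so truth is unambiguous and
#' margin-controlled), negative controls carry only contaminant SVs,
#' positive controls carry the mock community plus a controlled spill-in,
#' and colony counts / isolates are generated consistently with the injected
#' truth.
#'
#' @name synthetic_data
NULL

#' Default per-farm family baseline (mean relative abundances)
#'
#' The named-family means for farms A and K; per-farm columns sum to < 1 and
#' the remainder is assigned by the generator to a rare-tail pool (minor
#' families, trace contaminants and family-unassigned SVs).
#'
#' @return families x farms (A, K) numeric matrix of proportions.
#' @export
default_family_baseline <- function() {
  fam <- c(Corynebacteriaceae   = NA, Staphylococcaceae    = NA,
           Aerococcaceae        = NA, Ruminococcaceae      = NA,
           Peptostreptococcaceae = NA, Streptococcaceae    = NA,
           Micrococcaceae       = NA, Lachnospiraceae      = NA,
           Moraxellaceae        = NA, Leuconostocaceae     = NA,
           Carnobacteriaceae    = NA, Burkholderiaceae     = NA,
           Enterococcaceae      = NA, Pseudonocardiaceae   = NA)
  a <- c(0.383, 0.131, 0.052, 0.060, 0.025, 0.023, 0.020, 0.027,
         0.010, 0.004, 0.029, 0.013, 0.013, 0.010)
  k <- c(0.311, 0.185, 0.092, 0.034, 0.037, 0.029, 0.031, 0.023,
         0.031, 0.036, 0.008, 0.017, 0.015, 0.001)
  m <- cbind(A = a, K = k)
  rownames(m) <- names(fam)
  m
}

# lineage (phylum, class, order) and representative genus per family
fam_lineage <- function() {
  rbind_list <- function(...) do.call(rbind, list(...))
  m <- rbind_list(
    c("Corynebacteriaceae", "Actinobacteriota", "Actinobacteria", "Corynebacteriales", "Corynebacterium"),
    c("Staphylococcaceae", "Firmicutes", "Bacilli", "Staphylococcales", "Staphylococcus"),
    c("Aerococcaceae", "Firmicutes", "Bacilli", "Lactobacillales", "Aerococcus"),
    c("Ruminococcaceae", "Firmicutes", "Clostridia", "Oscillospirales", "Ruminococcus"),
    c("Peptostreptococcaceae", "Firmicutes", "Clostridia", "Peptostreptococcales", "Peptostreptococcus"),
    c("Streptococcaceae", "Firmicutes", "Bacilli", "Lactobacillales", "Streptococcus"),
    c("Micrococcaceae", "Actinobacteriota", "Actinobacteria", "Micrococcales", "Micrococcus"),
    c("Lachnospiraceae", "Firmicutes", "Clostridia", "Lachnospirales", "Blautia"),
    c("Moraxellaceae", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Acinetobacter"),
    c("Leuconostocaceae", "Firmicutes", "Bacilli", "Lactobacillales", "Leuconostoc"),
    c("Carnobacteriaceae", "Firmicutes", "Bacilli", "Lactobacillales", "Carnobacterium"),
    c("Burkholderiaceae", "Proteobacteria", "Gammaproteobacteria", "Burkholderiales", "Burkholderia"),
    c("Enterococcaceae", "Firmicutes", "Bacilli", "Lactobacillales", "Enterococcus"),
    c("Pseudonocardiaceae", "Actinobacteriota", "Actinobacteria", "Pseudonocardiales", "Saccharopolyspora"),
    c("Bacillaceae", "Firmicutes", "Bacilli", "Bacillales", "Bacillus"),
    c("Lactobacillaceae", "Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillus"),
    c("Prevotellaceae", "Bacteroidota", "Bacteroidia", "Bacteroidales", "Prevotella"),
    c("Pseudomonadaceae", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonas"),
    c("Xanthomonadaceae", "Proteobacteria", "Gammaproteobacteria", "Xanthomonadales", "Stenotrophomonas"),
    c("Sphingomonadaceae", "Proteobacteria", "Alphaproteobacteria", "Sphingomonadales", "Sphingomonas"),
    c("Actinomycetaceae", "Actinobacteriota", "Actinobacteria", "Actinomycetales", "Actinomyces"),
    c("Bacteroidaceae", "Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroides"),
    c("Bifidobacteriaceae", "Actinobacteriota", "Actinobacteria", "Bifidobacteriales", "Bifidobacterium"),
    c("Clostridiaceae", "Firmicutes", "Clostridia", "Clostridiales", "Clostridium"),
    c("Propionibacteriaceae", "Actinobacteriota", "Actinobacteria", "Propionibacteriales", "Cutibacterium"),
    c("Deinococcaceae", "Deinococcota", "Deinococci", "Deinococcales", "Deinococcus"),
    c("Enterobacteriaceae", "Proteobacteria", "Gammaproteobacteria", "Enterobacterales", "Escherichia"),
    c("Helicobacteraceae", "Campilobacterota", "Campylobacteria", "Campylobacterales", "Helicobacter"),
    c("Neisseriaceae", "Proteobacteria", "Gammaproteobacteria", "Burkholderiales", "Neisseria"),
    c("Porphyromonadaceae", "Bacteroidota", "Bacteroidia", "Bacteroidales", "Porphyromonas"),
    c("Rhodobacteraceae", "Proteobacteria", "Alphaproteobacteria", "Rhodobacterales", "Rhodobacter"))
  colnames(m) <- c("family", "phylum", "class", "order", "genus")
  as.data.frame(m, stringsAsFactors = FALSE)
}

# cultivable species per family, used when emitting isolates
family_species <- function() {
  list(
    Staphylococcaceae = c("Staphylococcus epidermidis",
                          "Staphylococcus chromogenes",
                          "Staphylococcus haemolyticus",
                          "Staphylococcus simulans",
                          "Staphylococcus xylosus"),
    Streptococcaceae = c("Streptococcus uberis", "Streptococcus dysgalactiae",
                         "Lactococcus lactis", "Lactococcus raffinolactis"),
    Enterococcaceae = c("Enterococcus faecalis", "Enterococcus gallinarum",
                        "Enterococcus malodoratus"),
    Aerococcaceae = "Aerococcus viridans",
    Corynebacteriaceae = c("Corynebacterium bovis",
                           "Corynebacterium amycolatum"),
    Micrococcaceae = "Micrococcus luteus",
    Moraxellaceae = "Acinetobacter lwoffii",
    Leuconostocaceae = "Leuconostoc mesenteroides",
    Carnobacteriaceae = "Carnobacterium divergens",
    Burkholderiaceae = "Burkholderia cepacia",
    Lactobacillaceae = "Lactobacillus plantarum",
    Bacillaceae = "Bacillus pumilus",
    Pseudonocardiaceae = "Saccharopolyspora rectivirgula",
    Pseudomonadaceae = "Pseudomonas aeruginosa")
}

#' Generator configuration
#'
#' All defaults encode the emulated study conditions: 30 cows per farm
#' sampled in 2 periods, Table-1-style family baselines per farm, depth
#' distribution with median about 6,000 and mean about 12,500 reads, a
#' dysbiosis event rate of 36/106 per cow-period with family weights
#' 20:5:4:7 (Staphylococcaceae : Streptococcaceae : Enterococcaceae :
#' other), injected dominant fractions in 0.65-0.95, and an overall
#' culture-infection rate near 42%. Invariants are checked before any
#' sampling.
#'
#' @param n_cows_per_farm cows per farm (farms are fixed to A and K).
#' @param n_periods sampling periods per cow.
#' @param family_baseline families x farms matrix of mean relative
#'   abundances; per-farm sums must be <= 1 (remainder goes to a rare-tail
#'   pool).
#' @param core_families the two negatively coupled core families (must be
#'   rows of `family_baseline`).
#' @param core_coupling log-scale covariance (<= 0) between the core
#'   families.
#' @param cow_effect_sd,quarter_effect_sd log-scale random-effect SDs.
#' @param depth_log_mean,depth_log_sd log-normal read-depth parameters
#'   (defaults: median ~5988, mean ~12549).
#' @param dysbiosis_rate probability of one injected dysbiosis event per
#'   cow-period.
#' @param dysbiosis_family_weights named weights for the injected family;
#'   the `other` entry is spread over the remaining non-core named families.
#' @param dominant_range range the injected dominant fraction is drawn from
#'   (low bound must exceed 0.60).
#' @param sibling_cap ceiling applied to the injected family's share in the
#'   event's sibling quarters (must be < 0.20).
#' @param n_sv_per_family SVs per named family.
#' @param contaminant_families families whose SVs populate negative controls.
#' @param n_contaminant_svs total contaminant SVs.
#' @param missing_quarter_rate probability a quarter sample is missing.
#' @param dysbiosis_depth_factor depth multiplier for dysbiotic samples
#'   (elevated bacterial load).
#' @param background_infection_rate culture-infection probability for
#'   non-dysbiotic quarters (dysbiotic quarters are always infected).
#' @param colony_missing_rate probability a specimen has no colony records.
#' @param n_neg_controls,n_pos_controls numbers of sequencing controls.
#' @param pos_spill_frac read fraction of non-mock spill-in SVs in positive
#'   controls.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return validated `generator_config` list.
#' @export
generator_config <- function(n_cows_per_farm = 30,
                             n_periods = 2,
                             family_baseline = default_family_baseline(),
                             core_families = c("Corynebacteriaceae",
                                               "Staphylococcaceae"),
                             core_coupling = -0.25,
                             cow_effect_sd = 0.45,
                             quarter_effect_sd = 0.35,
                             depth_log_mean = log(5988),
                             depth_log_sd = sqrt(2 * log(12549 / 5988)),
                             dysbiosis_rate = 36 / 106,
                             dysbiosis_family_weights =
                               c(Staphylococcaceae = 20,
                                 Streptococcaceae = 5,
                                 Enterococcaceae = 4,
                                 other = 7),
                             dominant_range = c(0.65, 0.95),
                             sibling_cap = 0.15,
                             n_sv_per_family = 8,
                             contaminant_families = c("Pseudomonadaceae",
                                                      "Xanthomonadaceae",
                                                      "Sphingomonadaceae"),
                             n_contaminant_svs = 6,
                             missing_quarter_rate = 0.06,
                             dysbiosis_depth_factor = 1,
                             background_infection_rate = 0.36,
                             colony_missing_rate = 0.02,
                             n_neg_controls = 4,
                             n_pos_controls = 2,
                             pos_spill_frac = 0.03,
                             seed = 1) {
  cfg <- as.list(environment())
  if (any(colSums(family_baseline) > 1))
    stop("family_baseline per-farm sums must be <= 1")
  if (any(family_baseline <= 0))
    stop("family_baseline entries must be strictly positive")
  if (!all(core_families %in% rownames(family_baseline)))
    stop("core_families must be rows of family_baseline")
  if (core_coupling > 0) stop("core_coupling must be <= 0")
  if (dominant_range[1] <= 0.60)
    stop("dominant_range low bound must exceed 0.60")
  if (dominant_range[2] > 1 || dominant_range[1] > dominant_range[2])
    stop("dominant_range must be an increasing pair within (0.60, 1]")
  if (sibling_cap >= 0.20) stop("sibling_cap must stay below 0.20")
  probs <- c(dysbiosis_rate, missing_quarter_rate,
             background_infection_rate, colony_missing_rate, pos_spill_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cow_effect_sd < 0 || quarter_effect_sd < 0)
    stop("random-effect SDs must be >= 0")
  structure(cfg, class = "generator_config")
}

#' Inject a dysbiosis event into a quarters x families proportion matrix
#'
#' Sets the target quarter's share of `family` to `fraction` (renormalizing
#' the quarter's other families to the remainder) and caps the same family at
#' `sibling_cap` in every other quarter, so the emitted event satisfies the
#' dysbiotic-quarter rule (> 0.60 dominant, < 0.20 elsewhere) by a margin.
#' Rows still sum to 1 after injection.
#'
#' @param qmat quarters x families proportion matrix (rows sum to 1).
#' @param quarter target quarter (rowname).
#' @param family target family (colname).
#' @param fraction injected dominant share (> 0.60).
#' @param sibling_cap ceiling on the family's share in sibling quarters
#'   (< 0.20).
#' @return modified matrix.
#' @export
inject_dysbiosis <- function(qmat, quarter, family, fraction,
                             sibling_cap = 0.15) {
  if (fraction <= 0.60) stop("injected fraction must exceed 0.60")
  if (sibling_cap >= 0.20) stop("sibling_cap must stay below 0.20")
  if (!quarter %in% rownames(qmat)) stop("quarter not present: ", quarter)
  if (!family %in% colnames(qmat)) stop("family not present: ", family)
  rescale_row <- function(row, fam, target) {
    names(row) <- colnames(qmat)  # dropped by extraction on 1-column input
    rest <- sum(row) - row[fam]
    if (rest <= 0)
      stop("cannot renormalize: no mass outside family ", fam)
    row[-match(fam, names(row))] <-
      row[-match(fam, names(row))] * (1 - target) / rest
    row[fam] <- target
    row
  }
  qmat[quarter, ] <- rescale_row(qmat[quarter, ], family, fraction)
  for (q in setdiff(rownames(qmat), quarter)) {
    if (qmat[q, family] > sibling_cap)
      qmat[q, ] <- rescale_row(qmat[q, ], family, sibling_cap)
  }
  qmat
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# The configured baselines are target MEAN relative abundances, but the mean
# of a logistic-normal is not the softmax of its location: the noise
# variance deflates dominant components. Fixed-point Monte Carlo correction
# of the location vector so that E[softmax(mu + noise)] matches the target.
calibrate_logmeans <- function(target, noise, n_iter = 6) {
  mu <- log(target)
  for (t in seq_len(n_iter)) {
    e <- exp(sweep(noise, 2L, mu, "+"))
    realized <- colMeans(e / rowSums(e))
    mu <- mu + log(target / realized)
  }
  mu
}

rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

#' Generate a complete synthetic dataset
#'
#' @param config a [generator_config].
#' @return list with `table` ([sv_table] including control samples),
#'   `taxonomy` ([taxonomy_table]), `metadata` ([sample_metadata]), `colony`
#'   ([colony_records]), `isolates` ([isolate_records]), `mock` (the
#'   mock-community reference) and `truth` (ground-truth log: dysbiosis
#'   events, infected samples, contaminant and spill-in SV ids, per-sample
#'   true depth).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  base <- config$family_baseline
  farms <- colnames(base)

  ## --- full composition: named families + rare tail + contaminants +
  ##     family-unassigned pool, per farm
  tail_fams <- setdiff(c("Bacillaceae", "Lactobacillaceae", "Prevotellaceae"),
                       rownames(base))
  cont_fams <- config$contaminant_families
  comp <- matrix(0, nrow(base) + length(tail_fams) + length(cont_fams) + 1L,
                 length(farms),
                 dimnames = list(c(rownames(base), tail_fams, cont_fams,
                                   "Unassigned"), farms))
  comp[rownames(base), ] <- base
  for (f in farms) {
    rem <- 1 - sum(base[, f])
    cont_mass <- min(0.003, rem / 4)
    unass_mass <- min(0.005, rem / 4)
    comp[cont_fams, f] <- cont_mass / length(cont_fams)
    comp["Unassigned", f] <- unass_mass
    tw <- c(0.5, 0.3, 0.2)[seq_along(tail_fams)]
    comp[tail_fams, f] <- (rem - cont_mass - unass_mass) * tw / sum(tw)
  }
  fam_names <- rownames(comp)

  ## --- SV pool
  n_sv_of <- stats::setNames(rep(config$n_sv_per_family, length(fam_names)),
                             fam_names)
  n_sv_of[tail_fams] <- 4L
  n_sv_of[cont_fams] <- pmax(1L, config$n_contaminant_svs %/% length(cont_fams))
  n_sv_of["Unassigned"] <- 4L
  sv_fam <- rep(fam_names, n_sv_of)
  sv_ids <- sprintf("SV_%04d", seq_along(sv_fam))
  sv_w <- unlist(lapply(n_sv_of, function(n) rdirichlet1(n, 0.8)),
                 use.names = FALSE)
  contaminant_svs <- sv_ids[sv_fam %in% cont_fams]
  spill_svs <- sv_ids[sv_fam %in% c("Prevotellaceae", "Unassigned")]

  mock <- mock_reference_default()
  mock_ids <- sprintf("SV_M%02d", seq_along(mock))
  junk_ids <- sprintf("SV_J%02d", 1:5)
  all_ids <- c(sv_ids, mock_ids, junk_ids)

  ## --- taxonomy
  lin <- fam_lineage()
  fam_of_mock <- unname(stats::setNames(genus_family_map(),
                                        names(genus_family_map()))[
                                          genus_of(mock)])
  fam_of_mock[genus_of(mock) == "Cutibacterium"] <- "Propionibacteriaceae"
  fam_of_mock[genus_of(mock) == "Actinomyces"] <- "Actinomycetaceae"
  fam_of_mock[genus_of(mock) == "Bifidobacterium"] <- "Bifidobacteriaceae"
  fam_of_mock[genus_of(mock) == "Clostridium"] <- "Clostridiaceae"
  fam_of_mock[genus_of(mock) == "Deinococcus"] <- "Deinococcaceae"
  fam_of_mock[genus_of(mock) == "Helicobacter"] <- "Helicobacteraceae"
  fam_of_mock[genus_of(mock) == "Neisseria"] <- "Neisseriaceae"
  fam_of_mock[genus_of(mock) == "Porphyromonas"] <- "Porphyromonadaceae"
  fam_of_mock[genus_of(mock) == "Rhodobacter"] <- "Rhodobacteraceae"
  tax_fams <- c(sv_fam, fam_of_mock, rep(NA_character_, length(junk_ids)))
  li <- lin[match(tax_fams, lin$family), ]
  tax_df <- data.frame(
    sv_id = all_ids, domain = "Bacteria",
    phylum = li$phylum, class = li$class, order = li$order,
    family = ifelse(tax_fams == "Unassigned" | is.na(tax_fams),
                    NA_character_, tax_fams),
    genus = ifelse(tax_fams == "Unassigned" | is.na(tax_fams),
                   NA_character_, li$genus),
    species = NA_character_, stringsAsFactors = FALSE)
  # mock SVs carry the strain species label; genus from the strain name
  tax_df$genus[match(mock_ids, tax_df$sv_id)] <- genus_of(mock)
  tax_df$species[match(mock_ids, tax_df$sv_id)] <- mock
  # unassigned pool: order-level assignment only
  una <- tax_df$sv_id %in% c(sv_ids[sv_fam == "Unassigned"], junk_ids)
  tax_df$phylum[una] <- "Firmicutes"
  tax_df$class[una] <- "Clostridia"
  tax_df$order[una] <- "Clostridiales"
  taxonomy <- taxonomy_table(tax_df)

  sv_length <- stats::setNames(
    c(sample(376:428, length(sv_ids) + length(mock_ids), replace = TRUE),
      sample(220:374, length(junk_ids), replace = TRUE)), all_ids)

  ## --- herd structure
  md <- list(); k <- 0L
  for (f in farms) for (ci in seq_len(config$n_cows_per_farm)) {
    cow <- sprintf("%s%02d", f, ci)
    parity <- sample(1:5, 1L)
    for (p in seq_len(config$n_periods)) {
      dim_days <- round(stats::rnorm(1, if (p == 1) 41 else 218, 12))
      for (q in QUARTERS) {
        if (stats::runif(1) < config$missing_quarter_rate) next
        k <- k + 1L
        md[[k]] <- data.frame(
          sample_id = paste(cow, p, q, sep = "_"), cow_id = cow, farm = f,
          quarter = q, period = p, role = "specimen",
          dim = max(5, dim_days), parity = parity, stringsAsFactors = FALSE)
      }
    }
  }
  md <- do.call(rbind, md)

  ## --- family proportions per specimen (logistic-normal with cow and
  ##     quarter effects plus the core-family coupling)
  n_fam <- length(fam_names)
  cows <- unique(md$cow_id)
  cow_eff <- matrix(stats::rnorm(length(cows) * n_fam, 0,
                                 config$cow_effect_sd),
                    length(cows), n_fam,
                    dimnames = list(cows, fam_names))
  s_couple <- sqrt(-config$core_coupling)
  c1 <- config$core_families[1]; c2 <- config$core_families[2]
  props <- matrix(0, nrow(md), n_fam,
                  dimnames = list(md$sample_id, fam_names))
  # calibrate per-farm locations so realized means match the baselines
  noise_sd <- sqrt(config$cow_effect_sd^2 + config$quarter_effect_sd^2)
  cal_noise <- matrix(stats::rnorm(3000 * n_fam, 0, noise_sd), 3000, n_fam,
                      dimnames = list(NULL, fam_names))
  zc <- stats::rnorm(3000)
  cal_noise[, c1] <- cal_noise[, c1] + s_couple * zc
  cal_noise[, c2] <- cal_noise[, c2] - s_couple * zc
  log_base <- apply(comp, 2L, calibrate_logmeans, noise = cal_noise)
  rownames(log_base) <- fam_names
  for (i in seq_len(nrow(md))) {
    eta <- log_base[, md$farm[i]] + cow_eff[md$cow_id[i], ] +
      stats::rnorm(n_fam, 0, config$quarter_effect_sd)
    z <- stats::rnorm(1)
    eta[c1] <- eta[c1] + s_couple * z
    eta[c2] <- eta[c2] - s_couple * z
    props[i, ] <- softmax(eta)
  }

  ## --- dysbiosis injection
  w <- config$dysbiosis_family_weights
  named_w <- w[setdiff(names(w), "other")]
  other_fams <- setdiff(rownames(base), c(config$core_families[1],
                                          names(named_w)))
  weights <- c(named_w,
               stats::setNames(rep(w[["other"]] / length(other_fams),
                                   length(other_fams)), other_fams))
  events <- list(); e <- 0L
  for (key in unique(paste(md$cow_id, md$period))) {
    idx <- which(paste(md$cow_id, md$period) == key)
    # the dominance rule is only defined for cow-periods with 3-4 quarters,
    # so truth events are injected only there
    if (length(idx) < 3L) next
    if (stats::runif(1) >= config$dysbiosis_rate) next
    qmat <- props[idx, , drop = FALSE]
    rownames(qmat) <- md$quarter[idx]
    target_q <- sample(rownames(qmat), 1L)
    target_f <- sample(names(weights), 1L, prob = weights)
    frac <- stats::runif(1, config$dominant_range[1],
                         config$dominant_range[2])
    qmat <- inject_dysbiosis(qmat, target_q, target_f, frac,
                             sibling_cap = config$sibling_cap)
    props[idx, ] <- qmat
    e <- e + 1L
    events[[e]] <- data.frame(
      cow_id = md$cow_id[idx][1L], period = md$period[idx][1L],
      quarter = target_q,
      sample_id = paste(md$cow_id[idx][1L], md$period[idx][1L], target_q,
                        sep = "_"),
      family = target_f, fraction = frac, stringsAsFactors = FALSE)
  }
  events <- if (e > 0L) do.call(rbind, events) else
    data.frame(cow_id = character(), period = integer(),
               quarter = character(), sample_id = character(),
               family = character(), fraction = numeric(),
               stringsAsFactors = FALSE)

  ## --- counts
  depth <- round(stats::rlnorm(nrow(md), config$depth_log_mean,
                               config$depth_log_sd))
  depth <- pmax(depth, 60)
  names(depth) <- md$sample_id
  is_dys <- md$sample_id %in% events$sample_id
  depth[is_dys] <- depth[is_dys] * config$dysbiosis_depth_factor
  sv_prob_of <- function(p_fam) {
    (p_fam[sv_fam] * sv_w)
  }
  # truth events must satisfy the dominance rule on the REALIZED counts, not
  # just the latent proportions; multinomial noise at low depth can cross the
  # 0.60/0.20 thresholds, so constrained samples are redrawn until the event
  # holds with margin
  constraint <- list()
  if (nrow(events) > 0L) for (j in seq_len(nrow(events))) {
    ev <- events[j, ]
    sibs <- md$sample_id[md$cow_id == ev$cow_id & md$period == ev$period &
                           md$quarter != ev$quarter]
    constraint[[ev$sample_id]] <- list(type = "dom", family = ev$family)
    for (s in sibs) constraint[[s]] <- list(type = "sib", family = ev$family)
  }
  fam_idx <- split(seq_along(sv_fam), sv_fam)
  counts <- matrix(0, nrow(md), length(all_ids),
                   dimnames = list(md$sample_id, all_ids))
  for (i in seq_len(nrow(md))) {
    pr <- sv_prob_of(props[i, ])
    cns <- constraint[[md$sample_id[i]]]
    for (try in 1:50) {
      drawn <- stats::rmultinom(1L, depth[i], pr)[, 1L]
      if (is.null(cns)) break
      share <- sum(drawn[fam_idx[[cns$family]]]) / depth[i]
      if (cns$type == "dom" && share > 0.62) break
      if (cns$type == "sib" && share < 0.18) break
    }
    counts[i, sv_ids] <- drawn
  }
  # sparse short junk SVs in a fifth of the specimens
  for (j in junk_ids) {
    hit <- stats::runif(nrow(md)) < 0.2
    counts[hit, j] <- stats::rpois(sum(hit), 6) + 1L
  }

  ## --- controls
  neg_ids <- sprintf("NEG%02d", seq_len(config$n_neg_controls))
  pos_ids <- sprintf("POS%02d", seq_len(config$n_pos_controls))
  ctrl_counts <- matrix(0, length(neg_ids) + length(pos_ids),
                        length(all_ids),
                        dimnames = list(c(neg_ids, pos_ids), all_ids))
  for (s in neg_ids) {
    nd <- round(stats::rlnorm(1, log(300), 0.5))
    ctrl_counts[s, contaminant_svs] <-
      stats::rmultinom(1L, nd, rdirichlet1(length(contaminant_svs), 5))[, 1L]
  }
  for (s in pos_ids) {
    pd <- round(stats::rlnorm(1, log(20000), 0.3))
    pr <- stats::setNames(numeric(length(all_ids)), all_ids)
    pr[mock_ids] <- (1 - config$pos_spill_frac) *
      rdirichlet1(length(mock_ids), 50)
    pr[spill_svs] <- config$pos_spill_frac *
      rdirichlet1(length(spill_svs), 1)
    ctrl_counts[s, ] <- stats::rmultinom(1L, pd, pr)[, 1L]
  }
  ctrl_md <- data.frame(
    sample_id = c(neg_ids, pos_ids), cow_id = NA_character_,
    farm = NA_character_, quarter = NA_character_, period = NA_integer_,
    role = rep(c("negative_control", "positive_control"),
               c(length(neg_ids), length(pos_ids))),
    dim = NA_integer_, parity = NA_integer_, stringsAsFactors = FALSE)

  metadata <- sample_metadata(rbind(md, ctrl_md))
  table <- sv_table(rbind(counts, ctrl_counts), sv_length)

  ## --- colony counts (dysbiotic quarters always infected; background rate
  ##     tuned so the overall infected fraction lands near 42%)
  infected <- is_dys | stats::runif(nrow(md)) <
    config$background_infection_rate
  colony <- list(); cc <- 0L
  has_colony <- stats::runif(nrow(md)) >= config$colony_missing_rate
  hi_classes <- c("c10_lt100", "c100_lt1000", "gt1000")
  lo_classes <- c("zero", "c1_lt10")
  for (i in seq_len(nrow(md))) {
    if (!has_colony[i]) next
    if (infected[i]) {
      aero <- sample(hi_classes, 1L, prob = c(0.5, 0.3, 0.2))
      anaero <- sample(COLONY_CLASSES, 1L,
                       prob = c(0.2, 0.2, 0.3, 0.2, 0.1))
    } else {
      aero <- sample(lo_classes, 1L, prob = c(0.6, 0.4))
      anaero <- sample(lo_classes, 1L, prob = c(0.7, 0.3))
    }
    cc <- cc + 1L
    colony[[cc]] <- data.frame(
      sample_id = rep(md$sample_id[i], 2L),
      condition = c("aerobic", "anaerobic"),
      colony_class = c(aero, anaero), stringsAsFactors = FALSE)
  }
  colony <- colony_records(do.call(rbind, colony))

  ## --- isolates: dysbiotic samples always yield isolates of the injected
  ##     family when it is cultivable; infected samples yield common milk
  ##     isolates; occasional background isolates elsewhere
  spp <- family_species()
  media_w <- c(TSA_blood_aerobic = 513, TSA_blood_anaerobic = 366,
               M17 = 219, MRS = 52)
  iso <- list(); ii <- 0L
  add_iso <- function(sample_id, species) {
    ii <<- ii + 1L
    iso[[ii]] <<- data.frame(
      sample_id = sample_id,
      medium = sample(names(media_w), 1L, prob = media_w),
      species = species,
      score = stats::runif(1, 2.01, 2.6), stringsAsFactors = FALSE)
  }
  common_iso <- c("Aerococcus viridans", "Staphylococcus epidermidis",
                  "Staphylococcus chromogenes", "Staphylococcus haemolyticus",
                  "Corynebacterium bovis", "Corynebacterium amycolatum")
  has_match <- logical(nrow(events))
  if (nrow(events) > 0L) for (j in seq_len(nrow(events))) {
    fam_spp <- spp[[events$family[j]]]
    if (!is.null(fam_spp)) {
      for (sp in sample(fam_spp, min(2L, length(fam_spp))))
        add_iso(events$sample_id[j], sp)
      has_match[j] <- TRUE
    }
  }
  events$has_matching_isolate <- has_match
  for (i in seq_len(nrow(md))) {
    if (infected[i] && !is_dys[i]) {
      for (sp in sample(common_iso, sample(1:3, 1L)))
        add_iso(md$sample_id[i], sp)
    } else if (!infected[i] && stats::runif(1) < 0.15) {
      add_iso(md$sample_id[i], sample(common_iso, 1L))
    }
  }
  isolates <- isolate_records(do.call(rbind, iso))

  truth <- list(
    dysbiosis_events = events,
    infected_samples = md$sample_id[infected],
    contaminant_svs = contaminant_svs,
    pos_spill_svs = spill_svs,
    junk_svs = junk_ids,
    depths = depth)

  list(table = table, taxonomy = taxonomy, metadata = metadata,
       colony = colony, isolates = isolates, mock = mock, truth = truth,
       config = config)
}
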
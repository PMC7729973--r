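#' Run the full analysis workflow
#'
#' QC filtering -> CSS normalization -> alpha/beta diversity and permutation
#' statistics -> family profiles -> dysbiotic-quarter calling -> infection
#' classification -> culture-sequencing concordance, optionally writing all
#' result tables and a stats JSON to `out_dir`.
#'
#' Conventions: alpha diversity and the dysbiosis rule use raw filtered
#' counts (richness estimators are depth-sensitive and the dominance rule is
#' defined on percent of reads); Bray-Curtis uses CSS-normalized abundances;
#' Jaccard uses presence/absence. Ordinations are compared by Procrustes on
#' their leading axes.
#'
#' @param dataset list with `table`, `taxonomy`, `metadata`, `colony`,
#'   `isolates`, `mock` (as produced by [generate_dataset], or assembled from
#'   the readers).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param n_perm permutations for all permutation tests.
#' @param seed integer seed for the permutation draws.
#' @param min_pct family-profile reporting threshold (percent of reads).
#' @param procrustes_axes number of leading ordination axes compared.
#' @return list with components `qc`, `depth`, `alpha`, `alpha_tests`,
#'   `distances`, `ordinations`, `procrustes`, `permanova`, `dispersion`,
#'   `correlations`, `profiles`, `dysbiosis`, `dysbiosis_summary`, `imi`,
#'   `imi_association`, `concordance`, `files`.
#' @export
run_pipeline <- function(dataset, out_dir = NULL, n_perm = 999, seed = 1,
                         min_pct = 0.5, procrustes_axes = 10) {
  md <- dataset$metadata
  qc <- qc_chain(dataset$table, md, dataset$taxonomy, dataset$mock)
  tbl <- qc$table
  depth <- depth_summary(tbl)

  fam_counts <- aggregate_to_family(tbl, dataset$taxonomy)
  fam_relab <- relative_abundance(fam_counts)
  css <- css_normalize(tbl)

  alpha <- alpha_diversity(tbl)
  farm_of <- stats::setNames(md$farm, md$sample_id)[alpha$sample_id]
  period_of <- stats::setNames(md$period, md$sample_id)[alpha$sample_id]
  alpha_tests <- list(
    chao1_farm = compare_alpha(alpha$chao1[farm_of == "A"],
                               alpha$chao1[farm_of == "K"]),
    shannon_farm = compare_alpha(alpha$shannon[farm_of == "A"],
                                 alpha$shannon[farm_of == "K"]),
    chao1_period = compare_alpha(alpha$chao1[period_of == 1],
                                 alpha$chao1[period_of == 2]),
    shannon_period = compare_alpha(alpha$shannon[period_of == 1],
                                   alpha$shannon[period_of == 2]))

  d_bray <- distance_matrix(css$normalized, "bray")
  d_jac <- distance_matrix(tbl$counts, "jaccard")
  ord_bray <- pcoa(d_bray)
  ord_jac <- pcoa(d_jac)
  trunc <- function(o) o$coordinates[, seq_len(min(procrustes_axes,
                                                   ncol(o$coordinates))),
                                     drop = FALSE]
  proc <- procrustes_protest(trunc(ord_bray), trunc(ord_jac),
                             n_perm = n_perm, seed = seed)

  perma <- list(
    farm_bray = permanova(d_bray, farm_of, n_perm, seed),
    farm_jaccard = permanova(d_jac, farm_of, n_perm, seed),
    period_bray = permanova(d_bray, period_of, n_perm, seed),
    period_jaccard = permanova(d_jac, period_of, n_perm, seed))
  disp <- list(
    farm_bray = beta_dispersion(d_bray, farm_of, n_perm, seed),
    period_bray = beta_dispersion(d_bray, period_of, n_perm, seed))

  cors <- family_correlations(fam_relab)

  profiles <- family_profiles(tbl, dataset$taxonomy, md, min_pct = min_pct)
  dysb <- call_dysbiosis(fam_relab, md)
  dsum <- dysbiosis_summary(dysb)

  imi <- classify_imi(dataset$colony, sample_ids = rownames(tbl$counts))
  imi_assoc <- tryCatch(
    imi_microbiota_association(d_bray, imi, n_perm, seed),
    error = function(e) list(error = conditionMessage(e)))
  conc <- concordance(dysb$calls, dataset$isolates, md)

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    files <- c(
      write_sv_table(tbl, file.path(out_dir, "filtered_sv_table.tsv"),
                     file.path(out_dir, "sv_lengths.tsv")),
      file.path(out_dir, "sv_lengths.tsv"),
      wtsv(data.frame(sample_id = rownames(fam_counts), fam_counts,
                      check.names = FALSE), "family_table.tsv"),
      wtsv(profiles, "family_profiles.tsv"),
      wtsv(dysb$calls, "dysbiosis_calls.tsv"),
      wtsv(alpha, "alpha_diversity.tsv"),
      wtsv(data.frame(sample_id = rownames(d_bray),
                      as.data.frame(unclass(d_bray)), check.names = FALSE),
           "distance_bray.tsv"),
      wtsv(data.frame(sample_id = rownames(d_jac),
                      as.data.frame(unclass(d_jac)), check.names = FALSE),
           "distance_jaccard.tsv"),
      wtsv(data.frame(sample_id = rownames(ord_bray$coordinates),
                      as.data.frame(trunc(ord_bray)), check.names = FALSE),
           "pcoa_bray.tsv"),
      wtsv(imi, "imi_status.tsv"),
      wtsv(if (nrow(conc$records) > 0) conc$records else
             data.frame(note = "no dysbiosis calls"), "concordance.tsv"))
    stats_json <- file.path(out_dir, "stats.json")
    jsonlite::write_json(list(
      depth = depth,
      filter = list(n_sv_in = qc$report$n_sv_in,
                    n_sv_out = qc$report$n_sv_out,
                    n_samples_in = qc$report$n_samples_in,
                    n_samples_out = qc$report$n_samples_out,
                    reads_removed_pct = qc$report$reads_removed_pct),
      alpha_tests = lapply(alpha_tests, function(t)
        list(statistic = t$statistic, p_value = t$p_value)),
      permanova = lapply(perma, function(t)
        list(pseudo_f = t$pseudo_f, p_value = t$p_value)),
      dispersion = lapply(disp, function(t)
        list(f_value = t$f_value, p_value = t$p_value)),
      procrustes = list(m2 = proc$m2, p_value = proc$p_value),
      dysbiosis = list(n_evaluated = dsum$n_evaluated,
                       n_dysbiotic = dsum$n_dysbiotic,
                       per_family = as.list(dsum$per_family)),
      imi = list(n_infected = sum(imi$status == "infected"),
                 n_not_infected = sum(imi$status == "not_infected"),
                 n_unknown = sum(imi$status == "unknown"),
                 association_p = imi_assoc$p_value),
      concordance = list(rate = conc$rate,
                         unmapped_genera = conc$unmapped_genera)),
      stats_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, stats_json)
  }

  list(qc = qc, depth = depth, alpha = alpha, alpha_tests = alpha_tests,
       distances = list(bray = d_bray, jaccard = d_jac),
       ordinations = list(bray = ord_bray, jaccard = ord_jac),
       procrustes = proc, permanova = perma, dispersion = disp,
       correlations = cors, profiles = profiles, dysbiosis = dysb,
       dysbiosis_summary = dsum, family_counts = fam_counts,
       family_relab = fam_relab, imi = imi, imi_association = imi_assoc,
       concordance = conc, files = files)
}
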
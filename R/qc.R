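#' Quality filtering of SV tables
#'
#' The retention rules applied before any analysis, each with a provenance
#' report of what was removed and why:
#' short amplicons (< 375 bases), shallow samples (< 2000 reads), weakly
#' supported SVs (< 10 reads), and control-based contaminant removal using the
#' sequencing controls (a mock-community positive control and negative
#' controls). All thresholds are strict.
#'
#' @name qc
NULL

filter_report <- function(n_sv_in, n_sv_out, n_samples_in, n_samples_out,
                          removed, reads_in, reads_out) {
  stopifnot(nrow(removed) == 0L ||
              all(removed$entity %in% c("sv", "sample")))
  structure(list(
    n_sv_in = n_sv_in, n_sv_out = n_sv_out,
    n_samples_in = n_samples_in, n_samples_out = n_samples_out,
    removed = removed,
    reads_removed_pct = 100 * (reads_in - reads_out) / reads_in
  ), class = "filter_report")
}

removed_df <- function(entity = character(), id = character(),
                       rule = character()) {
  data.frame(entity = entity, id = id, rule = rule,
             stringsAsFactors = FALSE)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> SVs %d -> %d, samples %d -> %d, %.2f%% of reads removed\n",
    x$n_sv_in, x$n_sv_out, x$n_samples_in, x$n_samples_out,
    x$reads_removed_pct))
  if (nrow(x$removed) > 0L)
    print(table(x$removed$entity, x$removed$rule))
  invisible(x)
}

subset_table <- function(x, samples = rownames(x$counts),
                         svs = colnames(x$counts)) {
  if (length(samples) == 0L)
    stop("all samples removed: filtered table would be empty")
  if (length(svs) == 0L)
    stop("all SVs removed: filtered table would be empty")
  sv_table(x$counts[samples, svs, drop = FALSE], x$sv_length[svs])
}

#' Remove short sequence variants
#'
#' SVs whose amplicon is shorter than `min_len` bases are removed (strict:
#' an SV of exactly `min_len` bases is retained). Order of the surviving SVs
#' is preserved.
#'
#' @param x an [sv_table].
#' @param min_len minimum amplicon length in bases.
#' @return list with elements `table` (filtered [sv_table]) and `report`
#'   (`filter_report`).
#' @export
filter_by_length <- function(x, min_len = 375) {
  len <- x$sv_length[colnames(x$counts)]
  drop <- names(len)[len < min_len]
  keep <- setdiff(colnames(x$counts), drop)
  out <- subset_table(x, svs = keep)
  list(table = out,
       report = filter_report(
         ncol(x$counts), length(keep), nrow(x$counts), nrow(x$counts),
         removed_df(rep("sv", length(drop)), drop,
                    rep("length_lt_min", length(drop))),
         sum(x$counts), sum(out$counts)))
}

#' Remove shallow samples, then weakly supported SVs
#'
#' Specimen samples with fewer than `min_sample_reads` total reads are removed
#' first; SVs with fewer than `min_sv_reads` reads summed over the surviving
#' samples are removed second. Both thresholds are strict ("fewer than").
#' The order is load-bearing: an SV whose support drops below the threshold
#' once a shallow sample is gone is removed. Control samples are exempt from
#' the depth rule (controls are expected to be shallow); SV support is counted
#' over surviving specimen samples.
#'
#' @param x an [sv_table].
#' @param metadata optional [sample_metadata] table; when `NULL` all samples
#'   are treated as specimens.
#' @param min_sample_reads,min_sv_reads strict retention thresholds.
#' @return list with `table` and `report`, as [filter_by_length].
#' @export
filter_low_support <- function(x, metadata = NULL, min_sample_reads = 2000,
                               min_sv_reads = 10) {
  samples <- rownames(x$counts)
  if (is.null(metadata)) {
    is_spec <- rep(TRUE, length(samples))
  } else {
    role <- stats::setNames(metadata$role, metadata$sample_id)[samples]
    is_spec <- !is.na(role) & role == "specimen"
  }
  depth <- rowSums(x$counts)
  drop_samples <- samples[is_spec & depth < min_sample_reads]
  keep_samples <- setdiff(samples, drop_samples)
  if (length(keep_samples) == 0L)
    stop("every sample is below ", min_sample_reads, " reads")
  m <- x$counts[keep_samples, , drop = FALSE]
  spec_keep <- intersect(keep_samples, samples[is_spec])
  support <- colSums(m[spec_keep, , drop = FALSE])
  drop_svs <- colnames(m)[support < min_sv_reads]
  keep_svs <- setdiff(colnames(m), drop_svs)
  out <- subset_table(x, samples = keep_samples, svs = keep_svs)
  removed <- rbind(
    removed_df(rep("sample", length(drop_samples)), drop_samples,
               rep("sample_reads_lt_min", length(drop_samples))),
    removed_df(rep("sv", length(drop_svs)), drop_svs,
               rep("sv_reads_lt_min", length(drop_svs))))
  list(table = out,
       report = filter_report(
         ncol(x$counts), length(keep_svs),
         nrow(x$counts), length(keep_samples),
         removed, sum(x$counts), sum(out$counts)))
}

#' Default mock-community reference (20-strain even mix)
#'
#' The strain list of the ATCC MSA-2002 20-strain even-mix whole-cell
#' standard, used as the sequencing positive control. Matching against SV
#' taxonomy is done at genus level.
#'
#' @return character vector of 20 species names.
#' @export
mock_reference_default <- function() {
  c("Acinetobacter baumannii", "Actinomyces odontolyticus",
    "Bacillus cereus", "Bacteroides vulgatus",
    "Bifidobacterium adolescentis", "Clostridium beijerinckii",
    "Cutibacterium acnes", "Deinococcus radiodurans",
    "Enterococcus faecalis", "Escherichia coli",
    "Helicobacter pylori", "Lactobacillus gasseri",
    "Neisseria meningitidis", "Porphyromonas gingivalis",
    "Pseudomonas aeruginosa", "Rhodobacter sphaeroides",
    "Staphylococcus aureus", "Staphylococcus epidermidis",
    "Streptococcus agalactiae", "Streptococcus mutans")
}

genus_of <- function(species) vapply(strsplit(species, "\\s+"), `[`, "", 1L)

#' Control-based contaminant removal
#'
#' Two rules, each tagged in the report:
#' \describe{
#'   \item{`positive_control_non_mock` (a)}{any SV detected (>= 1 read) in a
#'     positive control whose genus is not on the mock-community list is
#'     removed — spill-over or index hopping into the mock control flags the
#'     SV as untrustworthy.}
#'   \item{`negative_control_prevalent` (b)}{any SV present in at least
#'     `neg_prevalence` of the negative controls whose mean relative abundance
#'     in negative controls exceeds `neg_enrichment` times its mean relative
#'     abundance in specimens is removed — a transparent prevalence+enrichment
#'     stand-in for reagent-contaminant screening.}
#' }
#'
#' @param x an [sv_table] still containing the control samples.
#' @param metadata [sample_metadata] covering the table's samples.
#' @param mock character vector of mock-community species (genus matched);
#'   default [mock_reference_default()].
#' @param tax [taxonomy_table] giving each SV's genus.
#' @param neg_prevalence minimum fraction of negative controls an SV must
#'   appear in for rule (b).
#' @param neg_enrichment minimum ratio of negative-control to specimen mean
#'   relative abundance for rule (b).
#' @param rules which rules to apply.
#' @return list with `table` and `report`.
#' @export
control_filter <- function(x, metadata, mock = mock_reference_default(),
                           tax = NULL, neg_prevalence = 0.5,
                           neg_enrichment = 1.0, rules = c("a", "b")) {
  samples <- rownames(x$counts)
  role <- stats::setNames(metadata$role, metadata$sample_id)[samples]
  pos <- samples[!is.na(role) & role == "positive_control"]
  neg <- samples[!is.na(role) & role == "negative_control"]
  spec <- samples[!is.na(role) & role == "specimen"]
  removed <- removed_df()
  if ("a" %in% rules) {
    if (length(pos) == 0L)
      stop("positive-control rule enabled but no positive_control sample present")
    if (is.null(tax))
      stop("positive-control rule requires a taxonomy table")
    mock_genera <- unique(genus_of(mock))
    in_pos <- colSums(x$counts[pos, , drop = FALSE] > 0) > 0
    genus <- stats::setNames(tax$genus, tax$sv_id)[colnames(x$counts)]
    non_mock <- is.na(genus) | !genus %in% mock_genera
    drop_a <- colnames(x$counts)[in_pos & non_mock]
    removed <- rbind(removed,
                     removed_df(rep("sv", length(drop_a)), drop_a,
                                rep("positive_control_non_mock",
                                    length(drop_a))))
  }
  if ("b" %in% rules) {
    if (length(neg) == 0L)
      stop("negative-control rule enabled but no negative_control sample present")
    neg_m <- x$counts[neg, , drop = FALSE]
    prev <- colMeans(neg_m > 0)
    neg_ra <- colMeans(relative_abundance(neg_m))
    spec_ra <- colMeans(relative_abundance(x$counts[spec, , drop = FALSE]))
    drop_b <- colnames(x$counts)[prev >= neg_prevalence &
                                   neg_ra > neg_enrichment * spec_ra]
    removed <- rbind(removed,
                     removed_df(rep("sv", length(drop_b)), drop_b,
                                rep("negative_control_prevalent",
                                    length(drop_b))))
  }
  drop <- unique(removed$id)
  keep <- setdiff(colnames(x$counts), drop)
  out <- subset_table(x, svs = keep)
  # an SV can trip both rules; report counts unique SVs
  removed <- removed[!duplicated(removed$id), , drop = FALSE]
  list(table = out,
       report = filter_report(
         ncol(x$counts), length(keep), nrow(x$counts), nrow(x$counts),
         removed, sum(x$counts), sum(out$counts)))
}

#' Per-sample depth summary
#'
#' @param x an [sv_table] or counts matrix.
#' @return list with `mean`, `median`, `min`, `max` reads per sample.
#' @export
depth_summary <- function(x) {
  d <- sample_depths(x)
  list(mean = mean(d), median = stats::median(d),
       min = min(d), max = max(d))
}

#' Full QC chain
#'
#' Length filter, then sample-depth filter, then SV-support filter, then
#' control-based contaminant removal, then (optionally) removal of the control
#' samples themselves. Control rules are applied only when the metadata
#' contains samples of the corresponding role, which also makes the chain
#' idempotent: re-running it on its own output (controls gone) is the
#' identity.
#'
#' @inheritParams control_filter
#' @inheritParams filter_low_support
#' @param min_len minimum SV length in bases.
#' @param drop_controls remove control samples from the returned table.
#' @return list with `table` (specimen-level filtered [sv_table]), `report`
#'   (merged `filter_report`), and `steps` (per-step reports).
#' @export
qc_chain <- function(x, metadata = NULL, tax = NULL,
                     mock = mock_reference_default(),
                     min_len = 375, min_sample_reads = 2000,
                     min_sv_reads = 10, neg_prevalence = 0.5,
                     neg_enrichment = 1.0, drop_controls = TRUE) {
  reads_in <- sum(x$counts)
  n_sv_in <- ncol(x$counts); n_samples_in <- nrow(x$counts)
  s1 <- filter_by_length(x, min_len)
  s2 <- filter_low_support(s1$table, metadata, min_sample_reads, min_sv_reads)
  steps <- list(length = s1$report, low_support = s2$report)
  cur <- s2$table
  removed <- rbind(s1$report$removed, s2$report$removed)
  if (!is.null(metadata)) {
    role <- stats::setNames(metadata$role,
                            metadata$sample_id)[rownames(cur$counts)]
    rules <- c(if (any(role == "positive_control", na.rm = TRUE)) "a",
               if (any(role == "negative_control", na.rm = TRUE)) "b")
    if (length(rules) > 0L) {
      s3 <- control_filter(cur, metadata, mock, tax, neg_prevalence,
                           neg_enrichment, rules)
      steps$controls <- s3$report
      cur <- s3$table
      removed <- rbind(removed, s3$report$removed)
    }
    if (drop_controls) {
      ctrl <- rownames(cur$counts)[!is.na(role[rownames(cur$counts)]) &
                                     role[rownames(cur$counts)] != "specimen"]
      if (length(ctrl) > 0L) {
        cur <- subset_table(cur,
                            samples = setdiff(rownames(cur$counts), ctrl))
        removed <- rbind(removed,
                         removed_df(rep("sample", length(ctrl)), ctrl,
                                    rep("control_sample", length(ctrl))))
      }
    }
  }
  list(table = cur,
       report = filter_report(n_sv_in, ncol(cur$counts),
                              n_samples_in, nrow(cur$counts),
                              removed, reads_in, sum(cur$counts)),
       steps = steps)
}
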
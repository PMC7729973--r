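#' Family-level prevalence and abundance profiles
#'
#' The core-microbiota summary: for every family above an overall read-share
#' threshold, the percent of all retained reads, number of member SVs,
#' percent of quarter samples positive per farm, percent of cows positive
#' (in any sample, and the stricter in-every-sampled-period variant), and the
#' mean per-sample relative abundance per farm. Families below the threshold
#' are pooled into an `other` row so the read-share column is conservative.
#'
#' @param x filtered [sv_table] (specimen samples).
#' @param tax [taxonomy_table].
#' @param metadata [sample_metadata]; only specimen rows present in the
#'   table are used.
#' @param min_pct minimum overall percent of reads for a family to be
#'   reported individually.
#' @return data.frame with one row per reported family (plus `other`),
#'   columns: `family`, `pct_reads_total`, `n_sv`, `pct_quarters_farm_<f>`,
#'   `pct_cows_any`, `pct_cows_all_periods`, `mean_pct_reads_farm_<f>`,
#'   sorted by decreasing read share.
#' @export
family_profiles <- function(x, tax, metadata, min_pct = 0.5) {
  md <- metadata[metadata$role == "specimen" &
                   metadata$sample_id %in% rownames(x$counts), , drop = FALSE]
  m <- x$counts[md$sample_id, , drop = FALSE]
  fam_counts <- aggregate_to_family(m, tax)
  fam_sv <- stats::setNames(tax$family, tax$sv_id)[colnames(m)]
  n_sv_by_fam <- table(fam_sv[!is.na(fam_sv)])
  total <- sum(fam_counts)
  pct_total <- 100 * colSums(fam_counts) / total
  relab <- relative_abundance(fam_counts)
  farms <- sort(unique(md$farm))
  fam_names <- colnames(fam_counts)

  prof_one <- function(cols) {
    pos <- rowSums(fam_counts[, cols, drop = FALSE]) > 0
    ra <- rowSums(relab[, cols, drop = FALSE])
    row <- list(pct_reads_total = sum(pct_total[cols]),
                n_sv = sum(n_sv_by_fam[cols]))
    for (f in farms) {
      in_farm <- md$farm == f
      row[[paste0("pct_quarters_farm_", f)]] <-
        100 * mean(pos[in_farm])
      row[[paste0("mean_pct_reads_farm_", f)]] <-
        100 * mean(ra[in_farm])
    }
    cow_pos <- tapply(pos, md$cow_id, any)
    row$pct_cows_any <- 100 * mean(cow_pos)
    # stricter variant: detected in every period in which the cow was sampled
    per_cp <- tapply(pos, list(md$cow_id, md$period), any)
    row$pct_cows_all_periods <-
      100 * mean(apply(per_cp, 1L, function(v) all(v[!is.na(v)])))
    row
  }

  keep <- fam_names[pct_total >= min_pct]
  keep <- keep[order(-pct_total[keep], keep)]
  rows <- lapply(keep, prof_one)
  pooled <- setdiff(fam_names, keep)
  out <- data.frame(family = keep,
                    do.call(rbind, lapply(rows, as.data.frame)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (length(pooled) > 0L)
    out <- rbind(out, data.frame(family = "other",
                                 as.data.frame(prof_one(pooled)),
                                 stringsAsFactors = FALSE, row.names = NULL))
  out
}
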
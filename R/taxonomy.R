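#' Taxonomy table
#'
#' Per-SV lineage down to genus plus an optional free-text species label.
#' Ranks must be filled left-to-right: an assigned rank below an unassigned
#' one (e.g. a genus without a family) violates the lineage contract.
#'
#' @param df data.frame with columns `sv_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus` (NA or "" = unassigned) and optionally
#'   `species`.
#' @return a validated `taxonomy_table` data.frame.
#' @export
taxonomy_table <- function(df) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  need <- c("sv_id", ranks)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("taxonomy table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"species" %in% names(df)) df$species <- NA_character_
  df <- df[, c(need, "species")]
  for (r in c(ranks, "species")) {
    df[[r]] <- as.character(df[[r]])
    df[[r]][!is.na(df[[r]]) & df[[r]] == ""] <- NA_character_
  }
  if (anyDuplicated(df$sv_id))
    stop("duplicated sv_id in taxonomy: ", df$sv_id[duplicated(df$sv_id)][1L])
  assigned <- !is.na(as.matrix(df[, ranks]))
  # left-to-right fill: once a rank is unassigned all deeper ranks must be too
  gap <- assigned[, -1L, drop = FALSE] & !assigned[, -length(ranks), drop = FALSE]
  if (any(gap))
    stop("rank assigned below an unassigned rank for SV: ",
         df$sv_id[which(rowSums(gap) > 0)[1L]])
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read / write a taxonomy table (TSV)
#'
#' @param path file path.
#' @return [taxonomy_table] (reader) or `path` invisibly (writer).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  taxonomy_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                   na.strings = c("NA", "")))
}

#' @rdname read_taxonomy
#' @param tax a [taxonomy_table].
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate SV counts to family level
#'
#' Sums counts over SVs sharing a family assignment. SVs without a family
#' assignment are dropped before aggregation (only SVs positively assigned to
#' family level enter the family-level analyses); total reads of the
#' family-assigned SVs are conserved per sample.
#'
#' @param x an [sv_table] or samples x SVs counts matrix.
#' @param tax a [taxonomy_table] covering the table's SVs.
#' @return samples x families numeric matrix.
#' @export
aggregate_to_family <- function(x, tax) {
  m <- if (inherits(x, "sv_table")) x$counts else x
  fam <- stats::setNames(tax$family, tax$sv_id)[colnames(m)]
  keep <- !is.na(fam)
  if (!any(keep))
    stop("no SV in the table has a family assignment in the taxonomy")
  m <- m[, keep, drop = FALSE]
  fam <- factor(fam[keep])
  out <- m %*% stats::model.matrix(~ fam - 1)
  colnames(out) <- levels(fam)
  out
}

#' Relative abundances by row
#'
#' @param m samples x taxa numeric matrix with positive row sums.
#' @return matrix of row-wise proportions.
#' @export
relative_abundance <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("sample with zero total reads: ", rownames(m)[which(rs <= 0)[1L]])
  sweep(m, 1L, rs, "/")
}
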
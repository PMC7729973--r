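#' Sample metadata, colony counts and isolate identifications
#'
#' Readers and validators for the per-sample tables that bind every statistic
#' to the herd structure: cow, farm (A/K), quarter (LF/LR/RF/RR), sampling
#' period (1/2) and sample role (specimen or sequencing control); ordinal
#' colony-count classes per plating condition; and MALDI-identified isolates
#' with their identification scores.
#'
#' @name metadata
NULL

QUARTERS <- c("LF", "LR", "RF", "RR")
FARMS <- c("A", "K")
ROLES <- c("specimen", "negative_control", "positive_control")
COLONY_CLASSES <- c("zero", "c1_lt10", "c10_lt100", "c100_lt1000", "gt1000")
MEDIA <- c("TSA_blood_aerobic", "TSA_blood_anaerobic", "M17", "MRS")

#' Validate sample metadata
#'
#' Specimens must carry cow, farm, quarter and period, with (cow, quarter,
#' period) unique; control samples have role `negative_control` or
#' `positive_control` and may omit cow/quarter. Unknown enum values are
#' rejected naming the offending sample.
#'
#' @param df data.frame with columns `sample_id`, `cow_id`, `farm`, `quarter`,
#'   `period`, `role` and optionally `dim` (days in milk) and `parity`.
#' @param quarter_map optional named character vector mapping other quarter
#'   dialects (e.g. `c("left front" = "LF")`) onto LF/LR/RF/RR.
#' @return validated metadata data.frame.
#' @export
sample_metadata <- function(df, quarter_map = NULL) {
  need <- c("sample_id", "cow_id", "farm", "quarter", "period", "role")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!"dim" %in% names(df)) df$dim <- NA_integer_
  if (!"parity" %in% names(df)) df$parity <- NA_integer_
  df$sample_id <- as.character(df$sample_id)
  df$cow_id <- as.character(df$cow_id)
  df$quarter <- as.character(df$quarter)
  if (!is.null(quarter_map)) {
    hit <- df$quarter %in% names(quarter_map)
    df$quarter[hit] <- unname(quarter_map[df$quarter[hit]])
  }
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  bad_role <- !df$role %in% ROLES
  if (any(bad_role))
    stop(sprintf("sample '%s' has unknown role '%s'",
                 df$sample_id[bad_role][1L], df$role[bad_role][1L]))
  spec <- df$role == "specimen"
  bad_farm <- spec & !df$farm %in% FARMS
  if (any(bad_farm))
    stop(sprintf("sample '%s' has unknown farm '%s'",
                 df$sample_id[bad_farm][1L], df$farm[bad_farm][1L]))
  bad_q <- spec & !df$quarter %in% QUARTERS
  if (any(bad_q))
    stop(sprintf("sample '%s' has unknown quarter '%s'",
                 df$sample_id[bad_q][1L], df$quarter[bad_q][1L]))
  bad_p <- spec & !df$period %in% c(1, 2, "1", "2")
  if (any(bad_p))
    stop(sprintf("sample '%s' has unknown period '%s'",
                 df$sample_id[bad_p][1L], df$period[bad_p][1L]))
  df$period <- as.integer(df$period)
  miss_cow <- spec & (is.na(df$cow_id) | df$cow_id == "")
  if (any(miss_cow))
    stop("specimen '", df$sample_id[miss_cow][1L], "' has no cow_id")
  key <- paste(df$cow_id, df$quarter, df$period, sep = "|")[spec]
  if (anyDuplicated(key))
    stop("duplicated specimen for (cow, quarter, period): ",
         key[duplicated(key)][1L])
  df
}

#' Read sample metadata from TSV
#'
#' @param path file path.
#' @inheritParams sample_metadata
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path, quarter_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_metadata(utils::read.delim(path, stringsAsFactors = FALSE,
                                    na.strings = c("NA", "")),
                  quarter_map = quarter_map)
}

#' Validate / read colony-count records
#'
#' One record per (sample, plating condition); colony classes are the ordinal
#' groups 0, 1-<10, 10-<100, 100-<1000, >1000 colonies per 0.1 mL plated.
#'
#' @param df data.frame with columns `sample_id`, `condition`
#'   (aerobic/anaerobic), `colony_class`.
#' @return validated data.frame; `colony_class` is an ordered factor.
#' @export
colony_records <- function(df) {
  need <- c("sample_id", "condition", "colony_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("colony table is missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  bad_c <- !df$condition %in% c("aerobic", "anaerobic")
  if (any(bad_c))
    stop(sprintf("sample '%s' has unknown condition '%s'",
                 df$sample_id[bad_c][1L], df$condition[bad_c][1L]))
  bad_k <- !df$colony_class %in% COLONY_CLASSES
  if (any(bad_k))
    stop(sprintf("sample '%s' has unknown colony class '%s'",
                 df$sample_id[bad_k][1L], df$colony_class[bad_k][1L]))
  key <- paste(df$sample_id, df$condition)
  if (anyDuplicated(key))
    stop("more than one colony record for (sample, condition): ",
         key[duplicated(key)][1L])
  df$colony_class <- factor(df$colony_class, levels = COLONY_CLASSES,
                            ordered = TRUE)
  df
}

#' @rdname colony_records
#' @param path file path.
#' @export
read_colony <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  colony_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Validate / read isolate identifications
#'
#' Isolates with identification score <= `min_score` are dropped (only
#' confident MALDI identifications, score > 2, are retained downstream).
#'
#' @param df data.frame with columns `sample_id`, `medium`, `species`, `score`.
#' @param min_score retention threshold on the identification score.
#' @return validated data.frame of retained isolates.
#' @export
isolate_records <- function(df, min_score = 2) {
  need <- c("sample_id", "medium", "species", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("isolate table is missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  bad_m <- !df$medium %in% MEDIA
  if (any(bad_m))
    stop(sprintf("sample '%s' has unknown medium '%s'",
                 df$sample_id[bad_m][1L], df$medium[bad_m][1L]))
  df$score <- as.numeric(df$score)
  df[df$score > min_score, , drop = FALSE]
}

#' @rdname isolate_records
#' @param path file path.
#' @export
read_isolates <- function(path, min_score = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  isolate_records(utils::read.delim(path, stringsAsFactors = FALSE),
                  min_score = min_score)
}
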
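#' Intramammary infection status from colony counts
#'
#' A quarter milk sample is classified as infected when more than 10 colonies
#' per 0.1 mL plated milk grew in at least one of the two incubation
#' conditions (aerobic/anaerobic TSA blood agar), i.e. its colony class is
#' `c10_lt100` or higher. Samples with no colony record are `unknown` and are
#' excluded from infected/not-infected groupings downstream.
#'
#' @param colony validated [colony_records] data.frame.
#' @param sample_ids samples to classify; defaults to those present in
#'   `colony`.
#' @return data.frame with `sample_id`, `status` (infected / not_infected /
#'   unknown) and `triggering` (conditions whose class met the threshold,
#'   comma-separated).
#' @export
classify_imi <- function(colony, sample_ids = unique(colony$sample_id)) {
  thr <- which(COLONY_CLASSES == "c10_lt100")
  res <- lapply(sample_ids, function(s) {
    rec <- colony[colony$sample_id == s, , drop = FALSE]
    if (nrow(rec) == 0L)
      return(data.frame(sample_id = s, status = "unknown", triggering = "",
                        stringsAsFactors = FALSE))
    hit <- as.integer(rec$colony_class) >= thr
    data.frame(sample_id = s,
               status = if (any(hit)) "infected" else "not_infected",
               triggering = paste(rec$condition[hit], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' PERMANOVA of microbiota composition against infection status
#'
#' Tests whether community composition differs between culture-infected and
#' not-infected quarter samples; `unknown` samples are excluded. Delegates to
#' [permanova].
#'
#' @param d dissimilarity matrix over samples.
#' @param imi data.frame from [classify_imi].
#' @inheritParams permanova
#' @return [permanova] result on the infected/not-infected grouping.
#' @export
imi_microbiota_association <- function(d, imi, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  status <- stats::setNames(imi$status, imi$sample_id)[rownames(d)]
  use <- !is.na(status) & status %in% c("infected", "not_infected")
  status <- status[use]
  if (length(unique(status)) < 2L)
    stop("need both infected and not-infected samples")
  if (min(table(status)) < 2L)
    stop("need at least 2 samples per infection status")
  permanova(d[use, use, drop = FALSE], status, n_perm = n_perm, seed = seed)
}
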
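#' Dysbiotic-quarter calling
#'
#' A quarter of a cow's udder is flagged as dysbiotic when, within the same
#' cow and sampling period, one bacterial family takes over more than 60% of
#' that quarter's reads while staying below 20% in every other available
#' quarter. Both thresholds are strict, the rule is applied per family
#' independently, and a cow-period is evaluated only when 3 or 4 quarter
#' samples are available. Family shares are computed from raw filtered read
#' counts (the rule is defined on percent of reads), never from normalized
#' values.
#'
#' @name dysbiosis
NULL

#' Split samples into per-cow-period quarter sets
#'
#' @param relab samples x families relative-abundance matrix (rows sum to 1).
#' @param metadata [sample_metadata] covering the rows; only specimens are
#'   used.
#' @return named list of `quarter_set` objects, each with `cow_id`, `period`
#'   and `quarters` (quarters x families proportion matrix, rownames LF/LR/
#'   RF/RR subset) plus per-quarter `sample_id`s.
#' @export
quarter_sets <- function(relab, metadata) {
  md <- metadata[metadata$role == "specimen" &
                   metadata$sample_id %in% rownames(relab), , drop = FALSE]
  keys <- paste(md$cow_id, md$period, sep = "|")
  out <- lapply(split(seq_len(nrow(md)), keys), function(idx) {
    rows <- md[idx, , drop = FALSE]
    q <- relab[rows$sample_id, , drop = FALSE]
    rownames(q) <- rows$quarter
    structure(list(cow_id = rows$cow_id[1L], period = rows$period[1L],
                   quarters = q,
                   sample_ids = stats::setNames(rows$sample_id, rows$quarter)),
              class = "quarter_set")
  })
  out
}

#' Call dysbiotic quarters within one cow-period
#'
#' For each family F and each available quarter q, a call is emitted iff F's
#' share in q strictly exceeds `dominant_thr` while staying strictly below
#' `background_thr` in every other available quarter. A cow-period with fewer
#' than 3 quarters is returned as "not evaluated" — a distinct state from
#' "evaluated, no call", so the evaluation denominator stays computable.
#'
#' @param qs a `quarter_set` (see [quarter_sets]).
#' @param dominant_thr strict lower bound on the dominant family's share.
#' @param background_thr strict upper bound on the family's share in all
#'   other quarters.
#' @return list with `evaluated` (logical), `n_quarters`, and `calls`
#'   (data.frame: cow_id, period, quarter, family, dominant_fraction,
#'   max_other_fraction, n_quarters_evaluated).
#' @export
call_dysbiotic_quarters <- function(qs, dominant_thr = 0.60,
                                    background_thr = 0.20) {
  q <- qs$quarters
  empty <- data.frame(cow_id = character(), period = integer(),
                      quarter = character(), family = character(),
                      dominant_fraction = numeric(),
                      max_other_fraction = numeric(),
                      n_quarters_evaluated = integer(),
                      stringsAsFactors = FALSE)
  if (any(abs(rowSums(q) - 1) > 1e-8))
    stop(sprintf("quarter proportions of cow %s period %s do not sum to 1",
                 qs$cow_id, qs$period))
  nq <- nrow(q)
  if (nq < 3L || nq > 4L)
    return(list(evaluated = FALSE, n_quarters = nq, calls = empty))
  calls <- empty
  for (fam in colnames(q)) {
    share <- q[, fam]
    for (i in seq_len(nq)) {
      others <- share[-i]
      if (share[i] > dominant_thr && all(others < background_thr)) {
        calls <- rbind(calls, data.frame(
          cow_id = qs$cow_id, period = qs$period,
          quarter = rownames(q)[i], family = fam,
          dominant_fraction = unname(share[i]),
          max_other_fraction = unname(max(others)),
          n_quarters_evaluated = nq, stringsAsFactors = FALSE))
      }
    }
  }
  list(evaluated = TRUE, n_quarters = nq, calls = calls)
}

#' Run the dysbiosis caller over a whole dataset
#'
#' @param relab samples x families relative-abundance matrix.
#' @param metadata [sample_metadata].
#' @inheritParams call_dysbiotic_quarters
#' @return list with `calls` (row-bound call table), `n_evaluated`,
#'   `n_not_evaluated`, and `per_set` (raw per-cow-period results).
#' @export
call_dysbiosis <- function(relab, metadata, dominant_thr = 0.60,
                           background_thr = 0.20) {
  sets <- quarter_sets(relab, metadata)
  res <- lapply(sets, call_dysbiotic_quarters,
                dominant_thr = dominant_thr, background_thr = background_thr)
  calls <- do.call(rbind, c(lapply(res, `[[`, "calls"),
                            list(make.row.names = FALSE)))
  list(calls = calls,
       n_evaluated = sum(vapply(res, `[[`, TRUE, "evaluated")),
       n_not_evaluated = sum(!vapply(res, `[[`, TRUE, "evaluated")),
       per_set = res)
}

#' Summarize dysbiosis calls
#'
#' @param x result of [call_dysbiosis].
#' @return list with `n_evaluated` (cow-periods with 3-4 quarters),
#'   `n_dysbiotic` (number of calls) and `per_family` (named call counts).
#' @export
dysbiosis_summary <- function(x) {
  per_family <- if (nrow(x$calls) > 0L) {
    tab <- table(x$calls$family)
    stats::setNames(as.integer(tab), names(tab))
  } else integer()
  list(n_evaluated = x$n_evaluated,
       n_dysbiotic = nrow(x$calls),
       per_family = sort(per_family, decreasing = TRUE))
}
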
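#' Sequence-variant count table
#'
#' The central object of the pipeline: a samples x SVs matrix of nonnegative
#' integer read counts together with the amplicon length (bases) of every SV.
#' Counts stay integral through all QC steps; normalized (real-valued)
#' abundances are a separate downstream object and are never written back.
#'
#' @param counts integer matrix, samples in rows (rownames = sample ids),
#'   sequence variants in columns (colnames = SV ids).
#' @param sv_length named integer vector giving the sequence length in bases
#'   for every SV in `counts`.
#' @return An object of class `sv_table`: a list with elements `counts` and
#'   `sv_length`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("sv1", "sv2")))
#' sv_table(m, c(sv1 = 400L, sv2 = 380L))
#' @export
sv_table <- function(counts, sv_length) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  x <- structure(list(counts = counts, sv_length = sv_length),
                 class = "sv_table")
  validate_sv_table(x)
}

#' @export
print.sv_table <- function(x, ...) {
  cat(sprintf("<sv_table> %d samples x %d SVs, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Validate an sv_table
#'
#' Checks the class invariants: nonnegative integral counts, unique non-empty
#' sample and SV identifiers, and a length entry for every SV. Errors name the
#' offending sample or SV.
#'
#' @param x an `sv_table`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_sv_table <- function(x) {
  counts <- x$counts
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("sv_table counts must carry sample ids (rownames) and SV ids (colnames)")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("sv_table must have at least one sample and one SV")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicated SV id: ", colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("count for sample '%s', SV '%s' is not a nonnegative integer: %s",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
                 format(counts[bad[1L, , drop = FALSE]])))
  missing_len <- setdiff(colnames(counts), names(x$sv_length))
  if (length(missing_len) > 0L)
    stop("no length entry for SV: ", missing_len[1L])
  len <- x$sv_length[colnames(counts)]
  if (any(!is.finite(len) | len <= 0 | len != round(len)))
    stop("SV lengths must be positive integers; offending SV: ",
         colnames(counts)[which(!is.finite(len) | len <= 0 | len != round(len))[1L]])
  x$sv_length <- len
  invisible(x)
}

#' Read an SV count table
#'
#' Reads a samples x SVs count table from tab-separated text or BIOM-JSON.
#' Orientation is normalized to samples x SVs: a TSV whose header starts with
#' `sv_id` is transposed on read. SV lengths come from a companion two-column
#' TSV (`sv_id`, `length`) or, for BIOM files, from a `length` field in the
#' observation metadata.
#'
#' @param path path to the count table.
#' @param format `"tsv"` or `"biom-json"`.
#' @param lengths path to a two-column TSV of SV lengths, or a named integer
#'   vector. Optional for BIOM files carrying observation metadata.
#' @return a validated [sv_table].
#' @export
read_sv_table <- function(path, format = c("tsv", "biom-json"), lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    id_col <- names(df)[1L]
    if (!id_col %in% c("sample_id", "sv_id"))
      stop("first column of an SV table must be 'sample_id' or 'sv_id', got '",
           id_col, "'")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    if (id_col == "sv_id") m <- t(m)
    if (!is.numeric(m))
      stop("non-numeric count in SV table '", path, "'")
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required to read BIOM files")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # biom stores obs x samples
    if (is.null(lengths)) {
      om <- biomformat::observation_metadata(b)
      if (!is.null(om) && "length" %in% colnames(om))
        lengths <- stats::setNames(as.integer(om[colnames(m), "length"]),
                                   colnames(m))
    }
  }
  if (is.character(lengths) && length(lengths) == 1L) {
    ldf <- utils::read.delim(lengths, stringsAsFactors = FALSE)
    if (!all(c("sv_id", "length") %in% names(ldf)))
      stop("SV length file must have columns 'sv_id' and 'length'")
    lengths <- stats::setNames(as.integer(ldf$length), as.character(ldf$sv_id))
  }
  if (is.null(lengths))
    stop("SV lengths are required (companion file, named vector, or BIOM metadata)")
  sv_table(m, lengths)
}

#' Write an SV count table (and its lengths) as TSV
#'
#' @param x an [sv_table].
#' @param path output path for the counts (samples x SVs, header
#'   `sample_id` + SV ids).
#' @param lengths_path optional output path for the two-column length table.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(x, path, lengths_path = NULL) {
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path)) {
    ldf <- data.frame(sv_id = names(x$sv_length),
                      length = as.integer(x$sv_length))
    utils::write.table(ldf, lengths_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Per-sample read totals
#'
#' @param x an [sv_table] or a counts matrix (samples x SVs).
#' @return named numeric vector of per-sample total reads.
#' @export
sample_depths <- function(x) {
  m <- if (inherits(x, "sv_table")) x$counts else x
  rowSums(m)
}
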
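#' Cumulative sum scaling (CSS) normalization
#'
#' For each sample, the scaling factor is the sum of its counts up to the
#' sample's `quantile`-th quantile of nonzero counts; each count is divided by
#' that factor and multiplied by `scale`. This damps the influence of a few
#' very deep samples / dominant features compared to total-sum scaling. The
#' quantile is fixed (default median of nonzero counts) rather than chosen
#' adaptively.
#'
#' @param x an [sv_table] or samples x features count matrix.
#' @param quantile quantile (in \[0,1\]) of the nonzero counts up to which
#'   counts are summed.
#' @param scale multiplier applied after division.
#' @return list with `normalized` (real-valued matrix, same shape) and
#'   `factors` (named per-sample scaling sums).
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 100), 1, 5,
#'             dimnames = list("s1", paste0("sv", 1:5)))
#' css_normalize(m)$factors  # median of nonzero counts is 3 -> 1+2+3 = 6
#' @export
css_normalize <- function(x, quantile = 0.5, scale = 1000) {
  m <- if (inherits(x, "sv_table")) x$counts else as.matrix(x)
  factors <- apply(m, 1L, function(cnt) {
    nz <- cnt[cnt > 0]
    if (length(nz) == 0L) return(0)
    q <- stats::quantile(nz, quantile, names = FALSE)
    sum(cnt[cnt <= q])
  })
  if (any(factors == 0))
    stop("zero CSS scaling factor for sample: ",
         rownames(m)[which(factors == 0)[1L]])
  list(normalized = sweep(m, 1L, factors, "/") * scale,
       factors = stats::setNames(factors, rownames(m)))
}

#' Chao1 richness estimate (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1`/`F2` are the numbers of
#' singleton/doubleton features; finite even when no doubletons are observed.
#'
#' @param counts nonnegative integer vector of feature counts for one sample.
#' @return the richness estimate (>= observed richness).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("chao1 requires nonnegative integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' @param counts nonnegative vector with positive total.
#' @return `-sum(p log p)` over nonzero proportions.
#' @export
shannon <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0)
    stop("shannon requires nonnegative counts with positive total")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Per-sample alpha diversity table
#'
#' @param x an [sv_table] or counts matrix (samples x features).
#' @return data.frame with `sample_id`, `richness`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  m <- if (inherits(x, "sv_table")) x$counts else as.matrix(x)
  data.frame(sample_id = rownames(m),
             richness = rowSums(m > 0),
             chao1 = apply(m, 1L, chao1),
             shannon = apply(m, 1L, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum |x - y| / sum (x + y)`; in \[0, 1\] for nonnegative input. Not a
#' metric (the triangle inequality can fail), which is why no triangle
#' property is claimed anywhere in the package.
#'
#' @param x,y equal-length nonnegative vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("negative abundance")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Jaccard dissimilarity on presence/absence
#'
#' `1 - |A intersect B| / |A union B|` over the two presence sets.
#'
#' @inheritParams bray_curtis
#' @return dissimilarity in \[0, 1\].
#' @export
jaccard_binary <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  a <- x > 0; b <- y > 0
  u <- sum(a | b)
  if (u == 0) stop("both vectors are all-zero")
  1 - sum(a & b) / u
}

#' Pairwise dissimilarity matrix
#'
#' @param m samples x features nonnegative matrix.
#' @param metric `"bray"` or `"jaccard"`.
#' @return symmetric `distance_matrix` (zero diagonal, sample ids as
#'   dimnames).
#' @export
distance_matrix <- function(m, metric = c("bray", "jaccard")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative abundance")
  if (any(rowSums(m) == 0))
    stop("all-zero sample: ", rownames(m)[which(rowSums(m) == 0)[1L]])
  if (metric == "bray") {
    num <- as.matrix(stats::dist(m, method = "manhattan"))
    rs <- rowSums(m)
    d <- num / outer(rs, rs, "+")
  } else {
    a <- m > 0
    inter <- tcrossprod(a)
    union <- outer(rowSums(a), rowSums(a), "+") - inter
    d <- 1 - inter / union
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(d, class = c("distance_matrix", class(d)))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centered matrix `-1/2 J D^2 J`; axes with
#' eigenvalue <= 0 (within numerical tolerance) are dropped, so the returned
#' coordinates give a best Euclidean embedding of the positive part of the
#' dissimilarity structure.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [distance_matrix]).
#' @return list of class `ordination` with `coordinates` (samples x axes,
#'   column-centered, ordered by decreasing eigenvalue), `eigenvalues` and
#'   `method`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix is not symmetric")
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  keep <- which(e$values > tol)
  if (length(keep) == 0L) stop("no positive eigenvalue: degenerate input")
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = e$values[keep],
                 method = "pcoa"),
            class = "ordination")
}

#' Pearson correlations among the most abundant families
#'
#' Restricted to families with mean relative abundance above `min_mean_pct`
#' percent, then the `top_k` most abundant of those (ties in mean abundance
#' broken lexicographically by family name). Zero-variance families yield NA
#' correlations.
#'
#' @param relab samples x families relative-abundance matrix.
#' @param top_k number of families to correlate.
#' @param min_mean_pct minimum mean relative abundance, in percent.
#' @return symmetric correlation matrix over the selected families.
#' @export
family_correlations <- function(relab, top_k = 30, min_mean_pct = 0.5) {
  if (nrow(relab) < 3L) stop("need at least 3 samples for correlations")
  mu <- colMeans(relab) * 100
  cand <- names(mu)[mu >= min_mean_pct]
  if (length(cand) == 0L) stop("no family above min_mean_pct")
  cand <- cand[order(-mu[cand], cand)]
  sel <- utils::head(cand, top_k)
  r <- suppressWarnings(stats::cor(relab[, sel, drop = FALSE],
                                   method = "pearson"))
  r
}
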
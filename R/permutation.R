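#' Permutation statistics on dissimilarity matrices
#'
#' PERMANOVA (pseudo-F from squared-distance partitioning), multivariate
#' homogeneity of group dispersions, Procrustes comparison of ordinations
#' with a PROTEST permutation test, and the rank-sum comparison used for
#' alpha diversity. Sampled permutation p-values use the add-one estimator
#' `(1 + b) / (1 + B)`; when the number of distinct group relabelings is
#' small enough they are replaced by exhaustive enumeration.
#'
#' @name permutation
NULL

# squared-distance partitioning: SS_total and per-permutation SS_within.
# labels_mat: n x B matrix of group labelings (columns are permutations).
ss_within <- function(d2, labels_mat) {
  n <- nrow(d2)
  groups <- unique(as.vector(labels_mat))
  ssw <- numeric(ncol(labels_mat))
  for (g in groups) {
    u <- (labels_mat == g) * 1
    ng <- colSums(u)
    ssw <- ssw + ifelse(ng > 0, colSums(u * (d2 %*% u)) / (2 * ng), 0)
  }
  ssw
}

pseudo_f <- function(ss_t, ssw, n, k) {
  ((ss_t - ssw) / (k - 1)) / (ssw / (n - k))
}

# all distinct assignments of labels to n positions with the given group
# sizes, as an n x (multinomial coefficient) matrix
enumerate_labelings <- function(labels) {
  sizes <- table(labels)
  rec <- function(pos, lev) {
    if (length(lev) == 1L)
      return(matrix(lev, length(pos), 1L,
                    dimnames = list(as.character(pos), NULL)))
    g <- lev[1L]; ng <- sizes[[g]]
    picks <- utils::combn(length(pos), ng)
    cols <- vector("list", ncol(picks))
    for (j in seq_len(ncol(picks))) {
      take <- pos[picks[, j]]
      rest <- rec(pos[-picks[, j]], lev[-1L])
      blk <- matrix(NA_character_, length(pos), ncol(rest),
                    dimnames = list(as.character(pos), NULL))
      blk[as.character(take), ] <- g
      blk[rownames(rest), ] <- rest
      cols[[j]] <- blk
    }
    do.call(cbind, cols)
  }
  rec(seq_along(labels), names(sizes))
}

n_distinct_labelings <- function(labels) {
  sizes <- table(labels)
  exp(lfactorial(length(labels)) - sum(lfactorial(sizes)))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA: the pseudo-F statistic partitions the sum of squared
#' dissimilarities into between- and within-group components; significance is
#' assessed by permuting group labels. When the number of distinct labelings
#' is at most `n_perm`, all of them are enumerated and the p-value is the
#' exact fraction of labelings with F at least as large as observed;
#' otherwise `n_perm` random permutations are drawn and
#' `p = (1 + b) / (1 + B)`.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each non-empty).
#' @param n_perm number of permutations.
#' @param seed integer seed for the label permutations.
#' @return list with `pseudo_f`, `p_value`, `n_perm_used`, `exhaustive`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length does not match the matrix")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  d2 <- d^2
  ss_t <- sum(d2) / (2 * n)
  k <- length(unique(groups))
  f_obs <- pseudo_f(ss_t, ss_within(d2, matrix(groups, n, 1L)), n, k)
  n_exact <- n_distinct_labelings(groups)
  if (n_exact <= n_perm) {
    labs <- enumerate_labelings(groups)
    f_perm <- pseudo_f(ss_t, ss_within(d2, labs), n, k)
    tol <- 1e-8 * max(1, abs(f_obs[is.finite(f_obs)]), na.rm = TRUE)
    hits <- sum(f_perm >= f_obs - tol | (is.infinite(f_obs) & is.infinite(f_perm)))
    return(list(pseudo_f = f_obs, p_value = hits / ncol(labs),
                n_perm_used = ncol(labs), exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  labs <- vapply(seq_len(n_perm), function(i) sample(groups),
                 character(n))
  f_perm <- pseudo_f(ss_t, ss_within(d2, labs), n, k)
  tol <- 1e-8 * max(1, abs(f_obs[is.finite(f_obs)]), na.rm = TRUE)
  hits <- sum(f_perm >= f_obs - tol | (is.infinite(f_obs) & is.infinite(f_perm)))
  list(pseudo_f = f_obs, p_value = (1 + hits) / (1 + n_perm),
       n_perm_used = n_perm, exhaustive = FALSE)
}

#' Multivariate homogeneity of group dispersions
#'
#' Samples are embedded by [pcoa] (axes with non-positive eigenvalues
#' dropped); each sample's dispersion is its Euclidean distance to its own
#' group centroid in that embedding. A one-way F statistic on the dispersions
#' is tested by permuting group membership of the dispersions. Groups of size
#' 1 get dispersion 0 but are excluded from the F test (with a warning).
#'
#' @inheritParams permanova
#' @return list with `distances` (named per-sample dispersion), `f_value`,
#'   `p_value`, `groups_used`.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length does not match the matrix")
  coords <- pcoa(d)$coordinates
  dist_to_centroid <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(coords[idx, , drop = FALSE])
    dist_to_centroid[idx] <-
      sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2L, cen)^2))
  }
  names(dist_to_centroid) <- rownames(d)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0L)
    warning("group(s) of size 1 excluded from the dispersion F test: ",
            paste(small, collapse = ", "))
  use <- groups %in% names(sizes)[sizes >= 2]
  z <- dist_to_centroid[use]
  gz <- groups[use]
  if (length(unique(gz)) < 2L) stop("fewer than 2 groups with >= 2 samples")
  f_obs <- anova_f(z, gz)
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) anova_f(z, sample(gz)),
                   numeric(1L))
  tol <- 1e-8 * max(1, abs(f_obs))
  p <- (1 + sum(f_perm >= f_obs - tol)) / (1 + n_perm)
  list(distances = dist_to_centroid, f_value = f_obs, p_value = p,
       groups_used = unique(gz))
}

anova_f <- function(y, g) {
  g <- as.factor(g)
  n <- length(y); k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Procrustes comparison of two ordinations, with PROTEST
#'
#' Finds the translation, orthogonal rotation and uniform scaling of `y` that
#' minimize the residual sum of squares against `x`, after normalizing both
#' configurations (centered, unit total sum of squares) so the statistic is
#' symmetric in its arguments. `m2` is the normalized residual
#' `1 - (sum of singular values)^2`; the PROTEST p-value permutes the rows of
#' `y`.
#'
#' @param x,y `ordination` objects or coordinate matrices over the same
#'   samples (matched by rownames when present). `y` is truncated or
#'   zero-padded to `x`'s axis count.
#' @param n_perm number of row permutations for PROTEST.
#' @param seed integer seed.
#' @return list with `m2`, `rotation`, `scaling`, `p_value`.
#' @export
procrustes_protest <- function(x, y, n_perm = 999, seed = NULL) {
  cx <- if (inherits(x, "ordination")) x$coordinates else as.matrix(x)
  cy <- if (inherits(y, "ordination")) y$coordinates else as.matrix(y)
  if (!is.null(rownames(cx)) && !is.null(rownames(cy))) {
    shared <- intersect(rownames(cx), rownames(cy))
    if (length(shared) < 3L) stop("fewer than 3 shared samples")
    cx <- cx[shared, , drop = FALSE]
    cy <- cy[shared, , drop = FALSE]
  }
  if (nrow(cx) != nrow(cy)) stop("ordinations cover different sample sets")
  if (nrow(cx) < 3L) stop("fewer than 3 shared samples")
  if (ncol(cy) < ncol(cx))
    cy <- cbind(cy, matrix(0, nrow(cy), ncol(cx) - ncol(cy)))
  cy <- cy[, seq_len(ncol(cx)), drop = FALSE]
  norm_cfg <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  cx <- norm_cfg(cx); cy <- norm_cfg(cy)
  stat <- function(a, b) {
    s <- svd(crossprod(a, b))
    list(m2 = 1 - sum(s$d)^2, rot = s$v %*% t(s$u), scaling = sum(s$d))
  }
  obs <- stat(cx, cy)
  if (!is.null(seed)) set.seed(seed)
  m2_perm <- vapply(seq_len(n_perm), function(i) {
    stat(cx, norm_cfg(cy[sample(nrow(cy)), , drop = FALSE]))$m2
  }, numeric(1L))
  p <- (1 + sum(m2_perm <= obs$m2 + 1e-12)) / (1 + n_perm)
  list(m2 = obs$m2, rotation = obs$rot, scaling = obs$scaling, p_value = p)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Exact two-sided p-value by full enumeration of rank splits when
#' `n1 + n2 <= max_exact` (ties handled via midranks); otherwise the
#' tie-corrected normal approximation of [stats::wilcox.test]. The statistic
#' is the Mann-Whitney U of the first group.
#'
#' @param x,y numeric samples for the two groups.
#' @param max_exact largest combined size for the enumeration branch.
#' @return list with `statistic` (U), `p_value`, `exact`.
#' @export
compare_alpha <- function(x, y, max_exact = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  v <- c(x, y)
  if (length(unique(v)) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(list(statistic = n1 * n2 / 2, p_value = 1, exact = TRUE))
  }
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= max_exact) {
    mu <- n1 * n2 / 2
    splits <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p_value = p, exact = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(statistic = u_obs, p_value = wt$p.value, exact = FALSE)
}
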
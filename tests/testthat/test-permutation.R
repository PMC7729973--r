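test_that("PERMANOVA exhaustive p equals full enumeration", {
  # two groups of 3: within-group distances 0, between 1 -> p = 2/20
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  g <- rep(c("x", "y"), each = 3)
  res <- permanova(d, g, n_perm = 999)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, 20L)
  expect_equal(res$p_value, 0.1)

  # random small instances match the brute-force oracle exactly
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(rpois(8 * 6, 4) + 1, 8, 6,
                dimnames = list(paste0("s", 1:8), paste0("f", 1:6)))
    d <- distance_matrix(m, "bray")
    g <- rep(c("x", "y"), each = 4)
    res <- permanova(d, g, n_perm = 999)
    expect_true(res$exhaustive)
    expect_equal(res$pseudo_f, oracle_pseudo_f(unclass(d), g))
    expect_equal(res$p_value, oracle_exhaustive_p(unclass(d), g))
  }
})

test_that("PERMANOVA handles exchangeable distances and matches vegan F", {
  # all pairwise distances equal: every relabeling gives the same F
  d <- matrix(0.7, 6, 6); diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  res <- permanova(d, rep(c("x", "y"), each = 3), n_perm = 999)
  expect_equal(res$p_value, 1)

  set.seed(14)
  m <- matrix(rpois(20 * 12, 5) + 1, 20, 12,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:12)))
  d <- distance_matrix(m, "bray")
  g <- rep(c("x", "y"), each = 10)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_false(res$exhaustive)

  # three groups also match the oracle F
  g3 <- rep(c("x", "y", "z"), times = c(7, 7, 6))
  res3 <- permanova(d, g3, n_perm = 99, seed = 1)
  expect_equal(res3$pseudo_f, oracle_pseudo_f(unclass(d), g3))
  ref3 <- vegan::adonis2(stats::as.dist(d) ~ g3, permutations = 99)
  expect_equal(res3$pseudo_f, ref3$F[1], tolerance = 1e-10)
})

test_that("beta dispersion: degenerate groups, scaling, vegan agreement", {
  # identical samples within a group -> zero dispersion
  m <- rbind(a1 = c(5, 1, 0), a2 = c(5, 1, 0), a3 = c(5, 1, 0),
             b1 = c(0, 4, 4), b2 = c(1, 2, 6), b3 = c(0, 5, 3))
  colnames(m) <- paste0("f", 1:3)
  d <- distance_matrix(m, "bray")
  res <- beta_dispersion(d, rep(c("a", "b"), each = 3), n_perm = 99,
                         seed = 1)
  expect_true(all(res$distances[1:3] < 1e-9))

  # doubling distances doubles every centroid distance
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  de <- as.matrix(dist(pts))
  g <- rep(c("x", "y"), each = 6)
  r1 <- beta_dispersion(de, g, n_perm = 49, seed = 1)
  r2 <- beta_dispersion(2 * de, g, n_perm = 49, seed = 1)
  expect_equal(r2$distances, 2 * r1$distances, tolerance = 1e-9)

  # Euclidean-embeddable input agrees with vegan::betadisper
  ref <- vegan::betadisper(stats::as.dist(de), g, type = "centroid")
  expect_equal(unname(r1$distances), unname(ref$distances),
               tolerance = 1e-8)

  # singleton group is excluded from F with a warning
  expect_warning(
    r3 <- beta_dispersion(de, c(rep("x", 6), rep("y", 5), "z"),
                          n_perm = 49, seed = 1),
    "size 1")
  expect_equal(unname(r3$distances["s12"]), 0)
})

test_that("Procrustes recovers rotated/scaled copies and is symmetric", {
  set.seed(15)
  x <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("s", 1:15), NULL))
  th <- 37 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  y <- 2.5 * x %*% rot + matrix(rep(c(3, -1), each = 15), 15, 2)
  res <- procrustes_protest(x, y, n_perm = 99, seed = 1)
  expect_lt(res$m2, 1e-10)

  # symmetry of m2 under swapping the configurations
  y2 <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("s", 1:15), NULL))
  r12 <- procrustes_protest(x, y2, n_perm = 49, seed = 1)
  r21 <- procrustes_protest(y2, x, n_perm = 49, seed = 1)
  expect_equal(r12$m2, r21$m2, tolerance = 1e-10)

  # vegan::protest computes the same statistic
  ref <- vegan::protest(x, y2, permutations = 49)
  expect_equal(r12$m2, ref$ss, tolerance = 1e-10)

  # unrelated configurations: m2 near 1, p not small
  expect_gt(r12$m2, 0.5)
  expect_gt(r12$p_value, 0.05)
  expect_error(procrustes_protest(x[1:2, ], y[1:2, ]), "3 shared")
})

test_that("null calibration: PERMANOVA and dispersion keep nominal size", {
  # modest replicate count here; the full calibration run lives in the
  # acceptance suite
  set.seed(16)
  n_rep <- 60
  rej_p <- 0; rej_d <- 0
  for (r in seq_len(n_rep)) {
    m <- matrix(rpois(16 * 10, 6) + 1, 16, 10,
                dimnames = list(paste0("s", 1:16), paste0("f", 1:10)))
    d <- distance_matrix(m, "bray")
    g <- sample(rep(c("x", "y"), each = 8))
    rej_p <- rej_p + (permanova(d, g, 99, seed = r)$p_value <= 0.05)
    rej_d <- rej_d + (beta_dispersion(d, g, 99, seed = r)$p_value <= 0.05)
  }
  # 3 binomial SEs around 0.05 with n = 60 is roughly [0, 0.13]
  expect_lt(rej_p / n_rep, 0.14)
  expect_lt(rej_d / n_rep, 0.14)
})
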
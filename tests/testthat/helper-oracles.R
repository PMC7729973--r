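# independent brute-force oracles used by both the unit and acceptance suites

# pseudo-F by direct double loop over sample pairs
oracle_pseudo_f <- function(d, groups) {
  n <- nrow(d); k <- length(unique(groups))
  ss_t <- 0; ss_w <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d[idx[a], idx[b]]^2
    ss_w <- ss_w + s / length(idx)
  }
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}

# exhaustive two-group permutation p over every distinct labeling
oracle_exhaustive_p <- function(d, groups) {
  n <- length(groups)
  n1 <- sum(groups == unique(groups)[1])
  f_obs <- oracle_pseudo_f(d, groups)
  splits <- utils::combn(n, n1)
  f_all <- apply(splits, 2, function(s) {
    g <- rep(unique(groups)[2], n)
    g[s] <- unique(groups)[1]
    oracle_pseudo_f(d, g)
  })
  mean(f_all >= f_obs - 1e-10 | (is.infinite(f_obs) & is.infinite(f_all)))
}
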
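# 1-D Gaussian mixture machinery shared by the copy-number calibration, the
# LOH naive-Bayes classifier and the read-depth-ratio homozygous-deletion
# model.

# EM for a univariate Gaussian mixture with fixed component count.
# Initialization assigns points to the nearest of `init_means` (k-means
# style single pass), then iterates standard EM. Deterministic given data and
# init_means. sd floor avoids collapse on near-duplicate data.
fit_gmm_1d <- function(x, init_means, tol = 1e-6, max_iter = 500,
                       sd_floor = 1e-4) {
  x <- x[is.finite(x)]
  k <- length(init_means)
  stopifnot(length(x) >= k)
  assign0 <- apply(abs(outer(x, init_means, "-")), 1, which.min)
  w <- tabulate(assign0, k) / length(x)
  mu <- vapply(seq_len(k), function(j) {
    if (any(assign0 == j)) mean(x[assign0 == j]) else init_means[j]
  }, numeric(1))
  sg <- vapply(seq_len(k), function(j) {
    if (sum(assign0 == j) > 1) stats::sd(x[assign0 == j]) else stats::sd(x) / k
  }, numeric(1))
  sg <- pmax(sg, sd_floor, na.rm = TRUE)
  w <- pmax(w, 1e-12)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sg[j])
    }, numeric(length(x)))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    w <- pmax(nk / length(x), 1e-12)
    # components that lose all responsibility keep their parameters
    upd <- nk > 1e-8
    mu[upd] <- (colSums(r * x) / nk)[upd]
    sg[upd] <- sqrt(colSums(r * (outer(x, mu, "-")^2)) / nk)[upd]
    sg <- pmax(sg, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sg, loglik = ll, n_iter = it)
}

# Posterior probability of component j for new points.
gmm_posterior <- function(fit, x, component = 1) {
  k <- length(fit$means)
  dens <- vapply(seq_len(k), function(j) {
    fit$weights[j] * stats::dnorm(x, fit$means[j], fit$sds[j])
  }, numeric(length(x)))
  dens <- matrix(dens, ncol = k)
  tot <- rowSums(dens)
  out <- dens[, component] / tot
  out[tot == 0] <- NA_real_
  out
}

# Equal-weighted-density crossing between two Gaussian components, restricted
# to the open interval between their means. Closed-form solution of
# w1 N(x; m1, s1) = w2 N(x; m2, s2) (quadratic in x; linear when s1 == s2).
gmm_crossing <- function(w1, m1, s1, w2, m2, s2) {
  stopifnot(m1 < m2)
  if (isTRUE(all.equal(s1, s2))) {
    # linear case: (m2^2 - m1^2 - 2 s^2 log(w1/w2)) / (2 (m2 - m1))
    x <- (m2^2 - m1^2 - 2 * s1^2 * log(w1 / w2)) / (2 * (m2 - m1))
    if (x <= m1 || x >= m2) return(NA_real_)
    return(x)
  }
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log((w1 * s2) / (w2 * s1))
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  roots <- roots[roots > m1 & roots < m2]
  if (length(roots) == 0) return(NA_real_)
  roots[1]
}

# Equal-tail-mass alternative: the point x between the means where
# P(X1 > x) = P(X2 < x), i.e. the two components' error masses balance.
gmm_tail_crossing <- function(m1, s1, m2, s2) {
  stopifnot(m1 < m2)
  f <- function(x) stats::pnorm(x, m1, s1, lower.tail = FALSE) -
    stats::pnorm(x, m2, s2)
  stats::uniroot(f, c(m1, m2), tol = 1e-10)$root
}
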
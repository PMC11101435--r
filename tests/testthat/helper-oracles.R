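# Independent oracles used to check the package's own implementations.

# Exhaustive circular-arc scan, written independently of the compiled
# implementation: vectorized over all (i, j) arc pairs via cumulative sums.
oracle_arc_scan <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  S <- c(0, cumsum(x))
  idx <- which(upper.tri(matrix(0, n + 1, n + 1)), arr.ind = TRUE)
  i <- idx[, 1] - 1L
  j <- idx[, 2] - 1L
  k <- j - i
  keep <- k >= 1 & k <= n - 1
  i <- i[keep]; j <- j[keep]; k <- k[keep]
  mean_in <- (S[j + 1] - S[i + 1]) / k
  mean_out <- (S[n + 1] - S[j + 1] + S[i + 1]) / (n - k)
  tt <- abs(mean_in - mean_out) / (s * sqrt(1 / k + 1 / (n - k)))
  b <- which.max(tt)
  list(i = i[b], j = j[b], tmax = tt[b])
}

# permutation p value with the same sequential stopping rule as the
# implementation under test, but independent code
oracle_perm_p <- function(x, tmax, nperm, alpha) {
  exceed <- 0
  for (p in seq_len(nperm)) {
    best <- oracle_arc_scan(sample(x))$tmax
    if (best >= tmax) exceed <- exceed + 1
    if (exceed > alpha * nperm) return(1)
    if (p >= 200 && exceed == 0) return(0)
  }
  exceed / nperm
}

# full exhaustive-search segmentation: recursion + undo, independent code;
# `crit` switches to the deterministic fixed-threshold acceptance rule
oracle_cbs <- function(x, alpha = 0.01, nperm = 1000, undo_sd = 3,
                       crit = NULL) {
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 4 || stats::sd(x[lo:hi]) == 0) return(integer())
    sc <- oracle_arc_scan(x[lo:hi])
    accept <- if (is.null(crit)) {
      oracle_perm_p(x[lo:hi], sc$tmax, nperm, alpha) < alpha
    } else {
      sc$tmax >= crit
    }
    if (!accept) {
      return(integer())
    }
    bps <- sort(unique(c(if (sc$i > 0) sc$i, if (sc$j < n) sc$j)))
    out <- bps + lo - 1
    bounds <- c(lo - 1, bps + lo - 1, hi)
    for (s in seq_len(length(bounds) - 1)) {
      out <- c(out, recurse(bounds[s] + 1, bounds[s + 1]))
    }
    sort(unique(out))
  }
  bps <- recurse(1, length(x))
  # undo rule: merge weakest adjacent pair while below threshold
  sd_est <- stats::mad(diff(x)) / sqrt(2)
  repeat {
    if (length(bps) == 0) return(bps)
    bounds <- c(0, bps, length(x))
    mns <- vapply(seq_len(length(bounds) - 1), function(s) {
      mean(x[(bounds[s] + 1):bounds[s + 1]])
    }, numeric(1))
    d <- abs(diff(mns))
    w <- which.min(d)
    if ((sd_est > 0 && d[w] <= undo_sd * sd_est) ||
          (sd_est == 0 && d[w] == 0)) {
      bps <- bps[-w]
    } else {
      return(bps)
    }
  }
}

# dense grid search for the weighted-density crossing of two Gaussians
oracle_grid_crossing <- function(w1, m1, s1, w2, m2, s2, n_grid = 400001) {
  grid <- seq(m1, m2, length.out = n_grid)
  f <- w1 * stats::dnorm(grid, m1, s1) - w2 * stats::dnorm(grid, m2, s2)
  sgn <- sign(f)
  flip <- which(sgn[-1] != sgn[-n_grid])[1]
  # linear interpolation inside the bracketing grid cell
  x0 <- grid[flip]; x1 <- grid[flip + 1]
  y0 <- f[flip]; y1 <- f[flip + 1]
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
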
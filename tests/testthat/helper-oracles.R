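# Independent oracles and small fixture builders used across the suite.

# dense multivariate-normal log density via explicit covariance inverse and
# determinant (no log-sum-exp / eigen shortcuts)
dense_mvn_logpdf <- function(x, Sigma) {
  n <- length(x)
  as.numeric(-0.5 * n * log(2 * pi) -
    0.5 * determinant(Sigma, logarithm = TRUE)$modulus -
    0.5 * drop(t(x) %*% solve(Sigma) %*% x))
}

# naive two-pass WAIC oracle on a draws x records log-likelihood matrix
naive_waic <- function(ll) {
  S <- nrow(ll)
  lpd <- 0
  p <- 0
  for (j in seq_len(ncol(ll))) {
    lpd <- lpd + log(sum(exp(ll[, j])) / S)
    m <- mean(ll[, j])
    p <- p + sum((ll[, j] - m)^2) / (S - 1)
  }
  list(waic = -2 * (lpd - p), lpd = lpd, p_waic = p)
}

# random connected-ish Erdos-Renyi graph (at least one edge)
random_graph <- function(n, p_edge = 0.5) {
  repeat {
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
    W <- W + t(W)
    if (sum(W) > 0) return(spatial_graph(W))
  }
}

# small simulated panel + panel_data for model-level tests
tiny_panel <- function(sp = 0.3, tm = 0.6, N = 6, Tt = 5, p = 2, seed = 7) {
  panel <- generate_panel(scenario(sp, tm, N, Tt, seed = seed), p = p,
                          k_neighbors = min(3, N - 1))
  list(panel = panel, data = as_panel_data(panel))
}

# central finite differences of a scalar function
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

ns <- asNamespace("stpcar")
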
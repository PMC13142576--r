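# Internal numeric helpers: zero-truncated normal draws/moments and
# Gauss-Hermite / Gauss-Legendre rules (Golub-Welsch, base eigen) used by
# the deterministic calibration quadrature.

# Draw from N(mean, sd) truncated to (0, Inf) by inverse-CDF so that a
# fixed RNG stream gives reproducible values.
rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  # guard against u == 1 rounding
  stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
}

# Mean and SD of the zero-truncated N(mean, sd).
truncnorm0_moments <- function(mean, sd) {
  a <- -mean / sd
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mean + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  list(mean = m, sd = sqrt(v), m2 = m^2 + v)
}

# Gauss-Hermite nodes/weights for integrals against exp(-x^2); the
# normal_gauss_hermite() wrapper rescales to E[f(Z)], Z ~ N(0,1).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[idx])
}

normal_gauss_hermite <- function(n) {
  gh <- gauss_hermite(n)
  list(nodes = sqrt(2) * gh$nodes, weights = gh$weights / sqrt(pi))
}

# Gauss-Legendre on [a, b].
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  x <- e$values[idx]
  w <- (2 * e$vectors[1, ]^2)[idx]
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Probability-weighted nodes for a zero-truncated N(mean, sd): map
# Gauss-Legendre nodes on the CDF scale through the normal quantile
# function, so plain weighted sums approximate expectations.
truncnorm0_nodes <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  gl <- gauss_legendre(n, lo, 1)
  list(nodes = stats::qnorm(gl$nodes, mean, sd),
       weights = gl$weights / (1 - lo))
}

# E[s_pop] / sigma for the n-divisor SD of k iid normals.
popsd_mean_factor <- function(k) {
  sqrt(2 / k) * exp(lgamma(k / 2) - lgamma((k - 1) / 2))
}

# Derive a stage-specific RNG seed from the top-level seed so that adding
# a generation stage never perturbs earlier streams.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 100000) * 7919 + offset) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
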
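# Deterministic calibration of the synthetic-cohort dispersion model.
#
# The generator's latent model for one subject is
#   score_j = 50 + shift + theta + sigma_i * eps_j ,  eps_j ~ N(0,1), j = 1..k
# with subject dispersion sigma_i drawn from a zero-truncated normal and
# ability theta ~ N(0, tau^2). Internal regression norming rescales every
# test by the same population factor f = 10 / s0, where s0 is the
# per-test score SD in the norming reference group, so the observed
# T-score panel is an affine image of the latent one. The subject's
# coefficient of variation is then
#   CoV_i = f * sigma_i * s_pop(eps) / (50 + f*(shift + theta + sigma_i*mean(eps)))
# For Gaussian eps the n-divisor SD s_pop(eps) is independent of
# mean(eps), so the first two moments of CoV reduce to one-dimensional
# normal integrals nested inside a truncated-normal integral. These are
# evaluated here by Gauss-Hermite / Gauss-Legendre quadrature, giving a
# forward model accurate to ~1e-10 within the model, which the
# calibration solvers invert.

#' Moments of the simulated coefficient of variation
#'
#' Computes the population mean and SD of the per-subject CoV implied by
#' the generator's dispersion model, together with the correlation
#' between CoV and the latent subject dispersion sigma (used to set
#' covariate correlations).
#'
#' @param mu_sigma,sd_sigma location and scale of the zero-truncated
#'   normal that subject dispersions are drawn from (latent units).
#' @param tau SD of the latent ability term.
#' @param shift latent group shift of the composite centre (0 for the
#'   norming reference group).
#' @param f norming rescale factor (10 / reference per-test SD). If
#'   `NULL`, the group is treated as the norming reference itself and
#'   `f` is derived self-consistently from `tau`, `mu_sigma`, `sd_sigma`.
#' @param n_tests number of scores entering the CoV (11 for the full
#'   battery, 5 for attention/executive).
#' @param n_sigma,n_z quadrature sizes.
#' @return list with `mean`, `sd`, `cor_sigma`, `f`.
#' @export
cov_model_moments <- function(mu_sigma, sd_sigma, tau = 0, shift = 0,
                              f = NULL, n_tests = 11,
                              n_sigma = 80, n_z = 40) {
  stopifnot(sd_sigma > 0, n_tests >= 2)
  sn <- truncnorm0_nodes(n_sigma, mu_sigma, sd_sigma)
  zq <- normal_gauss_hermite(n_z)
  tm <- truncnorm0_moments(mu_sigma, sd_sigma)
  if (is.null(f)) f <- 10 / sqrt(tau^2 + tm$m2)
  kf <- popsd_mean_factor(n_tests)
  es2 <- (n_tests - 1) / n_tests

  sig <- sn$nodes
  den_sd <- f * sqrt(tau^2 + sig^2 / n_tests)
  # D[s, z] = composite denominator
  # clip the (negligibly weighted) extreme corners where the composite
  # would be non-positive; the generator excludes such panels outright
  D <- pmax(50 + f * shift + outer(den_sd, zq$nodes), 1)
  inv1 <- as.vector((1 / D) %*% zq$weights)
  inv2 <- as.vector((1 / D^2) %*% zq$weights)
  m1_s <- f * sig * kf * inv1
  m2_s <- f^2 * sig^2 * es2 * inv2
  m1 <- sum(sn$weights * m1_s)
  m2 <- sum(sn$weights * m2_s)
  e_sig <- sum(sn$weights * sig)
  cov_sig <- sum(sn$weights * sig * m1_s) - m1 * e_sig
  v <- max(m2 - m1^2, 0)
  list(mean = m1, sd = sqrt(v),
       cor_sigma = if (v > 0) cov_sig / (sqrt(v) * tm$sd) else 0,
       f = f)
}

#' Calibrate subject-dispersion parameters to CoV targets
#'
#' Inverts [cov_model_moments()]: finds the zero-truncated-normal
#' parameters of the subject dispersion distribution whose implied CoV
#' mean and SD match the requested targets. When the reference group's
#' per-test SD is pinned to 10 by internal norming the target pair may
#' sit outside the attainable set (the within-battery sampling noise of
#' an 11-score SD puts a floor under SD(CoV) and a cap on the mean); in
#' that case the constrained least-relative-error optimum is returned
#' with `feasible = FALSE` and a message.
#'
#' @param target_mean,target_sd desired population mean and SD of CoV.
#' @param tau,shift,f,n_tests as in [cov_model_moments()].
#' @param label group label used in messages.
#' @return list with `mu_sigma`, `sd_sigma`, `f`, `achieved_mean`,
#'   `achieved_sd`, `cor_sigma`, `feasible`.
#' @export
calibrate_dispersion <- function(target_mean, target_sd, tau = 0,
                                 shift = 0, f = NULL, n_tests = 11,
                                 label = "group") {
  stopifnot(target_mean > 0, target_sd > 0)
  kf <- popsd_mean_factor(n_tests)
  centre <- 50 + (if (is.null(f)) 0 else f * shift)
  start <- c(log(target_mean * centre / kf),
             log(max(target_sd * centre / kf * 0.6, 0.3)))
  obj <- function(par) {
    m <- try(cov_model_moments(exp(par[1]), exp(par[2]), tau = tau,
                               shift = shift, f = f, n_tests = n_tests),
             silent = TRUE)
    if (inherits(m, "try-error")) return(1e6)
    ((m$mean - target_mean) / target_mean)^2 +
      ((m$sd - target_sd) / target_sd)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  mu_sigma <- exp(fit$par[1])
  sd_sigma <- exp(fit$par[2])
  mm <- cov_model_moments(mu_sigma, sd_sigma, tau = tau, shift = shift,
                          f = f, n_tests = n_tests)
  feasible <- sqrt(fit$value) < 1e-3
  if (!feasible) {
    message(sprintf(paste0(
      "CoV targets (%.3f, %.3f) for '%s' are not exactly attainable under ",
      "reference norming; using constrained optimum (%.4f, %.4f)"),
      target_mean, target_sd, label, mm$mean, mm$sd))
  }
  list(mu_sigma = mu_sigma, sd_sigma = sd_sigma, f = mm$f,
       achieved_mean = mm$mean, achieved_sd = mm$sd,
       cor_sigma = mm$cor_sigma, feasible = feasible)
}

#' Calibrate the conversion-model intercept
#'
#' Solves for the intercept of the generator's conversion logistic model
#' so that the expected one-year conversion fraction among followed
#' Stage-2 subjects equals `rate`, given the model slopes and the
#' marginal distributions of baseline CoV (normal approximation from the
#' calibrated dispersion model) and MDS-UPDRS III (normal clamped at 0,
#' mirroring the generator).
#'
#' @param rate target conversion fraction.
#' @param beta_cov,beta_updrs logistic slopes (log-odds per unit).
#' @param cov_mean,cov_sd moments of baseline CoV.
#' @param updrs_mean,updrs_sd parent normal parameters of the UPDRS-III
#'   distribution before clamping at zero.
#' @return the calibrated intercept (log-odds).
#' @export
calibrate_conversion_intercept <- function(rate, beta_cov, beta_updrs,
                                           cov_mean, cov_sd,
                                           updrs_mean, updrs_sd) {
  stopifnot(rate > 0, rate < 1, cov_sd > 0, updrs_sd > 0)
  zq <- normal_gauss_hermite(40)
  cov <- pmax(cov_mean + cov_sd * zq$nodes, 0)
  upd <- pmax(updrs_mean + updrs_sd * zq$nodes, 0)
  eta0 <- outer(beta_cov * cov, beta_updrs * upd, `+`)
  w2 <- outer(zq$weights, zq$weights)
  erate <- function(b0) sum(w2 * stats::plogis(b0 + eta0)) - rate
  stats::uniroot(erate, c(-30, 10), tol = 1e-12)$root
}
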
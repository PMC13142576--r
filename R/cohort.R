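# Synthetic cohort model: configuration, generation, and delimited-text IO.

# Default per-group clinical scale parameters. Means/SDs are the
# cohort summary values the generator emulates; values are drawn from a
# normal with these parent parameters, clamped to the instrument range
# and rounded to `unit` (0 = continuous). Heavily zero-skewed scales
# (e.g. control-group UPDRS-III) therefore realise somewhat different
# moments than the parent values; the analysis only relies on ordering
# and sign structure, not on exact scale moments.
default_scale_params <- function() {
  data.frame(
    scale = c("updrs3", "hoehn_yahr", "scopa_aut", "gds15", "quip",
              "stai_state", "upsit", "ess", "rbdsq"),
    hc_mean = c(1.82, 0.03, 6.15, 0.78, 0.12, 51.42, 34.48, 4.70, 1.82),
    hc_sd   = c(3.04, 0.22, 3.49, 1.09, 0.38, 12.60, 3.56, 3.18, 1.87),
    s2_mean = c(6.63, 0.38, 9.74, 1.50, 0.24, 57.37, 20.21, 5.55, 6.16),
    s2_sd   = c(7.93, 0.72, 5.77, 1.95, 0.59, 15.67, 6.33, 3.65, 4.24),
    lo = c(0, 0, 0, 0, 0, 20, 0, 0, 0),
    hi = c(132, 5, 69, 15, 8, 80, 40, 24, 13),
    unit = c(1, 0.5, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a synthetic prodromal cohort
#'
#' Builds the full parameter set for [simulate_cohort()]. Defaults state
#' the emulated world: a healthy-control group (n = 102) and an NSD-ISS
#' Stage 2 group (n = 832) assessed on an 11-score battery at baseline
#' and (for controls and a followed fraction of Stage 2, 440/832) about
#' one year later; group CoV distributions targeting mean (SD) 0.18
#' (0.07) vs 0.21 (0.10); a composite T-score gap of 3.43 points; and a
#' one-year conversion process with log-odds slopes 0.362 per CoV unit
#' and 0.09 per UPDRS-III point, intercept calibrated so that about
#' 100/440 followed Stage-2 subjects convert.
#'
#' Dispersion parameters (`mu_sigma_*`, `sd_sigma_*`) and the conversion
#' intercept are derived from the targets by the deterministic
#' quadrature calibration ([calibrate_dispersion()],
#' [calibrate_conversion_intercept()]) unless supplied explicitly.
#'
#' @param seed integer seed; all generation streams derive from it.
#' @param n_hc,n_stage2 group sizes.
#' @param follow_up_fraction fraction of Stage 2 with a complete Year-1
#'   battery, in (0, 1].
#' @param cov_target_hc,cov_target_s2 length-2 vectors `c(mean, sd)` of
#'   the target CoV distribution per group.
#' @param tau SD of the latent ability term (0 by default: in the
#'   calibrated world all within-group composite variation comes from
#'   within-battery noise; see the methods vignette).
#' @param composite_gap latent composite T-score deficit of Stage 2
#'   relative to controls, in T units.
#' @param mu_sigma_hc,sd_sigma_hc,mu_sigma_s2,sd_sigma_s2 optional
#'   explicit subject-dispersion parameters (bypass calibration).
#' @param beta_cov,beta_updrs conversion log-odds slopes.
#' @param beta0 conversion intercept; calibrated when `NULL`.
#' @param conversion_rate target conversion fraction among followed.
#' @param p_2b fraction of Stage 2 with dopaminergic deficit (2B).
#' @param p_hyposmia_s2 probability of the hyposmia flag in Stage 2.
#' @param target_correlations named vector of target correlations of
#'   CoV with subject covariates (age, education, gds15, stai_state).
#' @param year1_offset_mean,year1_offset_sd Year-1 visit offset (years).
#' @param scale_params clinical scale parameter table, see
#'   `cogdisp:::default_scale_params`.
#' @param quiet suppress calibration messages.
#' @return An object of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_hc = 30, n_stage2 = 60, quiet = TRUE)
#' cfg$beta_cov
#' @export
simulation_config <- function(seed = 1L,
                              n_hc = 102L,
                              n_stage2 = 832L,
                              follow_up_fraction = 440 / 832,
                              cov_target_hc = c(0.18, 0.07),
                              cov_target_s2 = c(0.21, 0.10),
                              tau = 0,
                              composite_gap = 3.43,
                              mu_sigma_hc = NULL, sd_sigma_hc = NULL,
                              mu_sigma_s2 = NULL, sd_sigma_s2 = NULL,
                              beta_cov = 0.362,
                              beta_updrs = 0.09,
                              beta0 = NULL,
                              conversion_rate = 100 / 440,
                              p_2b = 0.5,
                              p_hyposmia_s2 = 0.9,
                              target_correlations = c(age = 0.135,
                                                      education = -0.201,
                                                      gds15 = 0.107,
                                                      stai_state = 0.154),
                              year1_offset_mean = 1.0,
                              year1_offset_sd = 0.1,
                              scale_params = default_scale_params(),
                              quiet = FALSE) {
  if (n_hc <= 0 || n_stage2 <= 0) stop("group sizes must be positive")
  if (follow_up_fraction <= 0 || follow_up_fraction > 1) {
    stop("follow_up_fraction must be in (0, 1]")
  }
  stopifnot(length(cov_target_hc) == 2, length(cov_target_s2) == 2,
            all(cov_target_hc > 0), all(cov_target_s2 > 0), tau >= 0,
            year1_offset_sd > 0, all(scale_params$hc_sd > 0),
            all(scale_params$s2_sd > 0))

  wrap <- if (quiet) suppressMessages else identity
  if (is.null(mu_sigma_hc) || is.null(sd_sigma_hc)) {
    cal_hc <- wrap(calibrate_dispersion(cov_target_hc[1], cov_target_hc[2],
                                        tau = tau, label = "hc"))
  } else {
    stopifnot(sd_sigma_hc > 0)
    mm <- cov_model_moments(mu_sigma_hc, sd_sigma_hc, tau = tau)
    cal_hc <- list(mu_sigma = mu_sigma_hc, sd_sigma = sd_sigma_hc,
                   f = mm$f, achieved_mean = mm$mean, achieved_sd = mm$sd,
                   cor_sigma = mm$cor_sigma, feasible = NA)
  }
  f <- cal_hc$f
  shift_s2 <- -composite_gap / f
  if (is.null(mu_sigma_s2) || is.null(sd_sigma_s2)) {
    cal_s2 <- wrap(calibrate_dispersion(cov_target_s2[1], cov_target_s2[2],
                                        tau = tau, shift = shift_s2, f = f,
                                        label = "stage2"))
  } else {
    stopifnot(sd_sigma_s2 > 0)
    mm <- cov_model_moments(mu_sigma_s2, sd_sigma_s2, tau = tau,
                            shift = shift_s2, f = f)
    cal_s2 <- list(mu_sigma = mu_sigma_s2, sd_sigma = sd_sigma_s2,
                   f = f, achieved_mean = mm$mean, achieved_sd = mm$sd,
                   cor_sigma = mm$cor_sigma, feasible = NA)
  }
  upd <- scale_params[scale_params$scale == "updrs3", ]
  if (is.null(beta0)) {
    beta0 <- calibrate_conversion_intercept(conversion_rate, beta_cov,
                                            beta_updrs,
                                            cal_s2$achieved_mean,
                                            cal_s2$achieved_sd,
                                            upd$s2_mean, upd$s2_sd)
  }
  structure(list(
    seed = as.integer(seed), n_hc = as.integer(n_hc),
    n_stage2 = as.integer(n_stage2),
    follow_up_fraction = follow_up_fraction,
    cov_target_hc = cov_target_hc, cov_target_s2 = cov_target_s2,
    tau = tau, composite_gap = composite_gap, f = f, shift_s2 = shift_s2,
    calibration = list(hc = cal_hc, s2 = cal_s2),
    beta_cov = beta_cov, beta_updrs = beta_updrs, beta0 = beta0,
    conversion_rate = conversion_rate,
    p_2b = p_2b, p_hyposmia_s2 = p_hyposmia_s2,
    target_correlations = target_correlations,
    year1_offset_mean = year1_offset_mean,
    year1_offset_sd = year1_offset_sd,
    scale_params = scale_params
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  seed %d; n = %d HC + %d Stage 2 (follow-up %.3f)\n",
              x$seed, x$n_hc, x$n_stage2, x$follow_up_fraction))
  cat(sprintf("  CoV targets: HC %.3f (%.3f) -> achieved %.4f (%.4f)\n",
              x$cov_target_hc[1], x$cov_target_hc[2],
              x$calibration$hc$achieved_mean, x$calibration$hc$achieved_sd))
  cat(sprintf("               S2 %.3f (%.3f) -> achieved %.4f (%.4f)\n",
              x$cov_target_s2[1], x$cov_target_s2[2],
              x$calibration$s2$achieved_mean, x$calibration$s2$achieved_sd))
  cat(sprintf("  conversion: logit p = %.3f + %.3f CoV + %.3f UPDRS-III\n",
              x$beta0, x$beta_cov, x$beta_updrs))
  invisible(x)
}

clamp_round <- function(x, lo, hi, unit) {
  if (unit > 0) x <- round(x / unit) * unit
  pmin(pmax(x, lo), hi)
}

#' Simulate a synthetic prodromal cohort
#'
#' Generates one participant-visit table with the statistical structure
#' the downstream dispersion analysis assumes: two groups with
#' group-specific subject dispersion, demographically structured raw
#' scores on the 11-test battery (so that regression norming has
#' signal), clinical scales, biomarker flags (SAA positivity, DAT
#' deficit), and a Year-1 visit whose functional-impairment flag is
#' drawn from a logistic model in baseline CoV and UPDRS-III. Identical
#' seed and configuration give a byte-identical table.
#'
#' @param config a [simulation_config()].
#' @param registry the test registry (see [test_registry()]).
#' @param seed optional seed overriding `config$seed` (convenient for
#'   replicate studies without re-running calibration).
#' @param keep_latent attach the generator's ground truth as extra
#'   columns (`cov_latent`: the baseline CoV on the population-normed
#'   scale that the conversion draws used). Intended for generator
#'   validation (e.g. parameter-recovery studies free of CoV
#'   measurement error); `NA` on follow-up rows.
#' @return A data.frame, one row per participant-visit, with the column
#'   schema documented in [cohort_dictionary()].
#' @examples
#' cfg <- simulation_config(seed = 7, n_hc = 20, n_stage2 = 40, quiet = TRUE)
#' coh <- simulate_cohort(cfg)
#' table(coh$group, coh$visit_index)
#' @export
simulate_cohort <- function(config, registry = test_registry(),
                            seed = NULL, keep_latent = FALSE) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config object")
  }
  check_registry(registry)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  n1 <- config$n_hc; n2 <- config$n_stage2; n <- n1 + n2
  group <- rep(c("hc", "stage2"), c(n1, n2))
  is_s2 <- group == "stage2"
  cal <- config$calibration
  f <- config$f
  ntest <- nrow(registry)

  ## --- subject-level latents ------------------------------------------
  set.seed(derive_seed(config$seed, 101))
  mu_s <- ifelse(is_s2, cal$s2$mu_sigma, cal$hc$mu_sigma)
  sd_s <- ifelse(is_s2, cal$s2$sd_sigma, cal$hc$sd_sigma)
  sigma <- rtruncnorm0(n, mu_s, sd_s)
  theta <- stats::rnorm(n, 0, config$tau)
  tm_hc <- truncnorm0_moments(cal$hc$mu_sigma, cal$hc$sd_sigma)
  tm_s2 <- truncnorm0_moments(cal$s2$mu_sigma, cal$s2$sd_sigma)
  z_sigma <- ifelse(is_s2, (sigma - tm_s2$mean) / tm_s2$sd,
                    (sigma - tm_hc$mean) / tm_hc$sd)
  shift <- ifelse(is_s2, config$shift_s2, 0)

  ## --- demographics, correlated with subject dispersion ---------------
  set.seed(derive_seed(config$seed, 211))
  tc <- config$target_correlations
  atten <- ifelse(is_s2, cal$s2$cor_sigma, cal$hc$cor_sigma)
  mix <- function(target) {
    rho <- pmin(pmax(target / atten, -0.95), 0.95)
    rho * z_sigma + sqrt(1 - rho^2) * stats::rnorm(n)
  }
  age <- ifelse(is_s2, 67.77, 64.64) +
    ifelse(is_s2, 6.39, 12.11) * mix(tc[["age"]])
  age <- pmin(pmax(round(age, 1), 35), 95)
  education <- ifelse(is_s2, 16.39, 16.28) +
    ifelse(is_s2, 2.71, 2.92) * mix(tc[["education"]])
  education <- pmin(pmax(round(education), 6), 24)
  sex <- ifelse(stats::runif(n) < ifelse(is_s2, 0.583, 0.569), "M", "F")

  ## --- clinical scales -------------------------------------------------
  set.seed(derive_seed(config$seed, 307))
  sp <- config$scale_params
  scales <- list()
  for (i in seq_len(nrow(sp))) {
    nm <- sp$scale[i]
    mu <- ifelse(is_s2, sp$s2_mean[i], sp$hc_mean[i])
    sd <- ifelse(is_s2, sp$s2_sd[i], sp$hc_sd[i])
    z <- if (nm %in% c("gds15", "stai_state")) mix(tc[[nm]]) else stats::rnorm(n)
    scales[[nm]] <- clamp_round(mu + sd * z, sp$lo[i], sp$hi[i], sp$unit[i])
  }
  # MoCA: HC drawn from the >= 27 inclusion-conditioned distribution
  set.seed(derive_seed(config$seed, 311))
  moca_hc <- round(stats::qnorm(stats::runif(n, stats::pnorm(26.5, 28.75, 1.23), 1),
                                28.75, 1.23))
  moca_s2 <- clamp_round(stats::rnorm(n, 26.85, 2.29), 0, 30, 1)
  moca <- ifelse(is_s2, moca_s2, pmin(moca_hc, 30))
  moca_y1 <- ifelse(is_s2,
                    clamp_round(moca - round(stats::rnorm(n, 0.2, 1.2)), 0, 30, 1),
                    clamp_round(moca - round(stats::rnorm(n, 0.1, 0.9)), 0, 30, 1))

  ## --- biomarker flags -------------------------------------------------
  set.seed(derive_seed(config$seed, 401))
  saa_positive <- is_s2
  dat_deficit <- ifelse(is_s2, stats::runif(n) < config$p_2b, NA)
  hyposmia <- is_s2 & stats::runif(n) < config$p_hyposmia_s2

  ## --- test scores ------------------------------------------------------
  raw_panel <- function(eps) {
    demo <- outer(rep(1, n), registry$beta_age) * (age - 65) / 10 +
      outer(rep(1, n), registry$beta_edu) * (education - 16) / 3 +
      outer(sex == "M", registry$beta_sex)
    good <- (shift + theta + sigma * eps) / 10
    dirn <- ifelse(registry$higher_is_worse, -1, 1)
    sweep(sweep((good + demo), 2, registry$raw_sd * dirn, `*`),
          2, registry$raw_mean, `+`)
  }
  set.seed(derive_seed(config$seed, 503))
  eps0 <- matrix(stats::rnorm(n * ntest), n, ntest)
  raw0 <- raw_panel(eps0)
  set.seed(derive_seed(config$seed, 509))
  eps1 <- matrix(stats::rnorm(n * ntest), n, ntest)
  raw1 <- raw_panel(eps1)
  colnames(raw0) <- colnames(raw1) <- registry$test

  ## --- follow-up, conversion -------------------------------------------
  set.seed(derive_seed(config$seed, 601))
  offset1 <- pmax(stats::rnorm(n, config$year1_offset_mean,
                               config$year1_offset_sd), 0.1)
  followed <- !is_s2 | stats::runif(n) < config$follow_up_fraction

  # latent baseline CoV on the population-normed scale: the same draws
  # the analysis pipeline will see, up to finite-reference noise
  t_lat <- 50 + f * (shift + theta + sigma * eps0)
  lat_mean <- rowMeans(t_lat)
  lat_sd <- sqrt(rowMeans((t_lat - lat_mean)^2))
  cov_lat <- ifelse(lat_mean > 0, lat_sd / lat_mean, NA)

  set.seed(derive_seed(config$seed, 701))
  u_conv <- stats::runif(n)
  p_conv <- stats::plogis(config$beta0 + config$beta_cov * cov_lat +
                            config$beta_updrs * scales$updrs3)
  converted <- is_s2 & followed & !is.na(p_conv) & u_conv < p_conv

  ## --- assemble participant-visit rows ---------------------------------
  id <- sprintf("P%05d", seq_len(n))
  base_df <- data.frame(
    participant_id = id, group = group, visit_index = 0L,
    visit_offset_years = 0,
    age = age, sex = sex, education = education,
    stringsAsFactors = FALSE
  )
  base_df <- cbind(base_df, as.data.frame(raw0))
  base_df <- cbind(base_df, as.data.frame(scales))
  base_df$moca <- moca
  base_df$saa_positive <- saa_positive
  base_df$dat_deficit <- dat_deficit
  base_df$hyposmia <- hyposmia
  base_df$functional_impairment <- "none"
  if (keep_latent) base_df$cov_latent <- round(cov_lat, 6)

  keep <- followed
  y1_df <- base_df[keep, , drop = FALSE]
  y1_df$visit_index <- 1L
  y1_df$visit_offset_years <- round(offset1[keep], 3)
  y1_df$age <- round(y1_df$age + offset1[keep], 1)
  y1_df[, registry$test] <- as.data.frame(raw1[keep, , drop = FALSE])
  y1_df$moca <- moca_y1[keep]
  y1_df$functional_impairment <- ifelse(converted[keep], "slight", "none")
  if (keep_latent) y1_df$cov_latent <- NA_real_

  out <- rbind(base_df, y1_df)
  out <- out[order(out$participant_id, out$visit_index), , drop = FALSE]
  rownames(out) <- NULL
  num <- registry$test
  out[num] <- lapply(out[num], function(x) round(x, 4))
  out
}
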
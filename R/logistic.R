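# Binomial logistic regression by iteratively reweighted least squares,
# with Wald inference, likelihood-ratio test against the intercept-only
# model, Nagelkerke R-squared and the Hosmer-Lemeshow decile-of-risk
# calibration statistic. Written from first principles; stats::glm is
# used only as an independent cross-check in the test suite.

#' Fit a binomial logistic regression
#'
#' Maximum likelihood via IRLS with an intercept, converged when the
#' largest coefficient update falls below `tol` (default 1e-8) or after
#' `max_iter` iterations. Standard errors come from the inverse observed
#' information at the optimum. Runaway coefficient growth (complete or
#' quasi-separation) is detected and reported via `converged = FALSE`
#' and a warning rather than silently returned.
#'
#' @param y binary outcome vector (0/1 or logical), both classes present.
#' @param X data.frame or matrix of predictors (no intercept column);
#'   `NULL` fits the intercept-only model.
#' @param max_iter,tol IRLS controls.
#' @return An object of class `"logistic_fit"`: coefficient table with
#'   odds ratios and 95% Wald CIs, log-likelihoods `ll` and `ll_null`,
#'   LR chi-square with df and p, Cox-Snell and Nagelkerke R-squared,
#'   fitted probabilities, score residual, convergence state.
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rbinom(200, 1, plogis(-0.5 + 0.8 * x))
#' fit <- fit_logistic(y, data.frame(x = x))
#' fit$coefficients
#' @export
fit_logistic <- function(y, X, max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (is.null(X)) {
    Xm <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.data.frame(X)
    Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  }
  ok <- stats::complete.cases(Xm) & !is.na(y)
  Xm <- Xm[ok, , drop = FALSE]
  yv <- y[ok]
  n <- nrow(Xm)
  k <- ncol(Xm)
  if (n <= k) stop("need more observations than parameters")

  beta <- numeric(k)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xm %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-10)
    XtWX <- crossprod(Xm * w, Xm)
    score <- crossprod(Xm, yv - p)
    delta <- tryCatch(solve(XtWX, score),
                      error = function(e) stop("singular information matrix: ",
                                               conditionMessage(e)))
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
    if (max(abs(drop(Xm %*% beta))) > 40 && max(abs(delta)) > 1) {
      diverged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(if (diverged)
      "possible complete or quasi-separation: coefficients diverging"
      else paste("IRLS did not converge within max_iter iterations",
                 "(possible complete or quasi-separation)"))
  }
  eta <- drop(Xm %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(Xm * pmax(p * (1 - p), 1e-10), Xm)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  pw <- 2 * stats::pnorm(-abs(z))
  orci <- or_from_coef(beta, se)

  ll <- sum(yv * log(pmax(p, 1e-300)) + (1 - yv) * log(pmax(1 - p, 1e-300)))
  pbar <- mean(yv)
  ll0 <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  lr <- 2 * (ll - ll0)
  lr_df <- k - 1
  r2 <- nagelkerke_r2(ll0, ll, n)

  coef_tab <- data.frame(
    term = colnames(Xm), estimate = beta, se = se, z = z, p = pw,
    or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coef_tab, n = n, y = yv, fitted = p,
    ll = ll, ll_null = ll0,
    lr_chisq = lr, lr_df = lr_df,
    lr_p = stats::pchisq(lr, lr_df, lower.tail = FALSE),
    r2_cox_snell = r2$cox_snell, r2_nagelkerke = r2$nagelkerke,
    score_residual = max(abs(crossprod(Xm, yv - p))),
    vcov = vcov, converged = converged, iterations = iter
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, LL = %.3f (null %.3f)\n",
              x$n, x$ll, x$ll_null))
  cat(sprintf("  LR chi-square(%d) = %.2f, p = %.4g; Nagelkerke R2 = %.3f\n",
              x$lr_df, x$lr_chisq, x$lr_p, x$r2_nagelkerke))
  ct <- x$coefficients
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-14s B = %8.4f (SE %.4f)  p = %.4g  OR %.3f [%.3f, %.3f]\n",
                ct$term[i], ct$estimate[i], ct$se[i], ct$p[i],
                ct$or[i], ct$ci_low[i], ct$ci_high[i]))
  }
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Odds ratio with 95% Wald interval from a log-odds coefficient
#'
#' @param b,se coefficient and standard error (vectors allowed).
#' @return data.frame with `or`, `ci_low`, `ci_high`.
#' @examples
#' or_from_coef(0.362, 0.1367)  # OR 1.44, CI 1.10-1.88
#' @export
or_from_coef <- function(b, se) {
  stopifnot(all(se >= 0))
  zc <- 1.959964
  data.frame(or = exp(b), ci_low = exp(b - zc * se),
             ci_high = exp(b + zc * se))
}

#' Nagelkerke (rescaled Cox-Snell) R-squared
#'
#' @param ll0,ll1 null and fitted log-likelihoods (`ll1 >= ll0`).
#' @param n number of observations.
#' @return list with `cox_snell` and `nagelkerke`.
#' @export
nagelkerke_r2 <- function(ll0, ll1, n) {
  stopifnot(n > 0)
  if (ll1 < ll0 - 1e-8) stop("ll1 must be >= ll0")
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  maxcs <- 1 - exp(2 * ll0 / n)
  list(cox_snell = cs,
       nagelkerke = if (maxcs > 0) cs / maxcs else 0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are sorted by fitted probability and split into `g`
#' near-equal decile-of-risk groups (tied probabilities stay together;
#' empty groups reduce g with a message). The statistic sums
#' (O - E)^2 / E over groups and both outcome classes, with df = g - 2.
#'
#' @param y binary outcomes.
#' @param p fitted probabilities in (0, 1).
#' @param g number of risk groups (default 10).
#' @return list with `chisq`, `df`, `p`, `g`, and the per-group
#'   observed/expected table.
#' @export
hosmer_lemeshow <- function(y, p, g = 10) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p), all(p > 0 & p < 1))
  if (length(y) < g) stop("need at least g observations")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1),
                               type = 7, names = FALSE))
  if (length(br) < 3) stop("fitted probabilities too concentrated to group")
  grp <- cut(p, breaks = br, include.lowest = TRUE)
  grp <- droplevels(grp)
  g_eff <- nlevels(grp)
  if (g_eff < g) message("Hosmer-Lemeshow groups reduced to ", g_eff,
                         " by ties")
  o1 <- tapply(y, grp, sum)
  e1 <- tapply(p, grp, sum)
  nn <- tapply(y, grp, length)
  o0 <- nn - o1
  e0 <- nn - e1
  chisq <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- g_eff - 2
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       g = g_eff,
       table = data.frame(group = levels(grp), n = as.vector(nn),
                          observed = as.vector(o1),
                          expected = as.vector(e1)))
}

#' Fit the two one-year conversion models
#'
#' Model 1 regresses conversion on baseline total CoV controlling for
#' baseline motor severity (MDS-UPDRS III); model 2 uses the
#' attention/executive CoV instead. Followed subjects only. CoV enters
#' in raw units by default (one unit of CoV is large relative to its SD;
#' `standardize = TRUE` rescales both predictors to SD 1 for
#' sensitivity).
#'
#' @param outcomes conversion outcomes from [label_conversion()].
#' @param dispersion baseline dispersion results from
#'   [compute_dispersion()].
#' @param baseline participant-visit data.frame of baseline records
#'   (supplies `updrs3`).
#' @param standardize rescale predictors to unit SD before fitting.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return list with elements `total` and `ae` (each a `"logistic_fit"`
#'   with a `hosmer_lemeshow` component attached) and `n`.
#' @export
run_conversion_models <- function(outcomes, dispersion, baseline,
                                  standardize = FALSE, hl_groups = 10) {
  f <- outcomes[outcomes$followed, , drop = FALSE]
  if (nrow(f) == 0) stop("no followed Stage 2 participants")
  d0 <- dispersion[dispersion$visit_index == 0, , drop = FALSE]
  b0 <- baseline[baseline$visit_index == 0, c("participant_id", "updrs3")]
  dat <- merge(merge(f[c("participant_id", "converted")], d0,
                     by = "participant_id"),
               b0, by = "participant_id")
  dat <- dat[stats::complete.cases(dat[c("converted", "cov_total",
                                         "cov_ae", "updrs3")]), ]
  if (length(unique(dat$converted)) < 2) {
    stop("conversion outcome has a single class; model not identifiable")
  }
  prep <- function(x) if (standardize) as.numeric(scale(x)) else x
  hl_try <- function(fit) {
    # calibration diagnostic; not computable when fitted probabilities
    # saturate numerically (extreme linear predictors)
    tryCatch(hosmer_lemeshow(fit$y, fit$fitted, g = hl_groups),
             error = function(e) {
               message("Hosmer-Lemeshow not computable: ",
                       conditionMessage(e))
               NULL
             })
  }
  m_total <- fit_logistic(dat$converted,
                          data.frame(cov_total = prep(dat$cov_total),
                                     updrs3 = prep(dat$updrs3)))
  m_total$hosmer_lemeshow <- hl_try(m_total)
  m_ae <- fit_logistic(dat$converted,
                       data.frame(cov_ae = prep(dat$cov_ae),
                                  updrs3 = prep(dat$updrs3)))
  m_ae$hosmer_lemeshow <- hl_try(m_ae)
  list(total = m_total, ae = m_ae, n = nrow(dat))
}
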
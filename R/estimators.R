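# Univariable two-sample MR estimators: Wald ratio, IVW, MR-Egger,
# weighted median.
#
# Throughout, instruments are rows of a harmonized instrument set with
# columns beta_exposure, se_exposure, beta_outcome, se_outcome. IVW weights
# are the first-order inverse variances of the per-variant ratio estimates,
# w_j = (beta_exposure_j / se_outcome_j)^2, which makes IVW identical to
# weighted least squares of beta_outcome on beta_exposure through the
# origin with weights 1 / se_outcome^2.

mr_cols <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")

new_mr_result <- function(method, beta, se, pvalue, n_snps, ...) {
  structure(
    c(list(method = method, beta = beta, se = se, pvalue = pvalue,
           n_snps = n_snps), list(...)),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  ci <- ci_limits(x$beta, x$se)
  cat(sprintf(
    "<mr_result> %s: beta = %.4f (SE %.4f), p = %.3g, OR %s, n_snps = %d\n",
    x$method, x$beta, x$se, x$pvalue, format_or(x$beta, x$se), x$n_snps
  ))
  invisible(x)
}

#' Per-variant Wald ratio estimates
#'
#' The causal effect implied by a single instrument is the ratio of the
#' outcome and exposure associations, `beta_outcome / beta_exposure`. The
#' default standard error is the first-order delta approximation
#' `se_outcome / |beta_exposure|`; `second_order = TRUE` adds the term
#' propagating the exposure's sampling error,
#' `se^2 = se_outcome^2 / beta_exposure^2 +
#'   beta_outcome^2 * se_exposure^2 / beta_exposure^4`.
#'
#' @param data Harmonized instrument set (or any data frame with
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`).
#' @param second_order Use the second-order delta-method SE (default FALSE).
#' @return Tibble with one row per instrument: `variant_id` (when present),
#'   `method`, `beta`, `se`, `pvalue`.
#' @export
mr_wald_ratio <- function(data, second_order = FALSE) {
  assert_columns(data, mr_cols, "`data`")
  if (any(data$beta_exposure == 0)) {
    abort("Wald ratio undefined: `beta_exposure` contains zero")
  }
  beta <- data$beta_outcome / data$beta_exposure
  se2 <- data$se_outcome^2 / data$beta_exposure^2
  if (second_order) {
    se2 <- se2 + data$beta_outcome^2 * data$se_exposure^2 / data$beta_exposure^4
  }
  se <- sqrt(se2)
  tibble::tibble(
    variant_id = if ("variant_id" %in% names(data)) data$variant_id else
      as.character(seq_len(nrow(data))),
    method = "wald_ratio",
    beta = beta, se = se, pvalue = norm_p(beta, se)
  )
}

ivw_weights <- function(data) (data$beta_exposure / data$se_outcome)^2

#' Inverse-variance weighted (IVW) estimate
#'
#' The primary estimator: the inverse-variance weighted average of the
#' per-variant Wald ratios, equivalently a weighted through-origin
#' regression of outcome on exposure associations with weights
#' `1 / se_outcome^2`. The fixed-effect SE is `1 / sqrt(sum(w))`; the
#' multiplicative random-effects SE inflates it by `sqrt(Q / (n - 1))` when
#' Cochran's Q exceeds its degrees of freedom. `mode = "auto"` (the
#' default) reports the random-effects model exactly when overdispersion is
#' present, and the fixed-effect model otherwise; both SEs are always
#' retained in the result.
#'
#' @inheritParams mr_wald_ratio
#' @param mode `"auto"`, `"fixed"` or `"random"`.
#' @return An object of class `"mr_result"` with elements `method`
#'   (`"ivw_fixed"` or `"ivw_random"`), `beta`, `se`, `pvalue`, `n_snps`,
#'   `se_fixed`, `se_random`, `Q`, `Q_df`, `Q_pvalue`. Use [tidy()] /
#'   [glance()] for tibble views.
#' @examples
#' study <- simulate_study(simulation_config(n_variants = 30, seed = 7))
#' hs <- harmonize(select_instruments(study$tables$exposure),
#'                 study$tables$outcome)
#' tidy(mr_ivw(hs), exponentiate = TRUE)
#' @export
mr_ivw <- function(data, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  assert_columns(data, mr_cols, "`data`")
  n <- nrow(data)
  if (n < 2) abort("IVW requires at least 2 instruments")

  w <- ivw_weights(data)
  ratio <- data$beta_outcome / data$beta_exposure
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - beta)^2)
  df <- n - 1L
  overdispersion <- Q / df
  se_random <- se_fixed * sqrt(max(1, overdispersion))

  use_random <- switch(mode,
    fixed = FALSE,
    random = TRUE,
    auto = overdispersion > 1
  )
  se <- if (use_random) se_random else se_fixed
  new_mr_result(
    method = if (use_random) "ivw_random" else "ivw_fixed",
    beta = beta, se = se, pvalue = norm_p(beta, se), n_snps = n,
    se_fixed = se_fixed, se_random = se_random,
    Q = Q, Q_df = df, Q_pvalue = stats::pchisq(Q, df, lower.tail = FALSE),
    mode = mode
  )
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure associations with a
#' free intercept (weights `1 / se_outcome^2`), after orienting every
#' instrument so that `beta_exposure >= 0`. The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy, and its two-sided test is the Egger pleiotropy
#' test. SEs carry a multiplicative overdispersion factor floored at 1;
#' p-values use the t distribution with `n - 2` degrees of freedom.
#'
#' @inheritParams mr_wald_ratio
#' @return An object of class `"mr_egger"`: `estimate` (an `"mr_result"`
#'   for the slope) and `pleiotropy` (list with `intercept`, `se`,
#'   `pvalue`), plus `Q`, `Q_df`, `Q_pvalue` for the Egger fit.
#' @export
mr_egger <- function(data) {
  assert_columns(data, mr_cols, "`data`")
  n <- nrow(data)
  if (n < 3) abort("MR-Egger requires at least 3 instruments")

  s <- ifelse(data$beta_exposure < 0, -1, 1)
  bx <- s * data$beta_exposure
  by <- s * data$beta_outcome
  w <- 1 / data$se_outcome^2

  fit <- wls_fit(cbind(intercept = 1, slope = bx), by, w, floor_dispersion = TRUE)
  df <- n - 2L
  slope <- fit$coef[["slope"]]
  slope_se <- fit$se[["slope"]]
  int <- fit$coef[["intercept"]]
  int_se <- fit$se[["intercept"]]

  est <- new_mr_result(
    method = "egger", beta = slope, se = slope_se,
    pvalue = 2 * stats::pt(-abs(slope / slope_se), df), n_snps = n
  )
  structure(
    list(
      estimate = est,
      pleiotropy = list(
        intercept = int, se = int_se,
        pvalue = 2 * stats::pt(-abs(int / int_se), df)
      ),
      Q = fit$rss_w, Q_df = df,
      Q_pvalue = stats::pchisq(fit$rss_w, df, lower.tail = FALSE),
      n_snps = n
    ),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  pleiotropy intercept = %.4f (SE %.4f), p = %.3g\n",
              x$pleiotropy$intercept, x$pleiotropy$se, x$pleiotropy$pvalue))
  invisible(x)
}

# Weighted least squares by the normal equations. Returns coefficients,
# SEs (with residual overdispersion phi, optionally floored at 1),
# the weighted RSS and phi.
wls_fit <- function(X, y, w, floor_dispersion = TRUE) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  coef <- drop(solve(XtWX, XtW %*% y))
  resid <- y - drop(X %*% coef)
  rss_w <- sum(w * resid^2)
  df <- nrow(X) - ncol(X)
  phi <- if (df > 0) rss_w / df else 1
  if (floor_dispersion) phi <- max(1, phi)
  se <- sqrt(diag(solve(XtWX)) * phi)
  names(coef) <- names(se) <- colnames(X)
  list(coef = coef, se = se, rss_w = rss_w, phi = phi, XtWX = XtWX)
}

# Weighted median of ratio estimates: order the ratios, accumulate
# normalized weights, and interpolate where the centred cumulative weight
# crosses one half.
weighted_median_estimate <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  p <- weight[ord] / sum(weight)
  s <- cumsum(p) - p / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] < 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median estimate
#'
#' Takes the inverse-variance weighted median of the per-variant Wald
#' ratios; consistent as long as instruments holding more than half of the
#' total weight are valid. The SE comes from a seeded parametric bootstrap
#' that redraws exposure and outcome associations from their sampling
#' distributions and recomputes the weighted median.
#'
#' @inheritParams mr_wald_ratio
#' @param n_boot Number of bootstrap draws (default 1000; a warning is
#'   issued below 100).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @return An `"mr_result"` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  assert_columns(data, mr_cols, "`data`")
  n <- nrow(data)
  if (n < 3) abort("weighted median requires at least 3 instruments")
  if (n_boot < 100) warn("`n_boot` < 100: bootstrap SE will be unstable")

  ratio <- data$beta_outcome / data$beta_exposure
  w <- ivw_weights(data)
  beta <- weighted_median_estimate(ratio, w)

  boots <- with_optional_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(n, data$beta_exposure, data$se_exposure)
      by <- rnorm(n, data$beta_outcome, data$se_outcome)
      weighted_median_estimate(by / bx, (bx / data$se_outcome)^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_result(
    method = "weighted_median", beta = beta, se = se,
    pvalue = norm_p(beta, se), n_snps = n, n_boot = n_boot, seed = seed
  )
}
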
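# Sensitivity analyses: Cochran's Q heterogeneity, leave-one-out,
# simulation-based outlier detection (MR-PRESSO style), and the Steiger
# directionality test.

#' Cochran's Q heterogeneity test
#'
#' Measures dispersion of the per-variant Wald ratios around a reference
#' causal estimate: `Q = sum(w_j * (ratio_j - beta_ref)^2)` with the IVW
#' weights, compared against a chi-square distribution with `n - 1` degrees
#' of freedom. When `beta_ref` is the IVW estimate itself, Q equals the
#' weighted residual sum of squares of the through-origin IVW fit.
#'
#' @inheritParams mr_wald_ratio
#' @param beta_ref Reference effect; defaults to the IVW estimate of `data`.
#' @return Tibble with `Q`, `df`, `pvalue`.
#' @export
mr_cochran_q <- function(data, beta_ref = NULL) {
  assert_columns(data, mr_cols, "`data`")
  n <- nrow(data)
  if (n < 2) abort("Cochran's Q requires at least 2 instruments")
  if (is.null(beta_ref)) beta_ref <- mr_ivw(data)$beta
  w <- ivw_weights(data)
  ratio <- data$beta_outcome / data$beta_exposure
  Q <- sum(w * (ratio - beta_ref)^2)
  df <- n - 1L
  tibble::tibble(Q = Q, df = df,
                 pvalue = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each instrument in turn; a large
#' shift after removing one variant flags that variant as influential.
#'
#' @inheritParams mr_ivw
#' @return A tibble of class `"mr_loo"`, one row per omitted variant:
#'   `variant_id`, `n_snps`, `beta`, `se`, `pvalue`, `odds_ratio`,
#'   `ci_low`, `ci_high`. The full-set estimate is kept in the
#'   `"full_estimate"` attribute.
#' @export
mr_leave_one_out <- function(data, mode = "auto") {
  assert_columns(data, mr_cols, "`data`")
  n <- nrow(data)
  if (n < 3) abort("leave-one-out requires at least 3 instruments")
  ids <- if ("variant_id" %in% names(data)) data$variant_id else
    as.character(seq_len(n))

  rows <- purrr::map(seq_len(n), function(j) {
    est <- mr_ivw(data[-j, , drop = FALSE], mode = mode)
    ci <- ci_limits(est$beta, est$se)
    tibble::tibble(
      variant_id = ids[j], n_snps = est$n_snps, beta = est$beta, se = est$se,
      pvalue = est$pvalue, odds_ratio = exp(est$beta),
      ci_low = exp(ci[1]), ci_high = exp(ci[2])
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "full_estimate") <- mr_ivw(data, mode = mode)
  class(out) <- c("mr_loo", class(out))
  out
}

#' Simulation-based pleiotropy outlier test (MR-PRESSO style)
#'
#' Global test: each instrument's variance-standardized squared deviation
#' from the leave-one-out IVW prediction is summed into an observed
#' residual sum of squares, whose null distribution is obtained by `n_sim`
#' seeded parametric simulations under the no-pleiotropy model (outcome
#' associations redrawn around their leave-one-out predictions, exposure
#' associations around their estimates). Per-instrument outlier p-values
#' come from the same comparison per SNP, Bonferroni-adjusted over
#' instruments; flagged outliers are removed and a corrected IVW estimate
#' is reported.
#'
#' @inheritParams mr_wald_ratio
#' @param n_sim Number of null simulations (default 1000; at least 1000
#'   recommended so the Bonferroni-adjusted outlier test has resolution).
#' @param seed Optional integer seed.
#' @param outlier_p_threshold Bonferroni-adjusted p-value below which an
#'   instrument is declared an outlier (default 0.05).
#' @return An object of class `"mr_presso"`: `global_rss_p`, `outlier_tests`
#'   (tibble: `variant_id`, `rss`, `pvalue`, `p_bonferroni`, `outlier`),
#'   `outliers`, `corrected` (IVW `"mr_result"` without the outliers, or
#'   `NULL` when none were flagged), `n_sim`, `seed`.
#' @export
mr_presso <- function(data, n_sim = 1000, seed = NULL,
                      outlier_p_threshold = 0.05) {
  assert_columns(data, mr_cols, "`data`")
  n <- nrow(data)
  if (n < 4) abort("outlier test requires at least 4 instruments")
  ids <- if ("variant_id" %in% names(data)) data$variant_id else
    as.character(seq_len(n))

  w <- ivw_weights(data)
  ratio <- data$beta_outcome / data$beta_exposure
  S0 <- sum(w); S1 <- sum(w * ratio)
  beta_loo <- (S1 - w * ratio) / (S0 - w) # IVW estimate without variant j
  expected <- beta_loo * data$beta_exposure
  obs <- ((data$beta_outcome - expected) / data$se_outcome)^2
  rss_obs <- sum(obs)

  sim <- with_optional_seed(seed, {
    by_sim <- matrix(rnorm(n_sim * n, mean = rep(expected, each = n_sim),
                           sd = rep(data$se_outcome, each = n_sim)),
                     nrow = n_sim)
    bx_sim <- matrix(rnorm(n_sim * n, mean = rep(data$beta_exposure, each = n_sim),
                           sd = rep(data$se_exposure, each = n_sim)),
                     nrow = n_sim)
    res <- sweep(by_sim - sweep(bx_sim, 2, beta_loo, `*`), 2,
                 data$se_outcome, `/`)^2
    list(res = res, rss = rowSums(res))
  })
  if (sd(sim$rss) == 0) abort("degenerate zero-variance null simulation")

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + colSums(sim$res >= matrix(obs, n_sim, n, byrow = TRUE))) /
    (n_sim + 1)
  p_bonf <- pmin(1, outlier_p * n)
  is_outlier <- p_bonf < outlier_p_threshold

  corrected <- NULL
  if (any(is_outlier) && sum(!is_outlier) >= 2) {
    corrected <- mr_ivw(data[!is_outlier, , drop = FALSE])
    corrected$method <- "presso_corrected"
  }
  structure(
    list(
      global_rss_p = global_p,
      outlier_tests = tibble::tibble(
        variant_id = ids, rss = obs, pvalue = outlier_p,
        p_bonferroni = p_bonf, outlier = is_outlier
      ),
      outliers = ids[is_outlier],
      corrected = corrected,
      n_sim = n_sim, seed = seed, n_snps = n
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf(
    "<mr_presso> global RSS p = %.3g (%d sims); %d outlier%s%s\n",
    x$global_rss_p, x$n_sim, length(x$outliers),
    if (length(x$outliers) == 1) "" else "s",
    if (length(x$outliers) > 0) paste0(": ", paste(x$outliers, collapse = ", "))
    else ""
  ))
  if (!is.null(x$corrected)) {
    cat("  corrected "); print(x$corrected)
  }
  invisible(x)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against
#' the variance they explain in the outcome; a correct causal orientation
#' requires the former to exceed the latter. Per-variant variance explained
#' uses the t-statistic transform `r2_j = t_j^2 / (t_j^2 + n - 2)` (which
#' requires no allele-frequency or case-fraction information), summed over
#' instruments; the p-value is a Fisher-z test of the difference between
#' the two implied correlations across the independent samples.
#'
#' @inheritParams mr_wald_ratio
#' @param n_exposure,n_outcome GWAS sample sizes for the two traits (for a
#'   binary outcome, an effective sample size is appropriate).
#' @return Tibble with `r2_exposure`, `r2_outcome`, `direction_correct`,
#'   `statistic` (z), `pvalue`.
#' @export
mr_steiger <- function(data, n_exposure, n_outcome) {
  assert_columns(data, mr_cols, "`data`")
  if (n_exposure <= 3 || n_outcome <= 3) abort("sample sizes must exceed 3")
  t2r2 <- function(beta, se, n) {
    t2 <- (beta / se)^2
    sum(t2 / (t2 + n - 2))
  }
  r2_exp <- min(t2r2(data$beta_exposure, data$se_exposure, n_exposure), 1 - 1e-12)
  r2_out <- min(t2r2(data$beta_outcome, data$se_outcome, n_outcome), 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  tibble::tibble(
    r2_exposure = r2_exp, r2_outcome = r2_out,
    direction_correct = r2_exp > r2_out,
    statistic = z, pvalue = 2 * stats::pnorm(-abs(z))
  )
}
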
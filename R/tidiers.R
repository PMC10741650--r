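# broom-style tidiers for the package's fitted objects.

mr_tidy_row <- function(term, estimate, std.error, statistic, p.value,
                        conf_level, exponentiate) {
  ci <- ci_limits(estimate, std.error, conf_level)
  out <- tibble::tibble(
    term = term, estimate = estimate, std.error = std.error,
    statistic = statistic, p.value = p.value,
    conf.low = ci[1], conf.high = ci[2]
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Tidy an MR estimate
#'
#' @param x An `"mr_result"`.
#' @param conf_level Confidence level for the Wald interval.
#' @param exponentiate Report the estimate and interval on the odds-ratio
#'   scale (the SE stays on the log scale, as in broom).
#' @param ... Unused.
#' @return A one-row tibble with `method`, `n_snps`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  dplyr::mutate(
    mr_tidy_row("exposure", x$beta, x$se, x$beta / x$se, x$pvalue,
                conf_level, exponentiate),
    method = x$method, n_snps = x$n_snps, .before = 1
  )
}

#' @rdname tidy.mr_result
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_snps = x$n_snps,
    Q = x$Q %||% NA_real_, Q.df = x$Q_df %||% NA_integer_,
    Q.pvalue = x$Q_pvalue %||% NA_real_
  )
}

#' Tidy an MR-Egger fit
#'
#' @param x An `"mr_egger"`.
#' @inheritParams tidy.mr_result
#' @return A two-row tibble: the causal slope and the pleiotropy
#'   intercept. The intercept row is never exponentiated.
#' @method tidy mr_egger
#' @export
tidy.mr_egger <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  slope <- dplyr::mutate(
    mr_tidy_row("exposure", x$estimate$beta, x$estimate$se,
                x$estimate$beta / x$estimate$se, x$estimate$pvalue,
                conf_level, exponentiate),
    method = "egger", n_snps = x$n_snps, .before = 1
  )
  int <- dplyr::mutate(
    mr_tidy_row("pleiotropy_intercept", x$pleiotropy$intercept,
                x$pleiotropy$se, x$pleiotropy$intercept / x$pleiotropy$se,
                x$pleiotropy$pvalue, conf_level, FALSE),
    method = "egger", n_snps = x$n_snps, .before = 1
  )
  dplyr::bind_rows(slope, int)
}

#' @rdname tidy.mr_egger
#' @method glance mr_egger
#' @export
glance.mr_egger <- function(x, ...) {
  tibble::tibble(
    method = "egger", n_snps = x$n_snps, Q = x$Q, Q.df = x$Q_df,
    Q.pvalue = x$Q_pvalue,
    intercept.pvalue = x$pleiotropy$pvalue
  )
}

#' Tidy a multivariable MR fit
#'
#' @param x An `"mvmr_result"`.
#' @inheritParams tidy.mr_result
#' @return One row per exposure in the joint model.
#' @method tidy mvmr_result
#' @export
tidy.mvmr_result <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  dplyr::bind_rows(purrr::map(seq_along(x$exposures), function(i) {
    dplyr::mutate(
      mr_tidy_row(x$exposures[i], x$beta[[i]], x$se[[i]],
                  x$beta[[i]] / x$se[[i]], x$pvalue[[i]],
                  conf_level, exponentiate),
      method = "mvmr_ivw", n_snps = x$n_snps, .before = 1
    )
  }))
}

#' @rdname tidy.mvmr_result
#' @method glance mvmr_result
#' @export
glance.mvmr_result <- function(x, ...) {
  tibble::tibble(
    method = "mvmr_ivw", n_snps = x$n_snps, n_exposures = length(x$exposures),
    Q = x$Q, Q.df = x$Q_df, Q.pvalue = x$Q_pvalue,
    condition_number = x$condition_number
  )
}

#' Tidy an outlier-test result
#'
#' @param x An `"mr_presso"`.
#' @param ... Unused.
#' @return The per-instrument outlier-test tibble.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outlier_tests

#' @rdname tidy.mr_presso
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_rss_p = x$global_rss_p, n_outliers = length(x$outliers),
    n_snps = x$n_snps, n_sim = x$n_sim
  )
}

#' Tidy a mediation decomposition
#'
#' @param x An `"mr_mediation"`.
#' @param ... Unused.
#' @return One row per path coefficient (`A`, `B`, `C`, `C_prime`,
#'   `indirect`, `proportion`).
#' @method tidy mr_mediation
#' @export
tidy.mr_mediation <- function(x, ...) {
  tibble::tibble(
    term = c("A", "B", "C", "C_prime", "indirect", "proportion"),
    estimate = c(x$A, x$B, x$C, x$C_prime, x$indirect, x$proportion)
  )
}

#' @rdname tidy.mr_mediation
#' @method glance mr_mediation
#' @export
glance.mr_mediation <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, mediator = x$mediator, outcome = x$outcome,
    proportion = x$proportion,
    difference_proportion = x$difference_proportion,
    ci_low = x$ci_low, ci_high = x$ci_high, ci_method = x$ci_method
  )
}
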
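# shared internal helpers

# two-sided normal p-value from an estimate and its SE
norm_p <- function(beta, se) 2 * stats::pnorm(-abs(beta) / se)

# Wald-type confidence limits on the log scale
ci_limits <- function(beta, se, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(beta - z * se, beta + z * se)
}

# run `expr` under a fixed RNG state when a seed is supplied, without
# touching the caller's RNG otherwise
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

#' Format an odds ratio with its 95% confidence interval
#'
#' Exponentiates a log-odds estimate and its Wald limits and renders them to
#' three decimals as `"OR (low, high)"`, the precision used in published MR
#' result tables.
#'
#' @param beta Log-odds (or log-linear) effect estimate.
#' @param se Standard error of `beta`; must be positive.
#' @return A character vector like `"1.036 (1.029, 1.042)"`.
#' @examples
#' format_or(0.035, 0.0032)
#' @export
format_or <- function(beta, se) {
  if (any(se <= 0)) abort("`se` must be positive")
  sprintf(
    "%.3f (%.3f, %.3f)",
    exp(beta), exp(beta - 1.96 * se), exp(beta + 1.96 * se)
  )
}

#' Label p-values against a Bonferroni-adjusted family threshold
#'
#' Effects with p below `alpha_family / n_tests` are labelled
#' `"significant"`; those between the adjusted threshold and 0.05 are
#' `"potentially significant"`; the rest `"ns"`.
#'
#' @param p Vector of p-values.
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param n_tests Number of tests in the family (default 5, one per stroke
#'   outcome analogue).
#' @return Character vector of labels.
#' @export
significance_label <- function(p, alpha_family = 0.05, n_tests = 5) {
  cutoff <- alpha_family / n_tests
  dplyr::case_when(
    p < cutoff ~ "significant",
    p < 0.05 ~ "potentially significant",
    TRUE ~ "ns"
  )
}
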
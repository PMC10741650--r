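# Two-step mediation decomposition: the total effect C of an exposure on
# an outcome splits into a direct part C' and an indirect part A * B
# carried by a mediator, where A is the exposure's total effect on the
# mediator (univariable MR) and B the mediator's effect on the outcome
# adjusted for the exposure (multivariable MR).

#' Decompose a total causal effect into direct and mediated parts
#'
#' Computes the product-method indirect effect `A * B`, the mediated
#' proportion `A * B / C`, and, when the direct effect `C_prime` is
#' supplied, the difference-method proportion `(C - C_prime) / C` as a
#' cross-check. With noiseless linear effects the two methods agree
#' exactly.
#'
#' @param C Total effect of exposure on outcome (univariable MR).
#' @param A Total effect of exposure on mediator (univariable MR).
#' @param B Effect of mediator on outcome adjusted for exposure (MVMR).
#' @param C_prime Direct effect of exposure on outcome adjusted for the
#'   mediator (same MVMR); defaults to `C - A * B`.
#' @param exposure,mediator,outcome Trait labels carried into reports.
#' @return An object of class `"mr_mediation"` with elements `A`, `B`, `C`,
#'   `C_prime`, `indirect`, `proportion`, `difference_proportion`, and
#'   `proportion_defined` (`FALSE`, with `NA` proportions rather than an
#'   error, when `C == 0`). Confidence limits are added by
#'   [proportion_ci()].
#' @examples
#' decompose_mediation(C = log(1.113), A = 0.3, B = 0.1)
#' @export
decompose_mediation <- function(C, A, B, C_prime = NULL,
                                exposure = "exposure", mediator = "mediator",
                                outcome = "outcome") {
  C_prime <- C_prime %||% (C - A * B)
  indirect <- A * B
  defined <- is.finite(C) && C != 0
  structure(
    list(
      A = A, B = B, C = C, C_prime = C_prime,
      indirect = indirect,
      proportion = if (defined) indirect / C else NA_real_,
      difference_proportion = if (defined) (C - C_prime) / C else NA_real_,
      proportion_defined = defined,
      exposure = exposure, mediator = mediator, outcome = outcome,
      ci_low = NA_real_, ci_high = NA_real_, ci_method = NA_character_,
      seed = NULL
    ),
    class = "mr_mediation"
  )
}

#' Confidence interval for the mediated proportion
#'
#' Two methods for the sampling uncertainty of `A * B / C`, both treating
#' the three estimates as independent (non-overlapping two-sample
#' contrasts). The seeded parametric bootstrap (default) redraws
#' `(A, B, C)` from normal sampling distributions and takes percentile
#' limits of the recomputed proportion; it is preferred because the ratio
#' of correlated normals is itself poorly normal. The delta method uses
#' `var(A * B) = A^2 se_B^2 + B^2 se_A^2` and propagates the ratio to `C`
#' with zero covariances; it serves as a fast cross-check.
#'
#' @param decomp An [decompose_mediation()] result.
#' @param se_A,se_B,se_C Standard errors of the three inputs (positive;
#'   zero gives the degenerate point interval).
#' @param method `"bootstrap"` (default) or `"delta"`.
#' @param n_boot Bootstrap draws (default 10000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return `decomp` with `ci_low`, `ci_high`, `ci_method` (and `seed`)
#'   filled in. A warning is raised when more than 1% of bootstrap draws
#'   put `C` across zero, where the proportion is unstable.
#' @export
proportion_ci <- function(decomp, se_A, se_B, se_C,
                          method = c("bootstrap", "delta"),
                          n_boot = 10000, seed = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  if (any(c(se_A, se_B, se_C) < 0)) abort("standard errors must be non-negative")
  if (!decomp$proportion_defined) {
    warn("total effect C is zero: proportion CI undefined")
    return(decomp)
  }
  alpha <- 1 - conf_level
  if (method == "delta") {
    var_ind <- decomp$A^2 * se_B^2 + decomp$B^2 * se_A^2
    var_prop <- var_ind / decomp$C^2 +
      decomp$indirect^2 * se_C^2 / decomp$C^4
    z <- stats::qnorm(1 - alpha / 2)
    decomp$ci_low <- decomp$proportion - z * sqrt(var_prop)
    decomp$ci_high <- decomp$proportion + z * sqrt(var_prop)
  } else {
    draws <- with_optional_seed(seed, {
      Ad <- rnorm(n_boot, decomp$A, se_A)
      Bd <- rnorm(n_boot, decomp$B, se_B)
      Cd <- rnorm(n_boot, decomp$C, se_C)
      if (mean(sign(Cd) != sign(decomp$C)) > 0.01) {
        warn("proportion CI unstable: total effect C crosses zero in > 1% of bootstrap draws")
      }
      Ad * Bd / Cd
    })
    qs <- quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    decomp$ci_low <- qs[1]
    decomp$ci_high <- qs[2]
    decomp$seed <- seed
  }
  decomp$ci_method <- method
  decomp
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf(
    "<mr_mediation> %s -> %s -> %s\n  A = %.4f, B = %.4f, C = %.4f, C' = %.4f\n  indirect = %.4f, proportion mediated = %s",
    x$exposure, x$mediator, x$outcome, x$A, x$B, x$C, x$C_prime, x$indirect,
    if (x$proportion_defined) sprintf("%.2f%%", 100 * x$proportion) else "undefined (C = 0)"
  ))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" [95%% CI %.2f%%, %.2f%%; %s]",
                100 * x$ci_low, 100 * x$ci_high, x$ci_method))
  }
  cat("\n")
  invisible(x)
}

#' Two-step MR mediation analysis from summary statistics
#'
#' Runs the full two-step procedure: (1) select exposure instruments and
#' estimate the total effect `C` (exposure -> outcome) and the
#' exposure-to-mediator effect `A` by univariable IVW; (2) form the union
#' of exposure and mediator instruments and estimate the mediator's direct
#' effect `B` and the exposure's direct effect `C_prime` by multivariable
#' IVW; then decompose and attach a bootstrap CI for the mediated
#' proportion.
#'
#' @param exposure,mediator,outcome Summary-statistics tibbles
#'   ([read_sumstats()] layout).
#' @param qc A [qc_config()] applied when selecting instruments for each
#'   trait.
#' @param ld_info Optional pairwise LD table (see [select_instruments()]).
#' @param n_boot Bootstrap draws for the proportion CI.
#' @param seed Optional integer seed (bootstrap).
#' @param mediator_name Label for the mediator (default from the table's
#'   `"trait"` attribute, else `"mediator"`).
#' @return An `"mr_mediation"` object with the component fits attached as
#'   `fits` (list: `C`, `A` mr_results; `mvmr` mvmr_result).
#' @examples
#' study <- simulate_study(simulation_config(seed = 3))
#' med <- mediate_two_step(study$tables$exposure, study$tables$mediator,
#'                         study$tables$outcome, seed = 3)
#' tidy(med)
#' @export
mediate_two_step <- function(exposure, mediator, outcome, qc = qc_config(),
                             ld_info = NULL, n_boot = 5000, seed = NULL,
                             mediator_name = NULL) {
  mediator_name <- mediator_name %||% attr(mediator, "trait") %||% "mediator"
  exposure_name <- attr(exposure, "trait") %||% "exposure"
  outcome_name <- attr(outcome, "trait") %||% "outcome"

  iv_exp <- select_instruments(exposure, qc, ld_info)
  C_est <- mr_ivw(harmonize(iv_exp, outcome))
  A_est <- mr_ivw(harmonize(iv_exp, mediator))

  iv_med <- select_instruments(mediator, qc, ld_info)
  union_ids <- union(iv_exp$variant_id, iv_med$variant_id)
  exp_union <- exposure[exposure$variant_id %in% union_ids, , drop = FALSE]
  meds <- stats::setNames(list(mediator), mediator_name)
  hs_mv <- harmonize(exp_union, outcome, mediators = meds)
  mv <- mvmr_ivw(hs_mv, exposures = c("exposure", mediator_name))

  decomp <- decompose_mediation(
    C = C_est$beta, A = A_est$beta,
    B = mv$beta[[mediator_name]], C_prime = mv$beta[["exposure"]],
    exposure = exposure_name, mediator = mediator_name, outcome = outcome_name
  )
  decomp <- proportion_ci(
    decomp, se_A = A_est$se, se_B = mv$se[[mediator_name]], se_C = C_est$se,
    method = "bootstrap", n_boot = n_boot, seed = seed
  )
  decomp$fits <- list(C = C_est, A = A_est, mvmr = mv)
  decomp
}
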
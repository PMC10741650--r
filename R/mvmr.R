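# Multivariable MR: joint weighted regression of outcome associations on
# several exposures' associations, yielding direct effects.

#' Multivariable IVW estimate
#'
#' Regresses the outcome associations jointly on the association columns of
#' several exposures (weighted through-origin least squares, weights
#' `1 / se_outcome^2`), so each coefficient is that exposure's direct
#' effect conditional on the others. Per-coefficient SEs come from the
#' weighted normal equations with a multiplicative overdispersion factor
#' `max(1, Q / (n - K))`. With a single exposure this reduces exactly to
#' [mr_ivw()] (auto mode).
#'
#' A rank-deficient design raises an error naming the most collinear pair
#' of exposures; a high condition number triggers a warning, since near
#' collinearity (e.g. systolic with diastolic blood pressure) makes the
#' separate direct effects hard to identify.
#'
#' @param data Instrument set carrying `beta_<name>` / `se_<name>` columns
#'   for every exposure in the model plus `beta_outcome`, `se_outcome`
#'   (see [harmonize()] with `mediators`).
#' @param exposures Character vector of exposure names to include; defaults
#'   to `"exposure"` plus all mediators recorded on `data`.
#' @return An object of class `"mvmr_result"`: `exposures`, `beta`, `se`,
#'   `pvalue` (named vectors), `n_snps`, `Q`, `Q_df`, `Q_pvalue`,
#'   `condition_number`.
#' @export
mvmr_ivw <- function(data, exposures = NULL) {
  exposures <- exposures %||% c("exposure", attr(data, "mediators"))
  if (length(exposures) < 1) abort("no exposures specified")
  beta_cols <- paste0("beta_", exposures)
  assert_columns(data, c(beta_cols, "beta_outcome", "se_outcome"), "`data`")

  K <- length(exposures)
  n <- nrow(data)
  if (n <= K) abort("multivariable IVW requires more instruments than exposures")

  X <- as.matrix(data[beta_cols])
  colnames(X) <- exposures
  y <- data$beta_outcome
  w <- 1 / data$se_outcome^2

  Xw <- X * sqrt(w)
  qrX <- qr(Xw)
  if (qrX$rank < K) {
    cors <- stats::cor(X)
    cors[upper.tri(cors, diag = TRUE)] <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "collinear exposures: '%s' and '%s' are linearly dependent in the design",
      exposures[worst[2]], exposures[worst[1]]
    ))
  }
  cond <- kappa(Xw, exact = TRUE)
  if (K > 1 && cond > 30) {
    warn(sprintf(
      "nearly collinear MVMR design (condition number %.1f): direct effects of correlated exposures may be poorly identified",
      cond
    ))
  }

  fit <- wls_fit(X, y, w, floor_dispersion = TRUE)
  df <- n - K
  structure(
    list(
      exposures = exposures,
      beta = fit$coef, se = fit$se,
      pvalue = norm_p(fit$coef, fit$se),
      n_snps = n, Q = fit$rss_w, Q_df = df,
      Q_pvalue = stats::pchisq(fit$rss_w, df, lower.tail = FALSE),
      condition_number = cond
    ),
    class = "mvmr_result"
  )
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d instruments, %d exposure%s\n",
              x$n_snps, length(x$exposures),
              if (length(x$exposures) > 1) "s" else ""))
  print(tidy(x))
  invisible(x)
}
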
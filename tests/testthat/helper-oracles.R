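# Shared fixtures and independent oracles.
#
# The oracles deliberately use a different route than the package:
# weighted least squares goes through stats::lm, the weighted median
# through explicit enumeration.

# Random harmonized-instrument tibble with a known causal slope and
# optional intercept (directional pleiotropy).
make_instruments <- function(n, slope = 0.2, intercept = 0, seed = 1,
                             se_outcome_range = c(0.005, 0.02),
                             se_exposure = 0.005, noise = TRUE) {
  withr::with_seed(seed, {
    bx <- runif(n, 0.02, 0.15) * sample(c(-1, 1), n, replace = TRUE)
    se_y <- runif(n, se_outcome_range[1], se_outcome_range[2])
    by <- intercept * sign(bx) + slope * bx + if (noise) rnorm(n, 0, se_y) else 0
    tibble::tibble(
      variant_id = sprintf("v%02d", seq_len(n)),
      beta_exposure = bx, se_exposure = se_exposure,
      beta_outcome = by, se_outcome = se_y
    )
  })
}

# WLS oracle through lm(): through-origin unless intercept = TRUE.
# Returns coefficients and model-based SEs with multiplicative
# overdispersion floored at 1 (the package's convention).
lm_wls_oracle <- function(X, y, w, intercept = FALSE) {
  df <- as.data.frame(X)
  form <- if (intercept) y ~ . else y ~ . - 1
  fit <- lm(form, data = cbind(df, y = y), weights = w)
  sm <- summary(fit)
  coef <- stats::coef(fit)
  # lm's SEs already include sigma; rescale to the floored-dispersion rule
  se <- sm$coefficients[, "Std. Error"] / sm$sigma * max(1, sm$sigma)
  list(coef = coef, se = se, rss_w = sum(w * stats::resid(fit)^2))
}

# Brute-force weighted median: evaluate the weighted-quantile crossing by
# hand over the sorted ratios.
enum_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; p <- w[o] / sum(w)
  s <- cumsum(p) - p / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] < 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Small canonical-format sumstats tibble for IO tests.
toy_sumstats <- function() {
  tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    chromosome = c("1", "2", "3"),
    position = c(1000L, 2000L, 3000L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.2, 0.4, 0.3),
    beta = c(0.10, -0.05, 0.08),
    se = c(0.01, 0.012, 0.009),
    pvalue = c(1e-20, 3e-5, 2e-18),
    n = c(10000, 10000, 10000)
  )
}

# A fast small-study simulation config used across tests.
small_config <- function(...) {
  simulation_config(n_variants = 40, n_mediator_variants = 30, ...)
}
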
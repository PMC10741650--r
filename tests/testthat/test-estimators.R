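test_that("Wald ratio divides effects and propagates the outcome SE", {
  d <- tibble::tibble(beta_exposure = c(0.1, -0.1), se_exposure = 0.005,
                      beta_outcome = 0.02, se_outcome = 0.01)
  wr <- mr_wald_ratio(d)
  expect_equal(wr$beta, c(0.2, -0.2))
  expect_equal(wr$se, c(0.1, 0.1))
  expect_error(
    mr_wald_ratio(dplyr::mutate(d, beta_exposure = c(0, 0.1))), "zero"
  )
})

test_that("second-order Wald SE matches a Monte-Carlo propagation oracle", {
  d <- tibble::tibble(beta_exposure = 0.1, se_exposure = 0.01,
                      beta_outcome = 0.02, se_outcome = 0.01)
  se2 <- mr_wald_ratio(d, second_order = TRUE)$se
  mc <- withr::with_seed(99, {
    bx <- rnorm(1e6, d$beta_exposure, d$se_exposure)
    by <- rnorm(1e6, d$beta_outcome, d$se_outcome)
    sd(by / bx)
  })
  expect_equal(se2, mc, tolerance = 0.02)
  # and the first-order SE is smaller by construction
  expect_lt(mr_wald_ratio(d)$se, se2)
})

test_that("IVW collapses equal ratios exactly and matches hand arithmetic", {
  d <- tibble::tibble(beta_exposure = c(0.1, 0.2, 0.05), se_exposure = 0.005,
                      beta_outcome = c(0.02, 0.04, 0.01), se_outcome = 0.01)
  est <- mr_ivw(d)
  expect_equal(est$beta, 0.2)
  expect_equal(est$Q, 0)
  expect_equal(est$method, "ivw_fixed")

  # w = (0.1/0.01)^2 = 100 and (0.2/0.01)^2 = 400; ratios 0.3, 0.1
  d2 <- tibble::tibble(beta_exposure = c(0.1, 0.2), se_exposure = 0.005,
                       beta_outcome = c(0.03, 0.02), se_outcome = 0.01)
  expect_equal(mr_ivw(d2)$beta, (100 * 0.3 + 400 * 0.1) / 500)
  expect_equal(mr_ivw(d2, mode = "fixed")$se, 1 / sqrt(500))
})

test_that("IVW is invariant to instrument order and per-variant sign flips", {
  d <- make_instruments(15, seed = 3)
  base <- mr_ivw(d)
  perm <- withr::with_seed(1, d[sample(nrow(d)), ])
  expect_identical(mr_ivw(perm)[c("beta", "se", "Q")], base[c("beta", "se", "Q")])
  flip <- dplyr::mutate(d, beta_exposure = -beta_exposure,
                        beta_outcome = -beta_outcome)
  expect_equal(mr_ivw(flip)$beta, base$beta, tolerance = 1e-14)
  expect_error(mr_ivw(d[1, ]), "at least 2")
})

test_that("IVW and Egger equal the lm weighted-least-squares oracle", {
  for (s in 1:10) {
    d <- make_instruments(12, slope = 0.25, intercept = 0.005, seed = s)
    w <- 1 / d$se_outcome^2
    o_ivw <- lm_wls_oracle(cbind(x = d$beta_exposure), d$beta_outcome, w)
    est <- mr_ivw(d, mode = "fixed")
    expect_equal(est$beta, unname(o_ivw$coef), tolerance = 1e-12)
    expect_equal(mr_ivw(d)$Q, o_ivw$rss_w, tolerance = 1e-10)

    s2 <- ifelse(d$beta_exposure < 0, -1, 1)
    o_egg <- lm_wls_oracle(cbind(x = s2 * d$beta_exposure),
                           s2 * d$beta_outcome, w, intercept = TRUE)
    egg <- mr_egger(d)
    expect_equal(egg$estimate$beta, unname(o_egg$coef["x"]), tolerance = 1e-12)
    expect_equal(egg$pleiotropy$intercept, unname(o_egg$coef["(Intercept)"]),
                 tolerance = 1e-12)
    expect_equal(egg$estimate$se, unname(o_egg$se["x"]), tolerance = 1e-10)
  }
})

test_that("Egger recovers exact linear and affine generating models", {
  d <- make_instruments(10, slope = 0.3, seed = 5, noise = FALSE)
  egg <- mr_egger(d)
  expect_equal(egg$estimate$beta, 0.3, tolerance = 1e-12)
  expect_equal(egg$pleiotropy$intercept, 0, tolerance = 1e-12)

  d2 <- make_instruments(10, slope = 0.3, intercept = 0.01, seed = 5,
                         noise = FALSE)
  egg2 <- mr_egger(d2)
  expect_equal(egg2$estimate$beta, 0.3, tolerance = 1e-12)
  expect_equal(egg2$pleiotropy$intercept, 0.01, tolerance = 1e-12)
  expect_error(mr_egger(d[1:2, ]), "at least 3")
})

test_that("weighted median interpolates the weighted quantile correctly", {
  d <- tibble::tibble(beta_exposure = 1, se_exposure = 0.01,
                      beta_outcome = c(0.1, 0.2, 0.3), se_outcome = 1)
  # equal weights: the middle ratio exactly
  expect_equal(suppressWarnings(mr_weighted_median(d, n_boot = 50, seed = 1))$beta, 0.2)

  # hand-enumerated interpolation: ratios {0.1, 0.2, 0.4}, weights {.2,.3,.5}
  r <- c(0.1, 0.2, 0.4); w <- c(0.2, 0.3, 0.5)
  expect_equal(mrmediate:::weighted_median_estimate(r, w), 0.275)
  expect_equal(enum_weighted_median(r, w), 0.275)
  for (s in 1:20) {
    rr <- withr::with_seed(s, runif(7, -1, 1))
    ww <- withr::with_seed(s + 100, runif(7, 0.1, 5))
    expect_equal(mrmediate:::weighted_median_estimate(rr, ww),
                 enum_weighted_median(rr, ww))
  }
})

test_that("weighted median resists contamination below half the weight", {
  # 6 instruments at ratio 0.25 carry > 50% of weight, 4 arbitrary
  d <- tibble::tibble(
    beta_exposure = c(rep(0.1, 6), rep(0.05, 4)),
    se_exposure = 0.005,
    beta_outcome = c(rep(0.025, 6), c(0.05, -0.04, 0.09, 0.02)),
    se_outcome = 0.01
  )
  est <- mr_weighted_median(d, n_boot = 200, seed = 2)
  expect_equal(est$beta, 0.25)
  # property: any contamination of < 50% weight stays inside the clean range
  for (s in 1:10) {
    clean <- make_instruments(11, slope = 0.2, seed = s,
                              se_outcome_range = c(0.01, 0.01))
    clean$beta_exposure <- abs(clean$beta_exposure[1]) *
      sign(clean$beta_exposure) # equal weights: 3/11 < 50%
    dirty <- clean
    dirty$beta_outcome[1:3] <- dirty$beta_outcome[1:3] + 5 # wild outliers
    w <- (dirty$beta_exposure / dirty$se_outcome)^2
    expect_lt(sum(w[1:3]), 0.5 * sum(w))
    est <- mrmediate:::weighted_median_estimate(
      dirty$beta_outcome / dirty$beta_exposure, w
    )
    clean_ratios <- clean$beta_outcome / clean$beta_exposure
    expect_gte(est, min(clean_ratios))
    expect_lte(est, max(clean_ratios))
  }
})

test_that("weighted median bootstrap SE is seed-reproducible", {
  d <- make_instruments(10, seed = 8)
  a <- mr_weighted_median(d, n_boot = 300, seed = 42)
  b <- mr_weighted_median(d, n_boot = 300, seed = 42)
  expect_identical(a$se, b$se)
  expect_warning(mr_weighted_median(d, n_boot = 50, seed = 1), "unstable")
})

test_that("tidy and glance return broom-shaped tibbles", {
  d <- make_instruments(10, seed = 8)
  td <- tidy(mr_ivw(d), exponentiate = TRUE)
  expect_true(all(c("method", "term", "estimate", "std.error", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  expect_equal(td$estimate, exp(mr_ivw(d)$beta))
  expect_true(td$conf.low < td$estimate & td$estimate < td$conf.high)
  ge <- glance(mr_egger(d))
  expect_equal(ge$Q.df, 8)
  expect_equal(nrow(tidy(mr_egger(d))), 2)
})
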
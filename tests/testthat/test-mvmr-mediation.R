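test_that("single-exposure MVMR reduces exactly to univariable IVW", {
  d <- make_instruments(15, seed = 4)
  mv <- mvmr_ivw(d, exposures = "exposure")
  uni <- mr_ivw(d) # auto mode shares the floored-overdispersion SE rule
  expect_equal(unname(mv$beta), uni$beta, tolerance = 1e-12)
  expect_equal(unname(mv$se), max(uni$se_fixed, uni$se_random), tolerance = 1e-12)
})

test_that("MVMR recovers an exact two-exposure generating model", {
  withr::with_seed(10, {
    d <- tibble::tibble(
      beta_exposure = runif(20, -0.1, 0.1),
      beta_med = runif(20, -0.2, 0.2),
      se_outcome = runif(20, 0.005, 0.02)
    )
    d$beta_outcome <- 0.1 * d$beta_exposure + 0.3 * d$beta_med
  })
  mv <- mvmr_ivw(d, exposures = c("exposure", "med"))
  expect_equal(unname(mv$beta), c(0.1, 0.3), tolerance = 1e-12)
})

test_that("MVMR equals the multivariable lm oracle on random instances", {
  for (s in 1:10) {
    d <- withr::with_seed(s, tibble::tibble(
      beta_exposure = runif(25, -0.1, 0.1),
      beta_m1 = runif(25, -0.2, 0.2),
      se_outcome = runif(25, 0.005, 0.02),
      beta_outcome = rnorm(25, 0, 0.02)
    ))
    mv <- mvmr_ivw(d, exposures = c("exposure", "m1"))
    o <- lm_wls_oracle(cbind(exposure = d$beta_exposure, m1 = d$beta_m1),
                       d$beta_outcome, 1 / d$se_outcome^2)
    expect_equal(unname(mv$beta), unname(o$coef), tolerance = 1e-10)
    expect_equal(unname(mv$se), unname(o$se), tolerance = 1e-10)
  }
})

test_that("collinear designs error naming the pair; near-collinear warns", {
  d <- make_instruments(10, seed = 1)
  d$beta_copy <- 2 * d$beta_exposure
  expect_error(mvmr_ivw(d, exposures = c("exposure", "copy")),
               "collinear.*exposure.*copy")
  d$beta_near <- d$beta_exposure * (1 + rnorm(10, 0, 1e-4))
  expect_warning(mvmr_ivw(d, exposures = c("exposure", "near")),
                 "condition number")
})

test_that("mediation decomposition follows the product and difference algebra", {
  # null mediated path
  m0 <- decompose_mediation(C = 0.1, A = 0, B = 0.5)
  expect_equal(m0$indirect, 0)
  expect_equal(m0$proportion, 0)
  # simple arithmetic: 0.5 * 0.1 / 0.1 = 50%
  m1 <- decompose_mediation(C = 0.1, A = 0.5, B = 0.1)
  expect_equal(m1$indirect, 0.05)
  expect_equal(m1$proportion, 0.5)
  # product and difference methods agree exactly on noiseless linear truth
  A <- 0.3; B <- 0.12; Cp <- 0.07; C <- Cp + A * B
  m2 <- decompose_mediation(C = C, A = A, B = B, C_prime = Cp)
  expect_equal(m2$proportion, m2$difference_proportion, tolerance = 1e-14)
  # C = 0 flags rather than throws
  m3 <- decompose_mediation(C = 0, A = 0.3, B = 0.1)
  expect_false(m3$proportion_defined)
  expect_true(is.na(m3$proportion))
  expect_warning(proportion_ci(m3, 0.01, 0.01, 0.01), "undefined")
})

test_that("the proportion is invariant to a global sign change", {
  m <- decompose_mediation(C = 0.2, A = 0.4, B = 0.1, C_prime = 0.16)
  mflip <- decompose_mediation(C = -0.2, A = -0.4, B = -0.1, C_prime = -0.16)
  # (-A)(-B) = AB but C flips, so flip B's role: A -> mediator and mediator
  # -> outcome both reverse while the total reverses once
  expect_equal(mflip$proportion, -m$proportion)
  m2 <- decompose_mediation(C = -0.2, A = -0.4, B = 0.1, C_prime = -0.16)
  expect_equal(m2$proportion, m$proportion)
  expect_equal(m2$difference_proportion, m$difference_proportion)
})

test_that("proportion CIs: degenerate at zero noise, seeded, delta ~ bootstrap", {
  m <- decompose_mediation(C = 0.107, A = 0.3, B = 0.1)
  d0 <- proportion_ci(m, 0, 0, 0, method = "bootstrap", n_boot = 500, seed = 1)
  expect_equal(d0$ci_low, m$proportion)
  expect_equal(d0$ci_high, m$proportion)

  b1 <- proportion_ci(m, 0.01, 0.01, 0.01, n_boot = 2000, seed = 9)
  b2 <- proportion_ci(m, 0.01, 0.01, 0.01, n_boot = 2000, seed = 9)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_true(b1$ci_low <= m$proportion & m$proportion <= b1$ci_high)

  # well-conditioned case (|C|/se_C > 5): delta and bootstrap widths agree
  boot <- proportion_ci(m, 0.01, 0.005, 0.01, method = "bootstrap",
                        n_boot = 1e5, seed = 3)
  delta <- proportion_ci(m, 0.01, 0.005, 0.01, method = "delta")
  w_boot <- boot$ci_high - boot$ci_low
  w_delta <- delta$ci_high - delta$ci_low
  expect_lt(abs(w_delta - w_boot) / w_boot, 0.10)

  # unstable C triggers the instability warning
  mu <- decompose_mediation(C = 0.02, A = 0.3, B = 0.1)
  expect_warning(proportion_ci(mu, 0.01, 0.01, 0.02, n_boot = 2000, seed = 1),
                 "crosses zero")
})

test_that("two-step mediation on synthetic data recovers the truth direction", {
  study <- simulate_study(simulation_config(seed = 31))
  med <- mediate_two_step(study$tables$exposure, study$tables$mediator,
                          study$tables$outcome, n_boot = 1000, seed = 31)
  expect_equal(med$A, study$truth$A, tolerance = 0.1)
  expect_equal(med$C, study$truth$C, tolerance = 0.25)
  expect_equal(med$proportion, study$config$mediated_fraction, tolerance = 0.12)
  expect_true(med$ci_low <= med$proportion & med$proportion <= med$ci_high)
  expect_equal(nrow(tidy(med)), 6)
})
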
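test_that("the same configuration and seed regenerate tables bit-identically", {
  cfg <- small_config(seed = 17)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c <- simulate_study(small_config(seed = 18))
  expect_false(identical(a$tables$exposure$beta, c$tables$exposure$beta))
})

test_that("simulated sampling noise is calibrated: null z-scores are standard normal", {
  cfg <- simulation_config(
    n_variants = 10000, n_mediator_variants = 0,
    causal_total = 0, mediated_fraction = 0, effect_on_mediator = 0.3,
    seed = 5
  )
  study <- simulate_study(cfg)
  # outcome effects are all zero under C = 0, so its z-scores are null draws
  z <- study$tables$outcome$beta / study$tables$outcome$se
  ks <- stats::ks.test(z, "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("mean instrument F increases monotonically with exposure sample size", {
  fbar <- vapply(c(5e4, 2e5, 8e5), function(n) {
    s <- simulate_study(simulation_config(
      n_variants = 300, n_mediator_variants = 0, n_exposure = n, seed = 8
    ))
    mean((s$tables$exposure$beta / s$tables$exposure$se)^2)
  }, numeric(1))
  expect_true(all(diff(fbar) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(r2_range = c(0.5, 1.5)), "variance explained")
  expect_error(simulation_config(mediated_fraction = 0.5,
                                 effect_on_mediator = 0), "non-zero")
  expect_error(simulation_config(mediated_fraction = 1.2))
  expect_error(simulate_study(list()), "simulation_config")
})

test_that("null mediation yields C_prime = C and a near-zero estimated proportion", {
  cfg <- simulation_config(mediated_fraction = 0, pleiotropy_sd = 0, seed = 12)
  expect_equal(cfg$C_prime, cfg$causal_total)
  study <- simulate_study(cfg)
  med <- mediate_two_step(study$tables$exposure, study$tables$mediator,
                          study$tables$outcome, n_boot = 500, seed = 12)
  expect_lt(abs(med$proportion), 0.1)
})

test_that("effective outcome sample size follows the case/control harmonic rule", {
  cfg <- simulation_config(seed = 1)
  study <- simulate_study(cfg)
  cases <- cfg$case_fraction * cfg$n_outcome
  controls <- (1 - cfg$case_fraction) * cfg$n_outcome
  expect_equal(study$truth$n_eff_outcome, 4 / (1 / cases + 1 / controls))
  # a continuous outcome uses the nominal n
  cfg2 <- simulation_config(outcome_binary = FALSE, seed = 1)
  expect_equal(simulate_study(cfg2)$truth$n_eff_outcome, cfg2$n_outcome)
})

test_that("LD-block mode emits a pairwise r2 table that the clumper uses", {
  cfg <- simulation_config(n_variants = 10, n_mediator_variants = 0,
                           ld_block_size = 3, ld_r2 = 0.8, seed = 3)
  study <- simulate_study(cfg)
  expect_equal(nrow(study$tables$exposure), 30)
  expect_equal(nrow(study$ld_info), 10 * 3)
  kept <- select_instruments(study$tables$exposure,
                             qc_config(ld_r2_threshold = 0.1),
                             ld_info = study$ld_info)
  expect_equal(nrow(kept), 10) # one representative per block
})

test_that("write_study emits canonical tables and a truth sidecar", {
  skip_if_not_installed("jsonlite")
  dir <- withr::local_tempdir()
  study <- simulate_study(small_config(seed = 2))
  write_study(study, dir)
  expect_true(all(file.exists(file.path(
    dir, c("exposure.tsv", "mediator.tsv", "outcome.tsv", "truth.json")
  ))))
  back <- read_sumstats(file.path(dir, "exposure.tsv"))
  expect_equal(back$beta, study$tables$exposure$beta, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$C, study$truth$C)
  expect_equal(truth$seed, study$config$seed)
})
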
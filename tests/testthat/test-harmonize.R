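exp_tbl <- function(ea = "A", oa = "G", eaf = 0.3, beta = 0.1) {
  tibble::tibble(
    variant_id = "rs1", chromosome = "1", position = 1000L,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = 0.01, pvalue = 1e-20, n = 1e5
  )
}

out_tbl <- function(ea = "A", oa = "G", eaf = 0.3, beta = 0.2) {
  tibble::tibble(
    variant_id = "rs1", chromosome = "1", position = 1000L,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = 0.02, pvalue = 1e-4, n = 2e5
  )
}

test_that("allele resolution follows the hand-enumerated truth table", {
  # direct match: kept as-is
  hs <- harmonize(exp_tbl(), out_tbl())
  expect_equal(hs$beta_outcome, 0.2)
  # swapped labels: effect negated
  hs <- harmonize(exp_tbl(), out_tbl(ea = "G", oa = "A", eaf = 0.7))
  expect_equal(hs$beta_outcome, -0.2)
  # opposite strand, same orientation: kept
  hs <- harmonize(exp_tbl(), out_tbl(ea = "T", oa = "C"))
  expect_equal(hs$beta_outcome, 0.2)
  # opposite strand and swapped: negated
  hs <- harmonize(exp_tbl(), out_tbl(ea = "C", oa = "T", eaf = 0.7))
  expect_equal(hs$beta_outcome, -0.2)
  # unrelated alleles: dropped as incompatible
  hs <- harmonize(exp_tbl(), out_tbl(ea = "A", oa = "C"))
  expect_equal(nrow(hs), 0)
  expect_match(attr(hs, "qc_log")$reason, "incompatible alleles")
  # identical alleles: rejected as malformed
  hs <- harmonize(exp_tbl(), out_tbl(ea = "A", oa = "A"))
  expect_equal(nrow(hs), 0)
  expect_match(attr(hs, "qc_log")$reason, "malformed alleles")
})

test_that("palindromic variants are dropped near eaf 0.5, else frequency-aligned", {
  # eaf 0.49 is inside the default 0.08 window around 0.5
  hs <- harmonize(exp_tbl(ea = "A", oa = "T", eaf = 0.49),
                  out_tbl(ea = "A", oa = "T", eaf = 0.49))
  expect_equal(nrow(hs), 0)
  expect_match(attr(hs, "qc_log")$reason, "ambiguous palindromic")
  # frequencies on the same side of 0.5: kept
  hs <- harmonize(exp_tbl(ea = "C", oa = "G", eaf = 0.2),
                  out_tbl(ea = "C", oa = "G", eaf = 0.25))
  expect_equal(hs$beta_outcome, 0.2)
  # listed effect-allele frequencies on opposite sides: flipped
  hs <- harmonize(exp_tbl(ea = "C", oa = "G", eaf = 0.2),
                  out_tbl(ea = "C", oa = "G", eaf = 0.8))
  expect_equal(hs$beta_outcome, -0.2)
  # swapped labels whose frequency agrees with the exposure's effect
  # allele can only be the other strand: kept as-is
  hs <- harmonize(exp_tbl(ea = "C", oa = "G", eaf = 0.2),
                  out_tbl(ea = "G", oa = "C", eaf = 0.22))
  expect_equal(hs$beta_outcome, 0.2)
})

test_that("harmonization is idempotent", {
  study <- simulate_study(small_config(seed = 4, allow_palindromic = TRUE))
  iv <- select_instruments(study$tables$exposure)
  hs1 <- harmonize(iv, study$tables$outcome)
  # feed the harmonized outcome effects back in exposure orientation
  out2 <- dplyr::transmute(
    hs1,
    variant_id, chromosome = "1", position = 1L,
    effect_allele, other_allele, eaf,
    beta = beta_outcome, se = se_outcome, pvalue = 0.5, n = 1e5
  )
  hs2 <- harmonize(iv[iv$variant_id %in% hs1$variant_id, ], out2)
  expect_equal(hs2$beta_outcome, hs1$beta_outcome)
  expect_equal(hs2$variant_id, hs1$variant_id)
})

test_that("flipping a record's alleles and negating beta is an involution", {
  study <- simulate_study(small_config(seed = 9, allow_palindromic = TRUE))
  iv <- select_instruments(study$tables$exposure)
  out <- study$tables$outcome
  flipped <- dplyr::mutate(
    out,
    tmp = effect_allele, effect_allele = other_allele, other_allele = tmp,
    beta = -beta, eaf = 1 - eaf
  ) |> dplyr::select(-tmp)
  hs_a <- harmonize(iv, out)
  hs_b <- harmonize(iv, flipped)
  expect_equal(hs_b$variant_id, hs_a$variant_id)
  expect_equal(hs_b$beta_outcome, hs_a$beta_outcome, tolerance = 1e-12)
})

test_that("mediator tables are aligned and carried as extra columns", {
  study <- simulate_study(small_config(seed = 2))
  iv <- select_instruments(study$tables$exposure)
  hs <- harmonize(iv, study$tables$outcome,
                  mediators = list(bp = study$tables$mediator))
  expect_true(all(c("beta_bp", "se_bp") %in% names(hs)))
  expect_equal(attr(hs, "mediators"), "bp")
  expect_equal(nrow(hs), nrow(iv))
})
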
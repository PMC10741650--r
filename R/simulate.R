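# Synthetic multi-trait GWAS summary statistics with known causal and
# mediation structure.
#
# The generator emulates the post-clumping state of large-biobank GWAS:
# unlinked variants, per-variant sampling noise scaled by allele frequency
# and sample size (se = 1 / sqrt(2 * maf * (1 - maf) * n); for a binary
# outcome n is replaced by the effective size 4 / (1/cases + 1/controls)),
# and a causal chain exposure -> mediator -> outcome with configurable
# direct, mediated and pleiotropic effects. Mediator-specific instruments
# (variants with no exposure effect) are generated alongside the exposure's
# so the multivariable step is identified.

#' Configuration for the synthetic summary-statistics generator
#'
#' Defaults describe the study conditions the package targets: 86
#' independent exposure instruments from a biobank-scale exposure GWAS
#' (n = 350,474), a mediator GWAS of n = 757,601, and a binary outcome
#' GWAS of 40,585 cases / 406,111 controls, with a total causal effect of
#' 0.107 log-odds per SD of which 28% is mediated. Per-variant variance
#' explained is drawn uniformly from `r2_range`; the default (3e-4 to
#' 2e-3) matches strong biobank-scale loci, so essentially every exposure
#' variant clears genome-wide significance with F far above 10.
#'
#' @param n_variants Number of exposure-instrument variants (default 86).
#' @param n_mediator_variants Number of mediator-specific instrument
#'   variants with no exposure effect (default 80); these identify the
#'   mediator's direct effect in multivariable MR.
#' @param maf_range Minor-allele-frequency range, drawn uniformly.
#' @param r2_range Range of per-variant trait variance explained.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param outcome_binary Is the outcome a case/control trait? If so its
#'   effects are log-odds and its sampling noise uses the effective sample
#'   size implied by `case_fraction`.
#' @param case_fraction Proportion of cases in the outcome GWAS.
#' @param causal_total Total causal effect C of exposure on outcome.
#' @param mediated_fraction Proportion of C carried by the mediator, in
#'   `[0, 1]`; the mediator-to-outcome effect is derived as
#'   `B = C * mediated_fraction / A`.
#' @param effect_on_mediator Effect A of exposure on mediator (SD per SD).
#' @param pleiotropy_sd SD of direct (pathway-bypassing) variant effects;
#'   0 disables pleiotropy.
#' @param invalid_fraction Fraction of exposure variants given pleiotropic
#'   direct effects on mediator and outcome.
#' @param ld_block_size Variants per LD block (default 1 = unlinked). With
#'   blocks of size > 1 each causal signal is copied across the block and
#'   a pairwise `ld_info` table (within-block r-squared `ld_r2`) is
#'   emitted, exercising the clumping path.
#' @param ld_r2 Within-block r-squared reported in `ld_info`.
#' @param allow_palindromic Allow A/T and C/G allele pairs (default FALSE,
#'   so harmonization keeps every variant and instrument counts are
#'   deterministic).
#' @param mediator_name Trait label for the mediator table.
#' @param seed Integer seed; tables regenerate bit-identically from the
#'   same configuration.
#' @return A validated list of class `"simulation_config"` with derived
#'   truth values `B` and `C_prime`.
#' @export
simulation_config <- function(n_variants = 86,
                              n_mediator_variants = 80,
                              maf_range = c(0.05, 0.5),
                              r2_range = c(3e-4, 2e-3),
                              n_exposure = 350474,
                              n_mediator = 757601,
                              n_outcome = 446696,
                              outcome_binary = TRUE,
                              case_fraction = 40585 / 446696,
                              causal_total = 0.107,
                              mediated_fraction = 0.28,
                              effect_on_mediator = 0.3,
                              pleiotropy_sd = 0,
                              invalid_fraction = 0,
                              ld_block_size = 1,
                              ld_r2 = 0.9,
                              allow_palindromic = FALSE,
                              mediator_name = "mediator",
                              seed = 1) {
  stopifnot(
    n_variants >= 1, n_mediator_variants >= 0,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 1,
    maf_range[1] <= maf_range[2],
    length(r2_range) == 2, r2_range[1] > 0, r2_range[1] <= r2_range[2],
    n_exposure > 3, n_mediator > 3, n_outcome > 3,
    case_fraction > 0, case_fraction < 1,
    mediated_fraction >= 0, mediated_fraction <= 1,
    pleiotropy_sd >= 0, invalid_fraction >= 0, invalid_fraction <= 1,
    ld_block_size >= 1, ld_r2 > 0, ld_r2 <= 1
  )
  if (r2_range[2] >= 1) {
    abort("`r2_range` implies per-variant variance explained >= 1")
  }
  if (mediated_fraction > 0 && effect_on_mediator == 0) {
    abort("`mediated_fraction` > 0 requires a non-zero `effect_on_mediator`")
  }
  B <- if (effect_on_mediator != 0) {
    causal_total * mediated_fraction / effect_on_mediator
  } else 0
  structure(
    list(
      n_variants = as.integer(n_variants),
      n_mediator_variants = as.integer(n_mediator_variants),
      maf_range = maf_range, r2_range = r2_range,
      n_exposure = n_exposure, n_mediator = n_mediator,
      n_outcome = n_outcome, outcome_binary = outcome_binary,
      case_fraction = case_fraction,
      causal_total = causal_total, mediated_fraction = mediated_fraction,
      effect_on_mediator = effect_on_mediator,
      B = B, C_prime = causal_total * (1 - mediated_fraction),
      pleiotropy_sd = pleiotropy_sd, invalid_fraction = invalid_fraction,
      ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
      allow_palindromic = allow_palindromic,
      mediator_name = mediator_name,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# non-palindromic ordered allele pairs (effect, other)
nonpalindromic_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)
palindromic_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a multi-trait GWAS summary-statistics study
#'
#' Generates exposure, mediator and outcome summary-statistics tables from
#' a known causal structure. Per variant j: the minor-allele frequency is
#' uniform on `maf_range`; the true exposure effect is
#' `gamma_j = s_j * sqrt(r2_j / (2 maf (1 - maf)))` with random sign and
#' `r2_j` uniform on `r2_range` (a zero-mean, symmetric law); the mediator
#' effect is `A * gamma_j` plus direct pleiotropy for the invalid
#' fraction; the outcome effect is `C' * gamma_j + B * (mediator effect)`
#' plus pleiotropy noise. Mediator-specific variants carry effects
#' `delta_j` on the mediator only (transmitted to the outcome as
#' `B * delta_j`). Observed effects add normal noise with
#' `se = 1 / sqrt(2 maf (1 - maf) n)`; for the binary outcome `n` is the
#' effective size `4 / (1/cases + 1/controls)`. P-values come from the
#' normal tail. All three tables list every variant.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"synthetic_study"`: `config`; `truth` (list
#'   with `A`, `B`, `C`, `C_prime`, effective outcome sample size and a
#'   per-variant tibble of true effects); `tables` (named list of
#'   summary-statistics tibbles: `exposure`, `mediator`, `outcome`); and
#'   `ld_info` (`NULL` unless `ld_block_size > 1`).
#' @examples
#' study <- simulate_study(simulation_config(n_variants = 10, seed = 42))
#' study$tables$exposure
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a simulation_config()")
  }
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  blocks_e <- cfg$n_variants
  blocks_m <- cfg$n_mediator_variants
  bs <- cfg$ld_block_size
  m <- (blocks_e + blocks_m) * bs # total emitted variants
  block_id <- rep(seq_len(blocks_e + blocks_m), each = bs)
  is_exposure_variant <- block_id <= blocks_e

  variant_id <- sprintf("rs%d", 100000 + seq_len(m))
  chromosome <- as.character(rep_len(1:22, m))
  position <- 1000000L + 17000L * seq_len(m) + 500L * (seq_len(m) %% bs)
  pairs <- if (cfg$allow_palindromic) {
    rbind(nonpalindromic_pairs, palindromic_pairs)
  } else nonpalindromic_pairs
  pair_idx <- sample.int(nrow(pairs), m, replace = TRUE)
  effect_allele <- pairs[pair_idx, 1]
  other_allele <- pairs[pair_idx, 2]
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  var_g <- 2 * maf * (1 - maf)

  # block-level causal draws, copied across block members
  r2_block <- runif(blocks_e + blocks_m, cfg$r2_range[1], cfg$r2_range[2])
  sign_block <- sample(c(-1, 1), blocks_e + blocks_m, replace = TRUE)
  raw_effect <- (sign_block * sqrt(r2_block))[block_id] / sqrt(var_g)

  gamma <- ifelse(is_exposure_variant, raw_effect, 0)
  delta <- ifelse(is_exposure_variant, 0, raw_effect)

  n_invalid <- round(cfg$invalid_fraction * blocks_e)
  invalid_blocks <- if (n_invalid > 0) sample(blocks_e, n_invalid) else integer(0)
  is_invalid <- block_id %in% invalid_blocks
  pleio_med <- ifelse(is_invalid & cfg$pleiotropy_sd > 0,
                      rnorm(m, 0, cfg$pleiotropy_sd), 0)
  pleio_out <- ifelse(is_invalid & cfg$pleiotropy_sd > 0,
                      rnorm(m, 0, cfg$pleiotropy_sd), 0)

  A <- cfg$effect_on_mediator
  B <- cfg$B
  C_prime <- cfg$C_prime
  alpha <- A * gamma + delta + pleio_med # mediator effects
  beta_out_true <- C_prime * gamma + B * alpha + pleio_out

  n_eff_outcome <- if (cfg$outcome_binary) {
    cases <- cfg$case_fraction * cfg$n_outcome
    controls <- (1 - cfg$case_fraction) * cfg$n_outcome
    4 / (1 / cases + 1 / controls)
  } else cfg$n_outcome

  make_table <- function(true_beta, n_nominal, n_noise, trait) {
    se <- 1 / sqrt(var_g * n_noise)
    beta_obs <- true_beta + rnorm(m, 0, se)
    tbl <- tibble::tibble(
      variant_id = variant_id, chromosome = chromosome, position = position,
      effect_allele = effect_allele, other_allele = other_allele,
      eaf = maf, beta = beta_obs, se = se,
      pvalue = pmax(2 * pnorm(-abs(beta_obs / se)), .Machine$double.xmin),
      n = rep(n_nominal, m)
    )
    attr(tbl, "trait") <- trait
    tbl
  }

  tables <- list(
    exposure = make_table(gamma, cfg$n_exposure, cfg$n_exposure, "exposure"),
    mediator = make_table(alpha, cfg$n_mediator, cfg$n_mediator,
                          cfg$mediator_name),
    outcome = make_table(beta_out_true, cfg$n_outcome, n_eff_outcome, "outcome")
  )

  ld_info <- NULL
  if (bs > 1) {
    ld_info <- dplyr::bind_rows(lapply(split(variant_id, block_id), function(ids) {
      if (length(ids) < 2) return(NULL)
      combn_idx <- utils::combn(length(ids), 2)
      tibble::tibble(variant_a = ids[combn_idx[1, ]],
                     variant_b = ids[combn_idx[2, ]],
                     r2 = cfg$ld_r2)
    }))
  }

  structure(
    list(
      config = cfg,
      truth = list(
        A = A, B = B, C = cfg$causal_total, C_prime = C_prime,
        n_eff_outcome = n_eff_outcome,
        variants = tibble::tibble(
          variant_id = variant_id, block = block_id,
          is_exposure_instrument = is_exposure_variant,
          is_mediator_instrument = !is_exposure_variant,
          is_invalid = is_invalid,
          gamma = gamma, alpha = alpha, beta_outcome = beta_out_true,
          pleiotropy_mediator = pleio_med, pleiotropy_outcome = pleio_out
        )
      ),
      tables = tables,
      ld_info = ld_info
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d exposure + %d mediator instrument variants (seed %d)\n  truth: A = %.3f, B = %.4f, C = %.4f, C' = %.4f\n",
    x$config$n_variants, x$config$n_mediator_variants, x$config$seed,
    x$truth$A, x$truth$B, x$truth$C, x$truth$C_prime
  ))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the three summary-statistics tables with canonical headers (see
#' [write_sumstats()]), the LD table when present, and a JSON truth
#' sidecar recording the causal parameters and seed.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(study$tables)) {
    write_sumstats(study$tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  if (!is.null(study$ld_info)) {
    readr::write_tsv(study$ld_info, file.path(dir, "ld_info.tsv"),
                     progress = FALSE)
  }
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("the truth sidecar requires the 'jsonlite' package")
  }
  truth <- list(
    A = study$truth$A, B = study$truth$B, C = study$truth$C,
    C_prime = study$truth$C_prime, seed = study$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
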
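# Instrument selection: significance, confounder exclusion, instrument
# strength, and greedy LD pruning.

#' Quality-control configuration for instrument selection
#'
#' Bundles the thresholds applied by [select_instruments()]. The defaults
#' follow a stringent published analysis: genome-wide significance at
#' p < 5e-10, pairwise LD independence at r-squared above 1e-4, and the
#' conventional weak-instrument cutoff F < 10. Both unusually strict
#' thresholds are deliberate defaults and fully configurable.
#'
#' @param p_threshold Exposure p-value below which a variant qualifies as an
#'   instrument (default `5e-10`).
#' @param ld_r2_threshold Pairwise r-squared above which two variants are
#'   treated as dependent (default `1e-4`).
#' @param f_threshold Minimum per-variant F-statistic (default `10`).
#' @param excluded_variants Character vector of variant IDs to exclude, e.g.
#'   confounder-associated SNPs; see [lipid_confounder_snps()].
#' @param palindromic_eaf_window Half-width of the allele-frequency window
#'   around 0.5 inside which palindromic (A/T, C/G) variants are considered
#'   ambiguous during harmonization (default `0.08`).
#' @return A list of class `"qc_config"`.
#' @examples
#' qc_config(excluded_variants = lipid_confounder_snps())
#' @export
qc_config <- function(p_threshold = 5e-10,
                      ld_r2_threshold = 1e-4,
                      f_threshold = 10,
                      excluded_variants = character(),
                      palindromic_eaf_window = 0.08) {
  stopifnot(
    p_threshold > 0, p_threshold < 1,
    ld_r2_threshold > 0, f_threshold > 0,
    palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5
  )
  structure(
    list(
      p_threshold = p_threshold,
      ld_r2_threshold = ld_r2_threshold,
      f_threshold = f_threshold,
      excluded_variants = as.character(excluded_variants),
      palindromic_eaf_window = palindromic_eaf_window
    ),
    class = "qc_config"
  )
}

#' Per-variant instrument-strength F-statistic
#'
#' For a single-variant association the F-statistic equals the squared
#' z-score, `(beta / se)^2`; values below 10 conventionally flag weak
#' instruments.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s); must be strictly positive.
#' @return Numeric vector of F-statistics.
#' @examples
#' f_statistic(0.1, 0.01) # 100
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) abort("`se` must be strictly positive")
  (beta / se)^2
}

#' Packaged blood-lipid confounder SNP exclusion list
#'
#' Seven lipid-associated variants identified by confounder cross-referencing
#' of platelet-index instruments, shipped as a ready-made exclusion list for
#' `qc_config(excluded_variants = )`.
#'
#' @return Character vector of 7 rsIDs.
#' @export
lipid_confounder_snps <- function() {
  readLines(system.file("extdata", "lipid_confounder_snps.txt",
                        package = "mrmediate"))
}

#' Select genetic instruments from summary statistics
#'
#' Applies the instrument-selection filters in a fixed order (first matching
#' rule wins): (1) exposure p-value at or above `p_threshold`; (2) membership
#' in `excluded_variants`; (3) F-statistic below `f_threshold`; (4) linkage
#' disequilibrium with an already-retained variant, pruned greedily in order
#' of ascending p-value using the optional `ld_info` table. Variants absent
#' from `ld_info` are treated as independent.
#'
#' @param assocs Summary-statistics tibble (see [read_sumstats()]).
#' @param config A [qc_config()].
#' @param ld_info Optional long-format pairwise LD table with columns
#'   `variant_a`, `variant_b`, `r2`.
#' @return Tibble of retained variants (with an added `f_stat` column),
#'   sorted by ascending p-value. Attribute `"qc_log"` is a tibble
#'   (`variant_id`, `reason`) recording every removal. Errors if no variant
#'   survives.
#' @examples
#' study <- simulate_study(simulation_config(n_variants = 20, seed = 1))
#' iv <- select_instruments(study$tables$exposure, qc_config())
#' attr(iv, "qc_log")
#' @export
select_instruments <- function(assocs, config = qc_config(), ld_info = NULL) {
  if (is.null(assocs) || nrow(assocs) == 0) abort("`assocs` must be non-empty")
  assert_columns(assocs, c("variant_id", "beta", "se", "pvalue"), "`assocs`")

  dat <- dplyr::mutate(assocs, f_stat = f_statistic(.data$beta, .data$se))
  reason <- dplyr::case_when(
    dat$pvalue >= config$p_threshold ~ "not genome-wide significant",
    dat$variant_id %in% config$excluded_variants ~ "confounder-associated",
    dat$f_stat < config$f_threshold ~ "weak instrument",
    TRUE ~ NA_character_
  )

  surv <- dat[is.na(reason), , drop = FALSE]
  surv <- dplyr::arrange(surv, .data$pvalue, .data$variant_id)
  ld_reason <- character(0)
  ld_ids <- character(0)
  if (!is.null(ld_info) && nrow(surv) > 1) {
    assert_columns(ld_info, c("variant_a", "variant_b", "r2"), "`ld_info`")
    r2_of <- function(a, b) {
      hit <- (ld_info$variant_a == a & ld_info$variant_b == b) |
        (ld_info$variant_a == b & ld_info$variant_b == a)
      if (any(hit)) max(ld_info$r2[hit]) else 0
    }
    kept <- character(0)
    for (v in surv$variant_id) {
      dep <- any(vapply(kept, function(k) r2_of(v, k), numeric(1)) >
                   config$ld_r2_threshold)
      if (dep) {
        ld_ids <- c(ld_ids, v)
        ld_reason <- c(ld_reason, "in LD with retained variant")
      } else {
        kept <- c(kept, v)
      }
    }
    surv <- surv[!(surv$variant_id %in% ld_ids), , drop = FALSE]
  }

  qc_log <- dplyr::bind_rows(
    tibble::tibble(
      variant_id = dat$variant_id[!is.na(reason)],
      reason = reason[!is.na(reason)]
    ),
    tibble::tibble(variant_id = ld_ids, reason = ld_reason)
  )
  qc_log <- dplyr::arrange(qc_log, .data$variant_id)

  if (nrow(surv) == 0) {
    abort(sprintf("no instruments survive QC (%d candidate%s removed)",
                  nrow(qc_log), if (nrow(qc_log) > 1) "s" else ""))
  }
  attr(surv, "qc_log") <- qc_log
  attr(surv, "trait") <- attr(assocs, "trait")
  surv
}
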
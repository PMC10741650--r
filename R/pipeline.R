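# One-configuration orchestration: QC -> univariable MR per
# exposure-outcome pair -> sensitivity suite -> MVMR models -> mediation.

#' Pipeline configuration
#'
#' Collects every input and setting for [run_pipeline()]. Trait tables may
#' be tibbles ([read_sumstats()] layout) or file paths.
#'
#' @param exposures,outcomes Named lists of summary-statistics tables or
#'   paths (at least one each).
#' @param mediators Optional named list of mediator tables or paths.
#' @param qc A [qc_config()].
#' @param mode IVW mode passed through to [mr_ivw()].
#' @param n_boot Bootstrap draws (weighted median SE, mediation CI).
#' @param n_sim Simulations for the outlier test.
#' @param seed Integer seed governing every stochastic step.
#' @param ld_info Optional pairwise LD table.
#' @param alpha_family,n_tests Family-wise alpha and number of tests; the
#'   per-test significance threshold is their ratio (default 0.05 / 5).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(exposures, outcomes, mediators = NULL,
                            qc = qc_config(), mode = "auto",
                            n_boot = 1000, n_sim = 1000, seed = 1,
                            ld_info = NULL,
                            alpha_family = 0.05, n_tests = 5) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            alpha_family > 0, alpha_family < 1, n_tests >= 1)
  named_ok <- function(x) !is.null(names(x)) && all(names(x) != "")
  if (!named_ok(exposures) || !named_ok(outcomes) ||
      (length(mediators) > 0 && !named_ok(mediators))) {
    abort("`exposures`, `outcomes` and `mediators` must be named lists")
  }
  structure(
    list(exposures = exposures, outcomes = outcomes, mediators = mediators,
         qc = qc, mode = mode, n_boot = n_boot, n_sim = n_sim,
         seed = as.integer(seed), ld_info = ld_info,
         alpha_family = alpha_family, n_tests = n_tests),
    class = "pipeline_config"
  )
}

resolve_table <- function(x, trait) {
  if (is.character(x)) x <- read_sumstats(x, trait = trait)
  if (is.null(attr(x, "trait"))) attr(x, "trait") <- trait
  x
}

estimate_row <- function(est, exposure, outcome) {
  ci <- ci_limits(est$beta, est$se)
  tibble::tibble(
    exposure = exposure, outcome = outcome, method = est$method,
    n_snps = est$n_snps, beta = est$beta, se = est$se, pvalue = est$pvalue,
    odds_ratio = exp(est$beta), ci_low = exp(ci[1]), ci_high = exp(ci[2]),
    or_ci = format_or(est$beta, est$se)
  )
}

#' Run the full MR + mediation pipeline
#'
#' For every exposure-outcome pair: selects instruments, harmonizes,
#' screens causal direction (Steiger; failing pairs are flagged
#' `"possible reverse causation"` in the estimate table rather than
#' dropped), and computes the IVW (primary), MR-Egger and weighted-median
#' estimates with Cochran's Q, the Egger intercept, leave-one-out and the
#' simulation-based outlier test. For every exposure-outcome pair with
#' mediators it then fits each single-mediator MVMR model plus the joint
#' all-mediator model, and runs the two-step mediation decomposition per
#' mediator. Every stochastic step derives from `config$seed`, so
#' rerunning an identical configuration reproduces the bundle exactly.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `"mr_report"`: tibbles `estimates` (with
#'   significance labels and reverse-causation flags), `heterogeneity`,
#'   `pleiotropy`, `steiger`, `mediation`; lists `loo`, `presso`, `mvmr`,
#'   `qc_logs` keyed by pair/model; and `manifest` (seeds and thresholds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  exposures <- purrr::imap(config$exposures, resolve_table)
  outcomes <- purrr::imap(config$outcomes, resolve_table)
  mediators <- purrr::imap(config$mediators %||% list(), resolve_table)

  pairs <- tidyr::expand_grid(exposure = names(exposures),
                              outcome = names(outcomes))
  estimates <- list(); heterogeneity <- list(); pleiotropy <- list()
  steiger <- list(); loo <- list(); presso <- list(); qc_logs <- list()

  for (i in seq_len(nrow(pairs))) {
    e <- pairs$exposure[i]; o <- pairs$outcome[i]
    key <- paste(e, o, sep = " -> ")
    stage <- function(what, expr) {
      tryCatch(expr, error = function(err) {
        abort(sprintf("pipeline stage '%s' failed for %s: %s",
                      what, key, conditionMessage(err)))
      })
    }
    iv <- stage("instrument selection",
                select_instruments(exposures[[e]], config$qc, config$ld_info))
    hs <- stage("harmonization", harmonize(iv, outcomes[[o]],
                                           exposure_name = e, outcome_name = o))
    qc_logs[[key]] <- dplyr::bind_rows(attr(iv, "qc_log"), attr(hs, "qc_log"))

    st <- stage("Steiger test", mr_steiger(
      hs, n_exposure = stats::median(exposures[[e]]$n),
      n_outcome = stats::median(outcomes[[o]]$n)
    ))
    steiger[[key]] <- dplyr::mutate(st, exposure = e, outcome = o,
                                    .before = 1)

    ivw <- stage("IVW", mr_ivw(hs, mode = config$mode))
    egg <- stage("MR-Egger", mr_egger(hs))
    wm <- stage("weighted median",
                mr_weighted_median(hs, n_boot = config$n_boot,
                                   seed = config$seed))
    estimates[[key]] <- dplyr::bind_rows(
      estimate_row(ivw, e, o), estimate_row(egg$estimate, e, o),
      estimate_row(wm, e, o)
    ) |>
      dplyr::mutate(
        significance = significance_label(.data$pvalue, config$alpha_family,
                                          config$n_tests),
        reverse_causation_flag = !st$direction_correct & st$pvalue < 0.05
      )

    heterogeneity[[key]] <- dplyr::mutate(
      mr_cochran_q(hs, beta_ref = ivw$beta),
      exposure = e, outcome = o, .before = 1
    )
    pleiotropy[[key]] <- tibble::tibble(
      exposure = e, outcome = o,
      egger_intercept = egg$pleiotropy$intercept,
      se = egg$pleiotropy$se, pvalue = egg$pleiotropy$pvalue
    )
    loo[[key]] <- stage("leave-one-out", mr_leave_one_out(hs, mode = config$mode))
    if (nrow(hs) >= 4) {
      presso[[key]] <- stage("outlier test", mr_presso(
        hs, n_sim = config$n_sim, seed = config$seed
      ))
    }
  }

  mvmr <- list(); mediation <- list()
  if (length(mediators) > 0) {
    model_sets <- c(purrr::map(names(mediators), ~ .x),
                    if (length(mediators) > 1) list(names(mediators)))
    for (i in seq_len(nrow(pairs))) {
      e <- pairs$exposure[i]; o <- pairs$outcome[i]
      iv_exp <- select_instruments(exposures[[e]], config$qc, config$ld_info)
      for (ms in model_sets) {
        model_key <- paste(c(ms, e, o), collapse = "-")
        iv_ids <- unique(c(
          iv_exp$variant_id,
          unlist(purrr::map(ms, function(mn) {
            select_instruments(mediators[[mn]], config$qc,
                               config$ld_info)$variant_id
          }))
        ))
        exp_union <- exposures[[e]][exposures[[e]]$variant_id %in% iv_ids, ]
        hs_mv <- harmonize(exp_union, outcomes[[o]], mediators = mediators[ms],
                           exposure_name = e, outcome_name = o)
        mvmr[[model_key]] <- mvmr_ivw(hs_mv, exposures = c("exposure", ms))
      }
      for (mn in names(mediators)) {
        med_key <- paste(e, mn, o, sep = " -> ")
        mediation[[med_key]] <- mediate_two_step(
          exposures[[e]], mediators[[mn]], outcomes[[o]],
          qc = config$qc, ld_info = config$ld_info,
          n_boot = config$n_boot, seed = config$seed, mediator_name = mn
        )
      }
    }
  }

  mediation_table <- if (length(mediation) > 0) {
    dplyr::bind_rows(purrr::map(mediation, tidy_mediation_row))
  } else tibble::tibble()

  structure(
    list(
      estimates = dplyr::bind_rows(estimates),
      heterogeneity = dplyr::bind_rows(heterogeneity),
      pleiotropy = dplyr::bind_rows(pleiotropy),
      steiger = dplyr::bind_rows(steiger),
      loo = loo, presso = presso, qc_logs = qc_logs,
      mvmr = mvmr, mediation = mediation, mediation_table = mediation_table,
      manifest = list(
        seed = config$seed, qc = unclass(config$qc), mode = config$mode,
        n_boot = config$n_boot, n_sim = config$n_sim,
        alpha_family = config$alpha_family, n_tests = config$n_tests,
        per_test_threshold = config$alpha_family / config$n_tests,
        exposures = names(exposures), outcomes = names(outcomes),
        mediators = names(mediators)
      )
    ),
    class = "mr_report"
  )
}

tidy_mediation_row <- function(m) {
  tibble::tibble(
    exposure = m$exposure, mediator = m$mediator, outcome = m$outcome,
    A = m$A, B = m$B, C = m$C, C_prime = m$C_prime,
    indirect = m$indirect, proportion = m$proportion,
    proportion_pct = 100 * m$proportion,
    ci_low_pct = 100 * m$ci_low, ci_high_pct = 100 * m$ci_high,
    ci_method = m$ci_method
  )
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %d exposure-outcome pair%s\n",
              nrow(x$estimates) / 3,
              if (nrow(x$estimates) > 3) "s" else ""))
  print(dplyr::select(x$estimates, "exposure", "outcome", "method",
                      "n_snps", "or_ci", "pvalue", "significance"))
  if (nrow(x$mediation_table) > 0) {
    cat("mediation:\n")
    print(dplyr::select(x$mediation_table, "exposure", "mediator", "outcome",
                        "proportion_pct", "ci_low_pct", "ci_high_pct"))
  }
  invisible(x)
}

#' Write an MR report bundle to disk
#'
#' Emits the report's tables as TSV files, the QC logs as plain text, and
#' the run manifest as JSON under `dir`.
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("estimates", "heterogeneity", "pleiotropy", "steiger")) {
    readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  if (nrow(report$mediation_table) > 0) {
    readr::write_tsv(report$mediation_table, file.path(dir, "mediation.tsv"),
                     progress = FALSE)
  }
  log_lines <- unlist(purrr::imap(report$qc_logs, function(log, key) {
    c(paste0("## ", key),
      sprintf("%s\t%s", log$variant_id, log$reason))
  }))
  writeLines(log_lines %||% character(0), file.path(dir, "qc_log.txt"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing the manifest requires the 'jsonlite' package")
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
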
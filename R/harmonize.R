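# Allele harmonization across exposure, outcome and mediator tables.
#
# All effects in a harmonized instrument set refer to the exposure's effect
# allele. Strand flips are resolved by complementation; palindromic (A/T,
# C/G) variants are aligned by allele frequency or dropped when the
# frequency is too close to 0.5 to be informative.

allele_complement <- c(A = "T", C = "G", G = "C", T = "A")

# Decide, for one variant, how the other trait's effect maps onto the
# exposure orientation. Returns "keep", "flip", "drop_palindromic",
# "drop_incompatible" or "drop_malformed".
resolve_alleles <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, eaf_y, window) {
  if (ea_x == oa_x || ea_y == oa_y) return("drop_malformed")
  palindromic <- allele_complement[[ea_x]] == oa_x
  if (palindromic) {
    # strand is unidentifiable from labels; the allele pair must at least
    # agree, then frequency carries all the information
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) return("drop_incompatible")
    if (abs(eaf_x - 0.5) < window || abs(eaf_y - 0.5) < window) {
      return("drop_palindromic")
    }
    same_side <- (eaf_x > 0.5) == (eaf_y > 0.5)
    return(if (same_side) "keep" else "flip")
  }
  cea <- allele_complement[[ea_x]]
  coa <- allele_complement[[oa_x]]
  if (ea_y == ea_x && oa_y == oa_x) return("keep")
  if (ea_y == oa_x && oa_y == ea_x) return("flip")
  if (ea_y == cea && oa_y == coa) return("keep")
  if (ea_y == coa && oa_y == cea) return("flip")
  "drop_incompatible"
}

# Align one trait table onto the exposure orientation. Returns a list with
# the aligned tibble (variant_id, beta, se) and a qc_log of drops.
align_trait <- function(exposure, trait_tbl, trait_name, window) {
  joined <- dplyr::inner_join(
    dplyr::select(exposure, "variant_id",
                  ea_x = "effect_allele", oa_x = "other_allele", eaf_x = "eaf"),
    dplyr::select(trait_tbl, "variant_id",
                  ea_y = "effect_allele", oa_y = "other_allele", eaf_y = "eaf",
                  beta_y = "beta", se_y = "se"),
    by = "variant_id"
  )
  absent <- setdiff(exposure$variant_id, joined$variant_id)

  action <- purrr::pmap_chr(
    list(joined$ea_x, joined$oa_x, joined$eaf_x,
         joined$ea_y, joined$oa_y, joined$eaf_y),
    resolve_alleles, window = window
  )
  flip <- action == "flip"
  aligned <- tibble::tibble(
    variant_id = joined$variant_id[action %in% c("keep", "flip")],
    beta = ifelse(flip, -joined$beta_y, joined$beta_y)[action %in% c("keep", "flip")],
    se = joined$se_y[action %in% c("keep", "flip")]
  )

  drop_reasons <- c(
    drop_palindromic = "ambiguous palindromic",
    drop_incompatible = "incompatible alleles",
    drop_malformed = "malformed alleles"
  )
  dropped <- action %in% names(drop_reasons)
  qc_log <- dplyr::bind_rows(
    tibble::tibble(
      variant_id = joined$variant_id[dropped],
      reason = sprintf("%s (%s)", drop_reasons[action[dropped]], trait_name)
    ),
    tibble::tibble(
      variant_id = absent,
      reason = sprintf("absent from %s table", trait_name)
    )
  )
  list(aligned = aligned, qc_log = qc_log)
}

#' Harmonize exposure, outcome and mediator summary statistics
#'
#' Joins per-variant associations across traits and expresses every effect
#' for the exposure's effect allele. Swapped allele labels negate the effect
#' and reflect the frequency; strand flips (A<->T, C<->G complementation)
#' are resolved before matching; palindromic variants are aligned by allele
#' frequency, or dropped as ambiguous when either trait's frequency lies
#' within `palindromic_eaf_window` of 0.5. Irreconcilable or malformed
#' allele pairs are dropped and logged. Only variants present and alignable
#' in every table are retained.
#'
#' @param exposure,outcome Summary-statistics tibbles ([read_sumstats()]
#'   layout). `exposure` is typically the output of [select_instruments()].
#' @param mediators Optional named list of additional trait tables; their
#'   aligned effects appear as `beta_<name>` / `se_<name>` columns.
#' @param palindromic_eaf_window Ambiguity window around 0.5 (default 0.08).
#' @param exposure_name,outcome_name Trait labels stored as attributes.
#' @return An `instrument_set` tibble with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf` (exposure-oriented),
#'   `beta_exposure`, `se_exposure`, `pvalue_exposure`, `f_stat`,
#'   `beta_outcome`, `se_outcome`, plus mediator columns. Attributes:
#'   `"qc_log"` (dropped variants with reasons), `"exposure"`, `"outcome"`,
#'   `"mediators"`.
#' @examples
#' study <- simulate_study(simulation_config(n_variants = 20, seed = 1))
#' iv <- select_instruments(study$tables$exposure)
#' hs <- harmonize(iv, study$tables$outcome)
#' @export
harmonize <- function(exposure, outcome, mediators = NULL,
                      palindromic_eaf_window = 0.08,
                      exposure_name = NULL, outcome_name = NULL) {
  assert_columns(exposure,
                 c("variant_id", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pvalue"), "`exposure`")
  assert_columns(outcome,
                 c("variant_id", "effect_allele", "other_allele", "eaf",
                   "beta", "se"), "`outcome`")
  if (anyDuplicated(exposure$variant_id)) {
    abort("duplicate variant IDs in `exposure`")
  }
  exposure_name <- exposure_name %||% attr(exposure, "trait") %||% "exposure"
  outcome_name <- outcome_name %||% attr(outcome, "trait") %||% "outcome"

  malformed <- exposure$effect_allele == exposure$other_allele |
    !(exposure$effect_allele %in% valid_alleles) |
    !(exposure$other_allele %in% valid_alleles)
  qc_log <- tibble::tibble(
    variant_id = exposure$variant_id[malformed],
    reason = rep(sprintf("malformed alleles (%s)", exposure_name), sum(malformed))
  )
  exposure <- exposure[!malformed, , drop = FALSE]

  traits <- c(list(outcome), mediators)
  trait_names <- c(outcome_name, names(mediators))
  if (length(mediators) > 0 &&
      (is.null(names(mediators)) || any(names(mediators) == ""))) {
    abort("`mediators` must be a named list")
  }

  aligned <- vector("list", length(traits))
  for (i in seq_along(traits)) {
    res <- align_trait(exposure, traits[[i]], trait_names[i],
                       palindromic_eaf_window)
    aligned[[i]] <- res$aligned
    qc_log <- dplyr::bind_rows(qc_log, res$qc_log)
  }

  keep_ids <- Reduce(intersect, lapply(aligned, function(a) a$variant_id))
  out <- exposure |>
    dplyr::filter(.data$variant_id %in% keep_ids) |>
    dplyr::transmute(
      variant_id = .data$variant_id,
      effect_allele = .data$effect_allele,
      other_allele = .data$other_allele,
      eaf = .data$eaf,
      beta_exposure = .data$beta,
      se_exposure = .data$se,
      pvalue_exposure = .data$pvalue,
      f_stat = f_statistic(.data$beta, .data$se)
    )
  suffixes <- c("outcome", names(mediators))
  for (i in seq_along(aligned)) {
    a <- aligned[[i]][match(out$variant_id, aligned[[i]]$variant_id), ]
    out[[paste0("beta_", suffixes[i])]] <- a$beta
    out[[paste0("se_", suffixes[i])]] <- a$se
  }

  # drops recorded for variants that survived the other tables
  qc_log <- qc_log[!duplicated(paste(qc_log$variant_id, qc_log$reason)), ]
  qc_log <- dplyr::arrange(qc_log, .data$variant_id)

  structure(
    out,
    class = c("instrument_set", class(out)),
    qc_log = qc_log,
    exposure = exposure_name,
    outcome = outcome_name,
    mediators = names(mediators) %||% character(0)
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "<instrument_set> %s -> %s%s: %d instruments (%d dropped in harmonization)\n",
    attr(x, "exposure"), attr(x, "outcome"),
    if (length(attr(x, "mediators")) > 0) {
      paste0(" | mediators: ", paste(attr(x, "mediators"), collapse = ", "))
    } else "",
    nrow(x), nrow(attr(x, "qc_log"))
  ))
  NextMethod()
}
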
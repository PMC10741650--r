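# Reading and validating GWAS summary-statistics tables.
#
# The canonical on-disk layout is GWAS-SSF-like: one row per variant with
# columns variant_id, chromosome, base_pair_location, effect_allele,
# other_allele, effect_allele_frequency, beta, standard_error, p_value, n.
# In memory the package uses short names (position, eaf, se, pvalue).

canonical_columns <- c(
  variant_id = "variant_id",
  chromosome = "chromosome",
  position = "base_pair_location",
  effect_allele = "effect_allele",
  other_allele = "other_allele",
  eaf = "effect_allele_frequency",
  beta = "beta",
  se = "standard_error",
  pvalue = "p_value",
  n = "n"
)

numeric_fields <- c("position", "eaf", "beta", "se", "pvalue", "n")
valid_alleles <- c("A", "C", "G", "T")

#' Read GWAS summary statistics
#'
#' Reads a tab- or comma-delimited summary-statistics table into a validated
#' tibble with one row per variant. The expected headers are the canonical
#' GWAS-SSF-style names (`variant_id`, `chromosome`, `base_pair_location`,
#' `effect_allele`, `other_allele`, `effect_allele_frequency`, `beta`,
#' `standard_error`, `p_value`, `n`); other dialects are accommodated via
#' `column_map`. Rows violating basic invariants (non-positive SE, allele
#' frequency outside (0,1), identical or non-ACGT alleles, p-value outside
#' (0,1], unparseable numbers) are dropped and reported, with their line
#' numbers, in a warning and in the `"rejected"` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical
#'   header names to the names actually used in the file, e.g.
#'   `c(variant_id = "SNP", beta = "Effect")`.
#' @param delim Field delimiter; guessed from the header line when `NULL`.
#' @param trait Optional trait label stored as the `"trait"` attribute.
#' @return A tibble with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   Attribute `"rejected"` holds a tibble (`line`, `variant_id`, `reason`)
#'   of dropped rows.
#' @seealso [select_instruments()], [harmonize()], [write_sumstats()]
#' @export
read_sumstats <- function(path, column_map = NULL, delim = NULL, trait = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )

  file_names <- unname(canonical_columns)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(canonical_columns))
    if (length(bad) > 0) {
      abort(sprintf("unknown canonical column%s in `column_map`: %s",
                    if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")))
    }
    idx <- match(names(column_map), names(canonical_columns))
    file_names[idx] <- unname(column_map)
  }
  missing <- setdiff(file_names, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("mandatory column%s missing from %s: %s",
                  if (length(missing) > 1) "s" else "", path,
                  paste(missing, collapse = ", ")))
  }

  tbl <- tibble::as_tibble(setNames(raw[file_names], names(canonical_columns)))
  validate_sumstats(tbl, trait = trait, source = path)
}

# Validate a raw (character or typed) sumstats tibble with short names;
# returns the clean tibble, attaching the rejected-row log.
validate_sumstats <- function(tbl, trait = NULL, source = "sumstats") {
  n_raw <- nrow(tbl)
  parsed <- tbl
  unparseable <- rep(FALSE, n_raw)
  for (f in numeric_fields) {
    num <- suppressWarnings(as.numeric(tbl[[f]]))
    unparseable <- unparseable | (is.na(num) & !is.na(tbl[[f]]) & tbl[[f]] != "")
    parsed[[f]] <- num
  }
  parsed$effect_allele <- toupper(as.character(parsed$effect_allele))
  parsed$other_allele <- toupper(as.character(parsed$other_allele))

  reason <- dplyr::case_when(
    unparseable ~ "unparseable numeric field",
    is.na(parsed$se) | parsed$se <= 0 ~ "non-positive SE",
    is.na(parsed$eaf) | parsed$eaf <= 0 | parsed$eaf >= 1 ~ "allele frequency outside (0,1)",
    !(parsed$effect_allele %in% valid_alleles) |
      !(parsed$other_allele %in% valid_alleles) ~ "invalid allele code",
    parsed$effect_allele == parsed$other_allele ~ "identical alleles",
    is.na(parsed$pvalue) | parsed$pvalue <= 0 | parsed$pvalue > 1 ~ "p-value outside (0,1]",
    is.na(parsed$beta) ~ "missing beta",
    is.na(parsed$n) | parsed$n <= 0 ~ "non-positive sample size",
    TRUE ~ NA_character_
  )

  bad <- !is.na(reason)
  rejected <- tibble::tibble(
    line = which(bad) + 1L, # +1 for the header row
    variant_id = as.character(parsed$variant_id[bad]),
    reason = reason[bad]
  )
  if (nrow(rejected) > 0) {
    warn(sprintf(
      "%s: dropped %d of %d row%s failing validation (e.g. line %d: %s)",
      source, nrow(rejected), n_raw, if (n_raw > 1) "s" else "",
      rejected$line[1], rejected$reason[1]
    ))
  }

  out <- parsed[!bad, , drop = FALSE]
  out$position <- as.integer(out$position)
  out$n <- as.numeric(out$n)
  attr(out, "rejected") <- rejected
  attr(out, "trait") <- trait
  out
}

#' Write summary statistics with canonical headers
#'
#' Inverse of [read_sumstats()]: writes a tibble with the package's short
#' column names back to disk under the canonical GWAS-SSF-style headers.
#'
#' @param data Summary-statistics tibble as returned by [read_sumstats()]
#'   or found in [simulate_study()] output.
#' @param path Output file path; delimiter is a tab.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(data, path) {
  assert_columns(data, names(canonical_columns), "summary statistics")
  out <- setNames(data[names(canonical_columns)], unname(canonical_columns))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
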
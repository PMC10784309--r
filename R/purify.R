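#' Tissue-template NTP for contamination screening
#'
#' Runs nearest-template prediction against normal-tissue marker templates
#' (typically liver- and pancreas-specific gene sets) to find tumor samples
#' whose transcriptome resembles a normal tissue. A small FDR means the
#' sample's profile matches a tissue template better than random gene sets
#' do, i.e. likely contamination. Thin wrapper over [ntp_predict()]; the
#' matrix is log-transformed internally if still on the TPM scale.
#'
#' @inheritParams ntp_predict
#' @param templates Named list of >= 2 tissue marker sets.
#' @return An `ntp_result` tibble (see [ntp_predict()]) whose `predicted`
#'   column is the nearest tissue.
#' @export
tissue_ntp <- function(expr, templates, n_perm = 1000L, seed = 1L,
                       min_genes = 5L) {
  if (identical(expr_scale(expr), "tpm")) expr <- log_transform(expr)
  ntp_predict(expr, templates, n_perm = n_perm, seed = seed,
              min_genes = min_genes)
}

#' Split a cohort into purified and verification subsets
#'
#' Applies the contamination rule: a sample goes to the verification cohort
#' iff its tissue-NTP FDR is at or below `fdr_max` (it looks like a normal
#' tissue) AND its pathologist-estimated overall contamination fraction is
#' strictly above `contamination_min`. All other samples form the purified
#' cohort used for class discovery. Both boundary conventions (inclusive
#' FDR, strict contamination) follow the published rule.
#'
#' @param ntp An `ntp_result` from [tissue_ntp()].
#' @param clin Clinical tibble with `sample_id` and either
#'   `contamination_overall` or per-tissue `contamination_*` columns (summed
#'   and capped at 1 when the overall column is absent).
#' @param fdr_max Inclusive NTP FDR cutoff (default 0.1).
#' @param contamination_min Strict overall-contamination cutoff (default 0.25).
#' @return A tibble of class `cohort_split`: `sample_id`, `predicted_tissue`,
#'   `ntp_fdr`, `contamination_overall`, `cohort` (`"purified"` or
#'   `"verification"`), `rule_fired` (which condition(s) held).
#' @export
stratify_cohort <- function(ntp, clin, fdr_max = 0.1, contamination_min = 0.25) {
  if (!inherits(ntp, "ntp_result")) abort("`ntp` must come from tissue_ntp()/ntp_predict().")
  if (fdr_max < 0 || fdr_max > 1) abort("`fdr_max` must be in [0, 1].")
  if (contamination_min < 0 || contamination_min > 1) {
    abort("`contamination_min` must be in [0, 1].")
  }
  if (!"sample_id" %in% names(clin)) abort("`clin` needs a `sample_id` column.")
  missing <- setdiff(ntp$sample_id, clin$sample_id)
  if (length(missing) > 0) {
    abort(paste0("no clinical record for sample(s): ",
                 paste(head(missing, 5), collapse = ", "), "."))
  }
  clin <- ensure_overall_contamination(clin)
  joined <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(ntp), "sample_id", predicted_tissue = "predicted",
                  ntp_fdr = "fdr"),
    dplyr::select(clin, "sample_id", "contamination_overall"),
    by = "sample_id"
  )
  if (anyNA(joined$contamination_overall)) {
    bad <- joined$sample_id[is.na(joined$contamination_overall)][1]
    abort(paste0("sample '", bad, "' has no contamination_overall value."))
  }
  fdr_hit <- joined$ntp_fdr <= fdr_max
  contam_hit <- joined$contamination_overall > contamination_min
  out <- joined %>%
    mutate(
      cohort = ifelse(fdr_hit & contam_hit, "verification", "purified"),
      rule_fired = dplyr::case_when(
        fdr_hit & contam_hit ~ "ntp_fdr & contamination",
        fdr_hit ~ "ntp_fdr only",
        contam_hit ~ "contamination only",
        TRUE ~ "none"
      )
    )
  class(out) <- c("cohort_split", class(out))
  attr(out, "fdr_max") <- fdr_max
  attr(out, "contamination_min") <- contamination_min
  out
}

# derive contamination_overall from per-tissue fractions when absent
ensure_overall_contamination <- function(clin) {
  if ("contamination_overall" %in% names(clin)) return(clin)
  tissue_cols <- grep("^contamination_", names(clin), value = TRUE)
  if (length(tissue_cols) == 0) {
    abort("`clin` has neither `contamination_overall` nor per-tissue `contamination_*` columns.")
  }
  clin$contamination_overall <- pmin(1, rowSums(clin[, tissue_cols, drop = FALSE]))
  clin
}

#' Sample IDs of one side of a cohort split
#'
#' @param split A `cohort_split` from [stratify_cohort()].
#' @param which `"purified"` or `"verification"`.
#' @return Character vector of sample IDs.
#' @export
cohort_samples <- function(split, which = c("purified", "verification")) {
  which <- match.arg(which)
  split$sample_id[split$cohort == which]
}
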
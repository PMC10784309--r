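#' Pipeline run configuration
#'
#' Collects every threshold, clustering parameter and stage seed of the
#' pipeline in one validated object, so a run is a pure function of
#' (inputs, config). Defaults follow the published analysis where it states
#' them (NTP FDR cutoff 0.1, overall contamination cutoff 0.25, classifier
#' panel sizes 20/10, signature thresholds adjusted p < 0.01 with |fold
#' change| > 2 and target sizes 25/12) and common tool conventions elsewhere.
#'
#' @param seed Master integer seed; per-stage seeds are derived from it by
#'   fixed offsets unless given explicitly in `seeds`.
#' @param seeds Optional named list overriding stage seeds
#'   (`ntp`, `cluster`, `nmf`, `classify`, `simulate`).
#' @param ntp_fdr NTP FDR cutoff used by cohort stratification (inclusive).
#' @param contamination Overall contamination cutoff (strict `>`).
#' @param de_adj_p,de_abs_fc Differential-expression thresholds (BH-adjusted
#'   p, absolute linear fold change) used to build the prognostic signatures.
#' @param confident_call_fdr FDR at or below which an NTP call is confident.
#' @param k_range Candidate numbers of classes for consensus clustering.
#' @param reps Consensus subsampling repetitions.
#' @param subsample_frac Fraction of samples drawn per consensus repetition.
#' @param n_features Genes kept for clustering (top by median absolute
#'   deviation); `Inf` keeps all.
#' @param n_genes_c1,n_genes_c2 Classifier panel sizes per class.
#' @param sig_max_c1,sig_max_c2 Signature size caps per class.
#' @param n_perm NTP permutation count.
#' @param roc_years Horizons (years) for time-dependent AUC.
#' @param nri_horizon_days NRI evaluation horizon in days.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       seeds = list(),
                       ntp_fdr = 0.1,
                       contamination = 0.25,
                       de_adj_p = 0.01,
                       de_abs_fc = 2,
                       confident_call_fdr = 0.05,
                       k_range = 2:6,
                       reps = 1000L,
                       subsample_frac = 0.8,
                       n_features = 2000L,
                       n_genes_c1 = 20L,
                       n_genes_c2 = 10L,
                       sig_max_c1 = 25L,
                       sig_max_c2 = 12L,
                       n_perm = 1000L,
                       roc_years = 1:4,
                       nri_horizon_days = 730L) {
  seed <- as.integer(seed)
  default_seeds <- list(
    ntp = seed + 101L, cluster = seed + 202L, nmf = seed + 303L,
    classify = seed + 404L, simulate = seed + 505L
  )
  seeds <- modifyList(default_seeds, as.list(seeds))
  cfg <- list(
    seed = seed, seeds = seeds, ntp_fdr = ntp_fdr,
    contamination = contamination, de_adj_p = de_adj_p,
    de_abs_fc = de_abs_fc, confident_call_fdr = confident_call_fdr,
    k_range = as.integer(k_range), reps = as.integer(reps),
    subsample_frac = subsample_frac, n_features = n_features,
    n_genes_c1 = as.integer(n_genes_c1), n_genes_c2 = as.integer(n_genes_c2),
    sig_max_c1 = as.integer(sig_max_c1), sig_max_c2 = as.integer(sig_max_c2),
    n_perm = as.integer(n_perm), roc_years = as.numeric(roc_years),
    nri_horizon_days = as.numeric(nri_horizon_days)
  )
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  chk01 <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      abort(paste0("config field `", nm, "` must be a number in [", lo, ", ", hi, "]."))
    }
  }
  chk01(cfg$ntp_fdr, "ntp_fdr")
  chk01(cfg$contamination, "contamination")
  chk01(cfg$de_adj_p, "de_adj_p")
  chk01(cfg$confident_call_fdr, "confident_call_fdr")
  chk01(cfg$subsample_frac, "subsample_frac", lo = 1e-9)
  if (cfg$de_abs_fc < 1) abort("config field `de_abs_fc` must be >= 1 (linear fold change).")
  if (any(cfg$k_range < 2)) abort("config field `k_range` must not contain k < 2.")
  if (cfg$reps < 2) abort("config field `reps` must be >= 2.")
  if (cfg$n_perm < 10) abort("config field `n_perm` must be >= 10.")
  if (cfg$n_genes_c1 < 0 || cfg$n_genes_c2 < 0) abort("classifier sizes must be >= 0.")
  if (any(cfg$roc_years <= 0)) abort("`roc_years` must be positive.")
  if (cfg$nri_horizon_days <= 0) abort("`nri_horizon_days` must be positive.")
  for (nm in c("ntp", "cluster", "nmf", "classify", "simulate")) {
    s <- cfg$seeds[[nm]]
    if (is.null(s) || !is.numeric(s) || is.na(s)) {
      abort(paste0("stage seed `", nm, "` must be an explicit integer."))
    }
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Unknown fields are rejected, listed by name; missing fields take the
#' [run_config()] defaults. Validation happens before any computation.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(vals), allowed)
  if (length(extra) > 0) {
    abort(paste0("unknown config field(s): ", paste(extra, collapse = ", "), "."))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  flat <- x
  flat$seeds <- paste(names(x$seeds), unlist(x$seeds), sep = "=", collapse = " ")
  for (nm in names(flat)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(flat[[nm]]), collapse = " ")))
  }
  invisible(x)
}
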
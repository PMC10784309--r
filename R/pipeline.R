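#' Run the full subtyping and prognostic pipeline
#'
#' Executes the stages in order — purify (tissue NTP + contamination rule),
#' cluster (consensus clustering of the purified cohort; the minority class
#' is labelled C1, matching the poorer-prognosis mesenchymal/immune class
#' being the smaller one), classify (SNR marker panels + NTP over the whole
#' cohort), score (differential expression, signature construction, unified
#' prognostic score), survival (KM/log-rank, Cox models, time-dependent AUC,
#' NRI) — writing per-stage CSV/GMT outputs plus a JSON run summary with all
#' seeds into `outdir`. A failure in any stage aborts with the stage name.
#' The run is a pure function of (inputs, config): repeated runs with the
#' same seeds give identical outputs.
#'
#' @param expr TPM expression matrix.
#' @param clin Clinical tibble (see [survival_records()] and
#'   [stratify_cohort()] for the columns each stage needs).
#' @param tissue_templates Named list of >= 2 tissue marker gene sets for the
#'   purification NTP.
#' @param config A [run_config()].
#' @param outdir Output directory, created if absent.
#' @return Invisibly, a list with each stage's in-memory result and the
#'   summary.
#' @export
run_pipeline <- function(expr, clin, tissue_templates, config = run_config(),
                         outdir) {
  validate_config(config)
  if (!all(clin$sample_id %in% colnames(expr))) {
    abort("stage 'validate' failed: clinical samples missing from expression matrix.")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  expr_log <- log_transform(expr)

  ## -- purify ---------------------------------------------------------------
  split <- stage("purify", function() {
    ntp <- tissue_ntp(expr_log, tissue_templates, n_perm = config$n_perm,
                      seed = config$seeds$ntp)
    stratify_cohort(ntp, clin, fdr_max = config$ntp_fdr,
                    contamination_min = config$contamination)
  })
  readr::write_csv(split, file.path(outdir, "purify.csv"))
  purified <- cohort_samples(split, "purified")

  ## -- cluster --------------------------------------------------------------
  cl <- stage("cluster", function() {
    cc <- consensus_cluster(
      expr_subset(expr_log, samples = purified),
      k_range = config$k_range, reps = config$reps,
      subsample_frac = config$subsample_frac, seed = config$seeds$cluster,
      n_features = config$n_features
    )
    lab2 <- consensus_labels(cc, k = 2)
    sizes <- sort(table(lab2))
    subtype <- ifelse(lab2 == as.integer(names(sizes)[1]), "C1", "C2")
    list(cc = cc, subtype = setNames(subtype, names(lab2)))
  })
  readr::write_csv(
    cl$cc$labels %>% mutate(subtype = unname(cl$subtype[.data$sample_id])),
    file.path(outdir, "cluster_labels.csv")
  )
  readr::write_csv(cl$cc$metrics, file.path(outdir, "cluster_metrics.csv"))
  chosen <- cl$cc$consensus[[as.character(cl$cc$chosen_k)]]
  readr::write_csv(tibble::as_tibble(chosen, rownames = "sample_id"),
                   file.path(outdir, "consensus_matrix.csv.gz"))
  if (requireNamespace("ape", quietly = TRUE)) {
    write_dendrogram(hierarchical_dendrogram(expr_subset(expr_log, samples = purified)),
                     file.path(outdir, "dendrogram.newick"))
  }

  ## -- classify -------------------------------------------------------------
  clf <- stage("classify", function() {
    purified_expr <- expr_subset(expr_log, samples = names(cl$subtype))
    snr <- snr_scores(purified_expr, factor(cl$subtype, levels = c("C1", "C2")))
    templates <- select_classifier_genes(snr, c(config$n_genes_c1, config$n_genes_c2))
    ntp <- ntp_predict(expr_log, templates, n_perm = config$n_perm,
                       seed = config$seeds$classify,
                       confident_call_fdr = config$confident_call_fdr)
    list(snr = snr, templates = templates, ntp = ntp)
  })
  write_gmt(clf$templates, file.path(outdir, "classifier_templates.gmt"))
  readr::write_csv(clf$ntp, file.path(outdir, "ntp_calls.csv"))

  ## -- score ----------------------------------------------------------------
  sc <- stage("score", function() {
    purified_expr <- expr_subset(expr_log, samples = names(cl$subtype))
    de <- differential_expression(purified_expr,
                                  factor(cl$subtype, levels = c("C1", "C2")),
                                  ref = "C2")
    sig <- build_signatures(de, adj_p_max = config$de_adj_p,
                            abs_fc_min = config$de_abs_fc,
                            max_per_class = c(config$sig_max_c1, config$sig_max_c2))
    scores <- core37_score(expr_log, sig)
    list(de = de, sig = sig, scores = scores)
  })
  readr::write_csv(sc$de, file.path(outdir, "differential_expression.csv"))
  write_signature(sc$sig, file.path(outdir, "signature.gmt"))
  readr::write_csv(sc$scores, file.path(outdir, "scores.csv"))

  ## -- survival -------------------------------------------------------------
  sv <- stage("survival", function() {
    clin2 <- clin %>%
      mutate(subtype = unname(cl$subtype[.data$sample_id])) %>%
      left_join(dplyr::select(sc$scores, "sample_id", core37 = "unified",
                              "quartile"),
                by = "sample_id")
    covars <- intersect(c("age", "sex", "site", "stage_group"), names(clin2))
    rec_pure <- survival_records(dplyr::filter(clin2, !is.na(.data$subtype)),
                                 covariates = c("subtype", covars))
    rec_all <- survival_records(clin2, covariates = c("core37", "quartile", covars))
    km <- km_logrank(rec_pure, "subtype")
    cox_uni <- cox_fit(rec_pure, "subtype")
    cox_multi <- cox_fit(rec_pure, c(intersect(c("site", "stage_group"), covars), "subtype"))
    cox_score <- cox_fit(rec_all, c(intersect("age", covars), "core37"))
    auc <- time_dependent_auc(rec_all, "core37", years = config$roc_years)
    nri <- NULL
    if (all(c("age", "stage_group") %in% covars)) {
      lp_std <- stats::predict(cox_fit(rec_all, c("age", "stage_group"))$fit,
                               type = "lp")
      lp_new <- stats::predict(cox_score$fit, type = "lp")
      nri <- nri_compare(rec_all, lp_std, lp_new, horizon = config$nri_horizon_days)
    }
    list(km = km, cox_uni = cox_uni, cox_multi = cox_multi,
         cox_score = cox_score, auc = auc, nri = nri)
  })
  readr::write_csv(sv$km$medians, file.path(outdir, "km_medians.csv"))
  readr::write_csv(bind_rows(
    tidy(sv$cox_uni) %>% mutate(model = "univariate_subtype"),
    tidy(sv$cox_multi) %>% mutate(model = "multivariate"),
    tidy(sv$cox_score) %>% mutate(model = "age_core37")
  ), file.path(outdir, "cox_fits.csv"))
  jsonlite::write_json(
    list(auc = sv$auc,
         nri = if (!is.null(sv$nri)) unclass(sv$nri) else NULL),
    file.path(outdir, "auc_nri.json"), auto_unbox = TRUE, digits = NA
  )

  summary <- list(
    package_version = as.character(utils::packageVersion("ccatype")),
    r_version = as.character(getRversion()),
    config = unclass(config),
    n_samples = ncol(expr),
    n_genes = nrow(expr),
    n_purified = length(purified),
    n_verification = ncol(expr) - length(purified),
    chosen_k = cl$cc$chosen_k,
    class_proportions = as.list(prop.table(table(cl$subtype))),
    classifier_sizes = lengths(clf$templates),
    signature_sizes = lengths(sc$sig),
    km_logrank_p = sv$km$p,
    subtype_hr = tidy(sv$cox_multi) %>%
      filter(grepl("subtype", .data$term)) %>% pull("hr")
  )
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(split = split, cluster = cl, classifier = clf, score = sc,
                 survival = sv, summary = summary))
}
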
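# Shared fixtures, generated once per test run.

shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(n_samples = 80, n_genes = 600, seed = 7))
    }
    cache
  }
})

shared_log_expr <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- log_transform(shared_cohort()$expression)
    cache
  }
})

truth_subtypes <- function(cohort = shared_cohort()) {
  setNames(cohort$truth$subtype, cohort$truth$sample_id)
}

# small matrix builder with default gene/sample names
toy_expr <- function(values, scale = "log2p1", genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expr_matrix(m, scale = scale)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# hand-constructed NTP result for exercising the stratification rule alone
fake_ntp <- function(sample_id, fdr, predicted = "hepatic") {
  out <- tibble::tibble(
    sample_id = sample_id,
    predicted = rep_len(predicted, length(sample_id)),
    p = fdr, fdr = fdr,
    confident = fdr <= 0.05, ambiguous = FALSE
  )
  class(out) <- c("ntp_result", class(out))
  out
}
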
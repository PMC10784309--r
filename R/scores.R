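#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ranks on ties;
#' the highest-expressed gene carries the largest rank, hence the largest
#' weight). Walking down the list from the highest-expressed gene, the score
#' is the sum over all positions of the difference between the weighted
#' in-set empirical CDF (weights `rank^alpha`) and the unweighted out-of-set
#' ECDF. With `normalize = TRUE` all scores are divided by the range
#' (max - min) over every sample and set, the usual cross-sample
#' normalization. Scores depend on ranks only, so any strictly increasing
#' per-sample transform of expression leaves them unchanged.
#'
#' @param expr `log2p1` expression matrix.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]); each must
#'   overlap the matrix, and partial overlap is reported.
#' @param alpha Rank-weight exponent (default 0.75).
#' @param normalize Divide by the overall score range (default `TRUE`).
#' @return Tibble: `sample_id` plus one column per gene set, with attribute
#'   `method = "ssgsea"`.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.75, normalize = TRUE) {
  check_scale(expr, "log2p1", "ssgsea_score()")
  if (length(sets) == 0 || is.null(names(sets))) abort("`sets` must be a named list.")
  genes <- rownames(expr)
  present <- lapply(names(sets), function(nm) match_set(sets[[nm]], genes, nm))
  names(present) <- names(sets)
  n <- length(genes)
  scores <- matrix(NA_real_, ncol(expr), length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, genes) # walk from highest expression; ties by symbol
    w <- r^alpha
    for (si in seq_along(present)) {
      inset <- genes %in% present[[si]]
      m <- sum(inset)
      in_w <- ifelse(inset, w, 0)[ord]
      out_i <- as.numeric(!inset)[ord]
      p_in <- cumsum(in_w) / sum(in_w)
      p_out <- cumsum(out_i) / (n - m)
      scores[j, si] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  out <- tibble::as_tibble(scores, rownames = "sample_id")
  attr(out, "method") <- "ssgsea"
  attr(out, "alpha") <- alpha
  out
}

#' Combined z-score of a gene set
#'
#' Each gene is z-scored across samples; a sample's score is the sum of its
#' z-scores over the set genes divided by the square root of the number of
#' retained genes (Lee-style combined z). Zero-variance genes are dropped
#' with a warning; if every set gene has zero variance the call errors.
#'
#' @param expr `log2p1` expression matrix with >= 2 samples.
#' @param set Character vector of gene symbols.
#' @return Named numeric vector of per-sample scores.
#' @export
zscore_combine <- function(expr, set) {
  check_scale(expr, "log2p1", "zscore_combine()")
  if (ncol(expr) < 2) abort("per-gene z-scores need >= 2 samples.")
  present <- match_set(set, rownames(expr), "zscore set")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (all(sds == 0)) abort("all set genes have zero variance across samples.")
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0), " zero-variance gene(s) from z-score set."))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (sub - rowMeans(sub)) / sds
  colSums(z) / sqrt(nrow(sub))
}

#' Stromal, immune and combined microenvironment scores
#'
#' ssGSEA scores of user-supplied stromal and immune signature gene lists,
#' plus their sum as a combined score — a transcriptome-only summary of
#' non-tumor compartment abundance.
#'
#' @param expr `log2p1` expression matrix.
#' @param stromal_set,immune_set Character vectors of signature genes.
#' @param alpha,normalize Passed to [ssgsea_score()].
#' @return Tibble: `sample_id`, `stromal`, `immune`, `combined`.
#' @export
microenv_scores <- function(expr, stromal_set, immune_set, alpha = 0.75,
                            normalize = TRUE) {
  sc <- ssgsea_score(expr, list(stromal = stromal_set, immune = immune_set),
                     alpha = alpha, normalize = normalize)
  sc %>% mutate(combined = .data$stromal + .data$immune)
}

#' Score a collection of gene sets per sample
#'
#' Convenience dispatcher over [ssgsea_score()] and [zscore_combine()] for a
#' whole collection, returning one column per set.
#'
#' @param expr `log2p1` expression matrix.
#' @param sets Named list of gene sets.
#' @param method `"ssgsea"` (default) or `"zscore"`.
#' @param ... Passed to the underlying scorer.
#' @return Tibble: `sample_id` plus one column per set; attribute `method`.
#' @export
pathway_scores <- function(expr, sets, method = c("ssgsea", "zscore"), ...) {
  method <- match.arg(method)
  if (method == "ssgsea") return(ssgsea_score(expr, sets, ...))
  out <- tibble(sample_id = colnames(expr))
  for (nm in names(sets)) out[[nm]] <- unname(zscore_combine(expr, sets[[nm]]))
  attr(out, "method") <- "zscore"
  out
}

#' Z-score signature columns across samples
#'
#' Display transform for class-level summaries: each score column is
#' centered and scaled across samples. This is separate from the scores
#' themselves and changes no downstream statistic.
#'
#' @param scores Tibble with `sample_id` plus numeric score columns.
#' @return Tibble of the same shape with z-scored columns.
#' @export
normalize_scores <- function(scores) {
  num <- setdiff(names(scores), "sample_id")
  for (nm in num) {
    x <- scores[[nm]]
    s <- sd(x)
    scores[[nm]] <- if (s > 0) (x - mean(x)) / s else x * 0
  }
  scores
}
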
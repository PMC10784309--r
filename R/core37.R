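#' Differential expression between two molecular classes
#'
#' Per-gene two-class comparison on the `log2p1` scale. The default backend
#' is a two-sided Wilcoxon rank-sum test with Benjamini-Hochberg correction;
#' `method = "limma"` fits a moderated linear model instead (a model-based
#' slot where a count-model backend would plug in when raw counts are
#' available). The log2 fold change is the mean `log2p1` difference of the
#' non-reference class over the reference class.
#'
#' @param expr `log2p1` expression matrix.
#' @param labels Two-level factor over samples.
#' @param ref Reference class (default: the second factor level). Positive
#'   fold changes mean higher expression in the non-reference class.
#' @param method `"ranksum"` (default) or `"limma"`.
#' @return Tibble of class `de_result`: `gene`, `log2fc`, `p`, `adj_p`,
#'   ordered as the input genes; attribute `classes` stores
#'   (non-reference, reference).
#' @export
differential_expression <- function(expr, labels, ref = NULL,
                                    method = c("ranksum", "limma")) {
  check_scale(expr, "log2p1", "differential_expression()")
  method <- match.arg(method)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) abort("`labels` must have exactly two classes.")
  if (length(labels) != ncol(expr)) abort("`labels` length must match sample count.")
  ref <- ref %||% levels(labels)[2]
  if (!ref %in% levels(labels)) abort(paste0("`ref` class '", ref, "' not in labels."))
  other <- setdiff(levels(labels), ref)
  sizes <- table(labels)
  if (any(sizes < 3)) {
    abort(paste0("each class needs >= 3 samples; got ",
                 paste(names(sizes), sizes, sep = "=", collapse = ", "), "."))
  }
  in_other <- labels == other
  log2fc <- rowMeans(expr[, in_other, drop = FALSE]) -
    rowMeans(expr[, !in_other, drop = FALSE])
  if (method == "ranksum") {
    p <- apply(expr, 1, function(x) {
      suppressWarnings(wilcox.test(x[in_other], x[!in_other], exact = FALSE)$p.value)
    })
    p[is.na(p)] <- 1 # fully tied genes: no evidence
  } else {
    if (!requireNamespace("limma", quietly = TRUE)) {
      abort("method = 'limma' requires the 'limma' package.")
    }
    design <- cbind(Intercept = 1, other = as.numeric(in_other))
    fit <- limma::eBayes(limma::lmFit(expr, design))
    p <- fit$p.value[, "other"]
  }
  out <- tibble(
    gene = rownames(expr),
    log2fc = unname(log2fc),
    p = unname(p),
    adj_p = p.adjust(unname(p), method = "BH")
  )
  attr(out, "classes") <- c(other, ref)
  class(out) <- c("de_result", class(out))
  out
}

#' Build up-in-class signatures from a differential-expression result
#'
#' Genes passing `adj_p <= adj_p_max` and `|fold change| >= abs_fc_min`
#' (linear scale) are split by fold-change sign: positive log2 fold changes
#' become the C1-like (non-reference-up) signature, negative ones the
#' C2-like (reference-up) signature. Each list is ordered by decreasing
#' |log2 fold change| (ties by gene symbol) and truncated to
#' `max_per_class`. The defaults (adjusted p 0.01, fold change 2, sizes
#' 25/12) reproduce the published signature construction.
#'
#' @param de A `de_result` from [differential_expression()].
#' @param adj_p_max Adjusted-p cutoff (inclusive).
#' @param abs_fc_min Minimum absolute linear fold change (inclusive, >= 1).
#' @param max_per_class Integer pair: size caps for (C1-like, C2-like).
#' @return List of class `core_signature` with elements `c1_like` and
#'   `c2_like` (disjoint, non-empty gene vectors).
#' @export
build_signatures <- function(de, adj_p_max = 0.01, abs_fc_min = 2,
                             max_per_class = c(25L, 12L)) {
  if (!inherits(de, "de_result")) abort("`de` must come from differential_expression().")
  if (adj_p_max < 0 || adj_p_max > 1) abort("`adj_p_max` must be in [0, 1].")
  if (abs_fc_min < 1) abort("`abs_fc_min` must be >= 1 (linear fold change).")
  max_per_class <- as.integer(max_per_class)
  if (length(max_per_class) != 2 || any(max_per_class < 1)) {
    abort("`max_per_class` must be two positive integers.")
  }
  pass <- de$adj_p <= adj_p_max & abs(de$log2fc) >= log2(abs_fc_min)
  up <- de[pass & de$log2fc > 0, ]
  down <- de[pass & de$log2fc < 0, ]
  if (nrow(up) == 0 || nrow(down) == 0) {
    abort(paste0("no genes pass in one direction (up: ", nrow(up),
                 ", down: ", nrow(down), "); relax the thresholds."))
  }
  take <- function(tbl, n_max) {
    tbl <- tbl[order(-abs(tbl$log2fc), tbl$gene), ]
    head(tbl$gene, n_max)
  }
  sig <- list(c1_like = take(up, max_per_class[1]),
              c2_like = take(down, max_per_class[2]))
  class(sig) <- "core_signature"
  sig
}

#' Write a signature as a direction-tagged GMT
#'
#' @param sig A `core_signature`.
#' @param path Output GMT path; `c1_like` is tagged `up`, `c2_like` `down`.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  if (!inherits(sig, "core_signature")) abort("`sig` must come from build_signatures().")
  sets <- list(c1_like = sig$c1_like, c2_like = sig$c2_like)
  attr(sets, "direction") <- c(c1_like = "up", c2_like = "down")
  write_gmt(sets, path)
}

#' Read a direction-tagged signature GMT
#'
#' @param path GMT with sets `c1_like` and `c2_like` (any published 37-gene
#'   style signature serialized by [write_signature()], or hand-built).
#' @return A `core_signature`.
#' @export
read_signature <- function(path) {
  sets <- read_gmt(path)
  if (!all(c("c1_like", "c2_like") %in% names(sets))) {
    abort("signature GMT must contain sets 'c1_like' and 'c2_like'.")
  }
  sig <- list(c1_like = sets$c1_like, c2_like = sets$c2_like)
  class(sig) <- "core_signature"
  sig
}

#' Rank-based single-sample signature score
#'
#' For each sample, genes are ranked ascending (average ranks on ties) and
#' the score of an up-set is its mean rank, centered and rescaled so the
#' attainable range is exactly \[-0.5, +0.5\]: a set occupying the very top
#' ranks scores +0.5, the very bottom -0.5. A `down_set`, when given, is
#' scored on reversed ranks and the two scores add, giving a total range of
#' \[-1, 1\]. Depending only on ranks, the score is invariant to any
#' strictly increasing per-sample transform of expression.
#'
#' @param expr `log2p1` expression matrix.
#' @param up_set Character vector of genes expected high.
#' @param down_set Optional character vector of genes expected low.
#' @return Named numeric vector of per-sample scores.
#' @export
singscore <- function(expr, up_set, down_set = NULL) {
  check_scale(expr, "log2p1", "singscore()")
  genes <- rownames(expr)
  up <- match_set(up_set, genes, "up set")
  down <- if (!is.null(down_set)) match_set(down_set, genes, "down set")
  n <- length(genes)
  score_one <- function(r, set) {
    m <- length(set)
    if (m >= n) abort("signature cannot cover the whole gene universe.")
    mean_rank <- mean(r[set])
    (mean_rank - (m + 1) / 2) / (n - m) - 0.5
  }
  vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    names(r) <- genes
    s <- score_one(r, up)
    if (!is.null(down)) s <- s + score_one(n + 1 - r, down)
    s
  }, numeric(1)) |> setNames(colnames(expr))
}

#' Unified subtype-derived prognostic score
#'
#' Scores the C1-like and C2-like signatures separately with [singscore()]
#' (both as up-sets) and combines them as `unified = c1 - c2`, flipping the
#' sign of the reference-class component so that larger values mean more
#' C1-like (poorer-prognosis) biology. The unified score lies in \[-1, 1\]
#' and attains the bounds at extremal rank configurations. Quartile
#' categories are assigned within the scored cohort (Q4 = highest score,
#' most C1-like), with group sizes differing by at most one; ties are broken
#' by sample ID for determinism.
#'
#' @param expr `log2p1` expression matrix.
#' @param sig A `core_signature`.
#' @return Tibble of class `core_score`: `sample_id`, `c1_component`,
#'   `c2_component`, `unified`, `quartile` (factor Q1-Q4).
#' @export
core37_score <- function(expr, sig) {
  if (!inherits(sig, "core_signature")) abort("`sig` must come from build_signatures()/read_signature().")
  c1 <- singscore(expr, sig$c1_like)
  c2 <- singscore(expr, sig$c2_like)
  unified <- c1 - c2
  n <- length(unified)
  ord <- order(unified, names(unified))
  q <- integer(n)
  q[ord] <- ceiling(seq_len(n) / (n / 4))
  q <- pmin(q, 4L)
  out <- tibble(
    sample_id = names(unified),
    c1_component = unname(c1),
    c2_component = unname(c2),
    unified = unname(unified),
    quartile = factor(paste0("Q", q), levels = paste0("Q", 1:4))
  )
  class(out) <- c("core_score", class(out))
  out
}
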
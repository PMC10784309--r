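#' Signal-to-noise ratio of genes between two classes
#'
#' For each gene, `snr = (mu_A - mu_B) / (sd_A + sd_B)` on the `log2p1`
#' scale, where A is the first factor level of `labels`. Each class standard
#' deviation is floored at `sigma_floor * |mean|` (and at `sigma_floor`
#' itself when the mean is zero), the usual variance flooring of
#' signal-to-noise marker ranking, so constant genes stay finite. Genes are
#' ranked descending for the A direction and ascending for the B direction,
#' ties broken by gene symbol.
#'
#' @param expr `log2p1` expression matrix.
#' @param labels Two-level factor (or coercible) over the samples; the first
#'   level is class A.
#' @param sigma_floor Relative variance floor (default 0.2).
#' @return A tibble of class `snr_table`: `gene`, `snr`, `rank_a`, `rank_b`,
#'   with the class names kept in attribute `classes`.
#' @export
snr_scores <- function(expr, labels, sigma_floor = 0.2) {
  check_scale(expr, "log2p1", "snr_scores()")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) abort("`labels` must have exactly two classes.")
  if (length(labels) != ncol(expr)) abort("`labels` length must match sample count.")
  sizes <- table(labels)
  if (any(sizes < 3)) {
    abort(paste0("each class needs >= 3 samples; got ",
                 paste(names(sizes), sizes, sep = "=", collapse = ", "), "."))
  }
  a <- labels == levels(labels)[1]
  floor_sd <- function(s, m) {
    fl <- pmax(sigma_floor * abs(m), 0)
    s <- pmax(s, fl)
    ifelse(s == 0, sigma_floor, s)
  }
  mu_a <- rowMeans(expr[, a, drop = FALSE])
  mu_b <- rowMeans(expr[, !a, drop = FALSE])
  sd_a <- floor_sd(apply(expr[, a, drop = FALSE], 1, sd), mu_a)
  sd_b <- floor_sd(apply(expr[, !a, drop = FALSE], 1, sd), mu_b)
  snr <- (mu_a - mu_b) / (sd_a + sd_b)
  gene <- rownames(expr)
  ord_a <- order(-snr, gene)
  ord_b <- order(snr, gene)
  out <- tibble(
    gene = gene,
    snr = unname(snr),
    rank_a = order(ord_a), # rank of each gene in the A direction
    rank_b = order(ord_b)
  )
  attr(out, "classes") <- levels(labels)
  class(out) <- c("snr_table", class(out))
  out
}

#' Select classifier marker panels from an SNR table
#'
#' Takes the top `n_per_class[1]` genes in the class-A direction (largest
#' SNR) and the top `n_per_class[2]` in the class-B direction (most negative
#' SNR), ties broken by gene symbol. The default sizes (20, 10) reproduce the
#' published panel sizes of the subtype classifier.
#'
#' @param snr An `snr_table` from [snr_scores()].
#' @param n_per_class Integer pair: marker count for class A then class B.
#' @return A named list of two disjoint gene vectors (a template set), class
#'   names taken from the SNR table.
#' @export
select_classifier_genes <- function(snr, n_per_class = c(20L, 10L)) {
  if (!inherits(snr, "snr_table")) abort("`snr` must come from snr_scores().")
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 2 || any(n_per_class < 0)) {
    abort("`n_per_class` must be two non-negative integers.")
  }
  if (sum(n_per_class) > nrow(snr)) {
    abort(paste0("requested ", sum(n_per_class), " markers but only ",
                 nrow(snr), " genes are available."))
  }
  classes <- attr(snr, "classes")
  top_a <- snr$gene[order(snr$rank_a)][seq_len(n_per_class[1])]
  top_b <- snr$gene[order(snr$rank_b)][seq_len(n_per_class[2])]
  if (length(intersect(top_a, top_b)) > 0) {
    abort("marker panels overlap; request fewer genes per class.")
  }
  templates <- setNames(list(top_a, top_b), classes)
  templates[lengths(templates) > 0]
}

#' Nearest-template prediction with permutation confidence
#'
#' Classifies each sample by the cosine distance between its within-sample
#' z-scored expression over the union of template genes and the 0/1 indicator
#' vector of each class's markers. Significance comes from random gene sets:
#' for each of `n_perm` draws, a same-size gene set is sampled from the full
#' matrix universe and the same nearest-template distance is computed; the
#' nominal p-value is `(1 + #{null distance <= observed}) / (n_perm + 1)`.
#' Benjamini-Hochberg FDR is taken across samples, and calls with
#' `fdr <= confident_call_fdr` are flagged confident. Because the null
#' statistic is the same minimum-over-templates distance as the observed one,
#' nominal p-values are calibrated on signal-free data.
#'
#' @param expr `log2p1` expression matrix.
#' @param templates Named list of >= 2 marker gene vectors (class label ->
#'   markers), e.g. from [select_classifier_genes()] or [read_gmt()].
#' @param n_perm Number of random gene sets (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param confident_call_fdr FDR cutoff for a confident call (default 0.05).
#' @param min_genes Minimum template genes per class that must be present in
#'   the matrix (default 5).
#' @return A tibble of class `ntp_result`: `sample_id`, `predicted`, one
#'   `dist_<class>` column per template, `p`, `fdr`, `confident`,
#'   `ambiguous`. Ties in distance go to the lexicographically first class
#'   and are flagged ambiguous.
#' @export
ntp_predict <- function(expr, templates, n_perm = 1000L, seed = 1L,
                        confident_call_fdr = 0.05, min_genes = 5L) {
  check_scale(expr, "log2p1", "ntp_predict()")
  if (length(templates) < 2) abort("need >= 2 class templates.")
  if (is.null(names(templates))) abort("templates must be a named list.")
  universe <- rownames(expr)
  present <- lapply(names(templates), function(nm) {
    match_set(templates[[nm]], universe, nm, min_genes = min_genes)
  })
  names(present) <- names(templates)
  feat <- unlist(present, use.names = FALSE)
  if (anyDuplicated(feat)) abort("class templates must be disjoint gene sets.")
  m <- length(feat)
  k <- length(present)
  # indicator matrix: m template genes x k classes
  U <- matrix(0, m, k, dimnames = list(feat, names(present)))
  for (nm in names(present)) U[present[[nm]], nm] <- 1
  u_norm <- sqrt(colSums(U^2))

  zdist <- function(X) {
    # X: m x S slice; returns k x S cosine distances of column z-scores to U
    mu <- colMeans(X)
    Z <- sweep(X, 2, mu)
    znorm <- sqrt(colSums(Z^2))
    ok <- znorm > 0
    num <- crossprod(U, Z) # k x S
    D <- matrix(1, k, ncol(X))
    if (any(ok)) {
      D[, ok] <- 1 - sweep(num[, ok, drop = FALSE], 2, znorm[ok], "/") / u_norm
    }
    D
  }

  D_obs <- zdist(expr[feat, , drop = FALSE])
  ord_class <- order(names(present)) # lexicographic tie-break
  pred_idx <- apply(D_obs, 2, function(d) {
    i <- which(d == min(d))
    if (length(i) > 1) i <- i[order(match(i, ord_class))][1]
    i
  })
  d_min <- D_obs[cbind(pred_idx, seq_len(ncol(expr)))]
  is_tie <- apply(D_obs, 2, function(d) sum(abs(d - min(d)) < 1e-12) > 1)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  exceed <- integer(ncol(expr))
  for (b in seq_len(n_perm)) {
    idx <- sample(universe, m)
    Db <- zdist(expr[idx, , drop = FALSE])
    null_min <- do.call(pmin, lapply(seq_len(k), function(i) Db[i, ]))
    exceed <- exceed + (null_min <= d_min)
  }
  p <- (1 + exceed) / (n_perm + 1)
  fdr <- p.adjust(p, method = "BH")

  out <- tibble(
    sample_id = colnames(expr),
    predicted = names(present)[pred_idx]
  )
  for (i in seq_len(k)) out[[paste0("dist_", names(present)[i])]] <- D_obs[i, ]
  out$p <- p
  out$fdr <- fdr
  out$confident <- fdr <= confident_call_fdr
  out$ambiguous <- is_tie
  attr(out, "templates") <- present
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "confident_call_fdr") <- confident_call_fdr
  class(out) <- c("ntp_result", class(out))
  out
}
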
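#' Consensus clustering over subsampled clusterings
#'
#' For each candidate k, repeatedly subsamples a fraction of the samples,
#' clusters the subsample, and aggregates co-clustering into a consensus
#' matrix `M[i, j]` = (times i and j clustered together) / (times both were
#' drawn). Final labels come from average-linkage hierarchical clustering of
#' `1 - M`; the number of classes is chosen by minimum PAC (proportion of
#' ambiguous consensus entries strictly between `pac_bounds`). The default
#' inner clustering is average-linkage hierarchical clustering on
#' `1 - Pearson correlation` between samples; `inner = "kmeans"` uses k-means
#' on the subsampled expression instead.
#'
#' @param expr `log2p1` expression matrix.
#' @param k_range Candidate class numbers (all >= 2).
#' @param reps Subsampling repetitions (default 1000).
#' @param subsample_frac Fraction of samples per repetition, in (0, 1].
#' @param seed Integer seed.
#' @param inner `"hclust"` (default) or `"kmeans"`.
#' @param n_features Keep the top genes by median absolute deviation before
#'   clustering (default 2000; `Inf` keeps all).
#' @param pac_bounds Ambiguity window for PAC (default `c(0.1, 0.9)`).
#' @return A list of class `consensus_result`: `consensus` (named list of
#'   per-k matrices), `labels` (tibble `sample_id` x one `k<k>` column per
#'   k), `metrics` (tibble `k`, `pac`, `delta_area`), `cdf` (tibble of
#'   consensus-CDF curves), `chosen_k`.
#' @export
consensus_cluster <- function(expr, k_range = 2:6, reps = 1000L,
                              subsample_frac = 0.8, seed = 1L,
                              inner = c("hclust", "kmeans"),
                              n_features = 2000L,
                              pac_bounds = c(0.1, 0.9)) {
  check_scale(expr, "log2p1", "consensus_cluster()")
  inner <- match.arg(inner)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) abort("`k_range` must not contain k < 2.")
  if (subsample_frac <= 0 || subsample_frac > 1) {
    abort("`subsample_frac` must be in (0, 1].")
  }
  n <- ncol(expr)
  if (n < 2 * max(k_range)) {
    abort(paste0("need >= ", 2 * max(k_range), " samples for k up to ",
                 max(k_range), "; got ", n, "."))
  }
  expr <- filter_by_mad(expr, n_features)
  samples <- colnames(expr)
  n_sub <- max(max(k_range), round(subsample_frac * n))

  # Pearson distance between samples is computed once on all samples;
  # per-repetition subsampling just selects a submatrix of it.
  if (inner == "hclust") {
    cx <- cor(expr)
    dfull <- 1 - cx
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)
  for (b in seq_len(reps)) {
    idx <- sort(sample.int(n, n_sub))
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    if (inner == "hclust") {
      hc <- hclust(as.dist(dfull[idx, idx]), method = "average")
      for (ki in seq_along(k_range)) {
        lab <- cutree(hc, k_range[ki])
        conn <- outer(lab, lab, "==")
        co_cluster[[ki]][idx, idx] <- co_cluster[[ki]][idx, idx] + conn
      }
    } else {
      sub <- t(expr[, idx, drop = FALSE])
      for (ki in seq_along(k_range)) {
        lab <- kmeans(sub, centers = k_range[ki], nstart = 1, iter.max = 50)$cluster
        conn <- outer(lab, lab, "==")
        co_cluster[[ki]][idx, idx] <- co_cluster[[ki]][idx, idx] + conn
      }
    }
  }

  consensus <- lapply(co_cluster, function(cc) {
    m <- ifelse(co_sample > 0, cc / pmax(co_sample, 1), 0)
    diag(m) <- 1
    m <- (m + t(m)) / 2
    dimnames(m) <- list(samples, samples)
    m
  })

  labels <- tibble(sample_id = samples)
  pac <- numeric(length(k_range))
  cdf_rows <- list()
  grid <- seq(0, 1, by = 0.01)
  areas <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    m <- consensus[[ki]]
    hc <- hclust(as.dist(1 - m), method = "average")
    labels[[paste0("k", k_range[ki])]] <- cutree(hc, k_range[ki])
    ut <- m[upper.tri(m)]
    pac[ki] <- mean(ut > pac_bounds[1] & ut < pac_bounds[2])
    cdf_fun <- ecdf(ut)
    cdf_rows[[ki]] <- tibble(k = k_range[ki], value = grid, cdf = cdf_fun(grid))
    areas[ki] <- sum(diff(grid) * cdf_fun(grid)[-1])
  }
  delta_area <- c(areas[1], diff(areas) / pmax(areas[-length(areas)], .Machine$double.eps))
  chosen_k <- k_range[which.min(pac)]

  structure(list(
    consensus = consensus,
    labels = labels,
    metrics = tibble(k = k_range, pac = pac, delta_area = delta_area),
    cdf = dplyr::bind_rows(cdf_rows),
    chosen_k = chosen_k,
    inner = inner,
    reps = as.integer(reps),
    subsample_frac = subsample_frac,
    seed = as.integer(seed)
  ), class = "consensus_result")
}

filter_by_mad <- function(expr, n_features) {
  if (!is.finite(n_features) || n_features >= nrow(expr)) return(expr)
  mads <- apply(expr, 1, mad)
  keep <- rownames(expr)[order(-mads, rownames(expr))][seq_len(n_features)]
  expr_subset(expr, genes = sort(keep))
}

#' Cluster labels at the chosen (or given) k
#'
#' @param x A `consensus_result`.
#' @param k Number of classes; defaults to the PAC-chosen k.
#' @return Named integer vector of labels.
#' @export
consensus_labels <- function(x, k = NULL) {
  if (!inherits(x, "consensus_result")) abort("`x` must come from consensus_cluster().")
  k <- k %||% x$chosen_k
  col <- paste0("k", k)
  if (!col %in% names(x$labels)) abort(paste0("k = ", k, " was not searched."))
  setNames(x$labels[[col]], x$labels$sample_id)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> chosen k =", x$chosen_k, "\n")
  print(x$metrics)
  invisible(x)
}

#' Non-negative matrix factorization class discovery
#'
#' Multiplicative-update NMF minimizing generalized Kullback-Leibler
#' divergence (the Brunet variant), run `n_runs` times per candidate rank
#' from random non-negative initializations. For each rank, the connectivity
#' matrices of the runs (samples co-assigned by dominant coefficient) are
#' averaged into a run-consensus matrix, and the rank with the highest
#' cophenetic correlation of that consensus is selected. The objective is
#' checked to be non-increasing on every run.
#'
#' @param expr TPM (non-negative) expression matrix.
#' @param rank_range Candidate ranks.
#' @param n_runs Random restarts per rank (default 30).
#' @param max_iter Maximum multiplicative updates per run (default 500).
#' @param tol Relative objective-decrease convergence tolerance.
#' @param seed Integer seed; run seeds derive from it by fixed offsets.
#' @param n_features Keep top genes by median absolute deviation (default
#'   `Inf`, all genes).
#' @return A list of class `nmf_result`: `fits` (per rank: `W`, `H`,
#'   `divergence`, `labels` of the best run), `metrics` (tibble `rank`,
#'   `cophenetic`, `best_divergence`), `chosen_rank`, `labels` (named vector
#'   at the chosen rank).
#' @export
nmf_cluster <- function(expr, rank_range = 2:6, n_runs = 30L, max_iter = 500L,
                        tol = 1e-5, seed = 1L, n_features = Inf) {
  check_scale(expr, "tpm", "nmf_cluster()")
  if (any(expr < 0)) abort("NMF requires a non-negative matrix.")
  rank_range <- sort(unique(as.integer(rank_range)))
  if (any(rank_range < 1)) abort("ranks must be >= 1.")
  if (max(rank_range) >= min(dim(expr))) {
    abort(paste0("max rank ", max(rank_range), " must be < min(dim) = ",
                 min(dim(expr)), "."))
  }
  expr_f <- filter_by_mad(log_transform(expr), n_features)
  V <- 2^expr_f - 1 # back to TPM after feature filtering on the log scale
  V <- pmax(V, 0)
  attr(V, "expr_scale") <- NULL
  n <- ncol(V)
  samples <- colnames(V)

  fits <- list()
  coph <- numeric(length(rank_range))
  best_div <- numeric(length(rank_range))
  for (ri in seq_along(rank_range)) {
    r <- rank_range[ri]
    runs <- vector("list", n_runs)
    for (run in seq_len(n_runs)) {
      runs[[run]] <- nmf_kl_fit(V, r, max_iter, tol,
                                seed = as.integer(seed) + 1000L * ri + run)
    }
    divs <- vapply(runs, `[[`, numeric(1), "divergence")
    best <- runs[[which.min(divs)]]
    best_div[ri] <- min(divs)
    conn <- matrix(0, n, n)
    for (run in runs) {
      lab <- run$labels
      conn <- conn + outer(lab, lab, "==")
    }
    conn <- conn / n_runs
    if (r == 1 || length(unique(best$labels)) == 1) {
      coph[ri] <- NA_real_
    } else {
      d <- as.dist(1 - conn)
      if (max(d) == 0) {
        coph[ri] <- 1
      } else {
        hc <- hclust(d, method = "average")
        coph[ri] <- suppressWarnings(cor(cophenetic(hc), d))
        if (is.na(coph[ri])) coph[ri] <- 1 # zero-variance distances: perfectly stable
      }
    }
    fits[[as.character(r)]] <- list(
      W = best$W, H = best$H, divergence = best$divergence,
      labels = setNames(best$labels, samples), consensus = conn
    )
  }
  chosen <- if (all(is.na(coph))) rank_range[1] else rank_range[which.max(coph)]
  structure(list(
    fits = fits,
    metrics = tibble(rank = rank_range, cophenetic = coph,
                     best_divergence = best_div),
    chosen_rank = chosen,
    labels = fits[[as.character(chosen)]]$labels,
    seed = as.integer(seed)
  ), class = "nmf_result")
}

# one KL-NMF run with multiplicative updates; asserts monotone objective
nmf_kl_fit <- function(V, r, max_iter, tol, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  scale0 <- sqrt(mean(V) / r)
  W <- matrix(runif(g * r, 0.1, 1) * scale0, g, r)
  H <- matrix(runif(r * n, 0.1, 1) * scale0, r, n)
  kl_div <- function(WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / pmax(WH[pos], eps))) - sum(V) + sum(WH)
  }
  WH <- W %*% H
  d_prev <- kl_div(WH)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V / pmax(WH, eps))) / pmax(colSums(W), eps)
    WH <- W %*% H
    W <- W * ((V / pmax(WH, eps)) %*% t(H)) / rep(pmax(rowSums(H), eps), each = g)
    WH <- W %*% H
    d_cur <- kl_div(WH)
    if (d_cur > d_prev + 1e-8 * max(1, abs(d_prev))) {
      abort("NMF objective increased; multiplicative update violated monotonicity.")
    }
    if ((d_prev - d_cur) <= tol * max(1, abs(d_prev))) {
      d_prev <- d_cur
      break
    }
    d_prev <- d_cur
  }
  list(W = W, H = H, divergence = d_prev,
       labels = apply(H, 2, which.max))
}

#' @export
print.nmf_result <- function(x, ...) {
  cat("<nmf_result> chosen rank =", x$chosen_rank, "\n")
  print(x$metrics)
  invisible(x)
}

#' Average-linkage dendrogram over samples
#'
#' UPGMA (average-linkage) hierarchical clustering of samples on Euclidean
#' distances of their `log2p1` expression profiles. Samples are ordered by ID
#' before clustering so the tree is deterministic under input reordering.
#'
#' @param expr `log2p1` expression matrix with >= 2 samples.
#' @return An `hclust` object.
#' @export
hierarchical_dendrogram <- function(expr) {
  check_scale(expr, "log2p1", "hierarchical_dendrogram()")
  if (ncol(expr) < 2) abort("need >= 2 samples for a dendrogram.")
  expr <- expr_subset(expr, samples = sort(colnames(expr)))
  hclust(dist(t(expr), method = "euclidean"), method = "average")
}

#' Write a dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [hierarchical_dendrogram()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("writing Newick trees requires the 'ape' package.")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
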
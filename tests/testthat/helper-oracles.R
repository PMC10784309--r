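# Independent brute-force oracles. These re-derive each statistic from its
# definition with plain loops and are kept free of package internals.

# ssGSEA: walk the descending-expression list accumulating the weighted
# in-set ECDF minus the out-of-set ECDF, position by position.
oracle_ssgsea <- function(x, set, alpha) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- genes[order(-x, genes)]
  total_w <- sum(r[set]^alpha)
  n_out <- length(genes) - length(set)
  p_in <- 0; p_out <- 0; es <- 0
  for (g in ord) {
    if (g %in% set) p_in <- p_in + r[g]^alpha / total_w
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# rank signature score: mean set rank mapped onto [-0.5, 0.5] using the
# extreme attainable mean ranks enumerated directly.
oracle_singscore <- function(x, set) {
  n <- length(x)
  m <- length(set)
  r <- rank(x, ties.method = "average")
  mean_r <- mean(r[set])
  lo <- mean(seq_len(m))             # set occupies the bottom ranks
  hi <- mean(seq(n - m + 1, n))      # set occupies the top ranks
  (mean_r - (lo + hi) / 2) / (hi - lo)
}

# naive UPGMA agglomeration on a distance matrix; returns sorted merge
# heights and the full cophenetic matrix.
oracle_upgma <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d <- D
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    }
    i <- best[2]; j <- best[3]; h <- best[1]
    heights <- c(heights, h)
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    merged_d <- sapply(seq_len(k), function(l) {
      if (l == i || l == j) return(NA_real_)
      (sizes[i] * d[i, l] + sizes[j] * d[j, l]) / (sizes[i] + sizes[j])
    })
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], merged_d[keep]),
               c(merged_d[keep], 0))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  list(heights = sort(heights), cophenetic = coph)
}

# KM censoring curve evaluated by direct product over censoring times
oracle_censor_km <- function(time, event, t0, left = FALSE) {
  cens_times <- sort(unique(time[event == 0]))
  g <- 1
  for (ct in cens_times) {
    at_risk <- sum(time >= ct)
    n_cens <- sum(time == ct & event == 0)
    if ((left && ct < t0) || (!left && ct <= t0)) {
      g <- g * (1 - n_cens / at_risk)
    }
  }
  g
}

# IPCW cumulative/dynamic AUC by exhaustive weighted pair counting
oracle_auc_ipcw <- function(time, event, risk, t0) {
  cases <- which(time <= t0 & event == 1)
  controls <- which(time > t0)
  num <- 0; den <- 0
  for (i in cases) {
    wi <- 1 / oracle_censor_km(time, event, time[i], left = TRUE)
    for (j in controls) {
      wj <- 1 / oracle_censor_km(time, event, t0)
      conc <- if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
      num <- num + wi * wj * conc
      den <- den + wi * wj
    }
  }
  num / den
}
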
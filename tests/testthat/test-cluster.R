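ari <- function(a, b) mclust::adjustedRandIndex(a, b)

test_that("duplicated orthogonal profiles give a 0/1 consensus matrix", {
  set.seed(10)
  p1 <- rnorm(120)
  p2 <- rnorm(120)
  vals <- cbind(matrix(rep(p1, 20), ncol = 20), matrix(rep(p2, 20), ncol = 20))
  e <- toy_expr(vals, scale = "log2p1")
  cc <- consensus_cluster(e, k_range = 2, reps = 200, seed = 1)
  m <- cc$consensus[["2"]]
  truth <- rep(1:2, each = 20)
  within <- m[outer(truth, truth, "==")]
  between <- m[outer(truth, truth, "!=")]
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  expect_equal(ari(consensus_labels(cc, 2), truth), 1)
})

test_that("two well-separated Gaussian groups yield chosen k = 2 and perfect recovery", {
  set.seed(11)
  n_half <- 30
  g <- 200
  shift_a <- c(rep(3, 40), rep(0, g - 40)) # each group owns a 40-gene program
  shift_b <- c(rep(0, g - 40), rep(3, 40)) # shifted 3 noise-SDs when active
  vals <- cbind(
    matrix(rnorm(g * n_half, shift_a), nrow = g),
    matrix(rnorm(g * n_half, shift_b), nrow = g)
  )
  e <- toy_expr(pmax(vals + 5, 0), scale = "log2p1")
  cc <- consensus_cluster(e, k_range = 2:4, reps = 200, seed = 2)
  expect_identical(cc$chosen_k, 2L)
  expect_equal(ari(consensus_labels(cc), rep(1:2, each = n_half)), 1)
  expect_true(all(cc$metrics$pac >= 0 & cc$metrics$pac <= 1))
  # consensus entries stay in [0, 1] with unit diagonal
  for (m in cc$consensus) {
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(diag(m)), rep(1, ncol(e)))
    expect_equal(m, t(m))
  }
})

test_that("permuting sample order permutes the consensus of noiseless data", {
  set.seed(12)
  p1 <- rnorm(60); p2 <- rnorm(60)
  vals <- cbind(matrix(rep(p1, 10), ncol = 10), matrix(rep(p2, 10), ncol = 10))
  e <- toy_expr(vals, scale = "log2p1")
  perm <- sample(ncol(e))
  ep <- expr_matrix(e[, perm], scale = "log2p1")
  c1 <- consensus_cluster(e, k_range = 2, reps = 100, seed = 3)
  c2 <- consensus_cluster(ep, k_range = 2, reps = 100, seed = 3)
  m1 <- c1$consensus[["2"]][colnames(ep), colnames(ep)]
  expect_equal(m1, c2$consensus[["2"]])
})

test_that("consensus clustering validates its inputs", {
  e <- toy_expr(matrix(rnorm(100), 10), scale = "log2p1")
  expect_error(consensus_cluster(e, k_range = 1:2), "k < 2")
  expect_error(consensus_cluster(e, subsample_frac = 1.5), "subsample_frac")
  expect_error(consensus_cluster(e, k_range = 2:8), "samples")
})

test_that("k-means inner clustering recovers the same clean structure", {
  set.seed(13)
  vals <- cbind(matrix(rnorm(300, 5), ncol = 15), matrix(rnorm(300, -5), ncol = 15))
  e <- toy_expr(vals, scale = "log2p1")
  cc <- consensus_cluster(e, k_range = 2, reps = 100, seed = 4, inner = "kmeans")
  expect_equal(ari(consensus_labels(cc, 2), rep(1:2, each = 15)), 1)
})

test_that("NMF factorizes an exact rank-1 matrix to near-zero error", {
  set.seed(20)
  w <- runif(30, 1, 5)
  h <- runif(12, 1, 5)
  V <- expr_matrix(
    outer(w, h) |> (\(m) {rownames(m) <- sprintf("g%02d", 1:30)
                          colnames(m) <- sprintf("s%02d", 1:12); m})(),
    scale = "tpm"
  )
  res <- nmf_cluster(V, rank_range = 1, n_runs = 3, max_iter = 2000,
                     tol = 1e-12, seed = 1)
  fit <- res$fits[["1"]]
  rel_err <- norm(V - fit$W %*% fit$H, "F") / norm(V, "F")
  expect_lt(rel_err, 1e-6)
})

test_that("NMF labels recover a block-diagonal structure at rank 2", {
  set.seed(21)
  blk <- function(n, m) matrix(runif(n * m, 5, 10), n, m)
  V <- rbind(cbind(blk(20, 10), matrix(runif(200, 0, 0.01), 20, 10)),
             cbind(matrix(runif(200, 0, 0.01), 20, 10), blk(20, 10)))
  e <- toy_expr(V, scale = "tpm")
  res <- nmf_cluster(e, rank_range = 2:3, n_runs = 10, seed = 2)
  expect_identical(res$chosen_rank, 2L)
  expect_equal(ari(tidy(res, rank = 2)$label, rep(1:2, each = 10)), 1)
})

test_that("NMF rejects impossible ranks and the wrong scale", {
  e <- toy_expr(matrix(runif(50, 1, 2), 10, 5), scale = "tpm")
  expect_error(nmf_cluster(e, rank_range = 5), "min\\(dim\\)")
  le <- log_transform(e)
  expect_error(nmf_cluster(le), "requires a tpm matrix")
})

test_that("close samples merge first in the average-linkage dendrogram", {
  e <- toy_expr(matrix(c(0, 1, 11), nrow = 1), scale = "log2p1",
                samples = c("a", "b", "c"))
  hc <- hierarchical_dendrogram(e)
  expect_equal(hc$height[1], 1) # a and b merge at their distance
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first_pair, c("a", "b"))
})

test_that("duplicated samples merge at height zero", {
  e <- toy_expr(cbind(c(1, 2), c(1, 2), c(5, 9)), scale = "log2p1")
  hc <- hierarchical_dendrogram(e)
  expect_equal(hc$height[1], 0)
  expect_error(hierarchical_dendrogram(toy_expr(matrix(1:3), scale = "log2p1")),
               ">= 2 samples")
})

test_that("the dendrogram equals brute-force UPGMA agglomeration", {
  set.seed(22)
  vals <- matrix(rnorm(18), nrow = 3) # 6 samples, 3 genes
  e <- toy_expr(vals, scale = "log2p1")
  hc <- hierarchical_dendrogram(e)
  D <- as.matrix(dist(t(vals)))
  oracle <- oracle_upgma(D)
  expect_equal(sort(hc$height), oracle$heights, tolerance = 1e-12)
  got_coph <- as.matrix(cophenetic(hc))
  ord <- match(colnames(e), hc$labels)
  expect_equal(unname(got_coph[colnames(e), colnames(e)]),
               unname(oracle$cophenetic), tolerance = 1e-12)
})
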
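test_that("differential expression handles degenerate and planted genes", {
  set.seed(50)
  n_per <- 30
  g <- 50
  vals_a <- matrix(rnorm(g * n_per, 4, 0.3), g)
  vals_b <- matrix(rnorm(g * n_per, 4, 0.3), g)
  vals_a[1, ] <- rnorm(n_per, 6, 0.3)  # planted true 4-fold (2 log2 units)
  vals_a[2, ] <- 3; vals_b[2, ] <- 3   # identical values in both classes
  e <- toy_expr(cbind(vals_a, vals_b), scale = "log2p1")
  labels <- factor(rep(c("C1", "C2"), each = n_per), levels = c("C1", "C2"))
  de <- differential_expression(e, labels, ref = "C2")
  expect_equal(de$log2fc[2], 0)
  expect_equal(de$adj_p[2], 1)
  expect_lt(de$adj_p[1], 0.01)
  expect_gt(abs(de$log2fc[1]), log2(2))
  # label swap negates every fold change
  de_sw <- differential_expression(e, labels, ref = "C1")
  expect_equal(de_sw$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_error(differential_expression(e, factor(rep(c("C1", "C2"), c(2, 58)))),
               ">= 3 samples")
})

test_that("the limma backend agrees with the rank-sum backend on strong effects", {
  skip_if_not_installed("limma")
  set.seed(51)
  e <- toy_expr(cbind(matrix(rnorm(200, 6), 20), matrix(rnorm(200, 4), 20)),
                scale = "log2p1")
  labels <- factor(rep(c("C1", "C2"), each = 10))
  d1 <- differential_expression(e, labels)
  d2 <- differential_expression(e, labels, method = "limma")
  expect_equal(d1$log2fc, d2$log2fc, tolerance = 1e-12)
  expect_true(all(d2$adj_p < 0.01))
})

test_that("signature construction filters, orders and truncates", {
  de <- tibble::tibble(
    gene = sprintf("g%02d", 1:8),
    log2fc = c(3, 2.5, 1.2, -3.5, -1.5, 0.2, 4, -0.9),
    p = rep(1e-5, 8),
    adj_p = c(rep(1e-4, 5), 0.5, 1e-4, 1e-4)
  )
  class(de) <- c("de_result", class(de))
  sig <- build_signatures(de, adj_p_max = 0.01, abs_fc_min = 2,
                          max_per_class = c(25, 12))
  expect_identical(sig$c1_like, c("g07", "g01", "g02", "g03"))  # |fc| desc
  expect_identical(sig$c2_like, c("g04", "g05"))
  # tightening adj_p can only shrink lists
  sig2 <- build_signatures(de, adj_p_max = 1e-6, abs_fc_min = 2) |>
    try(silent = TRUE)
  expect_true(inherits(sig2, "try-error")) # nothing passes: explicit error
  sig3 <- build_signatures(de, adj_p_max = 0.01, abs_fc_min = 2,
                           max_per_class = c(2, 1))
  expect_true(all(sig3$c1_like %in% sig$c1_like))
  expect_lte(length(sig3$c1_like), 2)
})

test_that("rank signature scores hit their exact bounds at extremal configurations", {
  n <- 10
  x <- seq_len(n)
  e <- toy_expr(matrix(x), scale = "log2p1")
  genes <- rownames(e)
  top <- genes[order(-x)][1:3]
  bottom <- genes[order(x)][1:3]
  expect_equal(unname(singscore(e, top)), 0.5)
  expect_equal(unname(singscore(e, bottom)), -0.5)
  expect_equal(unname(singscore(e, top, down_set = bottom)), 1)
})

test_that("rank signature scores match the brute-force mean-rank oracle", {
  # 6-gene sample with the set at ranks 2 and 5
  x <- c(10, 40, 15, 30, 22, 5)
  e <- toy_expr(matrix(x), scale = "log2p1")
  set <- rownames(e)[rank(x) %in% c(2, 5)]
  expect_equal(unname(singscore(e, set)), oracle_singscore(x, which(rank(x) %in% c(2, 5))),
               tolerance = 1e-12)
  set.seed(52)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    xx <- runif(n)
    ee <- toy_expr(matrix(xx), scale = "log2p1")
    m <- sample(seq_len(n - 1), 1)
    idx <- sample(n, m)
    expect_equal(unname(singscore(ee, rownames(ee)[idx])),
                 oracle_singscore(xx, idx), tolerance = 1e-12)
  }
})

test_that("rank signature scores survive monotone per-sample transforms", {
  set.seed(53)
  e <- toy_expr(matrix(runif(60), nrow = 20, ncol = 3), scale = "log2p1")
  up <- rownames(e)[1:4]
  down <- rownames(e)[5:7]
  base <- singscore(e, up, down)
  warped <- expr_matrix(e^3 + 1, scale = "log2p1")
  expect_equal(singscore(warped, up, down), base)
})

test_that("the unified score combines components with the C2 sign flipped", {
  n <- 20
  x <- seq_len(n)
  e <- toy_expr(cbind(x, rev(x)), scale = "log2p1")
  genes <- rownames(e)
  sig <- structure(list(c1_like = genes[(n - 3):n], c2_like = genes[1:4]),
                   class = "core_signature")
  sc <- core37_score(e, sig)
  # sample 1: c1-like genes at the very top, c2-like at the very bottom
  expect_equal(sc$unified[1], 1)
  expect_equal(sc$unified[2], -1)
  expect_equal(sc$unified, sc$c1_component - sc$c2_component)
  # equal components cancel
  sig_same <- structure(list(c1_like = genes[1:4], c2_like = genes[1:4]),
                        class = "core_signature")
  sc2 <- core37_score(e, sig_same)
  expect_equal(sc2$unified, rep(0, 2))
})

test_that("quartile categories are balanced and ordered by score", {
  set.seed(54)
  e <- toy_expr(matrix(runif(30 * 21), nrow = 30), scale = "log2p1")
  sig <- structure(list(c1_like = rownames(e)[1:5], c2_like = rownames(e)[6:10]),
                   class = "core_signature")
  sc <- core37_score(e, sig)
  sizes <- table(sc$quartile)
  expect_lte(diff(range(sizes)), 1)
  expect_true(min(sc$unified[sc$quartile == "Q4"]) >=
                max(sc$unified[sc$quartile == "Q1"]))
})

test_that("scored synthetic subtypes separate in the expected direction", {
  co <- shared_cohort()
  e <- shared_log_expr()
  truth <- truth_subtypes()
  labels <- factor(truth[colnames(e)], levels = c("C1", "C2"))
  de <- differential_expression(e, labels, ref = "C2")
  sig <- build_signatures(de)
  expect_lte(length(sig$c1_like), 25)
  expect_lte(length(sig$c2_like), 12)
  sc <- core37_score(e, sig)
  s1 <- sc$unified[truth[sc$sample_id] == "C1"]
  s2 <- sc$unified[truth[sc$sample_id] == "C2"]
  expect_gt(mean(s1), mean(s2))
  expect_lt(wilcox.test(s1, s2)$p.value, 0.01)
  expect_true(all(abs(sc$unified) <= 1))
})

test_that("signatures round-trip through direction-tagged GMT", {
  sig <- structure(list(c1_like = c("A", "B"), c2_like = c("C")),
                   class = "core_signature")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$c1_like, sig$c1_like)
  expect_identical(back$c2_like, sig$c2_like)
})
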
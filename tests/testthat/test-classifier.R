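two_class_expr <- function(vals_a, vals_b, genes = NULL) {
  m <- cbind(vals_a, vals_b)
  e <- toy_expr(m, scale = "log2p1", genes = genes)
  labels <- factor(rep(c("A", "B"), c(ncol(vals_a), ncol(vals_b))))
  list(expr = e, labels = labels)
}

test_that("SNR follows its definition with variance flooring", {
  # class A: mean 2, sd 1; class B: mean 0, sd 1 (exact by construction)
  a <- 2 + c(-sqrt(1.5), 0, sqrt(1.5), 0) # mean 2, sd 1 (n-1 denom, n=4)
  expect_equal(mean(a), 2); expect_equal(sd(a), 1)
  b <- a - 2
  tc <- two_class_expr(matrix(a, 1), matrix(b, 1))
  snr <- snr_scores(tc$expr, tc$labels)
  # floor: sd_A floored at 0.2*|2| = 0.4 < 1, so untouched; B mean 0 keeps sd 1
  expect_equal(snr$snr, (2 - 0) / (1 + 1), tolerance = 1e-12)

  # identical class means: zero SNR even for a constant gene
  tc2 <- two_class_expr(matrix(5, 1, 4), matrix(5, 1, 4))
  snr2 <- snr_scores(tc2$expr, tc2$labels)
  expect_equal(snr2$snr, 0)
  expect_true(is.finite(snr2$snr))
})

test_that("SNR is antisymmetric under class-label swap", {
  set.seed(40)
  tc <- two_class_expr(matrix(rnorm(40, 3), 10), matrix(rnorm(40, 2), 10))
  fwd <- snr_scores(tc$expr, tc$labels)
  swapped <- factor(tc$labels, levels = rev(levels(tc$labels)))
  bwd <- snr_scores(tc$expr, swapped)
  expect_equal(fwd$snr, -bwd$snr, tolerance = 1e-12)
  expect_error(snr_scores(tc$expr, factor(rep(c("A", "B"), c(2, 6)))),
               ">= 3 samples")
})

test_that("marker selection takes the top SNR genes per direction", {
  set.seed(41)
  n_null <- 1000
  planted <- 20
  a <- rbind(matrix(rnorm(planted * 10, 3 + 3), planted), # +3 log2 units in A
             matrix(rnorm(n_null * 10, 3), n_null))
  b <- matrix(rnorm((planted + n_null) * 10, 3), planted + n_null)
  genes <- c(sprintf("PLANT%02d", 1:planted), sprintf("NULL%04d", 1:n_null))
  tc <- two_class_expr(a, b, genes = genes)
  snr <- snr_scores(tc$expr, tc$labels)
  tpl <- select_classifier_genes(snr, c(20, 10))
  expect_setequal(tpl$A, genes[1:planted])
  expect_length(tpl$B, 10)
  expect_length(intersect(tpl$A, tpl$B), 0)
  expect_identical(lengths(select_classifier_genes(snr, c(0, 0))),
                   setNames(integer(0), character(0)))
  expect_error(select_classifier_genes(snr, c(2000, 10)), "available")
})

test_that("a template-matching sample is called with the smallest possible p", {
  set.seed(42)
  g <- 2000
  genes <- sprintf("g%04d", seq_len(g))
  tpl <- list(A = genes[1:20], B = genes[21:30])
  n_samp <- 6
  vals <- matrix(1, g, n_samp) # constant background defeats random gene sets
  vals[1:20, 1] <- 10          # sample 1 is exactly the class-A indicator
  vals[21:30, 2] <- 10         # sample 2 matches class B
  vals[, 3:n_samp] <- matrix(rnorm(g * 4, 5), g)
  e <- toy_expr(vals, scale = "log2p1", genes = genes)
  res <- ntp_predict(e, tpl, n_perm = 500, seed = 1)
  expect_identical(res$predicted[1], "A")
  expect_identical(res$predicted[2], "B")
  expect_equal(res$p[1], 1 / 501)
  expect_lt(res$dist_A[1], res$dist_B[1])
})

test_that("distance ties break to the first class name and are flagged", {
  g <- 40
  genes <- sprintf("g%02d", seq_len(g))
  tpl <- list(zeta = genes[1:10], alpha = genes[11:20])
  vals <- matrix(rep(seq(0.1, 4, length.out = g), 3), g, 3)
  vals[1:10, 1] <- 9  # equal-size panels, symmetric sample
  vals[11:20, 1] <- 9
  e <- toy_expr(vals, scale = "log2p1", genes = genes)
  res <- ntp_predict(e, tpl, n_perm = 50, seed = 2, min_genes = 5)
  expect_identical(res$predicted[1], "alpha") # lexicographically first
  expect_true(res$ambiguous[1])
})

test_that("NTP is invariant to sample order and per-sample affine transforms", {
  co <- shared_cohort()
  e <- shared_log_expr()
  sub <- expr_matrix(e[, 1:12], scale = "log2p1")
  tpl <- list(C1 = co$markers$c1_program[1:20], C2 = co$markers$c2_program[1:10])
  base <- ntp_predict(sub, tpl, n_perm = 100, seed = 5)
  perm <- c(4, 1, 12, 3, 2, 11, 6, 5, 10, 7, 9, 8)
  r_perm <- ntp_predict(expr_matrix(sub[, perm], scale = "log2p1"), tpl,
                        n_perm = 100, seed = 5)
  expect_identical(r_perm$predicted,
                   base$predicted[match(r_perm$sample_id, base$sample_id)])
  expect_equal(r_perm$dist_C1,
               base$dist_C1[match(r_perm$sample_id, base$sample_id)])
  # affine per-sample transform: z-scoring removes scale and offset
  aff <- sweep(sweep(sub, 2, runif(12, 0.5, 2), "*"), 2, rnorm(12), "+")
  aff <- expr_matrix(aff, scale = "log2p1")
  r_aff <- ntp_predict(aff, tpl, n_perm = 100, seed = 5)
  expect_identical(r_aff$predicted, base$predicted)
  expect_equal(r_aff$dist_C1, base$dist_C1, tolerance = 1e-10)
})

test_that("templates missing from the matrix raise a named error", {
  e <- toy_expr(matrix(rnorm(40), 10), scale = "log2p1")
  tpl <- list(A = c("zz1", "zz2", "zz3", "zz4", "zz5"),
              B = rownames(e)[1:5])
  expect_error(ntp_predict(e, tpl, n_perm = 20, seed = 1), "zz1")
})
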
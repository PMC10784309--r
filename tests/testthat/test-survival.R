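rec_tbl <- function(time, event, ...) {
  tibble::tibble(sample_id = sprintf("s%03d", seq_along(time)),
                 time = as.numeric(time), event = as.integer(event), ...)
}

test_that("cancer-unrelated deaths never enter the records", {
  clin <- tibble::tibble(
    sample_id = c("a", "b", "c"), os_days = c(100L, 200L, 300L),
    event = c(1L, 1L, 0L), death_unrelated = c(0L, 1L, 0L)
  )
  rec <- suppressMessages(survival_records(clin))
  expect_setequal(rec$sample_id, c("a", "c"))
  clin$os_days[1] <- 0L
  expect_error(suppressMessages(survival_records(clin)), "time > 0")
})

test_that("identical groups give a null log-rank test", {
  base <- rec_tbl(c(5, 8, 12, 20, 33), c(1, 1, 0, 1, 1))
  rec <- dplyr::bind_rows(base, base)
  rec$sample_id <- sprintf("s%03d", seq_len(nrow(rec)))
  km <- km_logrank(rec, rep(c("x", "y"), each = 5))
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  # S drops to 0.5 or below only at the post-censoring event time 20
  expect_equal(km$medians$median, rep(20, 2))
  expect_error(km_logrank(rec, rep("x", 10)), "non-empty|group")
})

test_that("the KM median matches the hand product-limit computation", {
  rec <- rec_tbl(1:9, rep(1, 9)) # uncensored events at days 1..9
  km <- km_logrank(dplyr::bind_rows(rec, rec_tbl(101:109, rep(1, 9))) |>
                     dplyr::mutate(sample_id = sprintf("q%03d", 1:18)),
                   rep(c("lo", "hi"), each = 9))
  expect_equal(km$medians$median[km$medians$group == "lo"], 5)
})

test_that("without censoring the KM curve equals the empirical survivor function", {
  set.seed(60)
  t <- sample(1:50, 30, replace = TRUE)
  fit <- survival::survfit(survival::Surv(t, rep(1, 30)) ~ 1)
  emp <- vapply(fit$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(fit$surv, emp, tolerance = 1e-12)
})

test_that("Cox fits recover null and true hazard ratios", {
  set.seed(61)
  labels <- rep(c("C1", "C2"), each = 500)
  s <- simulate_survival(labels, log_hr = log(2), baseline_rate = 1e-3,
                         censor_rate = 1e-9, seed = 8)
  rec <- rec_tbl(s$os_days, s$event, subtype = labels)
  fit <- cox_fit(rec, "subtype")
  td <- tidy(fit)
  expect_identical(td$term, "subtypeC1") # C2 is the reference level
  expect_gt(td$hr, 1.8); expect_lt(td$hr, 2.2)
  expect_true(td$conf_low < td$hr & td$hr < td$conf_high)

  s0 <- simulate_survival(labels, log_hr = 0, baseline_rate = 1e-3,
                          censor_rate = 1e-9, seed = 9)
  rec0 <- rec_tbl(s0$os_days, s0$event, subtype = labels)
  td0 <- tidy(cox_fit(rec0, "subtype"))
  expect_true(td0$conf_low < 1 & 1 < td0$conf_high)
  gl <- glance(cox_fit(rec0, "subtype"))
  expect_identical(gl$events, sum(rec0$event))
})

test_that("Cox validation rejects constant covariates and tiny event counts", {
  rec <- rec_tbl(c(3, 6, 9, 12), c(1, 0, 0, 0), grp = c("a", "a", "b", "b"),
                 flat = rep(1, 4))
  expect_error(cox_fit(rec, "flat"), "constant")
  expect_error(cox_fit(rec, c("grp", "flat")), "constant")
  rec2 <- rec_tbl(c(3, 6, 9, 12), c(0, 0, 0, 0), grp = c("a", "a", "b", "b"))
  expect_error(cox_fit(rec2, "grp"), "events")
})

test_that("time-dependent AUC is 1 for perfect ordering and ~0.5 under the null", {
  set.seed(62)
  t <- sort(sample(30:2000, 200))
  rec <- rec_tbl(t, rep(1, 200))
  perfect <- -as.numeric(t) # higher risk, earlier death
  auc <- time_dependent_auc(rec, perfect, years = 1:4)
  expect_equal(auc$auc, rep(1, 4))
  noise <- rnorm(200)
  auc0 <- time_dependent_auc(rec, noise, years = 2)
  expect_equal(auc0$auc, 0.5, tolerance = 0.1)
})

test_that("the censored AUC matches exhaustive IPCW pair counting", {
  # six records, one censored before the horizon
  time <- c(100, 250, 400, 500, 800, 900)
  event <- c(1, 0, 1, 1, 0, 1)
  risk <- c(0.9, 0.5, 0.8, 0.2, 0.4, 0.1)
  rec <- rec_tbl(time, event)
  got <- time_dependent_auc(rec, risk, years = 600 / 365.25)
  expect_equal(got$auc, oracle_auc_ipcw(time, event, risk, 600),
               tolerance = 1e-12)
  # horizons with no prior event are reported as missing
  early <- suppressMessages(time_dependent_auc(rec, risk, years = 50 / 365.25))
  expect_true(is.na(early$auc))
})

test_that("NRI is zero for identical models, antisymmetric, and maximal at 2", {
  set.seed(63)
  t <- c(100, 200, 300, 400, 900, 1000, 1100, 1200)
  ev <- c(1, 1, 1, 1, 0, 0, 0, 0)
  rec <- rec_tbl(t, ev)
  std <- rnorm(8)
  expect_equal(nri_compare(rec, std, std, horizon = 500)$nri, 0)
  # all events moved up, all non-events moved down
  new <- std + c(rep(1, 4), rep(-1, 4))
  res <- nri_compare(rec, std, new, horizon = 500)
  expect_equal(res$nri, 2)
  expect_equal(res$nri_event, 1)
  expect_equal(res$nri_nonevent, 1)
  # swapping models negates the index
  swapped <- nri_compare(rec, new, std, horizon = 500)
  expect_equal(swapped$nri, -res$nri)
  expect_error(nri_compare(rec, std, new, horizon = 5000), "beyond")
})

test_that("an informative new model earns a positive NRI under censoring", {
  set.seed(64)
  n <- 400
  risk_true <- rnorm(n)
  rate <- 1e-3 * exp(0.8 * risk_true)
  t_event <- rexp(n, rate)
  t_cens <- rexp(n, 8e-4)
  rec <- rec_tbl(pmax(1, ceiling(pmin(t_event, t_cens))),
                 as.integer(t_event <= t_cens))
  res <- nri_compare(rec, rnorm(n), risk_true, horizon = 730)
  expect_gt(res$nri, 0)
})

test_that("association wrappers run on contingency inputs", {
  f <- fisher_assoc(c("a", "a", "b", "b"), c("x", "y", "x", "y"))
  expect_true(f$p >= 0 && f$p <= 1)
  k <- kruskal_assoc(c(1, 2, 3, 10, 11, 12), rep(c("u", "v"), each = 3))
  expect_lt(k$p, 0.1)
})
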
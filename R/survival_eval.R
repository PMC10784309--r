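#' Assemble survival records from a clinical table
#'
#' Builds the analysis records for all survival estimators: keeps
#' `sample_id`, `time` (days from resection), `event` and any requested
#' covariates, and applies the exclusion rule — samples flagged
#' `death_unrelated = 1` never enter an estimator. Non-positive follow-up
#' times are an error.
#'
#' @param clin Clinical tibble with `sample_id`, `os_days`, `event` and
#'   optionally `death_unrelated`.
#' @param covariates Character vector of additional columns to carry.
#' @return Tibble: `sample_id`, `time`, `event`, covariates.
#' @export
survival_records <- function(clin, covariates = character()) {
  need <- c("sample_id", "os_days", "event")
  missing <- setdiff(c(need, covariates), names(clin))
  if (length(missing) > 0) {
    abort(paste0("clinical table lacks column(s): ", paste(missing, collapse = ", "), "."))
  }
  if ("death_unrelated" %in% names(clin)) {
    n_excl <- sum(clin$death_unrelated == 1, na.rm = TRUE)
    if (n_excl > 0) inform(paste0("excluding ", n_excl, " cancer-unrelated death(s)."))
    clin <- clin[clin$death_unrelated != 1, ]
  }
  if (any(clin$os_days <= 0)) {
    abort("non-positive follow-up time; survival records require time > 0.")
  }
  out <- tibble(sample_id = clin$sample_id,
                time = as.numeric(clin$os_days),
                event = as.integer(clin$event))
  for (nm in covariates) out[[nm]] <- clin[[nm]]
  out
}

#' Kaplan-Meier curves and log-rank test for a two-group contrast
#'
#' Product-limit estimates per group with the median survival time (first
#' time the curve reaches 0.5 or below) and the two-sample log-rank
#' chi-square test.
#'
#' @param records Tibble from [survival_records()].
#' @param group Name of a two-level grouping column in `records`, or a
#'   vector aligned with its rows.
#' @return List of class `km_result`: `medians` (tibble `group`, `n`,
#'   `events`, `median`), `chisq`, `df`, `p`, and the `survfit` object.
#' @export
km_logrank <- function(records, group) {
  g <- resolve_group(records, group)
  if (any(table(g) == 0) || nlevels(g) < 2) abort("every group must be non-empty.")
  dat <- data.frame(time = records$time, event = records$event, g = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = dat)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("g=all", names(tab)))
  medians <- tibble(
    group = sub("^g=", "", rownames(tab)),
    n = as.integer(tab[, "records"]),
    events = as.integer(tab[, "events"]),
    median = as.numeric(tab[, "median"])
  )
  if (sum(dat$event) == 0) abort("log-rank test needs at least one event.")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- length(sd_fit$n) - 1
  p <- pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  structure(list(medians = medians, chisq = unname(sd_fit$chisq), df = df,
                 p = p, fit = fit),
            class = "km_result")
}

resolve_group <- function(records, group) {
  if (is.character(group) && length(group) == 1 && group %in% names(records)) {
    factor(records[[group]])
  } else if (length(group) == nrow(records)) {
    factor(group)
  } else {
    abort("`group` must name a column of `records` or align with its rows.")
  }
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result> log-rank chisq =", signif(x$chisq, 4), " p =", signif(x$p, 3), "\n")
  print(x$medians)
  invisible(x)
}

#' Cox proportional-hazards fit with study reference levels
#'
#' Partial-likelihood fit (Efron tie handling by default) of
#' `Surv(time, event)` on the requested covariates. Categorical covariates
#' are releveled to the study's reference categories when present: site
#' `dCCA`, stage group `early`, molecular subtype `C2`, quartile `Q1`.
#' Constant covariates and models with more parameters than events are
#' rejected; likely separation (huge coefficient standard errors) is
#' flagged.
#'
#' @param records Tibble from [survival_records()] containing the covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie-handling method for [survival::coxph()] (default
#'   `"efron"`).
#' @return Object of class `cca_cox` wrapping the `coxph` fit; use [tidy()]
#'   for per-term hazard ratios and [glance()] for model summaries.
#' @export
cox_fit <- function(records, covariates, ties = "efron") {
  missing <- setdiff(covariates, names(records))
  if (length(missing) > 0) {
    abort(paste0("records lack covariate(s): ", paste(missing, collapse = ", "), "."))
  }
  dat <- as.data.frame(records[, c("time", "event", covariates)])
  refs <- c(site = "dCCA", stage_group = "early", subtype = "C2",
            quartile = "Q1", sex = "female")
  for (nm in covariates) {
    v <- dat[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (nm %in% names(refs) && refs[[nm]] %in% levels(v)) {
        v <- stats::relevel(v, ref = refs[[nm]])
      }
      dat[[nm]] <- v
      if (nlevels(v) < 2) abort(paste0("covariate `", nm, "` is constant."))
    } else if (length(unique(v)) < 2) {
      abort(paste0("covariate `", nm, "` is constant."))
    }
  }
  n_param <- sum(vapply(covariates, function(nm) {
    v <- dat[[nm]]
    if (is.factor(v)) nlevels(v) - 1L else 1L
  }, integer(1)))
  if (sum(dat$event) < n_param) {
    abort(paste0("only ", sum(dat$event), " events for ", n_param, " parameters."))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (any(!is.finite(stats::coef(fit)))) abort("Cox fit failed to converge.")
  separated <- any(sqrt(diag(fit$var)) > 10)
  if (separated) warn("very large coefficient standard error; possible separation.")
  structure(list(fit = fit, covariates = covariates, ties = ties,
                 separated = separated),
            class = "cca_cox")
}

#' @export
print.cca_cox <- function(x, ...) {
  cat("<cca_cox> n =", x$fit$n, " events =", x$fit$nevent, "\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy cca_cox
#' @export
tidy.cca_cox <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$fit, conf.int = conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(
    term = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    conf_low = unname(ci[, 3]),
    conf_high = unname(ci[, 4]),
    p = unname(co[, "Pr(>|z|)"])
  )
}

#' @method glance cca_cox
#' @export
glance.cca_cox <- function(x, ...) {
  f <- x$fit
  tibble(
    n = f$n, events = as.integer(f$nevent),
    loglik = f$loglik[2], loglik_null = f$loglik[1],
    concordance = unname(f$concordance["concordance"]),
    separated = x$separated
  )
}

# KM estimate of the censoring distribution G; returns a function G(t) and
# a left-limit version G(t-), both right-continuous step evaluations.
censor_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tms <- c(0, fit$time)
  srv <- c(1, fit$surv)
  g <- stats::stepfun(tms[-1], srv, right = FALSE)
  g_left <- function(t) {
    vapply(t, function(tt) {
      i <- which(tms < tt)
      srv[max(i)]
    }, numeric(1))
  }
  list(g = function(t) pmax(g(t), .Machine$double.eps),
       g_left = function(t) pmax(g_left(t), .Machine$double.eps))
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control discrimination of a risk score at each
#' horizon: cases are subjects with an observed event by time t (weighted by
#' `1 / G(T-)`, the censoring-KM left limit at their event time), controls
#' are subjects still under observation beyond t (weighted by `1 / G(t)`).
#' The AUC is the weighted proportion of case-control pairs ordered
#' correctly by the risk score, ties counting one half. Horizons with no
#' prior event give `NA` with a message.
#'
#' @param records Tibble from [survival_records()].
#' @param risk Numeric risk score (higher = riskier), a vector aligned with
#'   `records` or the name of one of its columns.
#' @param years Evaluation horizons in years (default 1:4).
#' @param days_per_year Days per year (default 365.25).
#' @return Tibble of class `td_auc`: `years`, `time_days`, `n_cases`,
#'   `n_controls`, `auc`.
#' @export
time_dependent_auc <- function(records, risk, years = 1:4,
                               days_per_year = 365.25) {
  risk <- resolve_risk(records, risk)
  km <- censor_km(records$time, records$event)
  out <- purrr::map_dfr(years, function(y) {
    t0 <- y * days_per_year
    case <- records$time <= t0 & records$event == 1
    ctrl <- records$time > t0
    if (!any(case)) {
      inform(paste0("no events before year ", y, "; AUC undefined."))
      return(tibble(years = y, time_days = t0, n_cases = 0L,
                    n_controls = sum(ctrl), auc = NA_real_))
    }
    w_case <- 1 / km$g_left(records$time[case])
    w_ctrl <- rep(1 / km$g(t0), sum(ctrl))
    r_case <- risk[case]
    r_ctrl <- risk[ctrl]
    cmp <- outer(r_case, r_ctrl, ">") + 0.5 * outer(r_case, r_ctrl, "==")
    wmat <- outer(w_case, w_ctrl)
    tibble(years = y, time_days = t0, n_cases = sum(case),
           n_controls = sum(ctrl),
           auc = sum(wmat * cmp) / sum(wmat))
  })
  class(out) <- c("td_auc", class(out))
  out
}

resolve_risk <- function(records, risk) {
  if (is.character(risk) && length(risk) == 1) {
    if (!risk %in% names(records)) abort(paste0("no column `", risk, "` in records."))
    risk <- records[[risk]]
  }
  if (length(risk) != nrow(records)) abort("`risk` must align with `records` rows.")
  as.numeric(risk)
}

#' Continuous net reclassification improvement between two risk models
#'
#' Compares a new risk score with a standard one at a fixed horizon using
#' the censoring-KM (IPCW) handling of incomplete follow-up: subjects with
#' an observed event by the horizon count as events (weight `1 / G(T-)`),
#' subjects followed beyond it as non-events (weight `1 / G(horizon)`);
#' subjects censored earlier contribute through the weights. The event
#' component is the weighted net proportion of events whose new risk exceeds
#' the standard risk; the non-event component is the net proportion of
#' non-events moved down; the total NRI is their sum (range \[-2, 2\]).
#'
#' @param records Tibble from [survival_records()].
#' @param standard_risk,new_risk Numeric risk vectors aligned with
#'   `records`, or names of its columns.
#' @param horizon Evaluation time in days; must not exceed the last
#'   follow-up.
#' @return List of class `nri_result`: `nri`, `nri_event`, `nri_nonevent`,
#'   `horizon`, `n_events`, `n_nonevents`.
#' @export
nri_compare <- function(records, standard_risk, new_risk, horizon) {
  standard_risk <- resolve_risk(records, standard_risk)
  new_risk <- resolve_risk(records, new_risk)
  if (horizon > max(records$time)) {
    abort("`horizon` lies beyond the last follow-up time.")
  }
  km <- censor_km(records$time, records$event)
  is_event <- records$time <= horizon & records$event == 1
  is_nonev <- records$time > horizon
  if (!any(is_event) || !any(is_nonev)) {
    abort("need both events and non-events by the horizon.")
  }
  up <- new_risk > standard_risk
  down <- new_risk < standard_risk
  w_ev <- 1 / km$g_left(records$time)
  w_ne <- 1 / km$g(horizon)
  we <- w_ev[is_event]
  p_up_e <- sum(we[up[is_event]]) / sum(we)
  p_down_e <- sum(we[down[is_event]]) / sum(we)
  wn <- rep(w_ne, sum(is_nonev))
  p_up_n <- sum(wn[up[is_nonev]]) / sum(wn)
  p_down_n <- sum(wn[down[is_nonev]]) / sum(wn)
  structure(list(
    nri = (p_up_e - p_down_e) + (p_down_n - p_up_n),
    nri_event = p_up_e - p_down_e,
    nri_nonevent = p_down_n - p_up_n,
    horizon = horizon,
    n_events = sum(is_event),
    n_nonevents = sum(is_nonev)
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat("<nri_result> horizon =", x$horizon, "days\n")
  cat("  NRI =", signif(x$nri, 4), "(event", signif(x$nri_event, 4),
      "+ non-event", signif(x$nri_nonevent, 4), ")\n")
  invisible(x)
}

#' Fisher's exact test of two categorical variables
#'
#' Convenience wrapper for class-versus-covariate association tables.
#'
#' @param x,y Factors or vectors of equal length, or `y = NULL` with `x`
#'   already a contingency table/matrix.
#' @return Tibble: `p`, `method`.
#' @export
fisher_assoc <- function(x, y = NULL) {
  tab <- if (is.null(y)) as.table(as.matrix(x)) else table(x, y)
  res <- stats::fisher.test(tab, simulate.p.value = prod(dim(tab)) > 10,
                            B = 10000)
  tibble(p = res$p.value, method = "fisher_exact")
}

#' Kruskal-Wallis test of a numeric variable across classes
#'
#' @param values Numeric vector.
#' @param groups Grouping factor of the same length.
#' @return Tibble: `statistic`, `df`, `p`, `method`.
#' @export
kruskal_assoc <- function(values, groups) {
  res <- stats::kruskal.test(values, as.factor(groups))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value, method = "kruskal_wallis")
}
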
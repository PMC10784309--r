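#' Specification for a synthetic cholangiocarcinoma-style cohort
#'
#' Describes the generative model the pipeline assumes: two latent expression
#' programs (a mesenchymal/immune C1 program and a metabolic/proliferative C2
#' program whose tail is a mitochondrial-tagged block), log-normal baseline
#' expression, convex tissue contamination with synthetic liver and pancreas
#' reference profiles correlated with anatomical site, and
#' proportional-hazards survival driven by subtype. All randomness flows from
#' `seed`.
#'
#' Defaults mirror the cohort structure the pipeline targets: class-1
#' prevalence 0.35, 60-gene programs with a 10-gene mitochondrial block,
#' effect size 2 log2 units, noise SD 0.5 log2 units, true subtype hazard
#' ratio 2 on an exponential baseline whose median matches the poorer-class
#' contrast, and ~35% censoring.
#'
#' @param n_samples Cohort size.
#' @param p_c1 Proportion of samples in subtype C1 (the poorer-prognosis
#'   class).
#' @param n_genes Total genes, including programs, tissue markers and filler.
#' @param program_size Genes per subtype program.
#' @param mt_block Genes at the end of the C2 program tagged as
#'   mitochondrial-encoded (`MT-` prefix).
#' @param effect Program up-shift in the owning class, log2 units.
#' @param noise_sd Per-gene Gaussian noise SD, log2 units.
#' @param tissue_marker_size Marker genes per tissue reference profile.
#' @param tissue_effect Marker up-shift in the tissue profile, log2 units.
#' @param p_contaminated Probability a sample is heavily contaminated.
#' @param contam_high,contam_low Uniform ranges for the mixing fraction of
#'   heavily contaminated and clean samples.
#' @param site_probs Named probabilities for anatomical sites
#'   (`dCCA`, `pCCA`, `iCCA`).
#' @param baseline_rate Exponential event hazard of the reference class C2
#'   (per day).
#' @param log_hr True log hazard ratio of C1 versus C2.
#' @param censor_rate Exponential censoring hazard (per day).
#' @param unrelated_death_rate Probability of a cancer-unrelated death flag.
#' @param seed Integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 200L,
                        p_c1 = 0.35,
                        n_genes = 2000L,
                        program_size = 60L,
                        mt_block = 10L,
                        effect = 2.0,
                        noise_sd = 0.5,
                        tissue_marker_size = 50L,
                        tissue_effect = 6,
                        p_contaminated = 0.3,
                        contam_high = c(0.4, 0.7),
                        contam_low = c(0, 0.10),
                        site_probs = c(dCCA = 0.43, pCCA = 0.31, iCCA = 0.26),
                        baseline_rate = log(2) / 565,
                        log_hr = log(2),
                        censor_rate = 9e-4,
                        unrelated_death_rate = 0.05,
                        seed = 1L) {
  spec <- list(
    n_samples = as.integer(n_samples), p_c1 = p_c1,
    n_genes = as.integer(n_genes), program_size = as.integer(program_size),
    mt_block = as.integer(mt_block), effect = effect, noise_sd = noise_sd,
    tissue_marker_size = as.integer(tissue_marker_size),
    tissue_effect = tissue_effect, p_contaminated = p_contaminated,
    contam_high = contam_high, contam_low = contam_low,
    site_probs = site_probs, baseline_rate = baseline_rate,
    log_hr = log_hr, censor_rate = censor_rate,
    unrelated_death_rate = unrelated_death_rate, seed = as.integer(seed)
  )
  if (spec$n_samples < 4) abort("`n_samples` must be >= 4.")
  if (spec$p_c1 <= 0 || spec$p_c1 >= 1) abort("`p_c1` must be in (0, 1).")
  if (spec$mt_block > spec$program_size) abort("`mt_block` cannot exceed `program_size`.")
  need <- 2L * spec$program_size + 2L * spec$tissue_marker_size
  if (need > spec$n_genes) {
    abort(paste0("program and tissue blocks need ", need, " genes but `n_genes` is ",
                 spec$n_genes, "."))
  }
  if (abs(sum(spec$site_probs) - 1) > 1e-8) abort("`site_probs` must sum to 1.")
  for (nm in c("p_contaminated", "unrelated_death_rate")) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) abort(paste0("`", nm, "` must be in [0, 1]."))
  }
  for (nm in c("contam_high", "contam_low")) {
    r <- spec[[nm]]
    if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2]) {
      abort(paste0("`", nm, "` must be an increasing range inside [0, 1]."))
    }
  }
  if (spec$baseline_rate <= 0 || spec$censor_rate <= 0) {
    abort("`baseline_rate` and `censor_rate` must be positive.")
  }
  if (spec$noise_sd < 0 || spec$effect < 0) abort("`effect` and `noise_sd` must be >= 0.")
  structure(spec, class = "cohort_spec")
}

#' Mix a tumor profile with a normal-tissue profile
#'
#' Convex combination `(1 - c) * tumor + c * tissue` of two TPM profiles,
#' renormalized so the result sums to 1e6. Models histological contamination
#' of a bulk sample by adjacent normal tissue.
#'
#' @param tumor,tissue Non-negative TPM vectors of equal length.
#' @param fraction Contamination fraction in `[0, 1]`.
#' @return Mixed TPM vector summing to 1e6.
#' @export
mix_contamination <- function(tumor, tissue, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single number in [0, 1].")
  }
  if (length(tumor) != length(tissue)) abort("profiles differ in length.")
  mixed <- (1 - fraction) * tumor + fraction * tissue
  mixed / sum(mixed) * 1e6
}

#' Simulate proportional-hazards survival for a two-class cohort
#'
#' Exponential event times with hazard
#' `baseline_rate * exp(log_hr * [label == C1])`, independent exponential
#' censoring, observed time = min(event, censoring) in whole days (ceiling,
#' so times are positive integers).
#'
#' @param labels Factor or character vector of subtype labels; `"C1"` carries
#'   the elevated hazard.
#' @param log_hr True log hazard ratio for C1 versus the reference.
#' @param baseline_rate Reference-class event hazard per day (> 0).
#' @param censor_rate Censoring hazard per day (> 0).
#' @param seed Integer seed.
#' @return Tibble with `os_days` (integer) and `event` (1 = death observed).
#' @export
simulate_survival <- function(labels, log_hr, baseline_rate, censor_rate, seed) {
  if (baseline_rate <= 0 || censor_rate <= 0) abort("rates must be positive.")
  n <- length(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  hazard <- baseline_rate * exp(log_hr * (as.character(labels) == "C1"))
  t_event <- rexp(n, rate = hazard)
  t_cens <- rexp(n, rate = censor_rate)
  tibble(
    os_days = as.integer(pmax(1, ceiling(pmin(t_event, t_cens)))),
    event = as.integer(t_event <= t_cens)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under a [cohort_spec()]: log-normal baseline expression with
#' the two subtype programs shifted up in their owning class, synthetic liver
#' and pancreas reference profiles mixed in at recorded fractions (tissue
#' choice correlated with anatomical site: hepatic with iCCA, pancreatic with
#' dCCA), per-sample TPM renormalization to 1e6, and exponential
#' proportional-hazards survival tied to subtype. Ground truth (subtype,
#' contamination, program gene lists, true relative risk) is returned
#' alongside the data.
#'
#' @param spec A `cohort_spec`.
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (TPM matrix), `clinical` (tibble matching the pipeline's clinical
#'   contract), `truth` (tibble), `templates` (liver/pancreas marker sets for
#'   tissue NTP), `markers` (true program gene lists) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must come from cohort_spec().")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$n_samples
  g <- spec$n_genes
  ps <- spec$program_size
  ts <- spec$tissue_marker_size

  c1_program <- sprintf("C1G%03d", seq_len(ps))
  n_nuc <- ps - spec$mt_block
  c2_program <- c(sprintf("C2G%03d", seq_len(n_nuc)),
                  sprintf("MT-SYN%02d", seq_len(spec$mt_block)))
  liver_markers <- sprintf("LIV%02d", seq_len(ts))
  panc_markers <- sprintf("PAN%02d", seq_len(ts))
  n_fill <- g - 2L * ps - 2L * ts
  filler <- sprintf("G%04d", seq_len(n_fill))
  genes <- c(c1_program, c2_program, liver_markers, panc_markers, filler)
  samples <- sprintf("S%03d", seq_len(n))

  subtype <- factor(ifelse(seq_len(n) <= round(spec$p_c1 * n), "C1", "C2"),
                    levels = c("C1", "C2"))
  subtype <- subtype[sample.int(n)]

  # baseline gene means on the log2 scale, shared by tumor and tissue profiles
  mu <- pmin(pmax(rnorm(g, mean = 3, sd = 2), 0), 8)
  names(mu) <- genes

  shift <- matrix(0, g, n, dimnames = list(genes, samples))
  shift[c1_program, subtype == "C1"] <- spec$effect
  shift[c2_program, subtype == "C2"] <- spec$effect
  logx <- mu + shift + matrix(rnorm(g * n, sd = spec$noise_sd), g, n)
  tumor_tpm <- 2^logx
  tumor_tpm <- sweep(tumor_tpm, 2, colSums(tumor_tpm), "/") * 1e6

  tissue_profile <- function(markers) {
    lt <- mu
    lt[markers] <- lt[markers] + spec$tissue_effect
    p <- 2^lt
    p / sum(p) * 1e6
  }
  liver_profile <- tissue_profile(liver_markers)
  panc_profile <- tissue_profile(panc_markers)

  site <- sample(names(spec$site_probs), n, replace = TRUE, prob = spec$site_probs)
  p_hepatic <- c(dCCA = 0.1, pCCA = 0.5, iCCA = 0.9)[site]
  contam_tissue <- ifelse(runif(n) < p_hepatic, "hepatic", "pancreatic")
  contaminated <- runif(n) < spec$p_contaminated
  frac <- ifelse(contaminated,
                 runif(n, spec$contam_high[1], spec$contam_high[2]),
                 runif(n, spec$contam_low[1], spec$contam_low[2]))

  expr <- tumor_tpm
  for (j in seq_len(n)) {
    prof <- if (contam_tissue[j] == "hepatic") liver_profile else panc_profile
    expr[, j] <- mix_contamination(tumor_tpm[, j], prof, frac[j])
  }
  expr <- expr_matrix(expr, scale = "tpm")

  surv <- simulate_survival(subtype, spec$log_hr, spec$baseline_rate,
                            spec$censor_rate, seed = spec$seed + 1L)
  death_unrelated <- as.integer(runif(n) < spec$unrelated_death_rate)

  minor <- function() round(runif(n, 0, 0.02), 4)
  contamination <- tibble(
    contamination_hepatic = round(ifelse(contam_tissue == "hepatic", frac, 0), 4),
    contamination_pancreatic = round(ifelse(contam_tissue == "pancreatic", frac, 0), 4),
    contamination_duodenal = minor(),
    contamination_lymphatic = minor(),
    contamination_neural = minor()
  )
  contamination_overall <- pmin(1, rowSums(contamination))

  clinical <- tibble(
    sample_id = samples,
    age = as.integer(pmin(pmax(round(rnorm(n, 63, 9)), 25), 82)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.67, 0.33)),
    site = site,
    stage_group = sample(c("early", "late"), n, replace = TRUE, prob = c(0.73, 0.27)),
    differentiation = sample(c("low_medium", "medium_high"), n,
                             replace = TRUE, prob = c(0.63, 0.37)),
    os_days = surv$os_days,
    event = surv$event,
    death_unrelated = death_unrelated
  ) %>%
    dplyr::bind_cols(contamination) %>%
    mutate(contamination_overall = contamination_overall)

  truth <- tibble(
    sample_id = samples,
    subtype = as.character(subtype),
    contaminated = contaminated,
    contam_tissue = contam_tissue,
    contam_fraction = frac,
    true_risk = exp(spec$log_hr * (subtype == "C1"))
  )

  structure(list(
    expression = expr,
    clinical = clinical,
    truth = truth,
    templates = list(hepatic = liver_markers, pancreatic = panc_markers),
    markers = list(c1_program = c1_program, c2_program = c2_program,
                   mt_block = c2_program[(n_nuc + 1):ps]),
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", ncol(x$expression), " samples x ",
      nrow(x$expression), " genes\n", sep = "")
  cat("  subtypes: ", paste(names(table(x$truth$subtype)),
                            table(x$truth$subtype), sep = "=", collapse = " "), "\n", sep = "")
  cat("  contaminated: ", sum(x$truth$contaminated), " samples\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression TSV, clinical CSV, ground-truth CSV and the tissue
#' template GMT for a generated cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) abort("`cohort` must come from generate_cohort().")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  write_gmt(cohort$templates, file.path(dir, "tissue_templates.gmt"))
  invisible(dir)
}
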
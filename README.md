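# ccatype

Anatomy-independent molecular subtyping and prognostic scoring for
cholangiocarcinoma (CCA) bulk RNA-seq.

CCA is conventionally classified by anatomical site (intrahepatic iCCA,
perihilar pCCA, distal dCCA), but resection specimens — especially distal
ones — often carry substantial normal-tissue contamination (liver, pancreas,
duodenum, lymph node, nerve) that distorts transcriptome-based clustering and
couples molecular "subtypes" to surgical anatomy rather than tumor biology.
`ccatype` implements a contamination-aware subtyping pipeline for
genes-by-samples TPM matrices:

1. **Purification.** Nearest-template prediction (NTP) against liver- and
   pancreas-specific marker templates flags samples whose transcriptome
   resembles normal tissue. A sample is moved to the *verification* cohort
   iff its NTP FDR ≤ 0.1 **and** its pathologist-estimated overall
   contamination fraction is > 25%; the remainder form the *purified*
   cohort used for discovery.
2. **Class discovery.** Consensus clustering (subsampled average-linkage
   clustering on 1 − Pearson correlation, aggregated into a consensus
   matrix, k chosen by minimum PAC) on the purified cohort; KL-divergence
   NMF with cophenetic rank selection and a UPGMA dendrogram are provided
   for the initial whole-cohort analysis. Two classes emerge: a
   mesenchymal/immunosuppressive **C1** (poorer prognosis, minority) and a
   metabolic/proliferative **C2**.
3. **Classifier.** Per-gene signal-to-noise ratio
   `SNR = (μ_A − μ_B) / (σ_A + σ_B)` (variance-floored) ranks
   class-correlated genes; the top 20 (C1) + 10 (C2) form templates for NTP
   with permutation p-values — random same-size gene sets give the null for
   the observed nearest-template cosine distance — and BH-FDR confidence
   calls, so the subtype of any external TPM profile can be predicted.
4. **Prognostic score.** Differential expression between classes
   (rank-sum on log2(TPM+1), BH; defaults adj. p ≤ 0.01, |FC| ≥ 2) yields a
   C1-like (≤25 genes) and C2-like (≤12 genes) signature. Each is scored per
   sample by a rank-based signature score (mean normalized rank, rescaled to
   [−0.5, 0.5]); the unified score `c1 − c2 ∈ [−1, 1]` increases with
   C1-likeness and is used continuously or by quartile.
5. **Survival evaluation.** Kaplan–Meier/log-rank, Cox proportional hazards
   (Efron ties, study reference levels), time-dependent IPCW AUC(t) and
   continuous net reclassification improvement (NRI) comparing an
   age + stage model against an age + score model. Cancer-unrelated deaths
   are excluded from every estimator.

Single-sample gene-set scoring (ssGSEA with rank-weighted ECDF differences,
combined z-scores, stromal/immune scores) is included for pathway-level
characterization of the classes, and a seeded synthetic cohort generator —
two latent expression programs, convex tissue-contamination mixing
correlated with anatomical site, exponential proportional-hazards survival
with a true subtype HR of 2 — makes every stage testable without any data
download.

## Worked example

```r
library(ccatype)

co   <- generate_cohort(cohort_spec(n_samples = 120, n_genes = 1000, seed = 1))
expr <- log_transform(co$expression)

# 1. flag contaminated samples and split the cohort
ntp   <- tissue_ntp(expr, co$templates, n_perm = 1000, seed = 2)
split <- stratify_cohort(ntp, co$clinical)
table(split$cohort)
#>     purified verification
#>           85           35

# 2. discover the two molecular classes on the purified cohort
pure <- expr_matrix(expr[, cohort_samples(split, "purified")], "log2p1")
cc   <- consensus_cluster(pure, k_range = 2:4, reps = 500, seed = 3)
glance(cc)
#>   chosen_k   pac  reps subsample_frac inner
#> 1        2     0   500            0.8 hclust
subtype <- factor(ifelse(consensus_labels(cc) ==
             names(which.min(table(consensus_labels(cc)))), "C1", "C2"))

# 3. classifier panels and the unified prognostic score
snr <- snr_scores(pure, subtype)
tpl <- select_classifier_genes(snr)      # 20 C1 + 10 C2 marker genes
de  <- differential_expression(pure, subtype, ref = "C2")
sig <- build_signatures(de)              # 25 C1-like + 12 C2-like genes
sc  <- core37_score(expr, sig)
head(sc, 3)
#>   sample_id c1_component c2_component unified quartile
#> 1 S001          -0.00617       0.281   -0.287 Q1
#> 2 S002           0.250         0.0361   0.214 Q4
#> 3 S003           0.284         0.0490   0.235 Q4

# 4. survival contrast of the discovered classes
rec <- survival_records(dplyr::mutate(co$clinical,
         subtype = unname(subtype[co$clinical$sample_id])), "subtype")
rec <- rec[!is.na(rec$subtype), ]        # purified samples only
km_logrank(rec, "subtype")
#> <km_result> log-rank chisq = 18.98  p = 1.32e-05
#>   group     n events median
#> 1 C1       30     22    254
#> 2 C2       51     28    780
tidy(cox_fit(rec, "subtype"))
#>   term         hr conf_low conf_high        p
#> 1 subtypeC1  3.95     2.05      7.62  4.1e-05
```

The discovered C1 class has markedly shorter overall survival (median 254 vs
780 days; the Cox estimate overshoots the planted hazard ratio of 2 at this
small purified-cohort size, its confidence interval spanning 2.05–7.62).
Quartiles of the unified score, `time_dependent_auc()` and `nri_compare()`
evaluate the score as a continuous prognostic biomarker, and
`run_pipeline()` executes all five stages in order, writing per-stage
CSV/GMT outputs plus a JSON run summary.

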
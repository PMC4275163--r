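# hirrecur

Prognostic modeling of hepatocellular carcinoma (HCC) recurrence from the
state of the *non-tumor* liver. After curative resection, HCC relapses
through two distinct mechanisms: early recurrence (within ~2 years),
driven by intrahepatic metastasis of the primary tumor, and late
recurrence (beyond 2 years), driven by de novo tumors arising in a
chronically injured, regenerating liver. `hirrecur` implements the full
analysis pipeline for separating the two:

1. **Signature derivation** — genes responding to hepatic injury and
   regeneration (HIR) are found by a random-variance *t*-test on paired
   pre/post-injury liver biopsies, kept only if significant at
   *p* < 0.005 in *every* dataset, and the whole comparison is guarded
   by a permutation global test. The random-variance test shrinks
   per-gene variances toward an inverse-gamma prior fitted across the
   gene ensemble:

       t~_g = d_g / sqrt(c * (m s_g^2 + 2/b) / (m + 2a)),   df = m + 2a

2. **Patient classification** — a Bayesian compound covariate predictor
   (BCCP) collapses signature expression into one score
   `c = Σ w_g x_g` (weights = training *t*-statistics), models it with
   class-conditional Gaussians, and emits a posterior probability that a
   patient's adjacent liver carries the HIR state (HIR vs quiescent/QT
   subgroup), with leave-one-out cross-validation.
3. **Risk scores and integration** — weighted Cox-score classifiers
   (e.g. a 186-gene tumor signature applied by published weights),
   threshold dichotomization, three-way integration of an HIR call with
   a tumor risk call, and Cramer's V concordance between classifiers.
4. **Survival machinery** — Kaplan–Meier/log-rank, multivariate Cox
   models with the standard clinical covariates, and early/late
   recurrence windows implemented as landmark analyses.
5. **Minimal models** — nearest-shrunken-centroid (PAM-style) gene
   selection with a cross-validated miscalculation curve,
   category-stratified 20-gene panels, and a univariate-screen +
   backward-stepwise compact predictor.
6. **Synthetic data** — a generator that plants an injury-responsive
   gene set in paired datasets and a latent HIR/QT class plus a
   piecewise-hazard recurrence process in HCC cohorts, so every stage is
   testable against known ground truth with no external downloads.

## Worked example

```r
library(hirrecur)

cfg <- syn_config(n_genes = 1000, n_signature = 50, cohort_size = 300,
                  seed = 29)
pd  <- generate_paired_datasets(cfg)
sig <- derive_signature(pd$datasets, alpha = 0.005)
sig
#> <hir_signature> 50 features / 50 unique genes (alpha=0.005)

co    <- generate_cohort(cfg, sig)
train <- do.call(cbind, lapply(pd$datasets, function(d) d$expression$values))
# ... train a BCCP on pooled pre (QT) / post (HIR) biopsies, then:
calls <- classify_cohort(model, match_and_center(co$adjacent, sig))
table(calls$label, co$truth$per_patient_class)
#>        HIR  QT
#>   HIR  120   0
#>   QT     0 180

clin <- co$clinical
clin$hir <- as.integer(calls$label == "HIR")
late <- window_subset(clin, recurrence_window("late", tau = 24))
cox_fit(late, "hir")
#>   term       hr       lo       hi          p
#> 1  hir 1.907251 1.206624 3.014697 0.00570916
```

The late-window confidence interval covers the generating hazard ratio
(`exp(beta_late) = 2.2` by default) because only the HIR class drives the
hazard after the 24-month changepoint; the tumor-derived score drives it
before. The same dissociation is what the pipeline is designed to detect
in real cohorts.

The command line mirrors the stages:

```sh
./exec/hirrecur run-all --config cfg.json --seed 7 --out out/
```

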
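# stratmet

Genotype-stratified integration of serum ¹H-NMR metabolomics with
cardiometabolic risk-factor clustering.

## What it is for

Cardiometabolic risk factors (CMRFs) — abdominal obesity, high
triglycerides, low HDL, elevated blood pressure, high fasting glucose —
cluster within individuals; three or more together define the metabolic
syndrome. stratmet is for population studies that hold, per subject, a
clinical phenotype table, SNP genotype calls, and a 1D ¹H-NMR serum
spectrum, and that want to know whether the serum metabolic signature of
CMRF clustering is shared across genotypes of candidate SNPs — or whether
some genotypes carry the clinical burden *without* the metabolic shift
("null-profile" genotypes).

The package provides, as composable functions plus an end-to-end runner:

* **ATP-III scoring** of the five CMRF components and grouping into
  group 1 (< 2 components), group 2 (= 2), group 3 (≥ 3);
* **NMR processing**: alanine-doublet referencing (1.478 ppm), 0.01-ppm
  bucketing of the 0.50–4.70 ppm region, total-area normalization, and
  integration of a 27-window metabolite panel;
* **SNP QC and association**: call rate, Hardy-Weinberg χ², additive
  logistic regression of group-3 membership, Bonferroni control;
* **Chemometrics**: mean centering + Pareto scaling, PCA, NIPALS PLS-DA,
  Venetian-blind cross-validation (Q2, RMSECV, accuracy), permutation
  validation, VIP scores, cross-validated ROC/AUROC;
* **Stratified integration** — the core statistic. For metabolite m and a
  genotype stratum s,

  ```
  r(m, s) = ( mean_3,s(m) − mean_1,s(m) ) / ( mean_3(m) − mean_1(m) )
  ```

  the group-3 minus group-1 mean difference inside the stratum, normalized
  by the same difference in the whole cohort: r ≈ 1 means the stratum
  shows the cohort-wide change, r ≈ 0 no change, r < 0 an opposite
  change. Together with per-stratum significance-band patterns
  (p > 0.01 / < 0.01 / < 0.001 / < 0.00001) and the fold change
  (mean₃ − mean₁)/mean₃, this flags genotype strata with a null metabolic
  profile;
* a **synthetic-cohort generator** (HWE genotypes, group-conditional
  phenotypes and metabolite levels, Lorentzian-peak spectra with exact
  window areas) so the full pipeline is testable without subject-level
  data.

## Worked example

```r
library(stratmet)

cfg    <- sim_config(n_subjects = 600, seed = 1)
cohort <- generate_cohort(cfg)               # phenotypes, genotypes, spectra

nmr      <- process_spectra(cohort$spectra)  # reference, bin, normalize, integrate
profiles <- score_cmrf(cohort$phenotypes)    # ATP-III components and groups

assoc <- snp_association(cohort$genotypes,
                         outcome = as.integer(profiles$group == 3))

sel <- profiles$group %in% c(1, 3)
cv  <- venetian_cv(nmr$quant[sel, ], as.integer(profiles$group[sel] == 3),
                   n_components = 2, seed = 1)
cv
#> <cv_report> 10-fold x 10 repeats, 2 components
#>   Q2 (correlation) = 0.631 | Q2 (1-PRESS/TSS) = 0.390
#>   RMSECV = 0.389 | accuracy = 0.807 | AUROC = 0.872

rep_ <- stratified_report(nmr$quant, profiles$group, cohort$genotypes,
                          covariates = cohort$phenotypes[, c("age", "sex",
                                                             "smoking")])
rep_$ratios[c("lactate", "cholesterol"), 1:4]
#>             global rs174589_AA rs174589_AB rs174589_BB
#> lactate          1        0.90        1.09         1.3
#> cholesterol      1        1.15        0.81         1.3
flag_null_profile(rep_)                      # all FALSE: no null genotype here
```

The Q2 shown is the correlation-based cross-validation statistic (the mean
fold-wise correlation between the held-out class code and its prediction);
`q2_press` is the conventional 1 − PRESS/TSS. The AUROC (0.872) is the
Mann-Whitney area under the cross-validated ROC for discriminating
group 3 from group 1. In the ratio matrix, every genotype stratum of this
cohort tracks the global group difference (r near 1), so no stratum is
flagged as a null profile; simulating a genotype whose carriers draw their
metabolites from the group-1 distribution (`sim_config(null_genotype =
list(snp = "rs1", genotype = "BB"), ...)`) makes exactly that stratum come
out flagged.

Reference relative levels also give self-contained quantities, e.g. the
cholesterol fold change `fold_change(3.53, 3.24)` = −0.0895 (lower in
group 3) and the lactate fold change `fold_change(2.02, 2.34)` = +0.1368.

`run_all(config, out_dir)` chains simulate/load → NMR → phenotyping →
association → PLS-DA → integration, persisting every stage as TSV plus a
`summary.json`; `inst/scripts/stratmet-run.R` is a shell wrapper.

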
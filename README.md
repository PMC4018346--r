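# snplasso

Case-control association analysis for candidate-gene tagSNP panels, built
around the two-track design used in hospital-based cancer epidemiology
(the motivating application is a ~1,000-case / ~1,000-control bladder-cancer
study of 184 tagSNPs in 18 genes of the p53 pathway):

* **Classical track** — per-SNP logistic regression adjusted for age group,
  gender, region and smoking, under four modes of inheritance (additive,
  dominant, recessive, codominant) with likelihood-ratio tests; polytomous
  (multinomial) heterogeneity tests across disease subphenotypes defined by
  stage/grade or by tumor p53 expression; SNP×SNP and SNP×smoking
  interaction scans; and min-p permutation correction for multiple testing.
* **Penalized track** — L1-penalized (LASSO) logistic regression over all
  SNPs simultaneously with unpenalized covariates,

  maximize  ℓ(β) − λ Σⱼ |βⱼ|   (penalty over the SNP block only),

  solved by proximal-Newton coordinate descent with exact zeros and KKT
  certificates; λ tuned by 5-fold cross-validated AIC; per-SNP
  *reproducibility* = % of 1,000 bootstrap resamples in which the SNP is
  selected (λ re-tuned per resample); and a post-selection likelihood-ratio
  test whose p-value is corrected by re-running selection on 10,000
  label permutations.

Support machinery includes a Hardy-Weinberg screen (Pearson 1-df chi-squared
in controls), minor-allele-frequency computation, frequency-based genotype
imputation, the immunohistochemistry histoscore (Σ pᵢ·i over staining
intensities i = 0..3, range 0–300) with median-split classification,
stage/grade subphenotype mapping, per-allele power calculations, and a
synthetic cohort generator that emulates the full data structure (HWE
genotypes with exponentially tilted case distributions, the published
covariate margins, subphenotypes, p53 histoscores) so the entire pipeline is
testable without access to individual-level study data.

## A worked example

```r
library(snplasso)

# synthetic study: the 184-SNP panel with one real effect (OR 1.35/allele)
specs <- default_snp_specs(184)
specs$per_allele_log_or[specs$snp_id == "rs6567355"] <- log(1.35)
sim <- simulate_cohort(sim_config(snp_specs = specs, seed = 1))

# single-SNP association, best mode of inheritance
r <- fit_snp_logistic(sim$genotypes$dosage[, "rs6567355"], sim$cohort,
                      moi = "additive", snp_id = "rs6567355")
round(c(OR = unname(r$or_point), lo = r$ci95[1, "lo"],
        hi = r$ci95[1, "hi"], p = r$p_value), 4)
#>     OR     lo     hi      p
#> 1.3905 1.2188 1.5864 0.0000

# multi-SNP engine: tuning, stability, post-selection inference
cd <- covariate_design(sim$cohort)
report <- stability_selection(sim$genotypes$dosage[cd$keep, ], cd$X, cd$y,
                              lasso_config(seed = 4, n_bootstrap = 100,
                                           n_perm_post = 1000))
print(report)
#> stability_report: lambda_opt = 36.62, selected = {rs6567355, snpF054, snpF120}
#>   post-selection LRT = 42.06 (df = 3), raw p = 3.9e-09, corrected p = 0.022
#>   rs6567355: reproducibility 90%
#>   snpF054: reproducibility 46%
#>   snpF120: reproducibility 54%
```

Reading the output: the per-allele odds ratio estimate 1.39 (95% CI
1.22–1.59) recovers the planted 1.35. The LASSO selects the causal SNP at
the cross-validated-AIC optimum together with two noise SNPs that happened
to fit this realization — and the bootstrap reproducibility separates them:
the real signal reappears in 90% of resamples, the hangers-on in about
half. The selection-aware permutation p-value (0.022) stays significant but
is three orders of magnitude larger than the naive chi-squared p, which is
exactly the over-optimism the correction removes. On null data the same
report typically shows an empty selected set and reproducibilities below
50%.

The whole pipeline (simulate → prep → association → LASSO → report) also
runs from the command line:

```sh
Rscript -e 'snplasso::pipeline_main()' all --out runs/demo --seed 7
```

writing per-stage artifacts (`genotypes.raw`, `cohort.csv`,
`assoc_results.csv`, `perm_corrected.csv`, `stability.csv`,
`lasso_report.json`, `summary.csv`) and a `run_log.txt` recording seeds and
decision switches.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models, the
synthetic-data assumptions and what green tests do and do not establish,
the numerical choices, and the known limitations.
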
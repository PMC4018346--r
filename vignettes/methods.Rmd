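---
title: "Candidate-gene case-control analysis with snplasso: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene case-control analysis with snplasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`snplasso` analyses a candidate-gene tagSNP panel in a case-control study.
The motivating design is a hospital-based bladder-cancer study: roughly one
thousand cases and one thousand controls genotyped at 184 tagSNPs spread over
18 genes of the p53 tumor-suppressor pathway, with categorical covariates
(age group, gender, recruitment region, smoking status), tumor subphenotypes
defined by stage/grade, and tumor p53 expression summarised by an
immunohistochemistry histoscore. The package provides both halves of the
analysis that such a study needs:

1. **Per-SNP classical inference** — covariate-adjusted logistic regression
   under four modes of inheritance, with likelihood-ratio tests, polytomous
   subphenotype heterogeneity, interaction scans, and a min-p permutation
   correction for multiplicity; and
2. **A multi-SNP selection engine** — L1-penalized (LASSO) logistic
   regression over all SNPs simultaneously with unpenalized covariates,
   penalty tuning by cross-validated AIC, bootstrap stability selection, and
   a permutation-corrected post-selection likelihood-ratio test.

Because individual-level genotypes for such studies are generally not
deposited, the package ships a synthetic cohort generator that reproduces
the statistical structure the analysis assumes, so every stage is testable
end-to-end.

# Models

## Per-SNP logistic models

For SNP $j$ with minor-allele dosage $g_{ij} \in \{0,1,2\}$, disease status
$y_i$ is modelled as

$$\operatorname{logit} P(y_i = 1) = \alpha + \beta^\top m(g_{ij}) +
\gamma^\top z_i,$$

where $z_i$ are the covariate dummies and $m(\cdot)$ is the
mode-of-inheritance coding: additive ($g$), dominant ($1\{g \ge 1\}$),
recessive ($1\{g = 2\}$), or codominant (free indicators for the
heterozygote and rare homozygote). Significance is the likelihood-ratio test
against the covariate-only null (1 df, 2 df for codominant); confidence
intervals are Wald intervals on the genotype log-odds, matching the common
reporting style of odds ratio with 95% CI alongside an LRT p-value. The
"best" mode of inheritance for a SNP is the one with the smallest LRT
p-value, with ties broken in the fixed order additive, dominant, recessive,
codominant.

Subphenotype heterogeneity uses polytomous (multinomial) logistic regression
of the outcome classes {control, low-risk NMIT, high-risk NMIT, MIT} —
or {control, p53-low, p53-high} — on the additive genotype plus covariates.
The heterogeneity statistic is the LRT of the model with free per-subtype
genotype log-odds against the model with a single shared genotype log-odds,
on (number of subtypes − 1) degrees of freedom. The multinomial likelihood
is maximized by BFGS with analytic gradients; the shared-coefficient
(constrained) model is a genuine parameter tie, not a refit trick, which is
why the fitter is implemented in the package rather than borrowed.

Interaction scans compare nested adjusted models with and without a single
product term: for SNP pairs, both additive dosages plus their product
(multiplicative per-allele interaction, 1 df); for smoking, the dosage
crossed with ever-smoking (never vs. ever).

## Min-p permutation correction

Family-wise correction of the per-SNP p-values uses the permutation null of
the family minimum: case/control labels *together with their covariates* are
permuted against the genotype matrix, the full test family is recomputed,
and the corrected p-value of SNP $j$ is

$$p^{\mathrm{corr}}_j = \frac{1 + \#\{b : \min_k p^{(b)}_k \le p_j\}}{B + 1}.$$

Permuting the (label, covariate) block jointly preserves both the
covariate–outcome association and any genotype–genotype dependence while
breaking only the genotype–outcome link, which is the null of interest.
The finite-sample +1 correction bounds corrected p-values below by
$1/(B+1)$; corrected values are additionally floored at the raw p-value,
since a Monte-Carlo estimate may otherwise undercut it by sampling noise.
Fewer than 100 permutations are refused (the tail is too unstable to be
meaningful).

## The penalized multi-SNP model

With all $p$ SNPs coded additively, the engine maximizes the penalized
log-likelihood

$$\ell(\beta) \;-\; \lambda \sum_{j=1}^{p} |\beta_j|,$$

where $\ell$ is the usual binomial log-likelihood over all SNP and covariate
terms and the penalty runs over the SNP block only: the intercept and
covariates are *adjusted for, not selected over*. SNP dosages are kept on
the raw 0/1/2 scale (no standardization), so penalized coefficients are
per-allele log odds ratios directly comparable with the single-SNP module.

The optimizer is a proximal-Newton (iteratively reweighted least squares)
outer loop with cyclic coordinate descent and soft-thresholding on the
weighted least-squares subproblem — the standard modern realization of a
Newton-Raphson scheme for this objective. Coordinate descent produces exact
zeros, so the selected set is the exact support; every returned fit carries
its Karush-Kuhn-Tucker residual as a certificate of convergence
($|\nabla_j \ell| \le \lambda$ at zeros, $\nabla_j \ell = \lambda\,
\mathrm{sign}(\beta_j)$ on the support, to tolerance).

**Penalty tuning.** The penalty grid is 50 log-spaced values from
$\lambda_{\max}$ (the smallest penalty zeroing every SNP, computed from the
score at the covariate-only MLE) down to $\lambda_{\max}/1000$. Coupling
5-fold cross-validation with AIC admits more than one reading; the one
implemented is: the cross-validated log-likelihood
$\ell_{\mathrm{cv}}(\lambda)$ (sum of held-out fold log-likelihoods, folds
stratified by outcome) is combined with the mean across-fold selected
support size as the degrees of freedom,
$\mathrm{AIC}(\lambda) = -2\,\ell_{\mathrm{cv}}(\lambda) + 2\,df(\lambda)$,
and $\lambda_{\mathrm{opt}}$ minimizes this profile with ties going to the
larger (sparser) penalty. The alternative reading — a plain AIC on the
full-data path fit — is available behind `cv_aic_method = "full_data"`.
This recipe is deliberately stringent: a SNP entering the path is shrunk
toward zero, so its held-out gain initially undersells its effect, and
moderate signals (Wald $z \lesssim 4$) often lose to the empty model. That
stringency is a feature of the procedure being emulated, which selected a
single SNP from a 184-SNP panel under "stringent criteria".

**Stability selection.** Reproducibility of each SNP is the percentage of
1,000 bootstrap resamples (size $n$, with replacement; an m-out-of-n
subsampling mode is available) in which the SNP enters the selected model,
with the penalty re-tuned on every resample — the stricter reading, since
tuning is part of the selection procedure being assessed. SNPs monomorphic
within a resample are unselectable there and count as not selected.

**Post-selection inference.** The selected set is tested by an unpenalized
LRT of covariates + selected SNPs against covariates only
(df = number selected). Because the set was chosen by the data, the naive
chi-squared p-value overstates significance; the corrected p-value re-runs
selection on label-permuted data and compares each permutation's own
post-selection LRT with the observed one (10,000 permutations by default).
Selection inside permutations reuses the observed
$\lambda_{\mathrm{opt}}$ rather than re-running cross-validation 10,000
times; full re-tuning per permutation is available behind
`retune_per_perm = TRUE` for reduced permutation counts. An empty selection
returns a corrected p of 1 by convention.

## Study power

`power_per_allele()` gives the analytic normal-approximation power of the
1-df per-allele test: the case genotype distribution is obtained by
exponential tilting of the control Hardy-Weinberg distribution at the design
odds ratio, and the test statistic is the log allelic odds ratio with its
allele-count variance. `power_simulate()` cross-checks it by simulating
case/control genotype counts and applying the additive LRT. At the design
point of the emulated study (1,058/1,138, control MAF 0.25, OR 1.3,
$\alpha = 0.05$) both give about 97%, comfortably above the 90% the study
reports.

# The synthetic cohort generator

The generator's defaults *are* the stated world of the emulated study:

* **Arms:** 1,058 cases and 1,138 controls, drawn retrospectively (each arm
  from its own distribution), which is the actual sampling design of a
  case-control study.
* **Panel:** 184 SNPs in 18 genes. Sixteen SNPs carry the published control
  genotype counts as traceable anchors (control MAFs 0.04–0.44); the
  remaining 168 null fillers have MAFs spread evenly over [0.05, 0.5] and
  gene labels cycling through the panel genes. All SNPs are independent
  (no LD) — the emulated panel consists of low-LD tagSNPs — with an
  MCAR missingness knob.
* **Genotype model:** controls follow Hardy-Weinberg equilibrium at the
  control MAF; cases follow the exponentially tilted distribution
  $P_{\mathrm{case}}(g) \propto P_{\mathrm{ctrl}}(g)\,e^{\beta g}$, which is
  exactly the case distribution implied by the additive logistic model —
  no rejection sampling, exact arm sizes by construction. (An optional
  prospective mode rejection-samples from the population model and errors
  out past an iteration cap.)
* **Covariates:** category probabilities for age (5 levels), gender,
  region (5), smoking (5, including a small "missing" category) are the
  published control margins; per-category disease log-odds are derived from
  the published case/control count ratios, so the tilted case distribution
  reproduces the case margins exactly (43% current smokers among cases vs
  25% among controls, 87% male). Covariates and genotypes are independent
  given disease status; per-region or per-age genotype structure is not
  modelled because the emulated study reports none.
* **Subphenotypes:** cases are assigned low-risk NMIT / high-risk NMIT / MIT
  with probabilities 0.625 / 0.175 / 0.200 — the midpoints of the ranges
  reported for bladder tumors (60–65%, 15–20%, 20–30%) — via a stage/grade
  pair drawn within the class, so the stage/grade mapping code is exercised.
* **p53 expression:** intensity-percentage vectors over intensities 0–3 are
  drawn from a Dirichlet(4, 2, 1.5, 1) — chosen once to put roughly half the
  cells at zero staining and give histoscores spanning the 0–300 range with
  a median near 95 — and classified low/high by the median split.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, population stratification, genotyping batch effects,
differential missingness, and any genotype–covariate dependence. A green
test therefore establishes that the statistical machinery is correct under
the stated model, not that it is robust to those artefacts.

# Numerical and convention choices

* **Rounding:** reported MAFs round half-up to 2 decimals (`round_half_up`),
  matching the convention of the published table (base R rounds half to
  even).
* **Minor allele orientation** is defined in controls; histoscore
  intensities are the standard 0–3 scale (score range 0–300); median-split
  ties classify as "low" (the emulated study does not state a tie rule).
* **HWE screening** is report-only at p ≤ 1e-4; nothing is excluded,
  matching the emulated study, which reported no departures at that
  threshold.
* **Imputation** replaces a phasing-based tool with per-SNP
  genotype-frequency sampling (cases and controls pooled), adequate at 184
  low-LD tagSNPs where neighbouring markers are uninformative; this is a
  deliberate, documented deviation.
* **Complete-case smoking:** samples with missing smoking status are
  dropped from all models, mirroring the explicit "missing" row of the
  emulated study's cohort table.
* **Codominant cells with zero count** collapse to the dominant coding with
  a warning rather than failing; degenerate fits (constant coding,
  separation, non-convergence) come back flagged, never as crashes.
* **Solver internals:** the penalized design is mean-centered before
  coordinate descent (slopes are invariant with an unpenalized intercept;
  the intercept is back-transformed), which conditions the solver far
  better than raw 0/1/2 columns; and tuning paths stop once the support
  exceeds `dfmax` (default 50) SNPs, since such dense solutions cannot
  minimize the CV-AIC here but dominate compute. Convergence is declared at
  a maximum coefficient change below 1e-7 within 100 outer iterations, and
  certified by the KKT residual. Under (quasi-)separation — common in
  bootstrap resamples and small CV folds — the unpenalized part of the MLE
  diverges and no coefficient-change criterion can ever be met, so the
  solver treats any log-odds passing ±12 (an odds ratio above 160,000,
  numerically infinite) as converged-at-infinity and stops; coefficients
  are additionally boxed at ±30 as a belt-and-braces safeguard.
* **Seeding:** a single global seed is fanned out to stages by a named
  substream hash, so stage order cannot silently change results; identical
  seed and configuration give byte-identical outputs.

# Known limitations

* The CV-AIC tuning is conservative for moderate effects by construction
  (see above); users wanting a less stringent screen can tune with
  `cv_aic_method = "full_data"` or inspect the reproducibility percentages
  directly.
* Reproducibility percentages split between strongly correlated markers;
  with a low-LD tag panel this is minor, but on dense panels the per-SNP
  percentages understate the reproducibility of the *signal*.
* The permutation schemes assume exchangeability of (label, covariate) rows
  against genotypes; under strong population structure that assumption
  would fail, and no stratification correction is provided (the emulated
  study is single-ancestry by design).
* The power calculation is for the unadjusted per-allele test; adjusting
  for covariates changes power only marginally here because the simulated
  covariates are independent of genotype.

# A worked example

```{r, eval = FALSE}
library(snplasso)

# a synthetic study: 184-SNP panel, one real effect
specs <- default_snp_specs(184)
specs$per_allele_log_or[specs$snp_id == "rs6567355"] <- log(1.25)
cfg <- sim_config(snp_specs = specs, missing_rate = 0.01, seed = 1)
sim <- simulate_cohort(cfg)

# prep: HWE screen and imputation
hw <- hwe_screen(sim$genotypes, sim$cohort)
gm <- impute_missing(sim$genotypes, seed = 2)

# single-SNP scan and permutation correction
scan <- snp_scan(gm, sim$cohort)
pc <- minp_permutation(gm, sim$cohort, n_perm = 1000, seed = 3)

# multi-SNP engine
cd <- covariate_design(sim$cohort)
report <- stability_selection(gm$dosage[cd$keep, ], cd$X, cd$y,
                              lasso_config(seed = 4))
print(report)
```

The same pipeline runs from the command line via
`pipeline_main(c("all", "--out", "run1", "--seed", "7"))`, writing per-stage
CSV/JSON artifacts and a run log that records the seeds and the decision
switches in force.
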
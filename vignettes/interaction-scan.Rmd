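---
title: "Additive gene-environment interaction scans with geiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive gene-environment interaction scans with geiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Whether an environmental exposure such as cigarette smoking changes disease
risk can depend on genotype: an exposure with no marginal association can
still raise risk sharply in carriers of particular alleles. `geiscan`
implements a genome scan for this situation in case-control data, built
around *additive interaction* on the odds-ratio scale. It was designed for
immune-mediated disease cohorts of the Immunochip era — for example
sarcoidosis phenotypes (Löfgren's and non-Löfgren's syndrome) scanned
against shared healthy controls with ever/never smoking as the exposure —
but nothing in the machinery is specific to that disease.

## The model

For one SNP, genotype is collapsed under a **dominant model**: an
individual is a carrier if they have at least one copy of the coded allele.
Carrier status crossed with the binary exposure partitions individuals into
four **combination groups**:

* `g00` — neither factor (reference),
* `g01` — exposed only,
* `g10` — carrier only,
* `g11` — both.

A logistic regression of case status on the three non-reference group
indicators plus covariates (sex, age, ancestry PCs, optionally an HLA
carrier flag),

$$\operatorname{logit} P(Y=1) = \beta_0 + \beta_{01} I_{01} + \beta_{10} I_{10}
  + \beta_{11} I_{11} + \gamma^T z,$$

yields covariate-adjusted odds ratios
$OR_{01} = e^{\beta_{01}}, OR_{10} = e^{\beta_{10}},
OR_{11} = e^{\beta_{11}}$ against $OR_{00} \equiv 1$. Departure from
additivity of the two excess risks is summarized by the **attributable
proportion due to interaction**

$$AP = \frac{OR_{11} - OR_{01} - OR_{10} + 1}{OR_{11}},$$

the share of the doubly exposed group's odds attributable to the two
factors acting together rather than separately. $AP = 0$ at the additive
null $OR_{11} = OR_{01} + OR_{10} - 1$; $AP \le 1$ always; $AP$ is
symmetric in the two single-exposure odds ratios.

### Inference on AP

The scan needs a per-SNP p-value, and the literature around this estimator
does not fix one canonically; we use the **first-order delta method** on
the coefficient scale (the Hosmer–Lemeshow approach). Writing
$AP(\beta)$, its gradient is

$$\left(-e^{\beta_{01}-\beta_{11}},\; -e^{\beta_{10}-\beta_{11}},\;
  1 - AP\right)$$

with respect to $(\beta_{01}, \beta_{10}, \beta_{11})$, and the standard
error follows from the observed-information covariance of the fit. The 95%
interval is $AP \pm 1.96\,SE$ and the p-value the two-sided normal tail.
The test suite bounds the delta approximation against a 1,000-replicate
parametric bootstrap on a fixed cohort (agreement within 15% relative is
required) and checks calibration of the test at the additive null
(type-I error $0.05 \pm 0.02$ over 1,000 null SNPs at $n = 4{,}000$).

Fits with a sparse combination cell (fewer than `min_cell = 5` individuals
by default), separation (non-finite or very large Wald standard errors), or
a non-positive-definite covariance block are flagged non-converged and
excluded from the FDR family rather than extrapolated — small strata are
where Wald intervals on AP degrade first, so flagging is safer than
reporting an unstable bound.

### Multiplicity and significance

Benjamini–Hochberg FDR is computed across all converged SNPs within one
phenotype scan (each phenotype is scanned separately against the shared
controls, so each has its own FDR family; the run log records the family
size actually used). A SNP is significant when $AP > 0$, AP p-value
$< 0.05$ and FDR $< 0.05$ — the scan looks only for risk-increasing
interaction; both thresholds are configurable.

### Coded allele

The coded allele defaults to the minor allele but is taken from input
metadata when supplied, and may be either allele per SNP (summary tables in
this literature sometimes code the major allele). There is deliberately no
automatic flipping of the coded allele toward larger AP: that would bias
the p-values.

## Around the core scan

**LD pruning and ancestry PCs.** Population structure enters the model
through principal components of an LD-pruned genotype subset. Pruning uses
the composite (genotypic) $r^2$ — the squared Pearson correlation of
unphased dosages — in a sliding window (defaults: $r^2 > 0.25$, window 50,
step 5, the common PLINK idiom; the window/step are configuration since
only the threshold is standard). PCA standardizes dosages by
$(d - 2\hat p)/\sqrt{2\hat p(1-\hat p)}$ with mean imputation of missing
calls, the EIGENSOFT convention; component signs are fixed by requiring the
first nonzero loading positive, so results are permutation-invariant.

**Tag pruning of results.** Significant SNPs are collapsed into independent
lead signals by greedy priority pruning: the smallest AP p-value becomes a
tag (ties broken by genomic position), and unassigned SNPs with
$r^2 > 0.80$ to it — restricted to the same locus when gene labels are
supplied — are assigned to that tag. Pruning runs after the FDR filter.

**Exposure baseline.** `smoking_or()` gives the no-genetics association of
the exposure with each phenotype (Wald OR, CI, p from the adjusted
logistic model), overall or within HLA strata; age enters linearly in
years and intervals are Wald, matching standard multivariable reporting.

## The synthetic cohort generator

Because no individual-level data of the motivating design are deposited,
validation rests on `simulate_cohort()`, whose defaults *are* the study
conditions the package targets: 292 cases and 2,966 controls, ever-smoking
prevalence 0.5 independent of genotype, biallelic SNPs in Hardy–Weinberg
equilibrium, a 73.8% female population with male sex raising disease odds
(default OR 3.0) and a protective per-year age effect (OR 0.985 around a
N(50, 15²) age distribution) so that covariate adjustment is exercised
realistically — the motivating cohorts had markedly younger, more often
male cases than controls.

Disease is drawn from a prospective logistic model in which each designated
causal SNP contributes its dominant main effect and a carrier-by-exposure
product term chosen so the four combination-group odds ratios are exactly
$(1, OR_{01}, OR_{10}, OR_{11})$ with
$OR_{11} = (OR_{01} + OR_{10} - 1)/(1 - AP_{\text{true}})$. Case-control
ascertainment is by rejection sampling to exact case and control counts,
which preserves those odds ratios (only the intercept shifts); if the case
count cannot be accrued within the iteration cap the generator stops and
advises a larger baseline risk. A truth table records the generative
$OR_{01}, OR_{10}, OR_{11}, AP$ per SNP. `inject_ld_block()` appends
correlated SNPs (keep-with-probability $\sqrt{r^2_{\text{target}}}$, else
redraw) for tag-pruning fixtures.

What the generator does **not** emulate: realistic genome-wide LD maps,
gene–environment correlation, admixture beyond a two-subpopulation PCA
fixture, HLA haplotype structure, or genotyping error. Passing tests
therefore demonstrate correctness of the estimator and pipeline under the
stated design, not robustness to those real-data complications.

## Validation design and problem sizes

The statistical acceptance checks in the test suite use these fixed
designs, chosen to match the conditions above at sizes where Monte-Carlo
error is well inside the asserted bands:

* type-I error at the additive null: one cohort of 1,000 cases / 3,000
  controls with 1,000 null SNPs (exposure OR 1.2, covariates active);
* AP recovery: 200 single-SNP replicates of the same cohort shape with
  planted $AP = 0.5$ (MAF 0.3, exposure prevalence 0.5), mean estimate
  within ±0.05;
* delta vs bootstrap SE: one fixed 3,000-individual cohort, 1,000
  parametric-bootstrap refits;
* end-to-end recovery: 50 seeded replicates of a 205-SNP scan (5 planted
  $AP = 0.6$ among 200 nulls), requiring ≥80% of planted SNPs flagged.

Worked examples pin the AP arithmetic to published combination odds
ratios. One such row recomputes to an AP one unit in the last printed
digit away from its published value because the published odds ratios are
themselves rounded to two decimals; the tests therefore assert agreement
to within one printed ulp, which is the precision the rounded inputs can
support.

## Numerical choices and degenerate inputs

* Logistic fits use iteratively reweighted least squares
  (`stats::glm.fit`) with convergence tolerance `1e-10` and up to 100
  iterations; covariance is the inverse observed information.
* Monomorphic SNPs are skipped (reported with reason, not fitted); LD with
  a monomorphic SNP is undefined and returned as `NA`, never 0.
* Missing dosages are `NA` throughout; the scan is per-SNP complete-case,
  PCA mean-imputes.
* Everything downstream of the generator is deterministic: the same
  genotypes, cohort and configuration give byte-identical result files.

## Limitations

AP is one of several additive-interaction summaries (RERI and the synergy
index are not reported); the delta-method interval is first-order and
degrades in small strata, which the sparse-cell flag mitigates but does
not remove; FDR families depend on how many SNPs enter a scan, so
adjusted values are comparable only within a run; and the no-flip coded
allele policy means a mis-specified coded allele tests interaction of the
other allele (use `recode_allele()` with external metadata).

## A minimal run

```r
library(geiscan)

spec <- simulation_spec(n_cases = 500, n_controls = 1500, n_snps = 50,
                        causal = 1:3, or01 = 1.2, or10 = 1.2,
                        ap_true = 0.6, baseline_risk = 0.08, seed = 7)
sim <- simulate_cohort(spec)

pruned <- ld_prune(sim$genotypes)
pcs <- compute_pcs(sim$genotypes, pruned, k = 2)
cohort <- cbind(sim$cohort, as.data.frame(pcs))

res <- run_scan(sim$genotypes, cohort, "LS",
                covariate_names = c("sex", "age", "PC1", "PC2"))
res[res$significant, c("snp_id", "or11", "ap", "ap_p", "fdr")]

tags <- priority_prune(res, sim$genotypes)
smoking_or(cohort, "LS")
```

The same pipeline runs file-to-file through `cmd_simulate()` /
`cmd_scan()` or the `inst/cli/geiscan.R` script.
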
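---
title: "Simulating variance-heterogeneity QTLs: model, estimators, design"
author: "vgwasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating variance-heterogeneity QTLs: model, estimators, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgwasim)
```

## The phenotype model

`vgwasim` simulates quantitative traits whose conditional distribution
given genotype is normal, with both the mean and the standard deviation
linear in minor-allele dose:

$$y = \mu + g^T\alpha + \epsilon, \qquad
  \epsilon \sim N\!\big(0, (\sigma + g^T\phi)^2\big).$$

A locus with $\phi \ne 0$ is a variance-heterogeneity QTL (vQTL): its
genotype classes differ in spread, the statistical footprint that
gene–gene and gene–environment interactions leave at an interacting locus.
The model's assumptions are worth stating because they bound what passing
tests demonstrate:

* conditional normality within each genotype class;
* additivity across causal loci on both the mean and the
  standard-deviation scale (no epistasis, no dominance interactions
  between loci);
* independence of the residual draw across samples.

### From effect sizes to parameters

Users specify, per causal locus, the *fraction of the total phenotypic
variance* $V_Y$ contributed by the locus's mean shift ($C_\mu$) and by its
variance shift ($C_V$), plus the baseline mean $\mu$ and $V_Y$ itself.
This parameterization is what makes planted signals comparable across
loci, frequencies and ploidies. Decomposing the total variance,

$$V_Y = \underbrace{Var(E[Y|G])}_{V_M = kpq\,\alpha^2}
      + \underbrace{Var(\sigma + g\phi)}_{V_V = kpq\,\phi^2}
      + \underbrace{E^2[\sigma + g\phi]}_{V_R = (\sigma + kq\phi)^2},$$

with $k = 1$ (haploid dose 0/1) or $k = 2$ (co-dominant diploid dose
0/1/2, Hardy-Weinberg), and inverting gives the closed forms implemented
in `solve_phenotype_model()`:

$$\alpha_i = \sqrt{C_\mu^{(i)} V_Y / (k p_i q_i)}, \quad
  \phi_i   = \sqrt{C_V^{(i)} V_Y / (k p_i q_i)}, \quad
  \sigma   = \sqrt{V_Y\big(1 - \textstyle\sum_i(C_\mu^{(i)} + C_V^{(i)})\big)}
             - k\,q^T\phi.$$

Under **complete dominance** only the minor-allele homozygote expresses the
shift, so the genotype collapses to a two-state 0/1 variable with carrier
frequency $q = q_{allele}^2$ and the haploid forms apply (implemented by
`solve_diploid_dominant()`). We note one subtlety of mapping: additive
0/1/2 doses with $2pq$ denominators serve co-dominance and the collapsed
two-state form serves complete dominance; this is the only assignment
consistent with the per-genotype mean/SD tables that define the model
(class frequencies $p, q$ with moments $\mu, \sigma$ and
$\mu + \alpha, \sigma + \phi$), and it is what the package implements
throughout.

### Feasibility

The square root in $\sigma$ must dominate $k\,q^T\phi$. Large minor-allele
frequencies combined with large variance effects demand $\sigma < 0$ —
there is no baseline spread that realizes the requested budget. The solver
**fails fast** and reports the largest feasible variance effect at the
given frequency ($C_V^{max} = (1 - C_\mu)\,p/(p + kq)$ in the single-locus
case) rather than clamping $\sigma$ to zero, which would silently shrink
the realized $V_Y$. The same guard rejects sign configurations (see below)
in which some attainable dose vector yields $\sigma + g^T\phi \le 0$.

### Signs

The closed forms are square roots, so the effect sizes are sign-invariant;
the package takes the non-negative root by default and exposes per-locus
`sign_alpha` / `sign_phi` flags for effect direction. Whether a
*variance-decreasing* minor allele ($\phi < 0$) is meaningful is a modeling
choice we leave to the user: it is off by default and feasibility-checked
when enabled.

### Multiple loci and linkage

The multi-locus $\sigma$ assumes *uncorrelated* causal doses. When causal
loci are in linkage disequilibrium the realized variance deviates from
$V_Y$ — correlated spread shifts reinforce each other. No analytic
correction exists for the additive model, so the package does not pretend
to one: `run_simulation()` records the realized variance and the pairwise
causal-dose correlations in its metadata, and the LD experiment
(`experiment_ld_scenarios()`) exploits exactly this reinforcement to show
clustered 3% vQTLs producing far stronger Brown-Forsythe signal than an
isolated one.

### Allele frequencies: realized, not nominal

By default the solver is fed frequencies *estimated from the genotype
matrix* (`estimate_maf()`, folded to $\le 0.5$), so effect shares refer to
the population actually simulated; nominal frequencies can be forced with
`q_override`. With theoretical frequencies, sampling error in the realized
MAF shifts realized effect sizes slightly — documented, not corrected.

## Verifying planted signals

`analytic_decomposition()` recomputes $(V_M, V_V, V_R)$ from solved
parameters; the solver/decomposition round-trip is exact to numerical
precision and is property-tested on a grid of effect sizes and
frequencies.

`empirical_decomposition()` is the *moment-based estimator* used as the
ground-truth oracle: per-dose-group sample means and standard deviations
are regressed on dose (size-weighted least squares, reducing to plain
group differences for two groups), giving $\hat\alpha$, $\hat\phi$ and the
baseline intercept $\hat\sigma$, which are plugged into the component
formulas with the realized frequency. Two known small biases: (i)
$E[\hat\alpha^2] = \alpha^2 + Var(\hat\alpha)$ inflates recovered shares
by $O(1/n)$; (ii) with several variance loci, each locus's group SDs
include the *other* loci's spread contributions inside a root-mean-square,
deflating $\hat\phi$ slightly (about 3–6% relative at the reference
configurations). Both are properties of the estimator, not the simulator,
and both are well inside the ±1 percentage-point tolerance the acceptance
checks use.

## The detectors

* **Linear association** — ordinary least squares of trait on dose,
  t test on $n-2$ df (the model behind PLINK's quantitative `assoc`).
  Implemented in closed form for scan speed; agrees with `lm()` to
  $10^{-10}$ in tests. Blind to pure variance effects by construction.
* **Brown-Forsythe** — absolute deviations from the per-group *median*,
  then a one-way ANOVA F statistic on $(k-1, n-k)$ df. We use the standard
  F reference distribution (asymptotically equivalent to a scaled
  chi-square at GWAS sample sizes); the statistic matches
  `car::leveneTest(center = median)` to $10^{-10}$ in tests. Median
  centering makes it blind to pure mean shifts. Grouping follows the dose
  coding: 2 groups for haploid or collapsed-dominant, up to 3 for
  co-dominant doses.
* **DGLM** — alternating estimation: weighted least squares of $y$ on dose
  with weights $1/\hat\sigma_i^2$, then a gamma GLM with log link of
  leverage-deflated squared residuals $d_i = r_i^2/(1-h_i)$ on dose with
  prior weights $(1-h_i)/2$, iterated until the relative change in the
  heteroscedastic-normal log-likelihood falls below `tol` (default
  $10^{-8}$, `max_iter` 100; non-convergence is reported with the last
  iterate, never silently). Wald tests: the mean coefficient against its
  WLS standard error; the dispersion coefficient with the gamma dispersion
  fixed at 2, since squared normal residuals are $\sigma^2\chi^2_1$. How
  published DGLM analyses combine the two signals is not standardized, so
  the package reports all three p-values — mean, dispersion, and a 2-df
  likelihood-ratio test against the homoscedastic no-effect null — and the
  joint LRT is what the benchmark experiments use for "combined"
  detection. All three detectors are type-I calibrated by simulation (1000
  null replicates at $\alpha = 0.05$, binomial tolerance) in the test
  suite.

`scan_associations()` applies detectors locus-by-locus, never aborts on a
degenerate locus (monomorphic or near-empty groups become flagged `NA`
rows), and emits a tidy table with $-\log_{10} p$ ready for Manhattan
plots. Raw p-values are reported; no genome-wide threshold is imposed.

## Synthetic genotypes: what they emulate, and what not

`generate_hwe()` draws doses Binomial(ploidy, MAF) independently per locus
— the Hardy-Weinberg ideal. `generate_ld_blocks()` adds block-structured
LD by haplotype copying: within a block each locus copies the previous
locus's allele with probability $\sqrt{r^2_{target}}$, else draws fresh,
giving adjacent-locus dose correlation $\approx \sqrt{r^2_{target}}$
(squared correlation $\approx r^2_{target}$) decaying geometrically with
distance; blocks are mutually independent; diploids sum two independent
haplotypes. Positions are placed uniformly over a 25 Mb segment by
default. This reproduces *qualitative* low-LD vs high-LD regimes — which
is all the LD experiments require — but not coalescent genealogy:
no demography, no recombination-rate map, no allele-frequency spectrum
from mutation-drift balance, no population structure. Conclusions that
depend on those features need genotypes from a population simulator
(read them in with `read_ms()`) or real data (`read_vcf()`). A
consequence for interpreting the test suite: passing recovery tests on
HWE genotypes shows the phenotype model and detectors behave as designed,
not that the detectors are robust to realistic LD, structure or
frequency spectra.

Causal-locus search (`select_loci()`) matches a MAF window and optional
minimum spacing; when several loci qualify, the tie-break is a *uniform
random draw under the run seed* rather than "first match", so repeated
experiments sample different architectures; `explicit_ids` pins loci when
that is not wanted. Over-constrained criteria are an error reporting the
eligible count — bounds are never silently relaxed.

## Numerical and degenerate-input choices

* All stochastic entry points take a required integer `seed` and are
  bit-reproducible (`withr::with_seed`; the caller's RNG state is never
  touched). Every simulation records its seed, solved parameters and
  realized frequencies in a metadata sidecar sufficient to replay it.
* Monomorphic loci are retained in genotype matrices but excluded from
  causal eligibility and flagged in scans (undefined frequency / zero
  variance).
* `empirical_decomposition()` requires $\ge 2$ samples per genotype group
  and errors otherwise; a constant phenotype vector returns an all-zero
  decomposition.
* Missing VCF genotypes: per-locus mean-dose imputation with a reported
  count (option: drop samples). ms positions tied at printed precision are
  nudged by $10^{-9}$ to keep coordinates strictly increasing.
* The dispersion-submodel responses are floored at `1e-300` and fitted
  variances at `1e-12` to keep the gamma GLM defined when a residual is
  numerically zero.

## Reference experiment scales

The packaged experiments default to reduced scales chosen so the complete
suite runs in minutes on one CPU while keeping every qualitative contrast
detectable: 2,000 samples and 5,000 loci per chromosome for the
signal-recovery experiment, 400-locus segments for the LD scenarios, 50
replicates for effect-share recovery, 1,000 replicates for type-I
calibration. Genome-scale runs (tens of thousands of SNPs, $n = 10^4$) use
the same code paths via the scale arguments.

## Known limitations

* No epistasis or any non-additive multi-locus effect; no case/control
  thresholding; no covariates or population-structure correction in the
  detectors (use dedicated mixed-model tooling for that).
* The effect-size calibration is exact under HWE and causal-locus
  independence; under LD between causal loci the realized $V_Y$ drifts by
  design (reported, not corrected).
* The DGLM is the basic two-submodel form; published extensions (random
  effects for population structure, covariate-adjusted dispersion) are out
  of scope.
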
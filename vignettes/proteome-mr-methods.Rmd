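---
title: "Methods: proteome-wide MR and colocalization with protmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR and colocalization with protmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmr)
```

# The problem

Circulating proteins are a natural reservoir of drug targets: they are
measurable at scale, and genetic variants that shift a protein's plasma
level (protein quantitative trait loci, pQTLs) can act as natural
randomized interventions on that protein. `protmr` implements a
proteome-wide two-sample Mendelian randomization (MR) scan of protein
exposures against disease outcomes, followed by Bayesian colocalization
of candidate signals and annotation of prioritized proteins against
druggable-genome tiers and therapeutic-target development phases. Every
stage consumes only GWAS summary statistics, so the pipeline can be
exercised end-to-end on simulated data with known ground truth.

# Model and estimators

For variant $j$, let $\hat\beta_{Xj}$ (s.e. $\sigma_{Xj}$) be its
association with the protein and $\hat\beta_{Yj}$ (s.e. $\sigma_{Yj}$)
its association with the outcome, harmonized to a common effect allele.
Under the instrumental-variable assumptions the causal effect $\theta$
of the protein on the outcome satisfies
$\beta_{Yj} = \theta\,\beta_{Xj}$ for every valid instrument.

* **Wald ratio** (single instrument):
  $\hat\theta = \hat\beta_Y/\hat\beta_X$. The first-order delta-method
  standard error is $\sigma_Y/|\hat\beta_X|$; the second-order form adds
  the exposure-noise term
  $\sqrt{\sigma_Y^2/\hat\beta_X^2 + \hat\beta_Y^2\sigma_X^2/\hat\beta_X^4}$.
* **IVW**: the inverse-variance-weighted mean of per-variant ratios with
  weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, algebraically the
  weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the
  origin. The default multiplicative random-effects standard error
  scales the fixed-effect one by $\max(1, \sqrt{Q/(n-1)})$.
* **Cochran's Q** about the IVW estimate tests instrument
  heterogeneity; **MR-Egger** refits the regression with a free
  intercept (after orienting all $\hat\beta_X \ge 0$) whose distance
  from zero estimates directional pleiotropy.

Colocalization uses Wakefield's approximate Bayes factor per variant,
$\log\mathrm{ABF} = \tfrac12\log(1-r) + z^2 r/2$ with
$r = w/(w+\sigma^2)$ for prior effect variance $w$, and enumerates the
five single-causal-variant hypotheses H0–H4. All accumulation is done in
log space with log-sum-exp; the H3 term, a difference of sums, is
clamped at zero if floating-point cancellation drives it negative.

# Thresholds and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_iv` | 1e-5 | instrument association p-value (strict `<`) |
| `maf` | 0.01 | minor-allele frequency; MAF <= 0.01 removed |
| `cis_bp` | 1e6 | cis window around the gene footprint, inclusive |
| `r2`, `window_kb` | 0.001, 10000 | greedy LD-clumping cutoffs |
| `fmin` | 10 | minimum instrument F statistic, $(\beta/\sigma)^2$ |
| `candidate_p` | 5e-4 | MR p gating colocalization |
| `p1`, `p2`, `p12` | 1e-4, 1e-4, 1e-5 | coloc per-variant priors |
| prior sd | 0.15 / 0.2 | ABF effect prior, quantitative / binary |
| PH4 calls | > 0.75 strong; 0.5–0.75 medium | colocalization evidence |

The Bonferroni boundary of the top significance tier is
$0.05/n_{\text{proteins tested}}$, recomputed per run; at the
full-scale design size of 3,083 proteins it is $1.62\times10^{-5}$.
Tier boundaries are half-open as printed
(`****`, `***`, `**`, `*`, `ns`).

Boundary conventions the sources leave implicit, fixed here once:
the p-value filter is strictly `<`; MAF exactly 0.01 is removed; the
cis window is measured from the gene body's start/end with inclusive
boundaries; clumping ties on p (which arise when p underflows at
extreme z) are broken by larger $|z|$, then smaller position, making
output independent of row order.

# Harmonization

Outcome records are oriented to the exposure's effect allele: matching
pairs are kept, swapped pairs sign-flip the outcome beta and complement
its frequency, and irreconcilable pairs are dropped. Palindromic (A/T,
C/G) variants carry no strand information in their labels, so allele
frequency decides: if either trait's frequency falls inside the open
window (0.42, 0.58) the variant is dropped as unresolvable, otherwise
the orientation placing both frequencies on the same side of 0.5 is
chosen. The window is a declared default, configurable; no proxy-variant
search is attempted for variants absent from the outcome GWAS.

# What the simulator emulates

`simulate_pair()` builds one cis region: `n_snps` variants with AR(1)
linkage disequilibrium $r_{ij} = \rho^{|i-j|}$ (positive definite by
construction; $\rho$ gives one-knob control of clumping difficulty), a
single causal variant per associated trait, and sampling noise. Marginal
effects are propagated from the sparse causal effects on the
noncentrality scale, $E[z] = R\,z_{\text{causal}}$ — the per-allele-scale
marginal model. This keeps the causal variant the strongest expected
signal whatever its neighbours' allele frequencies, and makes the Wald
ratio equal $\theta$ at every variant of the region, since the
standard-error scale factors cancel between the two traits. Observed
betas add multivariate normal noise with covariance
$D R D$, $D = \mathrm{diag}(\text{se})$, the sampling distribution of
marginal estimates from a single cohort; standard errors follow
$1/\sqrt{2 n f (1-f)}$ for a standardized trait and the
case-fraction-inflated analogue $1/\sqrt{2 n \phi(1-\phi) f(1-f)}$ on
the log-odds scale for binary outcomes.

Scenarios follow the five colocalization hypotheses. Under H4 the
outcome's effect at the shared variant is
$\theta\,\beta_c + \beta_{\text{pleio}}$. The configuration type carries
no separate outcome-side effect size, so under H2/H3 the outcome's own
causal variant is given an effect of magnitude $\theta\,\beta_c$,
keeping both signals comparably powered; the realized protein-on-outcome
effect recorded in the ground truth is zero outside H4.

Defaults are the study conditions used throughout the tests: 50 variants,
$\rho = 0.9$, $n = 50{,}000$ for both traits, causal $\beta_c = 0.3$ SD
per allele (pQTL effect sizes are not catalogued by the sources; 0.1–0.5
SD is the plausible range and 0.3 is fixed once as the default), MAF
uniform on (0.05, 0.5), 10% palindromic variants, $\theta = 0.3$. What
the simulator does **not** emulate: realistic human LD maps (only AR(1)
and block concatenations), sample overlap between exposure and outcome
cohorts (assumed zero, as in two-sample MR), imputation error, allele
frequency differences between cohorts, and multi-signal regions. Passing
calibration tests on these data therefore demonstrates correctness of the
estimators and plumbing, not robustness to those real-data features.

# Numerical and design choices

* **Delta-method order.** The pipeline's single-instrument path defaults
  to the second-order Wald standard error
  (`run_config(wald_second_order = TRUE)`). With one strong cis
  instrument the first-order form ignores exposure-side noise and its
  95% intervals cover ~0.94 rather than 0.95 under the default
  conditions when $\theta \neq 0$; the second-order form restores
  nominal coverage. `wald_ratio()` itself keeps the conventional
  first-order default for comparability with other two-sample MR
  software.
* **P-value underflow.** Two-sided normal p-values underflow to 0 for
  $|z| \gtrsim 38.5$. The simulator floors them at the smallest positive
  double, and the validator clamps (rather than rejects) exact zeros:
  discarding the strongest associations as "invalid" would silently
  remove the causal variant.
* **F statistic.** Per-variant $F = (\beta/\sigma)^2$; the
  variance-explained form is available via `compute_f_stat(method =
  "r2")`.
* **Coloc region.** The colocalization region is the same cis window
  used for instrument selection; the single-causal-variant assumption is
  retained (multi-signal conditioning is out of scope, and tends to make
  the reported PH4 conservative in multi-signal regions).
* **Degenerate inputs.** Empty filter results are legal (flagged, not
  errors); zero overlapping variants in harmonization or coloc is a hard
  error; Egger with fewer than 3 instruments is flagged not-computed.
* **Determinism.** `simulate_study()` derives per-protein seeds from one
  master seed; `run_scan()` is a pure function of its inputs, so reruns
  are byte-identical and protein processing order cannot affect content.

# Problem sizes used in the test suite

Calibration checks run at the scale a laptop handles in seconds to
minutes: 500 replicates for effect recovery and coverage, 1,000 for the
type-I error of the IVW test, 200 per colocalization scenario, 300 for
Egger pleiotropy recovery, and brute-force oracle comparisons on regions
of at most 20 variants (coloc) or 8 variants (clumping). The full-scale
design constants (3,083 proteins = 2,112 + 1,970 − 999 across the two
panels; 33 outcomes; the druggability tier counts 9/8/18/16 and the
26 development-phase annotations) are recomputed from the bundled
fixture tables rather than re-derived from raw consortium data, which is
out of scope.

# Known limitations

Single causal variant per region and per trait; no trans-pQTL
instruments, Steiger filtering, proxy lookup, weighted-median/mode
estimators, or cross-source meta-analysis (the two exposure panels are
analyzed side by side and never pooled — no pooling formula is published
for the design this package emulates). Annotation relies on bundled
transcriptions of the published druggability and outcome tables, not on
live database queries.
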
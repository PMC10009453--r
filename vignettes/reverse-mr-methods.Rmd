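---
title: "Models and methods in revmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in revmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revmr)
```

## The reverse-MR model

Two-sample Mendelian randomization estimates the effect of an exposure on
an outcome from GWAS summary statistics alone. In the *reverse* framing,
the exposure is genetic liability to a binary disease — a latent
continuous propensity instrumented by the disease's associated variants —
and the outcomes are quantitative biomarkers, typically a correlated
panel of NMR metabolic traits. Associations may reflect causes of the
disease, consequences of the developing disease process, or correlates of
liability; all are informative about the disease's metabolic signature.

For variant $j$, let $\gamma_j$ (SE $\sigma_{\gamma j}$) be its effect on
liability (log-odds per allele) and $\Gamma_j$ (SE $\sigma_{\Gamma j}$)
its effect on the outcome trait (SD units per allele). The working model
is

$$\Gamma_j = \theta\,\gamma_j + \alpha_j + \varepsilon_j,$$

where $\theta$ is the causal effect of liability on the trait and
$\alpha_j$ is horizontal pleiotropy (a path from variant to outcome not
through liability). The instrumental-variable assumptions are relevance
($\gamma_j \ne 0$, checked by the mean F-statistic), independence, and
exclusion ($\alpha_j = 0$); the sensitivity estimators progressively
relax the third.

Estimates for a binary-disease exposure are multiplied by
$\ln 2 \approx 0.693$ so they read as the SD-unit difference in the
outcome per *doubling* of genetic liability; this is a pure rescaling and
leaves z-statistics and p-values unchanged.

## Estimators

With weights $w_j = 1/\sigma_{\Gamma j}^2$:

* **IVW** is the zero-intercept weighted regression
  $\hat\theta = \sum w_j\gamma_j\Gamma_j / \sum w_j\gamma_j^2$,
  algebraically the inverse-variance-weighted mean of the per-variant
  Wald ratios $\Gamma_j/\gamma_j$ with first-order weights
  $\gamma_j^2/\sigma_{\Gamma j}^2$. Heterogeneity is Cochran's
  $Q = \sum w_j(\Gamma_j - \hat\theta\gamma_j)^2$, referred to
  $\chi^2_{J-1}$. The default variance model is multiplicative random
  effects: the fixed-effect SE is inflated by
  $\max\{1, \sqrt{Q/(J-2)}\}$, so overdispersed instrument sets get
  honestly wider intervals while the fixed-effect SE is never deflated.
  A fixed-effect variant is available by flag.
* **MR-Egger** adds an intercept to the weighted regression after
  orienting all exposure effects positive. The slope estimates $\theta$
  allowing *all* variants to be pleiotropic, under the InSIDE assumption
  that pleiotropy is independent of instrument strength; the intercept
  estimates average directional pleiotropy and its p-value is the
  standard pleiotropy test. SEs are inflated by
  $\max\{1, \sqrt{Q_E/(J-2)}\}$ with $Q_E$ Rücker's Q about the Egger
  fit ($\chi^2_{J-2}$).
* The **weighted median** orders the Wald ratios and interpolates the
  cumulative normalized weights $s_j = \sum_{k\le j} w_k' - w_j'/2$ at
  $s = 0.5$. It is consistent while valid instruments carry more than
  half the weight, and is the estimator least moved by single outliers.
  Its SE is the SD of the estimate over parametric-bootstrap resamples
  of $(\gamma_j, \Gamma_j)$ from their normal sampling distributions
  (default 1000 resamples; the seed is a required argument so results
  are reproducible).
* The **weighted mode** is the argmax of a weighted normal-kernel
  density of the Wald ratios, consistent when the largest homogeneous
  cluster of instruments is valid. The bandwidth is
  $\varphi \times 0.9\,\min(\mathrm{sd},\mathrm{mad})\,J^{-1/5}$
  computed on the ratio distribution ($\varphi = 1$ by default; the
  median-absolute-deviation term keeps the plug-in robust to outlying
  ratios, and the sd term takes over in the degenerate case
  $\mathrm{mad} = 0$). The density is evaluated on a 512-point grid
  spanning the ratios plus three bandwidths; exact argmax ties are
  broken toward the grid midpoint; identical ratios short-circuit to
  that common value.

Wald-ratio SEs are first order ($\sigma_{\Gamma j}/|\gamma_j|$),
ignoring exposure-side uncertainty — the convention of standard
two-sample MR tooling and a documented limitation: with mean F around
100–200 the induced attenuation of $\hat\theta$ is a fraction of a
percent, but it grows as $1/F$ and matters for weak instruments.
P-values are two-sided normal throughout (not t-based) so the five
estimates are comparable.

## Outlier screening and multivariable MR

**Radial MR** rewrites the IVW fit so each variant's contribution to Q
is explicit: $Q_j = w_j^{(r)}(\beta_j - \hat\beta)^2$ with radial weights
$w_j^{(r)} = \gamma_j^2/\sigma_{\Gamma j}^2$ and Wald ratios $\beta_j$.
A variant is flagged when the upper-tail $\chi^2_1$ probability of its
$Q_j$ falls below a threshold (default 0.05, uncorrected; a Bonferroni
mode is available), and the model is re-estimated once with all flagged
variants removed. Screening is a single pass by design — the flagging
threshold is a screening rule, not a test with guaranteed error rates;
an iterative mode exists behind a flag. Because the first-pass slope is
fitted with the outliers still included, their weight share leaks into
every residual: with planted outliers carrying a few percent of the
radial weight the false-flag rate runs about one point above nominal,
which is visible in the package's own simulations and inherent to
single-pass screening.

**Multivariable MR** estimates direct effects of two (or more)
liabilities whose instruments overlap — as for two cardiometabolic
diseases sharing risk loci — by the zero-intercept weighted regression
of $\Gamma_j$ on $(\gamma_{1j}, \gamma_{2j})$ over the union of both
instrument sets. Each coefficient is the effect of one liability holding
the other fixed; univariable estimates are biased toward the other
liability's effect by the instrument-effect overlap (for
$\gamma_{2j} = \lambda\gamma_{1j} + e_j$, the univariable slope on
exposure 1 converges to $\theta_1 + \lambda\theta_2$). The design is
guarded by an eigenvalue condition-number check (collinear exposure
columns are an error, not a silent near-singular solve). Per-exposure
*marginal* mean F is reported; conditional instrument-strength
diagnostics are out of scope since no pleiotropy-robust sensitivity
models are attached to the MVMR fit.

## Panels, strata, multiplicity

`run_panel()` repeats harmonisation and estimation over a list of
outcome traits; one trait's failure is recorded without aborting the
rest, and there is no cross-outcome state, so cost is linear in trait
count.

Age-stratified analyses contrast per-stratum estimates with the
two-sample z-test $z = (\beta_a - \beta_b)/\sqrt{se_a^2 + se_b^2}$.
This assumes the strata are estimated in non-overlapping samples — true
by construction for disjoint age tertiles of one cohort, and stated as
an assumption for any other use. The formal contrast is an addition
over simply reporting per-stratum estimates side by side and is
labelled as such in pipeline output.

For a panel of correlated traits, Bonferroni over the raw trait count is
too strict. The effective number of tests is the smallest number of
principal components of the trait correlation matrix whose eigenvalues
sum to at least 95% of the trait count; the threshold is
$\alpha$ divided by that number, reported both exactly and rounded to
one significant figure (0.05 over 33 components gives 0.0015…,
reported as 0.002). The component count can also be fixed directly in
configuration when it comes from external literature rather than from a
matrix at hand.

The cross-disease profile comparison regresses one liability's
per-trait estimates on the other's by OLS *with* intercept (the
with/without choice was open; with an intercept the slope is invariant
to a location shift of either profile, and on near-centred effect panels
the slope is essentially unchanged either way) and reports slope and
$R^2$; a flat, low-$R^2$ profile pair indicates distinct metabolic
signatures.

## The synthetic-data generator

`sim_config()` fixes the full generative law; all defaults were chosen
once, as the package's study conditions, and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| instruments $J$ | 150 | scale of a large disease GWAS instrument set after pruning (order 150–170) |
| $\theta$ | 0.3 | moderate liability effect in SD units per unit log-odds |
| $\gamma_j$ | $N(0.08, 0.03^2)$ | per-allele log-odds effects of genome-wide-significant loci |
| exposure sizes | 20,000 / 200,000 | case/control scale giving unambiguously strong instruments (mean F ≈ 200) at desk-scale cost |
| outcome $N$ | 118,466 | the N of the motivating NMR metabolomics GWAS |
| maf | $U(0.05, 0.5)$ | common variants, as instrument sets are |
| pleiotropy $\alpha_j$ | none; directional: $N(0.02, 0.01^2)$ on 30% of variants | the robustness scenarios' law |
| planted outliers | offset 10 $\sigma_{\Gamma j}$ | unambiguous contaminants for screening checks |
| panel | 20 traits, exchangeable r = 0.3 | stands in for a 249-trait NMR panel at test scale |
| strata prevalences | 0.05 / 0.17 / 0.29 | statin-use prevalence in age tertiles of the motivating cohort |
| medication modifier | −0.9 | reverses a modest positive $\theta$ in the oldest stratum, emulating medication mediation |

Standard errors use the conventional summary-statistics approximations
$\sigma_{\gamma j} = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n_\mathrm{eff}}$
with $n_\mathrm{eff} = 4/(1/\mathrm{cases} + 1/\mathrm{controls})$ for
the binary exposure, and the analogous unit-variance form for continuous
outcomes. Observed effects are the true effects plus normal noise at
those SEs. Medication mediation is modelled as the simplest mechanism
that reproduces an age-dependent distortion: the effective effect in
stratum $s$ is $\theta_s = \theta + m \cdot p_s$ with $p_s$ the
stratum's medication prevalence — an additive shift proportional to how
often a $\theta$-opposing treatment is taken. Alternatives (multiplicative
attenuation, per-individual mediation) would need individual-level
structure the summary-statistic generator deliberately avoids.

Harmonisation stressors (palindromic variants at frequency 0.5,
strand-complemented and allele-swapped emissions) default to zero and
are switched on in dedicated scenarios; palindromic frequency 0.5 is
the worst case, in which every palindrome is uninformative and must be
dropped. Each component (exposure, second exposure, outcome noise,
pleiotropy, panel noise, per-stratum noise) draws from its own RNG
stream derived from the master seed, so enabling one component never
perturbs another and identical configurations are byte-identical on
disk.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: LD-consistent effect correlation
(the block LD matrix only exercises pruning logic), sample-overlap
correlation between exposure and outcome errors, winner's-curse
distortion of selected instruments (instruments are strong enough that
selection barely truncates), non-normal effect distributions, and
assay- or pipeline-specific artefacts of real NMR GWAS.

## Numerical and design choices

* Strict inequalities for instrument selection (p < threshold) and
  pruning (discard at r² > threshold, keep at equality); p-value ties in
  clumping broken by lexicographic rsid for determinism.
* Palindrome frequency band: a palindromic variant is kept only when
  both allele frequencies are outside [0.42, 0.58] and on the same side
  of 0.5 (0.42 is the convention of the standard harmonisation routine;
  configurable). Palindromes with a missing frequency are dropped —
  frequency is the only disambiguator.
* Positive-exposure orientation is applied *inside* MR-Egger only; the
  other estimators are orientation-invariant and see the native
  harmonised orientation.
* The IVW overdispersion divisor J−2 (shared with Egger) follows the
  package's stated convention; Q degrees of freedom are J−1 (IVW) and
  J−2 (Egger).
* Degenerate inputs: an exposure effect of exactly zero is a
  degenerate-instrument error for Wald ratios; fewer than 2 (IVW) or 3
  (Egger/median/mode/radial) kept variants is an
  insufficient-instruments error; every harmonisation exclusion is a
  recorded disposition, never an error.
* Simulation sizes used by the test-suite and acceptance script (chosen
  as the package's validation conditions): 2000 replicates for coverage,
  300 for the directional-pleiotropy regime, 200 each for the
  weighted-median regimes and radial screening, 500 for MVMR
  separation. Recovery checks compare the replicate mean against truth
  within twice the replicate SD — the Monte-Carlo estimate of the
  estimator's sampling SD.

## Known limitations

First-order Wald weights (no NOME correction, no exposure-uncertainty
term); no proxy-variant lookup for outcome-missing instruments; single
ancestry and genome build assumed (no liftover); no MR-PRESSO /
contamination-mixture / Steiger-filtering estimators; MVMR without
pleiotropy-robust sensitivity models; indels and multi-allelic variants
out of scope.
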
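---
title: "Functional-response analysis for community-module experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-response analysis for community-module experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frmodule)
```

## The scientific problem

Comparative functional responses — the relationship between prey density
and the number of prey a predator kills per unit time — are used in
invasion ecology to compare the per-capita impact of an invasive predator
against its native analogue. `frmodule` implements this comparison for
*community-module* experiments, where the focal predator–prey pair sits
inside a small web of interacting species: a native or invasive amphipod
predator (*Gammarus duebeni celticus* vs. *G. pulex*), its acanthocephalan
or microsporidian parasites, a higher-order fish predator contributing
only visual and olfactory cues, and one of three invertebrate prey species
(*Asellus aquaticus*, *Simulium* spp., *Baetis rhodani*). The design is a
2 (predator) × 2 (parasitism) × 2 (fish) × 7 (density) factorial with four
replicates per cell: 224 trials per prey species.

## The model

Trials run for a fixed duration with no prey replacement, so the fitted
model must account for prey depletion. The package uses the Rogers
random-predator equation for a Type II response,

$$N_e = N_0 \left\{ 1 - \exp\!\big(a (N_e h - T)\big) \right\},$$

where $N_e$ is the number of prey eaten, $N_0$ the initial density, $T$
the trial duration, $a$ the attack rate and $h$ the handling time. The
implicit equation is solved explicitly on the principal branch of the
Lambert $W$ function:

$$N_e = N_0 - \frac{W_0\!\big(a h N_0\, e^{-a (T - h N_0)}\big)}{a h}.$$

`lambert_w0()` is a vectorized Halley iteration with branch-point series
and large-argument asymptotic starts, accurate to $10^{-10}$ relative
error on its defining identity; arguments too large for `exp()` are
handled in log space so deep handling-limited regimes do not overflow.

Two alternatives share the same depletion structure so that all variants
can be compared within one likelihood: a **Type I** (linear) response
defined as the $h = 0$ limit, $N_e = N_0(1 - e^{-aT})$ — we use this
depletion-consistent form rather than Holling's rectilinear model because
a non-replacement design makes a strictly linear-in-$N_0$ response
internally inconsistent — and a **Type III** response in which the attack
rate is density dependent, $a(N_0) = b N_0 / (1 + c N_0)$. The Type III
parameterisation is a design choice of this package (a saturating Hassell
form; with $c = 0$ it reduces to the two-parameter version); fixing the
functional form keeps the AIC comparison across variants well defined.

### Time units

$T$ is expressed in experiment-duration units: the 40-hour trial maps to
$T = 1$ by default, and $a$ (per duration unit) and $h$ (duration units
per prey) scale accordingly. Any other unit can be used, as all three
quantities rescale together.

## Treatment coding

Treatment effects enter through indicator variables. For the comparison
across prey modules, for example,

$$a = a_I + a_B B_i + a_S S_i, \qquad h = h_I + h_B B_i + h_S S_i,$$

with $B_i, S_i \in \{0, 1\}$ indicating *B. rhodani* and *Simulium*
trials; the base (intercept) level is *A. aquaticus*. Within a prey
module the same device codes predator species, parasitism and fish
presence, extended to interactions whose indicators are products of the
main-effect indicators. `build_indicator_rows()` constructs these design
matrices with deterministic column order; the base cell is always the
all-zero row.

The likelihood is binomial around the Rogers prediction:
$N_e \sim \mathrm{Binomial}(N_0,\ \hat N_e / N_0)$. The likelihood family
is a declared design choice — binomial is the standard choice for
depletion designs with a fixed number of prey at risk, and it matches the
proportion-based phenomenological test. Parameters are optimised on the
natural scale so treatment effects can be negative (handling-time
reductions are the scientifically central quantity); any parameter vector
implying $a \le 0$ or $h < 0$ in an observed cell receives an infinite
penalty instead of being transformed away, which keeps estimates and
standard errors directly interpretable on the reported scale.

`fit_fr()` runs a Nelder–Mead pass refined by BFGS from five jittered
starts (attack rate initialised from a disc-equation linearisation on the
lower densities, handling time from $1/\max N_e$, effects from zero,
intercepts jittered ±50%). Standard errors come from the inverse
finite-difference observed Hessian (central differences, step
$10^{-5}\max(|\theta|, 1)$); a singular Hessian returns estimates with
SEs flagged unavailable rather than failing. Wald $z = \hat\theta /
\mathrm{SE}$ and two-sided normal $p$-values mirror standard regression
output; no multiple-testing adjustment is applied. Custom contrasts use
the delta method on the estimated covariance.

## Workflow

`run_analysis()` executes the stages in the order an analyst would:

1. **Control QC** — prey survival without amphipods must exceed 96.5%
   overall (`control_survival_qc()`), so treatment mortality is
   attributable to predation.
2. **Replicate exclusion** — trials where the amphipod moulted, or where
   dissection found early-stage acanthella or multiple cystacanths, are
   excluded (`filter_replicates()`); a parasite-status mismatch between
   assignment and dissection is excluded by default but configurable,
   since the protocol for that case is genuinely ambiguous.
3. **Day-bias diagnostic** — Spearman rank correlation of kills against
   experiment start day within each module, exact permutation p-value for
   $n \le 8$.
4. **Response-type test** — per community module, a binomial GLM of
   proportion killed on a raw quadratic in density. A significant
   negative first-order term indicates Type II; significant positive
   first-order followed by significant negative second-order indicates
   Type III; anything else is inconclusive and falls through to AIC
   comparison of Type I/II/III no-treatment fits. Density is entered
   untransformed because the sign rules refer to raw-density
   coefficients; the quadratic degree is fixed at 2 (the degree the rules
   use) but exposed for sensitivity work.
5. **Mechanistic fits** — one between-module model (prey coding on both
   $a$ and $h$), then one model per prey module with a *simplified*
   attack rate (intercept only) and fully treatment-coded handling time
   — four fits in total. The simplified attack rate reflects the
   observation that within-module variation is carried by handling time.
6. **Bootstrap envelopes** — nonparametric case bootstrap (n = 1500 by
   default): whole pots resampled with replacement, stratified by
   treatment × density cell so each resample preserves the factorial
   design; failed refits are dropped, counted, and flagged above 20%.
   Equi-tailed 2.5/97.5% quantiles of the predicted curve per density
   give the envelope. Case (not residual) resampling and stratification
   are declared choices: resampling pots respects the trial as the unit
   of observation, and stratification avoids resamples that lose whole
   design cells. Strata are treatment cells, deliberately *not*
   treatment × density: resampling within strata of only four pots
   deflates the bootstrap variance by the per-stratum factor
   $(n_s - 1)/n_s = 0.75$, which caps envelope coverage near 91% no
   matter how large the dataset; cell-level strata keep the factorial
   design intact while making that deflation negligible, and measured
   coverage of the 95% envelope is then consistent with nominal.
7. **Partial consumption** — per-replicate proportion of killed prey only
   partially eaten (among replicates with ≥ 2 kills, matching the
   recording rule), tested against density, predator, parasitism and
   fish with tie-corrected Kruskal–Wallis tests; exact permutation
   p-values for N ≤ 10. Density is treated as a 7-level factor. We
   report df = k − 1 (6 for the 7-level density factor); summaries
   elsewhere that subscript H with the number of groups rather than its
   degrees of freedom differ from this convention by one.

```{r, eval = FALSE}
cfg <- fr_config(scenario = default_scenario(), seed = 1, out_dir = "out")
run <- run_analysis(cfg)
print(run)
```

## The synthetic-data generator

Raw trial data for this kind of experiment are rarely deposited, so the
generator is a first-class module: every downstream stage is exercised on
data with the statistical structure the analysis assumes.
`default_scenario()` encodes the study conditions: the full factorial per
prey species; Type II consumption whose handling time varies by treatment
(base values per prey — *A. aquaticus* $a = 0.981, h = 0.307$;
*Simulium* $a = 2.564, h = 0.162$; *B. rhodani* $a = 1.362, h = 0.063$ —
with the corresponding treatment-coded handling-time effects, and
intercept-only attack rates within modules); partial consumption whose
probability is logistic in density, calibrated so pooled proportions are
rare for *A. aquaticus* (~1%) and substantial for *Simulium* (~14%) and
*B. rhodani* (~24%), independent of the treatment factors; control
mortality of 1.5% per individual (survival ≈ 98.5%, above the 96.5% QC
threshold); and exclusion processes (moult probability 0.02 per
replicate; acanthella and multiple-cystacanth probabilities 0.08 each
among parasitised *G. pulex*, yielding roughly the handful of repeats per
prey species a real run reports).

Two observation models are provided, and the distinction matters for what
passing tests mean:

* **binomial** — kills are Binomial($N_0$, Rogers expectation / $N_0$):
  exactly the fitting likelihood. Parameter-recovery and coverage checks
  use this model so they measure the estimator, not model
  misspecification.
* **event** — a mechanistic alternating renewal process: exponential
  search times with total hazard $a \times$ (prey remaining), a fixed
  handling block $h$ after each kill (the classic disc-equation
  derivation), until time $T$ or extinction. Its kill distribution is
  deliberately *not* the likelihood's, and is used for robustness
  checks.

Real data will differ from both in ways the generator does not emulate:
overdispersion from between-animal variability, within-trial
nonstationarity (hunger, time of day), and any dependence of partial
consumption on treatment. Green tests therefore demonstrate correctness
of the machinery and calibration under the stated generative assumptions,
not robustness to every field complication.

Reproducibility: one root seed; each experimental unit draws from its
own substream whose seed is drawn once from the root-seeded stream and
assigned by unit index, so row order never changes draws and a seed
fixes the dataset byte-for-byte. The substream seeds are random rather
than arithmetically spaced on purpose: Mersenne-Twister streams seeded
at nearby integers carry weak cross-stream correlation, and even a mean
pairwise correlation of a few thousandths inflates the sampling variance
of estimators computed over hundreds of trials by tens of percent —
enough to wreck coverage checks. Randomly drawn seeds remove the
alignment that causes it.

## Numerical choices and degenerate inputs

* Lambert arguments within $10^{-12}$ below the branch point $-1/e$ are
  clamped; further below is a domain error.
* $a h < 10^{-12}$ routes to the $h = 0$ closed form (the Lambert
  expression is 0/0 there).
* Binomial probabilities are clamped to $[10^{-9}, 1 - 10^{-9}]$ inside
  the likelihood.
* All-prey-eaten (or none-eaten) datasets set a boundary flag and are
  reported non-converged rather than returning spurious SEs.
* Complete or quasi-separation in the type-test GLM (saturated linear
  predictors) is flagged non-converged, not fatal.
* All-tied Kruskal–Wallis inputs return $H = 0$, $p = 1$ (the tie
  correction is undefined there).
* Bootstrap refits warm-start from the point estimate with a single
  Nelder–Mead pass; this is what makes 1500 refits per module practical,
  and the non-convergence accounting stays honest (refits that hit the
  iteration cap are dropped and counted).

## Problem sizes used in the checks

The test-suite simulations use 200 datasets for parameter recovery (40
replicates per density), 200 for response-type classification (16
replicates per density), and 200 for bootstrap coverage with envelopes of
300 resamples; these sizes give Monte-Carlo standard errors small enough
to distinguish calibration failures from noise while keeping a full run
on one core comfortable.

## Known limitations

* Handling time is assumed constant in density; density-dependent
  handling (plausibly induced by partial consumption at high density)
  would bias the fitted asymptote, and modelling partial consumption
  inside the functional-response likelihood is out of scope.
* No random-effects structure: replicates are treated as independent,
  so between-animal heterogeneity inflates apparent binomial dispersion.
* The Type III form is one of several in use; conclusions about Type III
  classification are conditional on the chosen parameterisation.
* Bootstrap envelopes are percentile intervals; no bias correction or
  acceleration is applied.
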
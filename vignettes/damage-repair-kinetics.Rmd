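---
title: "Modelling DNA damage and repair kinetics from comet-assay time-courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA damage and repair kinetics from comet-assay time-courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometRepair)
```

## The problem

After a radiotherapy fraction, DNA strand breaks appear in tumour cells
within minutes and are removed over the following hours. The alkaline
comet assay measures this per cell: fragmented DNA migrates into a
"tail" whose fluorescence fraction (%DNA in tail) quantifies damage.
Serial fine-needle aspirates sampled shortly before a 6 Gy fraction and
at 15, 30, 60, 120 and 360 min after it yield a median %DNA-in-tail
time-course per patient and fraction; γH2AX immunohistochemistry
(nuclear foci marking double-strand-break sites) provides a parallel,
slower-decaying readout. `cometRepair` implements a compartmental
kinetic model for these time-courses, a solver and fitter for it,
descriptive statistics for both assays, and a synthetic per-cell data
generator so that every stage is testable without patient material.

## The kinetic model

Primary damage `n0` (single- and double-strand breaks are both visible
under alkaline conditions) is induced in proportion to the dose rate
$R(t)$ of a rectangular pulse:

$$\frac{dn_0}{dt} = k_\mathrm{cleav} R(t) - (k_{0,f} + k_{0,s})\, n_0 .$$

Damage is detected by one of two abstract repair pathways ("fast" and
"slow"; they deliberately are not identified with NHEJ or HR). Each
pathway processes detected damage with first-order kinetics delayed by
a lag $t_{r,p}$ that lumps the intermediate enzymatic steps:

$$\frac{dn_{1,p}}{dt} = k_{0,p} n_0 - k_{1,p}\, n_{1,p}(t - t_{r,p}),
\qquad
\frac{dn_{2,p}}{dt} = k_{1,p}\, n_{1,p}(t - t_{r,p}) - k_{2,p} n_{2,p}^2 ,$$

so the system is a set of delay differential equations (DDEs). Final
repair is second order because two fragment ends are rejoined. All five
compartments migrate in the tail, so the observable is their sum plus a
baseline $b_n$ that is co-estimated with the kinetic parameters. The
delayed transfer term appears identically in the outflow of $n_{1,p}$
and the inflow of $n_{2,p}$; this placement conserves mass exactly and
is the one design point the equations leave open (the alternative —
delaying only one side — would create or destroy damage during the
lag).

Two induction variants exist: the default `simple` law above, and an
`extended` law $k_\mathrm{cleav} R\,(\varepsilon + D)$ accounting for
two-hit fragment liberation and pre-existing breaks. With data at a
single dose rate the two are indistinguishable up to a rescaling of
$k_\mathrm{cleav}$, so `simple` is the default. No saturation of target
sites is modelled (tail fractions stay well below 100 %).

Units: $k_\mathrm{cleav}$ carries %DNA/Gy, $k_0$ and $k_1$ are 1/min,
$k_2$ is per-%DNA per min (a second-order constant), $t_r$ and $b_n$
are minutes and %DNA. Reference parameter tables that label every
constant "min⁻¹" are used verbatim as magnitudes in these working
units (`pooledSarcomaParameters()`).

The model is symmetric under exchange of the two pathway blocks
(`swapPathways()`), and the one-pathway reduction
(`reduceToOnePathway()`) pins the slow rates at zero.

## Numerics

`simulateDamage()` integrates the DDEs by the method of steps on a
fixed grid (default 0.05 min; RK4, with an explicit Euler mode kept as
a cross-check oracle). Delayed values are read from the stored
trajectory by linear interpolation, with a zero history before the
pulse onset at $t = 0$; with step ≪ delay the interpolation error is
far below the solver error. Fixed stepping was chosen over adaptive
control deliberately: delays of up to ~20 min with smooth dynamics make
a 0.01–0.05 min step cheap, and a fixed grid gives bit-reproducible
trajectories.

Two details matter:

* **Pulse quadrature.** The dose rate is discontinuous at the pulse
  edges. Each step therefore uses the analytic average of the
  rectangular pulse over the step interval instead of pointwise
  evaluations; the induction integral is then exact for any step size
  and the post-pulse total (with $k_2 = 0$) equals
  $k_\mathrm{cleav} \times \mathrm{dose}$ to round-off. The exported
  `doseRateAt()` keeps the pointwise half-open definition.
* **Negativity.** A DDE with a zero pre-pulse history can transiently
  overdraw $n_{1,p}$: the delayed outflow sees the compartment as it
  was $t_{r,p}$ minutes ago. The default `limit-outflow` policy caps
  the delayed outflow at the amount that would empty the compartment
  within one step and scales the matching inflow to $n_{2,p}$
  identically, so the correction is mass-preserving; activations are
  counted on the trajectory (`nClamped`). A `hard-clamp` policy
  (floor negatives after the step) is available for comparison.

The integrator is written in C++ (via Rcpp) because the fitter and its
brute-force oracle together need on the order of 10⁵ simulations; one
360 min trajectory at step 0.05 costs ~2 ms.

## Fitting

`errorOfFit()` is the unweighted sum of squared errors between the
model observable and the observed medians, with RMSE reported
alongside; published "error of fit" values for this model family do not
state their metric, so none of them is asserted anywhere in the
package. Observation times are minutes after pulse end; the
pre-treatment point is an observation at a negative time at which the
model predicts $b_n$ — no baseline subtraction is performed, consistent
with co-estimating $b_n$.

`evolutionaryFit()` is a (μ+λ) evolution strategy with Gaussian
mutation and elitism, followed by Nelder-Mead refinement (the "gradient
search" role). Rate constants are searched in log₁₀ space because
fitted values span several orders of magnitude; the delay and $b_n$
are searched linearly. Defaults: population 32, 200 generations,
mutation σ = 0.25 log-units (annealed by 0.995 per generation, floored
at 5 %), 4 elites, polish of the top 4 individuals. Default bounds:
rates 10⁻⁴–10³, delays 0–60 min, $b_n$ from 0 to the smallest observed
median. All draws come from one seeded generator; two runs with the
same seed are identical to the byte.

Nested-model comparisons use a warm start: the fitted one-pathway
optimum is injected into the two-pathway population and kept verbatim
as a final candidate. Because the two-pathway model with an exactly
zero slow block is structurally identical to the reduction, the
reported two-pathway error can never exceed the one-pathway error —
the comparison is a guarantee, not a hope.

`gridSearchFit()` is a deliberately naive full-factorial log-grid
evaluation of the one-pathway objective (8 points per axis by default);
it exists as an independent optimality oracle for the evolutionary
search, not as a fitter.

### Identifiability

With six observed medians and six free parameters the fit is close to
an interpolation problem, and two structural trade-offs dominate:
the observable depends on the detection and processing rates mainly
through their convolution, so $k_0$ and $k_1$ can nearly exchange roles
("flip-flop", familiar from pharmacokinetics); and a discrete delay
$t_r$ trades against the first-order lag $1/k_1$, leaving mostly the
total transit time identified. At 10 % multiplicative noise the global
SSE optimum is typically *not* in the truth basin — the fitted curve is
excellent while individual parameters (especially $t_r$ and the
unsorted $k_1$) can be far off. Sorting the two chain rates resolves
the flip-flop and recovers the processing rate and the second-order
constant to within a factor of ~2; the delay remains weakly identified
at this design. The test suite and the acceptance script report these
recovery errors honestly rather than asserting precision that the
design cannot deliver; denser sampling (especially between 120 and
360 min) or multi-dose-rate data would be required to pin the delay.

For the same reason the noise-free self-consistency check is stated as
a warm-start contract (a fit seeded with the generating parameters
returns them with zero error) plus a fit-quality bound for random
starts, not as exact parameter recovery by global search: the SSE
landscape contains broad spurious basins that random-start searches
enter far more often than the narrow global one.

## Assay statistics

`summarizeComet()` reduces per-cell records to per-group medians, IQRs
(linear-interpolation quartiles, `stats::quantile` type 7 — Tukey
hinges would differ on small samples) and 95 % percentile-bootstrap
CIs of the median (2000 resamples, seeded). The bootstrap and the
permutation test sort each sample before resampling so that summaries
are invariant to record order. `differencesFromBaseline()` reports the
difference of medians against the pre-treatment group with a bootstrap
CI and a seeded two-sided permutation p-value (10⁴ permutations) — a
desk-scale replacement for the repeated-measures mixed-model inference
used on the original patient data, which is out of scope here.
`poolTimecourses()` averages per-fraction median series point-wise.

For γH2AX scoring, `applyFociCap()` implements the overlap rule
literally: counts above 10 (where individual foci can no longer be
resolved) are recorded as 25 foci per cell; a count of exactly 10 is
kept. `summarizeH2ax()` reports the percentage of positive cells and
the median capped foci per nucleus with bootstrap CIs. "Positive" is
not defined by the assay description, so the package default — at
least 1 focus — is an explicit, configurable choice. The
"pre-next-fraction" time point is always its own label, never merged
with the pre-treatment baseline.

## Synthetic data

`generateCometDataset()` emulates the study design: by default 6
patients × 3 fractions × 300 cells at the six sampling times. Per-cell
tail intensities are Gamma distributed (right-skewed, positive) with
mean equal to the model observable scaled by lognormal patient
(σ = 0.2) and fraction (σ = 0.3) random effects — fraction-to-fraction
variability exceeded patient-to-patient variability in the motivating
data — and CV 0.6. Two percent of cells are replaced by uniform draws
in 60–100 %DNA, emulating sanguineous contamination and early-apoptotic
cells; values are clipped to [0, 100], which is negligible at realistic
means. `generateH2axDataset()` draws Poisson focus counts with mean
`0.25 + 0.8 × damage`, where the damage signal is the compartment total
passed through a first-order persistence filter (τ = 120 min) because
foci decay more slowly than the comet signal; the foci mean is tied to
*total* damage since the model deliberately does not separate break
types. These baseline/scale values were set so that roughly 20 % of
unirradiated cells are positive and positivity approaches 90 % at
30 min, the magnitudes reported for this assay. Generators are pure
functions of (inputs, seed) and write manifests recording truth,
design and seed.

What passing tests on these data do **not** show: real aspirates carry
sampling heterogeneity, necrosis, hypoxia and apoptotic
subpopulations that no Gamma-plus-contamination model captures, and
the generator's cells are exchangeable within a sample. Recovery
results on synthetic data are therefore upper bounds on what the real
design can identify.

`table1Fixture()` encodes the published difference-of-medians
time-course (10.80, 11.24, 7.11, 2.47, 1.24 %DNA above baseline at
15–360 min) as an observation series over a zero baseline; whether
those published values are differences of pooled medians or medians of
paired differences is not stated, and the fixture's metadata records
the assumption made.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: solver steps of
0.01–0.05 min; five seeded fits for the noisy-recovery study; a
32 768-point grid for the optimality oracle; 500 null simulations
(n = 30 per group, 999 permutations) for the type-I-error check; and
100 replicates (n = 500, 2000 resamples) for CI coverage. These sizes
give stable estimates while keeping a full run in minutes on one core.
Every stochastic routine takes an explicit seed, and the CLI stamps
each run directory with the seed and an MD5 hash of the effective
configuration.

## Known limitations

* No uncertainty quantification on fitted parameters (no profile
  likelihood or bootstrap CIs); the identifiability analysis above is
  the reason this would matter.
* No stiff or adaptive solvers; extremely fast rates (k·step ≫ 1) are
  handled by the outflow limiter rather than resolved.
* One- vs two-pathway is the only model-selection axis; no cell-cycle,
  oxygenation or cell-kill modelling, and no image-level synthesis.
* The melanoma arm of the motivating design (different fractionation,
  two patients) has no dedicated support.
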
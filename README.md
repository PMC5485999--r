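# cometRepair

Kinetic modelling of radiation-induced DNA damage formation and repair
from comet-assay time-courses.

## What this is for

After a radiotherapy fraction, DNA strand breaks in tumour cells appear
within minutes and are cleared over hours. The alkaline comet assay
measures this per cell — fragmented DNA migrates into a "tail" whose
fluorescence fraction (%DNA in tail) quantifies damage — and serial
fine-needle aspirates taken around a fraction yield a median
%DNA-in-tail time-course per patient; γH2AX focus counts provide a
parallel readout. This package is for researchers who want to turn such
time-courses into kinetic rate constants and delay times, and to test
the whole analysis chain on synthetic data with known ground truth.

It provides:

* a two-pathway compartment model of damage kinetics with delayed
  processing, solved as delay differential equations (DDEs) by a
  fixed-step method of steps (compiled core, RK4/Euler);
* an evolutionary parameter search with Nelder-Mead refinement, in
  log-rate space, with a brute-force grid oracle for cross-checking;
* assay statistics: median/IQR time-courses with bootstrap CIs,
  baseline differences with permutation p-values, γH2AX focus capping
  and positivity summaries;
* a seeded synthetic per-cell data generator emulating a fractionated
  study design (inter-patient/fraction heterogeneity, contamination
  outliers);
* a subcommand CLI binding the stages into reproducible runs.

## The model

Primary damage `n0` is induced in proportion to the dose rate R(t) of a
rectangular pulse and detected by one of two abstract pathways
(p ∈ {fast, slow}):

    dn0/dt   = kcleav R(t) − (k0,fast + k0,slow) n0
    dn1,p/dt = k0,p n0 − k1,p n1,p(t − tr,p)
    dn2,p/dt = k1,p n1,p(t − tr,p) − k2,p n2,p²

Processing is first order with a lag `tr,p` that lumps the intermediate
enzymatic steps (hence the DDEs); final repair is second order because
two fragment ends rejoin. All compartments are visible in the comet
tail, so the observable is `Σ ni + bn` with a co-estimated baseline
`bn`. A one-pathway model is the special case with the slow rates
pinned at zero. Details, units, numerical choices and identifiability
caveats are in `vignettes/damage-repair-kinetics.Rmd`.

## Worked example

```r
library(cometRepair)

params   <- pooledSarcomaParameters()          # reference one-pathway set
protocol <- irradiationProtocol(dose = 6, pulseDuration = 2)
traj     <- simulateDamage(params, protocol, horizon = 365)
data.frame(time_after_rt_min = c(15, 30, 60, 120, 360),
           pct_dna_in_tail = sampleObservable(traj, 2 + c(15, 30, 60, 120, 360)))
#>   time_after_rt_min pct_dna_in_tail
#> 1                15           15.81
#> 2                30           14.71
#> 3                60            9.01
#> 4               120            5.62
#> 5               360            4.55
```

The signal peaks at the first post-treatment sample (15.8 %DNA against
a 4.23 %DNA baseline) and has largely decayed by 6 h — the
fast-peak/rapid-decline shape this assay shows in vivo. Synthetic
per-cell data generated from the same truth reproduce it through the
statistics layer:

```r
design <- syntheticDesign(nPatients = 2, nFractions = 2, cellsPerSample = 300)
cells  <- generateCometDataset(params, protocol, design, seed = 42)
differencesFromBaseline(cells, nPerm = 2000, seed = 42)
#>   timepoint time_min difference ci_lower ci_upper p.value
#> 1       T15       15      11.58    10.49    12.50  0.0005
#> 2       T30       30      10.36     9.30    11.37  0.0005
#> 3       T60       60       4.74     4.32     5.18  0.0005
#> 4      T120      120       1.50     1.15     1.88  0.0005
#> 5      T360      360       0.36     0.06     0.74  0.0150
```

Each row is the median tail-intensity excess over the pre-treatment
group with a bootstrap 95% CI and a permutation p-value: strongly
elevated damage up to 60 min, near baseline again by 6 h. Fitting the
published difference time-course recovers a curve with sub-%DNA
residuals:

```r
fit <- evolutionaryFit(table1Fixture(), protocol, fitConfig(seed = 1))
fit
#> FitResult (one-pathway): SSE 0.372006, RMSE 0.249, seed 1
```

(Parameter point estimates from six medians are degenerate along known
trade-offs; see the vignette's identifiability section before
interpreting them.)

A command-line entry point wraps the same functions:

```sh
Rscript inst/cli/cometRepair.R simulate --config run.yaml --out-dir out/
Rscript inst/cli/cometRepair.R fit --obs medians.csv --mode one --seed 7 --out-dir out/
```

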
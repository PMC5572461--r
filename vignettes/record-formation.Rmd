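---
title: "How stratmix forms and samples mixed sedimentary records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How stratmix forms and samples mixed sedimentary records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stratmix` models how bioturbation and plankton population change jointly
shape single-specimen stable-isotope records of an abrupt carbon-isotope
excursion (CIE), and quantifies the probability that a sampled record
preserves no "intermediate" δ13C values even when the onset was gradual.
This vignette documents the model, its assumptions, the numerical choices,
and the design decisions that were genuinely open.

## 1. The mixing kernel

A point event — a packet of tracer particles deposited at the
sediment-water interface at one instant — is followed through ongoing
burial and biodiffusion. Depth below the interface `z` (cm) evolves per
10-yr step by the burial increment `w_s dt` plus a Gaussian step of
standard deviation `sqrt(Kv(z) dt)`, with reflection at `z = 0`; the
diffusivity profile is

```
Kv(z) = K0 * (1 - tanh((z - z0) / z_scale)) / 2
```

so mixing is near-maximal (`K0`) throughout the well-mixed layer, half of
maximal at its base `z0`, and negligible a few e-folding scales below.

Defaults (per-site physical parameters, Maud-Rise-like pelagic carbonate):

| parameter | default | meaning |
|---|---|---|
| `ws` | 2.5 cm/kyr (0.5 for onset experiments) | sedimentation rate |
| `K0` | 3 cm²/kyr | maximum biodiffusivity |
| `z0` | 10 cm | well-mixed-layer depth |
| `z_scale` | 1.5 cm | e-folding of the tanh rolloff |
| `dt`, `T` | 10 yr, 60 kyr | step and total mixing duration |
| `dz` | 0.2 cm | bin width |
| ensemble | 100 × 10,000 | runs × particles |

Two conventions here were open and are package decisions:

* **Step-size convention.** `Kv` is interpreted as the *variance rate* of
  the particle random walk (step s.d. `sqrt(Kv dt)`), not as a Fickian
  diffusion coefficient (`sqrt(2 Kv dt)`). Under the variance-rate
  convention the standard ensemble re-entrains particles to a maximum of
  roughly 25–30 cm above their deposition horizon, consistent with
  observed deep point-event tracer smearing that motivates these parameter
  values; the Fickian convention yields maxima near 45 cm.
* **No spurious-drift correction.** The diffusivity is evaluated at the
  pre-step depth and no `dKv/dz` drift term is added. With
  depth-decreasing diffusivity the uncorrected walk slightly overweights
  the low-diffusivity rolloff zone; this is a known, documented
  approximation of the underlying Lagrangian scheme.

Numerical details: the state variable is the deviation `u = z - ws*t`
from the undisturbed horizon, so the zero-diffusivity limit returns
exactly zero displacement; particles whose local diffusivity falls below
10⁻⁷ cm²/kyr are frozen (their residual diffusive spread over the rest of
the run is far below one bin) which keeps the per-run cost proportional to
mixed-zone residence; a stability warning is raised if the per-step
diffusive s.d. exceeds `z0`.

**The median profile.** Each run's displacements are binned at `dz`; the
per-bin *median* across runs is renormalised to unit mass. Binning before
taking the median is the only reading under which a median profile over an
ensemble is well defined. The median truncates bins occupied in fewer than
half the runs, so the profile's support is slightly narrower than the raw
ensemble range; renormalisation restores unit mass.

## 2. Record formation as convolution

The typical profile is applied to every 0.2-cm increment of a deposition
scenario, assuming mixing is stationary across the modeled interval
(mixing-intensity change across the event is deliberately not modeled).
Each destination bin keeps a per-source-horizon mass ledger, so
single-specimen values can later be drawn with the correct
deposition-time isotope distribution. Scenarios are padded above and below
by the profile support with edge-replicated abundances, and destination
bookkeeping bins extend beyond the analysis window, making per-clade mass
conservation exact and testable (relative error < 10⁻⁶ in the suite).

The stationarity assumption is validated by an independent route:
`direct_simulation_oracle()` releases particles for every increment at its
own deposition time and mixes each cohort through the remainder of the
run. The suite checks that the convolution agrees with this direct
simulation within 3 Monte-Carlo standard errors (binomial error of the
oracle draws plus profile-estimation error) in at least 95 % of interior
bins of a 200-increment step scenario.

Coordinates: internally the column is indexed by accumulated height (cm,
increasing upward, half-open 0.2-cm bins); core depth is reported as
`mbsf = ref_mbsf - height/100`.

## 3. Scenarios

* `step_scenario()` — the simplified two-clade configuration: a step CIE
  in both clades (mixed-layer 3.1 → 0 ‰, s.d. 0.30 ‰; thermocline
  1.6 → −0.4 ‰, s.d. 0.12 ‰) coincident with a step abundance change
  (mixed-layer to 50 %; thermocline to 0 for 10 cm — very low populations
  are approximated by a depositional gap — then 2.5 % of its initial
  abundance). Default onset at 170.80 mbsf.
* `bulk_scenario()` — bulk carbonate as the mass-weighted mean of a
  population shifting 1.6 → −0.4 ‰ whose abundance collapses below 1 %
  (0.5 % by default, configurable) for 10 cm, then 2.5 %.
* `ramp_scenario()` — the onset-duration experiments: a single
  mixed-layer clade whose population mean δ13C (3.1 → 0 ‰) and abundance
  (1 → 0.5) decline linearly over the onset interval
  `duration × ws` cm, at `ws = 0.5` cm/kyr. The modeled window spans
  20 cm below to 30 cm above the onset: enough below to contain the
  downward smear of the profile and enough above to contain the ramp and
  most of the upward smear.

## 4. Sampling and the intermediate-value statistic

Samples are contiguous 2-cm intervals (thickness = spacing, matching core
practice; both configurable). Within a sample, individuals are drawn with
replacement proportional to source-horizon mass — masses are expectations,
not enumerable individuals — and each value is its source-time population
mean plus `N(0, sd)` noise. A value is *intermediate* when it lies more
than 3 s.d. from both population means (strictly inside the open interval;
for the mixed-layer model that is (0.9, 2.2) ‰). With Gaussian noise a
pure cloud still produces ~0.135 % false positives per draw, which the
suite verifies against the Normal tail.

**Observed onset duration and detection.** The recorded duration is the
longest run of consecutive intermediate-bearing samples times the sample
spacing over `ws`. A run must span at least two consecutive samples by
default (`min_run = 2`): an isolated intermediate-bearing sample defines
no interval and is indistinguishable from an analytical outlier. This
choice was genuinely open, and it matters. Because mixing conserves mass,
the total expected number of intermediate-band individuals in a tiled
record is invariant to mixing and proportional to the onset duration, so
a "≥ 1 intermediate anywhere" detection rule saturates quickly (≈ 0.9 at
a 5-kyr onset) and cannot produce the strong threshold between 3- and
5-kyr onsets that the consecutive-sample duration statistic is meant to
capture; requiring two consecutive intermediate-bearing samples yields a
detection probability near one half at a 5-kyr onset and near zero for
step onsets, with the single-sample reading available via `min_run = 1`.
Both detection flavours are reported by `run_grid()`
(`detection_fraction` and `detection_fraction_any`).

Replicate count defaults to 100 per grid cell (binomial s.e. 0.05 at
p = 0.5). All replication is over the sampling stage only: scenario and
record formation are deterministic given the profile, and every replicate
seed derives from the grid seed.

At very large per-sample counts (n = 500) the Gaussian false-positive
floor makes nearly every sample intermediate-bearing (per-sample
false-positive probability 1 − (1 − 0.00135)⁵⁰⁰ ≈ 0.49), so observed
durations saturate toward the record length regardless of the true onset;
this is a property of the 3-s.d. rule itself, not of the mixing model,
and is why the suite's observed-duration recovery assertions at n = 500
fail while the same property holds at the headline n = 5 sampling.

## 5. Empirical abundance machinery

`sedimentary_abundance()` converts genus percentages plus preservation
covariates into sedimentary percent per genus. Decisions taken where the
procedure was underdetermined:

* The quantity of interest is *unfragmented* foraminiferal material, so
  the default computes `coarse × (100 − fragmentation)/100`; the literal
  product (`coarse × fragmentation/100`) is available via a switch because
  the two readings conflict in the source procedure's wording.
* The hand-fitted trend through the unfragmented series is replaced by a
  reproducible centred moving average over a 0.1-m window (configurable).
* Normalisation rescales every row's two-genus total to 100 by default;
  `normalize = "over100"` rescales only totals exceeding 100. The
  synthetic generator expresses genus percentages relative to the whole
  sediment, so its matching convention is `"over100"`.
* Negative regression predictions are clipped to zero (percentages cannot
  be negative); missing CaCO₃ is imputed as the mean of the adjacent
  depths, and every imputation is logged with a provenance flag.

`fit_unmixed_abundance()` recovers a piecewise-constant unmixed history on
user-supplied breakpoints by coordinate descent with box constraints
`[0, 100]`. The forward model is linear in segment levels, each update is
an exact quadratic minimisation, and the descent converges monotonically;
the iterative manual adjustment it replaces is not otherwise specified, so
a deterministic convex solver is the reproducible stand-in. The design
matrix replicates the record former's edge padding, so histories are
recoverable up to the column ends. A fitted gap (zero level) that leaves
more than `gap_floor` percent of the target unexplained raises a
diagnostic. The CIE onset depth in empirical fitting is treated as a free
parameter scanned over 170.70–170.80 mbsf.

## 6. The synthetic data generator

`generate_dataset()` emulates the depth-series structure the empirical
module expects: piecewise-constant two-clade histories with highs, lows
and gaps, excursion reductions of 80 % (mixed-layer) and 97.5 %
(thermocline) at a 170.74-mbsf onset; carbonate declining from a > 85 wt%
pre-event plateau to lows near 60 wt%; coarse-fraction and fragmentation
covariates generated from the imputation regressions plus Gaussian noise
(s.d. 2 points by default — the regressions were fit to scattered real
data, so exact covariates would be unrealistic); random masking of
covariate cells to exercise every imputation path; and single-individual
δ13C draws (4 per clade per 2-cm row) from the forward-mixed column.

What it does *not* emulate: species-level composition within genera,
size-fraction structure, dissolution as a separate process, δ18O, or
age-model uncertainty. Passing recovery tests on synthetic data therefore
demonstrates the internal consistency of the pipeline (generation →
normalisation → imputation → trend → fitting recovers the truth within
10 % at half-default noise), not the fidelity of any particular empirical
reconstruction.

## 7. Problem sizes in the test suite

The suite computes its shared profiles from reduced ensembles (8–10 runs
of 1,500 particles), uses 20 × 3,000 particles for the oracle-agreement
check with 800 particles per increment in the direct simulation, 100
replicates for the 5-kyr detection check (profile from 50 × 5,000), and
the full 100 × 10,000 standard ensemble for the re-entrainment check.
These sizes were chosen so each check's Monte-Carlo error is small against
its assertion tolerance. `scripts/acceptance.R` runs the full-scale
ensembles.

## 8. Known limitations

* Mixing parameters are constant in time; mixing-rate change across the
  event is out of scope by design.
* Size-dependent ("lumpy") mixing, winnowing, and dissolution are not
  modeled.
* The kernel discretization is first-order (Euler–Maruyama) without a
  gradient-drift correction; profile tails therefore carry a small
  systematic bias relative to the exact Fokker–Planck solution.
* The ensemble-maximum displacement is an extreme-value statistic: across
  independent full-scale ensembles it ranges over several centimetres, so
  single-ensemble values should be read with that spread in mind.
* Detection probabilities at small onset durations scale roughly with the
  square of the intermediate-band mass under the consecutive-sample rule,
  so they are sensitive to the among-individual s.d. and to sample
  alignment relative to the onset.
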
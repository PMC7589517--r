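---
title: "Methods: the in-droplet relocation model and its estimators"
author: "bactoline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the in-droplet relocation model and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`bactoline` re-implements, as a tested pipeline, the analysis of a
single-antibody droplet bioassay: individual antibody-secreting cells
(ASCs) are encapsulated with bacteria-coated nanoparticle aggregates
(bactolines) and a fluorescent anti-Ig probe, the relocation of probe
fluorescence onto the bactoline is imaged over an hour, and each
included droplet yields an apparent dissociation constant (K_D app) and
an epitope-availability estimate for one secreted antibody. This
vignette documents the model, the estimators, the synthetic-data
generator that provides ground truth, and the design decisions taken
where the assay's published description leaves the implementation open.

## The forward relocation model

Three species live in a droplet: secreted antibody `A` (accumulating
over time), surface epitopes `E` on the bactoline, and the labelled
detection probe `P` at 45 nM. We model two 1:1 mass-action equilibria
with ligand depletion, each solved by the numerically stable quadratic
root,

$$[XY] = \frac{2\,X_t Y_t}{\,X_t + Y_t + K + \sqrt{(X_t+Y_t+K)^2 - 4X_tY_t}\,},$$

with the following assumptions:

* **Probe independence.** The probe binds the antibody Fc while the
  epitope occupies the paratope, so probe binding is independent of
  epitope engagement and has equal affinity for free and surface-bound
  antibody. The probe riding on surface-bound antibody is therefore
  `POB = [PA] * [AE] / A_t`.
* **Relocation readout.** `R = 1 + gain * POB / (P_t - POB)`, a ratio of
  bactoline to background fluorescence with baseline exactly 1. The
  `gain` is the local concentration factor of the bead aggregate.
* **Surface avidity.** Binding to a dense, repetitive bacterial surface
  is effectively multivalent. We keep K_D app as the solution-scale
  quantity that calibration speaks about, and use
  `K_D,surf = kd_app / avidity` in the droplet equilibrium. Without
  this factor no parameter set can satisfy two facts at once: the
  relocation maximum y_max is insensitive to affinity (which requires
  near-saturated epitopes at the peak, i.e. peak concentrations well
  above 10 x K_D,surf), while secreting cells accumulate only ~30 nM of
  antibody in an hour and still show in-window maxima for affinities up
  to and beyond 50 nM. A single dimensionless avidity factor
  reconciles the two regimes; it is configuration-exposed like the
  other detection-side parameters.
* **Quasi-equilibrium in time.** Binding equilibrates fast relative to
  the 15-min imaging interval, so a cell's trace is the equilibrium
  curve evaluated at the accumulated concentration
  `c(t) = SR * t * corr / (N_A * V)`.

The resulting curve reproduces the Hook effect: `R(0) = 1`, a single
interior maximum, and descent back toward 1 as excess free antibody
sequesters the probe away from the bactoline.

### Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `droplet_volume_pL` | pL | 50 | droplet size of the screen |
| `probe_total_nM` | nM | 45 | in-droplet detection-antibody concentration |
| `imaging_times_min` | min | 0,15,30,45,60 | five reads, every 15 min for an hour |
| `corr` | — | 1 | free volume-correction scalar of the time-to-concentration conversion |
| `kd_detect_nM` | nM | 1 | tight Fc binding of the reporter |
| `gain` | — | 22 | places default peaks in the 1.2–4.6 relocation range observed for bactolines |
| `avidity` | — | 40 | puts trace maxima of 1–250 nM binders inside the one-hour window while keeping y_max affinity-invariant |

`gain` and `avidity` were fixed once, by requiring the model to
reproduce the assay's qualitative behaviour (peak heights, y_max
insensitivity to affinity across two decades, in-window trace maxima),
and are not revisited by any test.

## Curve features and calibration

For a titration or time trace, `y_max` is the maximum and `x_max` the
earliest abscissa achieving it (plateau ties go to the earliest point;
an argmax on either end of the series means "no defined maximum" and
the droplet is excluded). For a trace the corrected feature is

$$\alpha = \frac{y_\max}{x_\max \cdot \widetilde{SR} \cdot corr},$$

with `x_max * SR * corr` converted to nM, and affinity follows the
log-linear map

$$K_{D,\mathrm{app}}\,[\mathrm{nM}] = e^{(\alpha - \beta_0)/\beta_1}.$$

Two forms of the map ship with the package:

* `paper_calibration()`: the published preset `beta0 = 0.969`,
  `beta1 = -0.014` (and y_max slopes 0.46 / 0.67 per ELISA-signal unit
  for the ovalbumin and bacteria systems). The absolute alpha scale of
  that instrument cannot be reconstructed from stated units (its `corr`
  is undocumented), so the preset is kept for reference and anchor
  tests.
* `default_calibration()`: the refit used by the synthetic pipeline. It
  simulates noise-free concentration titrations of the forward model
  for eight calibrants log-spaced over 0.5–100 nM at mid-range capacity
  (mirroring how the original map was built from commercial
  antibodies), extracts alpha from each, and fits
  `alpha ~ log(kd)` by least squares. The fit refuses fewer than three
  distinct calibrants and non-negative slopes.

Of the two published, mutually inverted definitions of alpha
(`y_max/x_max` in the estimation formula vs `x_max/y_max` in a figure
caption) the package uses `y_max/x_max`, the only form consistent with
a negative `beta1`.

Classification uses the published thresholds — affinity high
(< 10 nM), intermediate (10–50 nM), low (> 50 nM); epitope availability
low (y_max < 2), intermediate (2–3), high (> 3). The published
intervals leave boundary points unassigned, so the middle class is
closed (`[10, 50]`, `[2, 3]`): a measure-zero decision, centralized in
`classify_kd()` / `classify_epitope()`. (The methods text's
"high availability ... y_max < 3" is treated as a typo for
`y_max > 3`, which is what the results section states.)

## The per-droplet pipeline

`build_cell_record()` applies, in order: cell present; a detectable
relocation increase (final minus initial relocation above
`k * sigma_noise`, default `k = 3` with baseline noise SD 0.01, both
exposed — the assay description gives no number); an interior maximum.
Each droplet yields exactly one of a fully classified record or an
`excluded_reason` in `{no_cell, no_increase, no_interior_max}` — the
exclusion is exhaustive and exclusive by construction and asserted by
the tests.

Because individual cells secrete at unknown rates, the published
pipeline converts time with the cohort *median* rate (250 IgG/s); the
package exposes this as `sr_mode = "median"` and adds
`sr_mode = "oracle"` (use each cell's true rate), which only synthetic
data can exercise and which separates the median-rate approximation
from all other error sources. `sr_sensitivity()` quantifies the
approximation per record: recomputing with median ± 1 SD rates it
reports the fold range both through the exponential alpha map and under
the linear reading (concentration ∝ rate, max single-side factor
250/100 = 2.5 at 250 ± 150).

`estimate_secretion_rate()` is a deliberate simplification of the
upstream beadline procedure (published separately): it inverts a
supplied relocation-to-concentration calibration on the ascending
branch and converts the OLS slope of concentration over time to
molecules/s, flooring negative slopes at zero.

## Two-density ELISA

Kinetic reads are linear over the hour, so per-well responses are OLS
slopes. Dose-response curves at single and double coating density are
fitted with a three-parameter Hill equation (baseline fixed at 0:
wells are blocked and washed), and the paired EC50s enter the
two-density affinity estimator. The printed form,

$$K = \frac{1}{2\,(2\cdot EC50_{1x} - EC50_{2x})},$$

has reciprocal-concentration units; the package returns it verbatim
(`beatty_value`) and returns its reciprocal
`2 * (2*EC50_1x - EC50_2x)` as `kd_app_nM`. The factor 2 is
bivalent-site bookkeeping: for IgG the reacting species is binding
sites at twice the antibody concentration. Under equilibrium with
plate-antigen depletion the half-saturation point in antibody units is
`EC50 = (K_D + L/2)/2` for site capacity `L`, so
`2*(2*EC50_1x - EC50_2x)` recovers K_D exactly when the coating is
doubled; `simulate_elisa()` implements exactly this geometry and the
test suite round-trips affinities of 0.2–24 nM through the full
slope → Hill → estimator chain to within a few percent. The Hill
plateau (maximal turnover rate) measures capacity; doubling the coating
doubles it.

## The synthetic-data generator

`simulate_population()` emulates the statistical structure the
estimators assume:

* cells per droplet ~ Poisson(λ), default λ = 0.2 (the single-cell
  loading regime of 5–10 million cells/ml in 50 pL droplets); droplets
  with several cells are one secreting event, as the assay cannot
  distinguish doublets;
* isotype ∈ {IgG, IgM, none} (default 3% / 3% / 94% for an immunized
  cohort);
* secretion rates log-normal, parameterised by median and SD (IgG
  250 ± 150/s, IgM 300 ± 117/s) — log-normal because rates are
  positive and right-skewed and only median ± SD are reported;
* (K_D app, epitope capacity) from a 3×3 mixture. The default weights
  follow the reported structure of bacterially immunized repertoires
  (about half the mass in the high-affinity/high-epitope bin, < 5%
  low-affinity); per-class sampling ranges (kd log-uniform in 0.5–4,
  18–35, 80–250 nM; capacity uniform in ranges mapping onto the y_max
  bands) sit well inside the class boundaries, representing class
  centres;
* bactoline size ~ Normal(164, 30) truncated positive (the 2-D imaging
  estimate; CV ≈ 18%), linearly rescaling each droplet's epitope
  capacity — the paper gives no count-to-concentration conversion, so
  the scaling constant is the configurable capacity unit itself;
* noise: multiplicative with CV 0.05 on `R − 1` (so baselines stay near
  1) plus additive jitter of SD 0.01, which makes empty-droplet traces
  read `1 ± noise` and gives the `k·sigma` detection rule something to
  threshold against.

All randomness flows from the mandatory seed; identical configurations
reproduce byte-identical populations.

What the generator does **not** emulate: spatial diffusion and
photobleaching, bead-aggregation physics, real microscope optics and
image files, chamber stitching, or kinetic (non-equilibrium) binding.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions — not that those assumptions hold for any
particular instrument.

## What recovery the pipeline can and cannot achieve

`benchmark_bin_recovery()` simulates a 500-cell noise-free validation
population (one secreting cell per droplet) and runs the pipeline in
oracle and median-rate modes against a refit calibration; agreement is
reported over droplets passing the interior-maximum filter, which is
identical in both modes. Two structural limits keep even oracle-mode
recovery below 100%:

1. **Epitope–affinity confounding in alpha.** The correction
   `alpha = y_max / x_max` removes capacity only if `x_max` scales
   multiplicatively with capacity. In any mass-action model of this
   family, capacity enters `y_max` multiplicatively but `x_max`
   additively, so part of the capacity spread leaks into the affinity
   estimate.
2. **Discretisation of x_max.** With five imaging points the observed
   peak time snaps to a 15-min grid, a relative concentration error of
   up to ~30% that propagates into K_D through the map.

In addition, bactoline-size variability (CV 18%) rescales per-droplet
capacity across y_max class boundaries, so a few percent of epitope
classes flip even with perfect features. The acceptance script computes
the resulting recovery rates on every run (typically ~0.75–0.8 for both
oracle bin recovery and median-rate kd-class agreement under the
default mixture); the test suite asserts the median-rate contract
(≥ 60%) and deliberately keeps the idealised 100% oracle assertion,
which fails and documents this limit. The published analysis faces the
same physics — its authors report K_D app varying by a factor of ~3
when rates one SD from the median are used — so the classification into
three broad affinity classes, rather than point estimates, is the
appropriate resolution of the assay.

## Numerical choices

* The quadratic equilibrium root uses the product form
  `2ab/(s + sqrt(s^2 - 4ab))`, avoiding catastrophic cancellation for
  tight binders; the test suite cross-checks it against an independent
  fixed-point iteration to 1e-9 and verifies mass conservation over
  10^4-point random sweeps.
* Unimodality of sampled curves is decided on first-difference sign
  changes with a relative tolerance of 1e-9, ignoring numerically flat
  plateau steps.
* Argmax ties break to the earliest point; plateau maxima ending at the
  last imaging time count as non-interior.
* Segmentation selects the brightest fraction of in-droplet pixels with
  ties broken by fixed column-major scan order (hence invariance to
  constant intensity shifts), labels 4-connected components, and drops
  components strictly smaller than half the selected area.
* Bacteria counts are redrawn until positive (truncation); with
  mean/SD = 164/30 the rejection rate is negligible.
* Problem sizes: the recovery benchmark uses 500 cells, generator
  moment checks use 10^4 draws, model sweeps use 10^4 parameter points
  — sizes at which every Monte-Carlo tolerance in the suite is stable
  across seeds.

## Limitations

* K_D app absorbs avidity; the avidity scalar is a modelling bridge,
  not a measured quantity, and the absolute K_D scale of the synthetic
  system is its own unit convention (hence refit-by-default).
* Calibration uncertainty is not propagated into per-droplet intervals;
  the median-rate sensitivity (`sr_sensitivity()`) is the only reported
  uncertainty, as in the original analysis.
* The ELISA module abstracts enzyme kinetics to a linear slope and
  ignores absorbance optics.
* Segmentation operates on abstract pixel grids; real image-file
  ingestion is out of scope.
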
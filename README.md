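# bactoline

Analysis of droplet-microfluidic single-antibody bioassays against
bacterial surfaces.

In these screens, individual antibody-secreting cells (ASCs) from
immunized mice are encapsulated in ~50 pL droplets together with an
elongated aggregate of magnetic nanoparticles coated with heat-killed
bacteria (a *bactoline*) and a fluorescent anti-Ig detection probe
(45 nM). Secreted antibody binds surface epitopes on the bactoline and
relocates the probe onto it; the *relocation* ratio R (bactoline signal
over droplet background, baseline 1) is imaged every 15 min for an hour.
From each droplet's time trace the package estimates the apparent
dissociation constant (K_D app) of the secreted antibody against the
bacterial surface and the density of the recognized epitope, and
aggregates cells into the 3×3 affinity × epitope-density heat maps used
to compare antibody repertoires across immunizations.

The package is written for assay developers and computational
immunologists who want a fully testable, ground-truth-driven
re-implementation of this analysis: every estimator can be exercised
end-to-end on synthetic droplet populations with known per-cell latents.

## The model and estimators

**Forward relocation model.** Secreted antibody A, surface epitopes E
and detection probe P obey two 1:1 mass-action equilibria with ligand
depletion, solved in closed quadratic form:

- A + E ⇌ AE with surface dissociation constant K_D,app / avidity
  (the avidity scalar models multivalent binding on the dense bacterial
  surface),
- P + A ⇌ PA with K_D,detect (the probe binds the Fc, independently of
  epitope engagement).

Probe on the bactoline is POB = PA·(AE/A), and

    R = 1 + gain · POB / (P_total − POB).

R(0) = 1 exactly and R → 1 as A → ∞: the curve rises, peaks and falls —
the Hook effect of homogeneous immunoassays. The peak height y_max
grows with epitope capacity but is insensitive to affinity, while the
peak position x_max moves right with K_D app; these two features carry
the assay's information.

**Per-droplet estimation.** A trace must show a *defined maximum*
(interior to the imaging window) to be processed. The time of the
maximum is converted to the antibody concentration accumulated by then,
c(t) = SR·t·corr/(N_A·V) with SR the median secretion rate
(250 IgG/s), and the corrected feature

    α = y_max / (x_max · SR · corr)

is mapped to affinity through the log-linear calibration
K_D app [nM] = exp((α − β₀)/β₁) (shipped preset: β₀ = 0.969,
β₁ = −0.014; the default pipeline refits β from simulated titrations of
known calibrants). Cells are binned as high (< 10 nM), intermediate
(10–50 nM) or low (> 50 nM) affinity, and as low (y_max < 2),
intermediate (2–3) or high (> 3) epitope availability.

**Two-density ELISA.** Kinetic reads are linear, so per-well responses
are OLS slopes; Hill fits at single and double coating density give
EC50s, and K_D app = 2·(2·EC50_1x − EC50_2x) (the two-density estimator
with bivalent-IgG site bookkeeping; the printed association-constant
form 1/(2(2·EC50_1x − EC50_2x)) is reported alongside).

**Repertoire statistics.** Screened cells are droplets × λ (Poisson
occupancy); the package computes Ig-SC frequencies, class-switch
ratios, specific and cross-reactive fractions, 3×3 heat maps with
marginals and differences, and pooled-variance two-tailed t-tests
across mice.

## Worked example

```r
library(bactoline)

## a titration of the forward model
p  <- binding_params(kd_app_nM = 1.5, epitope_total_nM = 3)
cv <- titration_curve(p, assay_constants(), 10^seq(-1, 2.5, length.out = 200))
extract_features(cv$y, x = cv$x)
#> y_max 2.516 at x = 10.1164 (interior maximum)

## calibration refit from simulated titrations of known calibrants
map <- default_calibration()
map
#> Calibration map (refit)
#>   alpha = 0.2448 -0.04581 * ln(K_D [nM])
#>   ...
#>   refit from 8 calibrants, R^2 = 0.931

## a synthetic screen, analyzed with the median-rate pipeline
cfg <- synth_config(n_droplets = 2000, seed = 7)
pop <- simulate_population(cfg)
rec <- analyze_droplets(pop$traces, map = map)
table(rec$excluded_reason, useNA = "ifany")
#>         no_cell     no_increase no_interior_max            <NA>
#>            1630             321              20              29

repertoire_heatmap(rec)
#> Repertoire heat map (n = 29 included records)
#>                low intermediate  high   sum
#> high         0.069        0.241 0.483 0.793
#> intermediate 0.103        0.000 0.000 0.103
#> low          0.103        0.000 0.000 0.103
#> sum          0.276        0.241 0.483 1.000
```

The relocation maximum of 2.52 at ~10 nM is a mid-capacity, high-affinity
curve; in the screen, 29 of 2000 droplets yield classified cell records
(most droplets hold no cell at λ = 0.2, and cells without a detectable
relocation increase or an interior maximum are excluded, mirroring the
assay's filtering). Most classified cells fall in the high-affinity /
high-epitope bin, as configured in the generator's ground-truth mixture.

A two-density ELISA round trip:

```r
el <- analyze_elisa_plates(simulate_elisa(1.5))
el$kd$kd_app_nM    #> 1.501  (true 1.5 nM)
el$capacity$ratio  #> 2.002  (double coating doubles the plateau)
```

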
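---
title: "Models, assumptions and design choices in lemnaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in lemnaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemnaquant)
```

## The measurement problem

Duckweed fronds float on the water surface of a crystallizing dish and
propagate clonally, so total frond area is the natural growth variable:
it can be read non-destructively from a single top-down photograph, and
under constant conditions it grows exponentially. The experimental
design this package serves grows dishes under several constant growth
light intensities (PPFD, µmol photons m⁻² s⁻¹; the default layout uses
100, 200, 500 and 700 with three replicate dishes each), photographs
each dish daily over a 4-day window, and complements the growth data
with PAM chlorophyll-fluorescence yields and HPLC pigment
concentrations sampled at the end of the window.

## Frond-area measurement

The image pipeline is deliberately simple and fully parameterized:

1. **Water mask.** With a fixed camera the dish interior is a known
   circle, so the default mask source is configured geometry
   (`center_px`, `radius_px`, `metres_per_px`), which makes the mask
   exact and the water area `pi * (radius_px * metres_per_px)^2`. An
   auto-detection fallback estimates the background color from the
   image border, flags pixels that deviate from it, and fits a circle
   through the blob's centroid and equivalent-area radius; it refuses
   images whose flagged region does not fill the fitted circle (fill
   fraction < 0.9), because a non-circular detection means the scene
   assumption is broken and a silent mask would corrupt every
   downstream number.
2. **Color threshold.** Fronds are green on bluish water: pixels are
   kept when their HSV hue lies in `[0.16, 0.50]` (green window on the
   0–1 hue circle) with saturation ≥ 0.20 and value ≥ 0.10. No
   published threshold values exist for this procedure, so the defaults
   were chosen once against the synthetic scene palette and are exposed
   in `frond_thresholds()` for recalibration on real imagery. An
   optional minimum-blob-size filter (default **off**) suppresses salt
   noise; it is off by default because removing pixels departs from the
   plain thresholding definition of the measurement.
3. **Area.** `coverage_fraction = frond pixels / water pixels`;
   `frond_area_m2 = coverage_fraction * water_area_m2`. The small bias
   between the pixelated water disc and the analytic circle area
   (≈ 0.02% at the default resolution) is far inside the 5% acceptance
   envelope.

## Growth model and photon budget

Relative growth rate uses the endpoint definition
`RGR = (ln FA4 - ln FA0) / t4` — the first and last photographs only —
because that is the field's standard two-point estimator for
exponentially growing duckweed cultures. A log-linear regression over
all days is available behind `method = "regression"` for robustness
checks, but it is not the default: with daily imaging of an
exponentially growing culture the two estimators agree in expectation,
and the endpoint form keeps `project_area(fit, t4) == FA4` an exact
identity that the test-suite leans on.

The photon dose integrates the flux `PPFD * 0.0864 * FA0 * exp(RGR t)`
(0.0864 = 10⁻⁶ mol/µmol × 86 400 s/day) in closed form,
`expm1(RGR * t4) / RGR`, which is numerically stable down to
|RGR| ≈ 10⁻³⁰⁰; below 10⁻¹² day⁻¹ the code switches to the series limit
`t4 (1 + RGR t4 / 2)` to make RGR = 0 exact. The switch point is far
below any biologically meaningful rate, and an acceptance test sweeps a
dense grid across the switch against adaptive quadrature (≤ 10⁻⁹
relative error required).

Light-use efficiency is the ratio definition
`(FA4 - FA0) / photons_received`. For an endpoint fit it reduces
algebraically to `RGR / (0.0864 * PPFD)` — the implementation computes
the ratio, and the identity serves as an independent cross-check. One
consequence worth stating: at equal initial area and equal RGR, the
dose ratio between two PPFDs is the bare PPFD ratio, so raising the
growth light from 100 to 700 µmol m⁻² s⁻¹ means exactly 600% more
photons for the same growth — the headline efficiency trade-off. (If
each treatment's own, slightly higher RGR is used instead, the increase
exceeds 600%; `photon_dose_ratio()` supports both readings, and the
acceptance target uses the equal-RGR one.)

## PSII energy partitioning

The partitioning assumes at most 80% of absorbed photons can be used by
PSII photochemistry (`max_efficiency = 0.8`, a named argument rather
than a hard-coded constant): photochemistry `P = Fv'/Fm' * qP`, thermal
dissipation `D = 0.8 - Fv'/Fm'`, excess `E = Fv'/Fm' * (1 - qP)`, with
`P + D + E = 0.8` an algebraic identity. Two validity decisions are
explicit rather than silent:

* **Out-of-range F.** Noise can push steady-state F outside
  `[Fo', Fm']`, making qP leave `[0, 1]`. Records are flagged and left
  unclamped by default (`clamp_qp = TRUE` opts in), because silent
  clamping hides instrument problems.
* **Photoinhibition gate.** Reading `0.8 - Fv'/Fm'` as photoprotective
  dissipation is only justified when dark Fv/Fm rebounds after a
  low-light recovery; `psii_table()` gates `partition_valid` on a
  post-recovery floor (default 0.75). Quenching-ratio NPQ (Fm/Fm′ − 1)
  is deliberately not computed: a residual post-recovery depression of
  dark Fv/Fm contaminates it.
* **Rates are incident-based.** `rate_P/D/E = fraction * PPFD_i` uses
  incident PPFD. True absorbed rates are proportionally lower (frond
  absorptance is not separable into chlorophyll vs carotenoid
  absorption without a dedicated measurement), so the outputs are
  labelled as incident-based and no absorptance correction is applied.

## Pigment pools

Concentration units are carried through from the input, never
converted; per-chlorophyll ratios are plain quotients that are mol/mol
only if the input is molar. The pre/post-recovery averaging rule
reflects chemistry: zeaxanthin (Z) interconverts with violaxanthin (V)
within the 30-min recovery, so Z is reported per recovery state
(headline value = pre-recovery), while the *pool* V+A+Z is
recovery-stable and is averaged as a pool — mean of the pre-pool and
post-pool sums, not of per-pigment averages. The conversion state is
reported as Z/(V+A+Z); an alternative convention counts half of
antheraxanthin as converted ((Z+0.5A)/(V+A+Z)), but the plain Z
fraction is what the downstream regression against dark Fv/Fm expects
here, so that is what is implemented.

## Group statistics

The studentized-range distribution comes from `stats::ptukey()` — a
vetted numerical routine there is no reason to re-derive — while the
ANOVA decomposition, Tukey–Kramer statistic
`q = |mean_i - mean_j| / sqrt(MSW/2 (1/n_i + 1/n_j))` and the compact
letter display are implemented in the package because they are its
reported surface. The letter algorithm is insert-and-absorb: one column
initially holds all groups; each significant pair splits every column
containing both members into two copies (one without each member);
subset columns are absorbed. This guarantees the display invariant —
two groups share a letter **iff** their adjusted p ≥ α — which the
tests verify against the pairwise decisions over hundreds of randomized
designs, including non-transitive patterns. With equal n the
Tukey–Kramer standard error collapses to the classic HSD, which the
tests check against `TukeyHSD()`. α defaults to 0.05. When MSW = 0 the
q statistic is degenerate; pairs with unequal means are declared
significant, identical pairs not.

## The synthetic-data generator

The generator states a world and keeps it fixed:

* **Scene.** A 400 × 400 px photograph of a 145-mm dish (radius 180 px,
  i.e. 72.5 mm / 180 px ≈ 0.4 mm per pixel) on a dark bench with
  bluish water. Fronds are ellipses with semi-axes 1.2–3.0 mm — the
  scale of individual *Lemna* fronds — placed by rejection sampling
  without overlap, which matches the visually discrete, non-overlapping
  fronds of a real dish and makes the ground-truth mask exact. About
  30% of fronds ("mother fronds") are rendered 20% darker to stress the
  color threshold.
* **Exact ground truth.** For each imaged day the analytic target
  `FA0 * exp(RGR t)` is quantized to whole pixels and the placement
  closes the gap exactly: the final ellipse is sized to the remainder
  and trimmed pixel-wise. `true_area_m2` is therefore both the mask
  pixel count times the pixel area *and* the analytic value to within
  half a pixel — so at zero growth all imaged days have identical
  ground truth, and recovery tests compare against a sharp number.
* **Overflow.** Non-overlapping placement saturates well below full
  coverage, so scenarios whose final-day area exceeds 60% of the water
  surface (`max_packing_fraction`) are rejected up front with an
  explicit message.
* **Fluorescence.** Yield rows are constructed by inverting the PSII
  definitions at an arbitrary yield scale (Fm′ = 2, Fm = 2.5), so at
  zero noise the derived Fv′/Fm′, 1 − qP and Fv/Fm reproduce the
  configured truth to floating-point precision. Noise, when requested,
  is multiplicative Gaussian clipped positive, since yields are
  positive intensities. Default per-PPFD truths follow the qualitative
  high-light-acclimation pattern (Fv′/Fm′ falling from 0.72 to 0.38,
  1 − qP rising from 0.15 to ~0.58, dark Fv/Fm dipping before recovery
  and rebounding above 0.8) — no per-dish raw yields are published for
  this design, so these defaults mimic the trends only.
* **Pigments.** Default means follow the canonical acclimation trends
  (chlorophyll down, V+A+Z pool up, zeaxanthin from ≈ 0 at the lowest
  PPFD to about a third of the pool at the highest, lutein and
  β-carotene modestly down). The post-recovery sample converts a
  configurable fraction (default 0.5) of zeaxanthin back to
  violaxanthin, conserving the pool. Dark Fv/Fm is co-generated as
  `intercept + slope * Z/(V+A+Z)` (defaults 0.84 and −0.3: a modest
  depression reaching ≈ 0.74 at a Z fraction of 1/3), so the
  regression stage has an exactly known target.

**What a green test does and does not establish.** The synthetic dishes
have uniform lighting, a clean background, no roots, no specular
reflections, no frond overlap and a color palette chosen to be
separable; real imagery has all of these. A passing recovery test
establishes that the pipeline's arithmetic and plumbing are correct,
not that the default thresholds will segment any particular camera's
photographs — those must be recalibrated per rig.

## Determinism and seeds

Every generator takes an explicit seed; the dish renderer derives one
sub-seed per imaged day so days are independently reproducible, and the
pipeline derives per-dish seeds from the master seed. Repeated runs of
an identical configuration produce byte-identical CSVs. One deliberate
consequence of exact-count placement: two runs differing only in seed
rearrange fronds but report identical measured areas, because the
ground-truth pixel count is the same.

## Known limitations

* HPLC chromatogram processing, oxygen-electrode photosynthetic
  capacity, starch staining and absorptance measurement are out of
  scope; pigments and fluorescence enter as tables.
* The imaging model assumes one circular dish per image, photographed
  perpendicularly; tilted or multi-dish frames are not handled.
* Growth-trend curve fitting beyond the linear Fv/Fm ~ Z/(V+A+Z)
  regression is not provided: the nonlinear model family used for
  figure trend lines in this literature is not standardized, and
  guessing one would suggest false comparability.
* Frond counting, mother/daughter classification and root detection
  are non-goals.
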
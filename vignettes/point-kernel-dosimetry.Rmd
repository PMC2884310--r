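---
title: "Point-kernel dosimetry for heterogeneous brachytherapy applicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-kernel dosimetry for heterogeneous brachytherapy applicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachydose)
```

## The problem and the model

Intracavitary brachytherapy for cervical carcinoma places sealed Cs-137 or
Ir-192 sources in an intrauterine tandem and two vaginal ovoids. Conventional
planning superposes single-source dose-rate tables measured in homogeneous
water, which ignores three perturbations that are always present in the real
treatment: the source capsules, the steel applicator walls, and any shields.
This package computes dose rates with those heterogeneities in the model,
fast enough for interactive checking, by a point-kernel ray-tracing method
rather than stochastic transport.

Each line source is discretized into point emitters at a step `delta_l`; for
each emitter–point pair the engine traces the straight ray through the solid
geometry into per-material path lengths, attenuates each spectrum line
exponentially, multiplies by an effective buildup factor for the traversed
layer stack, and converts the energy fluence rate to dose to water through
mass energy-absorption coefficients (collision-kerma approximation, valid
where charged-particle equilibrium holds — everywhere beyond a fraction of a
millimetre from interfaces at these energies). Key physical assumptions:

* **Line-of-sight transport.** Scatter enters only through buildup factors;
  there is no angular redistribution. This is the standard point-kernel
  trade-off: accurate to a few per cent in broad water-like media, weakest
  deep inside strongly shielded shadows.
* **Infinite-medium buildup.** GP buildup factors are tabulated for infinite
  homogeneous media; near the patient surface the true scatter contribution
  is smaller than the model's.
* **Kerma approximation.** Dose equals collision kerma in water via
  `(mu_en/rho)_w`; secondary-electron transport is not modeled.

## Buildup: GP form and two-region composition

A single material layer of optical thickness `x` (mean free paths) uses the
five-parameter geometric-progression fitting function, with coefficients
`(b, c, a, x_K, d)` interpolated linearly in log-energy:

$$B(x) = 1 + (b-1)\frac{K^x-1}{K-1}, \qquad
K(x) = c\,x^{a} + d\,\frac{\tanh(x/x_K-2)-\tanh(-2)}{1-\tanh(-2)},$$

falling back to the linear branch `1 + (b-1)x` when `|K-1| < 1e-9` (the two
branches agree there; the guard only avoids 0/0). For a two-layer stack,
numbered source to detector, the Kalos composition rule is applied, with the
branch chosen by effective atomic number: for $Z_1 > Z_2$ (capsule or shield
first, tissue second — the usual brachytherapy case)

$$B = B_2(l_2) + \frac{B_1(l_1)-1}{B_2(l_1)-1}\,[B_2(l_1+l_2)-B_2(l_2)],$$

and for $Z_2 > Z_1$ the variant with the $e^{-1.7 l_2}$ memory term and the
Compton-fraction ratio $(\mu_C/\mu)_1/(\mu_C/\mu)_2$. One printed form of the
low-Z-first rule circulates with `B2(l2+l2)` in the bracket; this package
reads it as the total thickness $l_1+l_2$, the only reading that reduces
correctly in the same-material and $l_1\to 0$ limits (both limits are
property-tested).

Stacks deeper than two layers are collapsed by a left fold from the source
side: the two layers nearest the source become a pseudo-layer carrying the
*second* layer's material and the combined optical thickness, and the fold
recurses outward. This is an approximation, adequate here because in every
shipped geometry the innermost layer of a >2 stack is the optically thin
active core (≲0.01 mfp). Layers thinner than `1e-4` mfp — millimetre air
channels — are dropped before composition: they are optically negligible but
would destabilize the `(B_1(l_1)-1)/(B_2(l_1)-1)` ratio. The same ratio is
bypassed entirely for `l1 < 1e-6` mfp, where the rule's correct limit
`B_2(l_2)` is returned directly.

## Packaged physics data

`inst/extdata/physics/` ships one delimited table per material (energy grid
0.05–1.5 MeV; linear attenuation, Compton fraction, GP coefficients) and the
water/air mass energy-absorption tables. Attenuation and `mu_en/rho` values
are transcribed from the standard Hubbell / Hubbell–Seltzer compilations.
The GP buildup coefficients and Compton fractions are a **synthetic
in-package fit** (hence the `_synthetic` file names): smooth coefficient sets
constructed to reproduce point-isotropic buildup behaviour consistent with
published moment-method data — e.g. water at 0.662 MeV gives
`exp(-mu r) B(mu r)` of `r round(local({m <- standard_library()$materials$water; x <- lookup_mu(m, 0.662) * c(5, 10); exp(-x) * gp_buildup(lookup_gp(m, 0.662), x)}), 3)`
at 5 and 10 cm, matching the well-known near-cancellation of attenuation and
buildup for Cs-137 in water. They are not a transcription of any standards
table; users with access to a validated buildup library should substitute
their own coefficients (the loader accepts any table in the documented
column order). Stainless steel carries iron data at 8.02 g/cm³; the
80%Pt/20%Fe alloy carries a mass-weighted mixture attenuation at
21.644 g/cm³ with platinum-like buildup; plastic and air reuse the water
(low-Z Compton) buildup shapes.

The Cs-137 spectrum is the single 0.662 MeV line with 0.851 photons per
decay (barium K X-rays contribute under half a per cent at these distances
and are omitted). The Ir-192 spectrum is a composite of the principal gamma
lines rescaled at load so the total is exactly 2.364 photons per decay.

## Source strength conversion

Clinical strengths are output-referenced: air-kerma strength `S_k` is the
air-kerma rate at 1 m, in the transverse plane, from the *assembled* source.
Because the engine traces every ray explicitly through the capsule wall,
converting `S_k` with a bare-nuclide kerma constant and then attenuating the
capsule again would count the filtration twice. `strength_to_activity()`
therefore divides by a capsule-filtered constant (`source_kerma_constant()`):
each line is attenuated through the radial wall thickness, with its GP
buildup, before the spectrum sum. For a 0.6 mm steel wall this is a ~1.5%
correction; for the 0.5 mm Pt/Fe wall of a CDC-type tube it is ~10%, which is
why it matters. The unfiltered `kerma_rate_constant()` remains available; for
Cs-137 it evaluates to
`r signif(kerma_rate_constant("Cs-137"), 4)` µGy·h⁻¹·m² per Bq, consistent
within ~4% with the conventional 350 µGy·h⁻¹·m² ↔ 120 mCi pairing.

Linear reference air-kerma rates (µGy·h⁻¹·m²·cm⁻¹), the customary strength
unit for caesium tubes, are converted over the source's **nominal (capsule)
length** of 2.0 cm, not the active length: the stated tandem rates
54.2/36.2/36.2 then correspond exactly to the classical 15/10/10
milligram-radium-equivalent Fletcher loading (7.227 µGy·h⁻¹·m² per mg-Ra-eq),
and the colpostat total of 72.3 to 10 mg-Ra-eq per source. Converting over
the 1.35 cm active length instead would understate every Fletcher dose rate
by a third, far outside the method's expected accuracy.

## Applicator reconstructions

The coordinate frame puts the origin at the external os on the tandem axis:
+y superior along the straight tandem, +x patient-left, +z anterior, so
Manchester point A is (±2, 2, 0) cm and point B (±5, 2, 0) cm. Dimensions not
stated anywhere had to be fixed once; they are:

* **Tube-source stacking.** CSA and CDC capsules are taken as 2.0 cm long
  (the standard caesium tube length) and stacked end to end, no gaps, from
  the inner fundus tip of the tandem at y = 6.0 cm — capsule centres at 5, 3,
  1 cm. The 1 mm closed source end faces the fundus, which offsets the active
  core 1 mm down from the capsule top. This stacking is the dominant
  reconstruction uncertainty in any reference-point comparison.
* **Ovoid placement.** Ovoid source centres at (±separation/2, −depth, 0),
  axes tilted in the sagittal plane (−40° for the tandem-and-ovoid LDR set,
  30° for the Fletcher sets), pivoting about the source centre.
* **Applicator walls.** Tandem and ovoid tubes are steel annuli (0.5 cm ID,
  0.6 cm OD) with the lumen left as ambient medium rather than air — the
  homogenized-applicator convention of the engine this package re-implements;
  an explicit air lumen would return a smaller wall effect, closer to what
  exact-geometry Monte Carlo reports. The tandem tube extends 4 cm below the
  os (toward the handle), which matters only for rays from an ovoid source to
  the contralateral reference points.
* **Active cores** are modeled as water-equivalent cylinders: caesium
  pollucite/glass self-absorption beyond the line-of-sight trace is below the
  method's resolution at 0.662 MeV.
* **Shielded vaginal cylinder.** 15 cm plastic shell (OD 3.0 cm, 0.5 cm
  wall), steel guide tube (0.4 cm OD), air gap, and a 0.8 cm thick tungsten
  sector of 90/180/270° centred on azimuth 180° (azimuth 0 = +z, the
  unshielded reference); the Ir-192 source sits on the axis 4.5 cm from the
  tip. The shield's axial span (10.8 cm, centred on the source region) is a
  reconstruction choice.

## Numerical choices

* Interpolation: log–log for attenuation and `mu_en/rho` (exact at nodes,
  geometric mean between), linear in log-energy for GP coefficients and
  Compton fractions. Out-of-range energies are errors, never extrapolated.
* Ray tracing collects every candidate surface crossing, then classifies
  *segment midpoints* against the prioritized region stack; grazing hits and
  duplicate crossings (dedup tolerance 1e-12 of ray length) therefore cannot
  corrupt the material assignment, and segment lengths partition the ray
  exactly by construction.
* Dose points inside an active pellet or on an emitter raise errors at the
  point API and are masked `NA` on grids.
* Isodose extraction uses marching squares with linear edge interpolation
  (`grDevices::contourLines`); masked nodes are filled with the finite grid
  maximum before contouring, which leaves clinical levels untouched because
  masked nodes sit inside source cores where the field is far above any
  plotted level.
* Discretization defaults: `delta_l` = 0.005 cm (the convergence-tested
  reference step) for point and plan evaluation; grids default to 0.05 cm,
  which changes near-field values by well under the refinement test's bound
  and is ~10× faster.

## What the tests do and do not show

The test fixtures are built in code: bare point emitters in water or in a
non-interacting medium (closed-form inverse-square and transmission checks),
thin shells and slabs (chord-length oracles against dense point sampling),
and the four applicator builders themselves. Property suites assert exact
ray-length conservation, trace/classify agreement, buildup invariants
(B ≥ 1, branch continuity, same-material collapse, thin-layer limits),
discretization conservation and convergence, left/right mirror symmetry,
isodose nesting and the √2-radius half-dose circle. Frozen-value tests pin
the interpolators, both Kalos branches, the layer fold and the full
single-emitter chain to an independent one-off arithmetic evaluation at
1e-9 relative. The acceptance script recomputes published reference-point
results for the two LDR loadings at the 0.005 cm reference step (1100 and
1350 emitters; grids in tests use 31–101 nodes per axis — sizes chosen so the
whole suite stays interactive).

What passing these suites does **not** show: agreement with measured dose in
patients. The models are idealized rigid applicators in infinite water; there
is no anatomy, no inter-applicator gap variability, no TG-43 anisotropy
function (line-of-sight capsule attenuation stands in for it), and the GP
coefficient fit is synthetic. Shielded-shadow doses inherit the point-kernel
method's known few-per-cent optimism. The package is a computational
cross-check, not a treatment planning system.

## Known limitations

* The >2-layer fold discards the identity of the innermost layer after each
  step; fine for thin cores, unsuitable for thick multi-shield stacks.
* GP tables span 0.05–1.5 MeV: adequate for Cs-137 and Ir-192, not for
  high-energy sources or low-energy seeds (I-125, Pd-103).
* Buildup in tungsten shadows is extrapolated physics — the GP data are
  infinite-medium, the shadow is not.
* ICRU-38 bladder/rectum points are anatomy-dependent and therefore user
  inputs; no defaults are claimed.
* Dwell-time optimization is out of scope; HDR dwell times are inputs, and
  prescription normalization is a post-scaling of the computed rates.
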
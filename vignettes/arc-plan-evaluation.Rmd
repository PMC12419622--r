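---
title: "Evaluating arc-therapy plans against a zero-margin conformal reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating arc-therapy plans against a zero-margin conformal reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcmetrics)
```

## The problem

Volumetric modulated arc therapy (VMAT) achieves conformal dose distributions
through heavily modulated multileaf collimator (MLC) motion, including leaf
travel across the open target aperture. In thoracic stereotactic body
radiotherapy this modulation interacts with breathing motion (the interplay
effect) and amplifies sensitivity to leaf-position errors. Dynamic conformal
arc (DCA) deliveries avoid this by keeping the aperture conformal to the
target at every gantry angle, at some cost in dose shaping; several planning
strategies (MU-limited VMAT re-optimisation, leaf-speed limits, native DCA
sequencing) try to get the best of both.

Judging how "DCA-like" a plan is requires a geometric score that is
independent of the dose engine. This package implements that score — an
intrusion-only ratio of area difference against a zero-margin reference
aperture — together with the standard dosimetric index panel used alongside
it, and a synthetic phantom/plan/dose generator so the whole pipeline is
testable with closed-form answers.

## The reference aperture and the intrusion score

For a target structure (here, the internal target volume, ITV) and a gantry
angle, the surface voxels are projected into the beam's-eye view (BEV). Two
projection models are provided: *divergent* (each point projected from the
source, at `sad` millimetres on the beam axis, onto the isocenter plane —
the physically correct model and the default) and *parallel* (drop the
beam-axis coordinate; a small-angle approximation kept as a cross-check,
since for targets within a few centimetres of the isocenter the two agree to
a fraction of a percent over a full arc). For each MLC leaf-pair band
\([y_i, y_{i+1})\) the reference aperture opens from the minimum to the
maximum projected \(x\) within the band; bands that see no target are
closed. Bands are half-open so they partition the plane and no point is
counted twice.

The score of a plan is

\[
\mathrm{ratio}(\%) \;=\; 100 \times
\frac{\sum_{\text{cp}} \sum_{\text{pairs}} A^{\text{intr}}}
     {\sum_{\text{cp}} \sum_{\text{pairs}} A^{\text{ref}}},
\]

where, per pair, \(A^{\text{ref}} = (r_R - r_L)\,h\) is the open reference
area and \(A^{\text{intr}} = \big[(r_R - r_L) - |(r_L, r_R) \cap (a_L,
a_R)|\big]\,h\) is the part of the reference opening blocked by the actual
leaves. Accounting is intrusion-only: leaves retracted beyond the reference
earn no credit and no penalty, and pairs whose reference is closed are
excluded from numerator and denominator (intrusion into "no target" is
undefined). A conformal plan scores exactly 0%, a fully blocked one 100%.
Control points are weighted equally by default (the metric is a per-segment
geometry score, not a fluence score); an MU-weighted variant is available
but off by default. Reference apertures are recomputed at each plan's actual
control-point angles, so plans with 79–121 control points are all handled
without assuming a 3-degree grid.

Two design points deserve a note. First, the denominator is taken as the
reference *open-aperture* area; when the aperture is fitted per band to the
target silhouette this equals the band-bounded target coverage, and it makes
the 0–100% range exact. Second, the per-pair arithmetic is closed-form
interval arithmetic; the test suite cross-checks it against an independent
0.1 mm pixel-rasterization oracle on 100 seeded random plans (agreement
within 0.5 percentage points) so the fast path can never silently drift from
the geometric definition.

## The dosimetric index panel

On a 3D dose grid (Gy) the package computes, with a closed (\(\ge\))
threshold everywhere — stated explicitly because conventions differ:

* **Conformation number** \(CN = \frac{V_{T,ref}}{V_T}\times
  \frac{V_{T,ref}}{V_{ref}}\) — coverage times selectivity, in \([0, 1]\].
* **Conformality index** \(CI = V_{ref} / V_T\).
* **Homogeneity index** \(HI = D_{max}/Rx\), plus the IDL-normalized variant
  \(HI \times \mathrm{idl}/100\), which equals 1 exactly when the maximum
  matches what the isodose-line prescription implies. The implied maximum is
  `idl_to_max_percent()`: \( \mathrm{round}(100^2/\mathrm{idl}) \), giving
  the familiar 200/167/143/125/111% series for 50–90% IDLs.
* **R50%**: volume receiving at least half the prescription over the PTV
  volume.
* **D2cm**: maximum dose (as % of prescription) at \(\ge 20\) mm from the
  PTV, using an exact separable Euclidean distance transform (compiled;
  anisotropic spacing honoured). If the grid does not extend 2 cm beyond the
  PTV on every side the function refuses rather than report a clipped
  maximum.
* **DVH queries**: \(D_{x\mathrm{cc}}\) by sorting voxel doses and linear
  partial-volume interpolation at the x-cc cut (so 0.03 cc queries are
  meaningful even when they are a fraction of a voxel), and \(V_d\) as the
  percentage of structure volume at \(\ge d\) Gy.

\(V_{ref}\) is computed over the whole grid by default; a body mask can
restrict it (`body =`), since protocols differ on whether dose outside the
patient counts. R50% and D2cm are compared against configurable
minor-deviation thresholds (defaults 5.8 and 58.0, the interpolated
protocol values for a ~12 cc PTV); the protocol interpolation table itself
is deliberately *not* implemented — thresholds are configuration, not code.
Dose grids on a different lattice than the structure are resampled to the
structure grid by trilinear interpolation first.

## The synthetic phantom

`generate_phantom()` builds the stated geometry: a 0.51 cc spherical gross
target volume (GTV), an ITV by margin expansion of 1 cm superiorly and
0.3 cm in all other directions (breathing motion is predominantly
cranio-caudal), and a PTV by a 0.5 cm isotropic setup margin. The default
grid is 1 mm isotropic — finer than a typical 2 mm planning CT — because the
metrics of a 0.5 cc target are unstable at 2 mm, and it extends more than
2 cm beyond the PTV so D2cm is computable.

Two numerical choices matter here:

* **Lattice alignment.** A sphere centred exactly on a voxel centre is a
  degenerate configuration for the centre-inside membership rule: the
  surface passes through shells of voxel centres and the voxelized volume
  errs by ~5% at 1 mm. Real anatomy never aligns with the grid, so the
  default grid is offset a quarter millimetre from the isocenter; the
  0.51 cc sphere then voxelizes to within ~1.2% (and the construction stays
  deterministic and grid-convergent).
* **Margin kernel.** Expansion is a Minkowski dilation by a
  half-ellipsoid-per-octant kernel evaluated centre-to-centre (the
  scipy/ITK convention). A binary mask localizes the true surface only to
  within half a voxel, and dilation — a sup-convolution — turns that
  uncertainty into a systematic radial bias of order h/2: bare centres
  under-reach the continuous Minkowski sum (measured −5.4% in volume for
  the 0.51 cc sphere + 5 mm at 1 mm spacing), an inscribed-ball convention
  overshoots (+7.5%), a voxel-as-cube convention overshoots more (+17%). No
  half-voxel convention is unbiased for curved surfaces, so we keep the
  plain convention and test expansion against the rigorous half-voxel
  bracket \([\frac{4}{3}\pi(r+m-h/2)^3, \frac{4}{3}\pi(r+m+h/2)^3]\) plus
  monotone improvement under refinement. Consequently the commercial
  planning-system volumes quoted for this geometry (ITV 3.14 cc, PTV
  11.91 cc — produced by an unpublished vendor expansion convention) are
  treated as reference values, not targets; our defaults land within ~10%
  of them and the comparison is reported informationally only.

## Synthetic plans and dose

`generate_conformal_plan()` fits the conformal aperture at every control
point and then applies a controlled departure, so every score has a known
answer:

* `intrusion_none()` — the reference identity (score exactly 0%).
* `intrusion_fixed(d)` — constant tip push-in; the score has the closed
  form \(100\sum \min(d, w_p)h_p / \sum w_p h_p\).
* `intrusion_sinusoidal(a, T)` — depth
  \(a\,(1 + \sin 2\pi i/T)/2\), emulating periodic leaf travel of a
  modulated arc.
* `intrusion_speed_limited(v)` — caps leaf travel per degree, emulating
  leaf-speed-limited delivery; `v = 0.1` mm/degree corresponds to the
  planning-system minimum of 0.01 cm/degree.

Five presets map the delivery styles compared in the evaluation workflow
onto these models (`synth_plan_preset()`): `vmat` (sinusoidal, 3 mm
amplitude, 20-control-point period — a representative modulation depth,
chosen once), `limu` (1 mm margin, no intrusion), `lsl` (0.1 mm/degree),
`dcat` (3 mm dosimetric margin, varying dose rate) and `cdcat` (same with
constant dose rate). Defaults not fixed by the stated geometry (total MU
3000, amplitudes, margins) were chosen once as clinically representative
values and are documented here rather than revisited. Plans default to a
single full coplanar arc of 121 control points (3-degree spacing) and a
45 Gy / 3-fraction prescription at a selectable isodose line.

`generate_synthetic_dose()` is deliberately *not* a dose engine: it is a
plateau inside the PTV with a monotone radial fall-off
\(\exp(-\ln 2\, (d/s)^p)\) of the distance to the PTV, rescaled if needed so
at least 95% of the PTV receives the prescription (the planning coverage
rule). Its only contract is analytic tractability: every isodose surface is
a known distance shell, so R50%, D2cm, CN and the DVH metrics all have
closed-form or brute-force-checkable answers. It reproduces none of the
scatter, buildup or heterogeneity physics of a real dose calculation, so a
green dose-metric test establishes the correctness of the *metrics*, never
the realism of the dose.

## What the tests do and do not establish

The suite couples every metric to an independent oracle: pixel
rasterization for aperture areas, explicit sort/scan loops for DVH queries,
all-pairs distances for the transform, closed forms for spheres and the
radial dose model, and byte-comparison for end-to-end determinism (outputs
embed the config hash and seed, and contain no timestamps). Green tests
mean the geometry and arithmetic are right on the synthetic world. They say
nothing about commercial-TPS plan quality: reproducing a planning system's
optimizer output, Monte Carlo dose, or the clinical tables derived from
them is out of scope, and log-file formats, leaf-end/tongue-and-groove
transmission, and 4D interplay simulation are explicit non-goals.

## Degenerate inputs and tie-breaks

* Empty silhouette → all leaf pairs closed; a target never in view makes
  the area-difference ratio an explicit undefined-metric error (CLI exit
  code 3), not NaN.
* A closed actual pair blocks its whole reference opening wherever it is
  parked (its open interval has zero width) — no special cases.
* Leaf-band membership is half-open; a point exactly on a boundary belongs
  to the band above it.
* DVH \(D_{x\mathrm{cc}}\) with \(x\) exceeding the structure volume is a
  per-query error entry, never an extrapolation.
* Margin expansion refuses to clip at the grid boundary (enlarge the grid
  instead); sphere construction errors name the violating axis.
* Plan files are versioned; an unknown version is an explicit format error.
  DICOM support is a minimal explicit-VR little-endian subset (the syntax
  this package writes); other transfer syntaxes are refused loudly.

## Known limitations

* The intrusion score is a geometric surrogate for delivery robustness; it
  is not dose-weighted and does not simulate target motion.
* Margin expansion inherits the half-voxel surface ambiguity of binary
  masks discussed above; volumes of sub-cc structures at coarse grids
  should be read with that bias in mind.
* The leaf-counting conventions used by commercial systems to report "how
  many leaves were considered" are vendor-specific and internally
  inconsistent between sources; this package counts open reference pairs
  explicitly and reports that number instead.
* DICOM reading targets files this package (or an equally minimal writer)
  produced; it is not a general-purpose DICOM toolkit.
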
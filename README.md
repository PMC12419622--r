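# arcmetrics

Audits arc-radiotherapy treatment plans (VMAT and dynamic conformal arc)
against a **zero-margin conformal reference**. For medical physicists and
planning researchers who want a dose-engine-independent answer to the
question *"how far do this plan's MLC leaves encroach on the target?"*,
alongside the standard dosimetric index panel used in lung SBRT plan
evaluation — all runnable on a fully synthetic phantom, with no clinical
data required.

## What it computes

At every control point of an arc, the target's surface voxels are projected
into the beam's-eye view (divergent projection from the source at SAD, or
parallel as a cross-check) and a per-leaf-pair reference aperture is fitted:
band *i* opens from the minimum to the maximum projected *x* of the
silhouette within the half-open band [yᵢ, yᵢ₊₁). The plan's score is the
intrusion-only **ratio of area difference**

    ratio (%) = 100 · Σ Area_diff / Σ Area_ref

where, per pair and control point, `Area_ref = (r_R − r_L)·h` is the open
reference area and `Area_diff` is the part of that opening blocked by the
actual leaves (overlap-complement; retraction beyond the reference neither
helps nor hurts). A conformal plan scores exactly 0 %, an all-closed plan
100 %.

On a 3D dose grid it computes the companion panel:

* CN = (V_T,ref / V_T) · (V_T,ref / V_ref) — conformation number
* CI = V_ref / V_T — conformality index
* HI = D_max / Rx, and normalized HI = HI · IDL/100 (isodose-line
  prescriptions imply a hot maximum: `idl_to_max_percent()` gives the
  200/167/143/125/111 % series for 50–90 % IDLs)
* R50 % and D2cm gradient metrics with protocol minor-deviation flags
  (defaults 5.8 / 58.0), D2cm via an exact Euclidean distance transform
* DVH queries: D_xcc (partial-volume interpolated) and V_d

Infrastructure: voxel-mask structures with anisotropic margin expansion,
minimal DICOM RT-PLAN / RT-DOSE / RT-STRUCT readers and writers (explicit
VR little endian), versioned plain-text plan/mask/dose formats, MU
bookkeeping (`mu_reduction_percent()`), a synthetic phantom (0.51 cc GTV →
ITV → PTV), synthetic arc plans with controlled intrusion models, an
analytic dose field, and a CLI.

## Worked example

```r
library(arcmetrics)

ph <- generate_phantom()           # 0.51 cc GTV; ITV +10/3 mm; PTV +5 mm
m  <- machine_model()              # SAD 1000 mm, 40 x 5 mm leaf pairs

vmat <- generate_conformal_plan(ph$ITV, m, synth_plan_preset("vmat"))
limu <- generate_conformal_plan(ph$ITV, m, synth_plan_preset("limu"))
area_difference_ratio(vmat, ph$ITV)
#> <area_difference_result> ratio 23.183% (divergent projection)
#>   intrusion 9075.0 mm^2 over reference 39145.0 mm^2 across 121 control points
area_difference_ratio(limu, ph$ITV)
#> <area_difference_result> ratio 0.000% (divergent projection)
#>   intrusion 0.0 mm^2 over reference 39145.0 mm^2 across 121 control points

mu_reduction_percent(5200.55, 4937.07)
#> [1] 5.1

rx  <- prescription_spec(15, 3, 80)       # 45 Gy / 3 fx at the 80% IDL
d   <- generate_synthetic_dose(ph$PTV, synth_dose_spec(prescription = rx))
oar <- make_sphere_structure(c(0.25, 0.25, -25), 11, ph$PTV$grid, "aorta_like")
plan_indices(d, ph$PTV, rx, oars = list(aorta_like = oar),
             oar_queries = list(aorta_like = list(d_cc = c(10, 0.03), v_gy = 11.4)))
#> <index_report>
#>   CN 0.6225  (VT 10.851 cc, Vref 17.430 cc, VT,ref 10.851 cc)
#>   CI 1.6063   HI 1.2500 (normalized 1.0000)
#>   R50% 5.462   D2cm 22.10% of prescription
#>   flags: R50% pass (<= 5.8), D2cm pass (<= 58.0)
#>   aorta_like: D10cc = 8.329 Gy, D0.03cc = 56.250 Gy, V11.4 = 73.158 %
```

Reading: the modulated VMAT-like plan blocks 23 % of the reference aperture
area (its leaves sweep across the target), the MU-limited style none. The
synthetic dose plateaus at the IDL-implied maximum (normalized HI = 1.0),
covers the PTV (CN components show full coverage, V_T,ref = V_T) and spills
to ~1.6× the PTV at the prescription isodose; both gradient metrics pass
their protocol thresholds.

The heavy lifting is also scriptable:

```sh
Rscript inst/cli/arcmetrics.R phantom    --out phantom/
Rscript inst/cli/arcmetrics.R synth-plan --target phantom/itv.svol --preset vmat --out vmat.dcm
Rscript inst/cli/arcmetrics.R compare    --plan vmat.dcm --target phantom/itv.svol --out cmp/
Rscript inst/cli/arcmetrics.R indices    --dose dose.dcm --ptv phantom/ptv.svol --rx-gy 45 \
                                         --n-fractions 3 --idl-percent 80 --out idx/
Rscript inst/cli/arcmetrics.R report     --inputs idx/ --out report.md
```

Exit codes: 0 success, 2 input/format error, 3 metric undefined (target
never in view). Every report embeds the seed and a config hash, and reruns
are byte-identical.

## Scope

The package evaluates plans; it does not create clinical ones. No dose
calculation, no optimizer emulation, no motion/interplay simulation, no
biological models — see the methods vignette
(`vignettes/arc-plan-evaluation.Rmd`) for the model assumptions, numerical
conventions (half-open leaf bands, closed dose thresholds, voxel-centre
membership, margin-kernel bias) and known limitations.
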
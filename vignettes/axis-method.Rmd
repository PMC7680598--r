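---
title: "Axis-based patellar height and joint-line measurement: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axis-based patellar height and joint-line measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patellaxis)
```

## The measurement model

All quantities are computed from named 2D landmarks on a calibrated lateral
knee radiograph, in millimetres, with the y axis increasing distally. The
orientation of x is free: every output is a distance, a ratio of distances,
or an unsigned angle, so the constructions are invariant to rigid motion of
the whole landmark set, and all ratio indices are additionally invariant to
uniform scaling (JLH, a length, scales linearly). These invariances are not
incidental — they are asserted per release by property tests over random
synthetic knees.

The classical indices follow their original constructions: IS is tendon
length over bony patellar length; mIS, CD and BP share the articular surface
length `b` as denominator and differ in the tibial reference (tendon
insertion, antero-superior tibial margin, perpendicular to the joint line).
The axis-based method replaces the marginal tibial reference with the tibial
shaft axis, the mid-diaphyseal line through two points nominally 70 and
110 mm distal to the plateau:

* **T1** — orthogonal projection of the fibular head tip onto the axis;
* **T2** — intersection of the axis with the joint line;
* **AP** = `a1 / b`, **jAP** = `a2 / b`, **JLH** = `|T1 T2|`,

with `a1`, `a2` the straight segment lengths from the inferior articular
pole to T1 and T2. We treat `a1`/`a2` as Euclidean segments rather than
along-axis projections because the construction is drawn that way on the
radiograph; the two choices coincide only when the pole lies on the axis.
JLH is reported unsigned — on anatomy and after arthroplasty T2 lies
proximal to T1 — but the signed along-axis offset is retained in the
construction object (`jlh_signed`) for degenerate or exotic configurations.

The key structural property is that T1 depends only on the shaft and the
fibula, both untouched by arthroplasty, while T2 rides on the joint line.
Pure joint-line elevation therefore changes jAP and JLH while leaving AP
fixed to machine precision, and pure tendon shortening changes the patellar
indices while leaving JLH fixed. The true/pseudo patella-baja classifier is
exactly this observation as a decision table:

| AP    | jAP   | JLH elevated | call          |
|-------|-------|--------------|---------------|
| low   | low   | (any)        | true_baja     |
| normal| low   | yes          | pseudo_baja   |
| normal| normal| (any)        | normal        |
| other combinations |        || indeterminate |

An explicit `indeterminate` label is kept instead of forcing a binary call:
the mechanism argument covers only the three canonical patterns, and a
low-AP/normal-jAP radiograph, for instance, is more likely mismeasured than
meaningfully classifiable.

## Parameters that matter

* **Joint-line elevation cutoff** (`jlh_elevated_mm`, default 5 mm).
  Clinical series repeatedly associate elevation beyond roughly 5–8 mm with
  poor outcomes; we default to the conservative lower end and leave it
  configurable.
* **"Abnormally low" cutoffs for AP and jAP.** No published normal range
  exists for the axis-based indices. Two modes are provided:
  absolute cutoffs, and a z-score mode deriving mean − 2 SD from a
  user-supplied reference cohort (at least 10 cases). Whether "low" should
  mean low against a population range or against the patient's own
  preoperative baseline is genuinely open; both usages are possible (the
  classifier accepts any thresholds), and neither is asserted as canonical.
* **Shaft-level tolerance** (`offset_tol_mm`, default 15 mm). Observers
  place the 70/110 mm mid-diaphyseal points approximately; deviations beyond
  the tolerance raise an advisory `OFFSET_OUT_OF_SPEC` flag, never an error.
  A hard error (`AXIS_SHORT`) occurs only below a 20 mm separation, where
  the axis direction itself becomes ill-conditioned.
* **ICC form** (default `ICC(2,1)`: two-way random effects, single
  measures, absolute agreement — the standard choice for inter-observer
  reliability of continuous radiographic measures). The form is always
  carried in the output; agreement and consistency forms differ materially
  whenever raters carry systematic offsets, and a silent mismatch is the
  classic reliability-reporting error. Confidence intervals use the exact
  F-based Shrout-Fleiss/McGraw-Wong constructions.

## The synthetic-knee generator

Real radiographs cannot be redistributed, so validation runs on a
parametric landmark simulator with known ground truth. The generator places
a straight vertical shaft axis, a joint line of chosen posterior slope
through T2 at the origin, mid-diaphyseal points at exactly 70 and 110 mm
perpendicular distance, the fibular tip at a chosen offset from T2, and a
patella suspended above the joint line with chosen articular, bony and
tendon lengths. Two placement parameters (`patella_anterior_offset`,
`patella_proximal_height`) locate the patella relative to the axis; they
are needed to realise the landmark constellation, since segment lengths
alone do not fix where the patella sits.

Default anatomy values (articular length 28 mm, patella 40 mm, tendon
40 mm, slope 9°, fibular tip 10.9 mm distal of T2) were chosen once so that
the noise-free index means of a default cohort are plausible for an
arthritic pre-arthroplasty population (AP ≈ 1.33, jAP ≈ 0.98, JLH ≈ 10.9 mm,
PTS = 9°); the bony patellar poles sit a fixed 2 mm anterior/beyond the
articular poles and the tendon runs straight distally. Cohort draws add
Gaussian dispersion per parameter (defaults in `anatomy_variation()`,
giving AP SD ≈ 0.17 and JLH SD ≈ 3 mm); the default joint-line-elevation
distribution is Normal(3.17, 3.06) mm, a realistic arthroplasty shift with
a large spread that includes negative draws (joint-line lowering),
truncated only at physical infeasibility (an elevation overrunning the
whole patella is rejected and resampled, with a logged count). No
distributional information exists for tendon shortening in routine TKA;
the default is zero and the parameter is exercised explicitly in tests.

Surgery is applied mechanistically: the joint-line landmarks (and the
margin landmark, which postoperatively annotates the implant surface)
translate along the shaft axis by the drawn elevation; tendon shortening
translates the whole patella distally along the tendon direction by the
drawn fraction of tendon length. This makes the ground truth exact: at zero
noise the measurement pipeline inverts the generator to 1e-9, and the
post-pre JLH difference equals the drawn shift identically.

Observer noise is isotropic Gaussian per landmark coordinate (default
0.5 mm, a realistic click precision on a calibrated radiograph), plus an
optional systematic per-rater bias. Each perturbation stream is keyed by
(seed, case, phase, rater, landmark), so repeats reproduce exactly while
raters, repeated readings and the pre/post radiographs of one knee stay
mutually independent — the phase key matters: without it the pre and post
films of a case would share perturbations and spuriously cancel noise in
the JLH difference.

What the simulator deliberately does *not* emulate: correlated annotation
errors (e.g. a rotated film shifting all landmarks coherently), shaft
curvature, osteophyte-induced ambiguity of the marginal landmarks, the
partially obscured postoperative articular surface, and projective
distortion. Passing tests therefore demonstrate correctness of the
measurement constructions and statistics under the stated noise model, not
robustness to every failure mode of real radiography — the marginal-landmark
fragility that motivates the axis method is precisely what the simulator's
clean landmarks cannot show.

## Numerical choices

* Lines are anchored two-point objects with unit directions; intersections
  solve the 2×2 system by Cramer's rule and reject configurations with
  |sin(angle)| ≤ 1e-9 as degenerate (the axis and joint line are nearly
  perpendicular on any plausible film, so near-parallelism means corrupt
  input).
* Angles are computed in radians and reported in degrees, folded into
  [0, 90]; PTS is 90° minus the axis/joint-line angle.
* Degenerate-low ratios (numerator 0, e.g. a margin clicked on the
  articular pole) are returned as 0 rather than raised: they are
  geometrically meaningful.
* Zero-variance paired differences use the convention t = 0, p = 1 when the
  mean difference is zero and t = ±Inf, p = 0 (flagged) otherwise.
* Geometry tests compare against an independent homogeneous-line-coordinate
  re-derivation at 1e-9; ICC tests compare the direct mean-squares path
  against `aov()`-based mean squares at 1e-9, and against the analytic
  variance-components value σ²ₛ/(σ²ₛ+σ²ₑ) on simulated matrices.

## Problem sizes used in the test suite

Property tests run 1000 random knees for oracle-equivalence and invariance
checks; classifier accuracy uses a three-arm cohort of 90 knees noise-free
and 300 at σ = 0.5 mm; elevation recovery uses 175 knees (matching a
typical single-centre arthroplasty cohort); ICC calibration uses 500
subjects × 2 raters and the noise-monotonicity sweep 200 knees per noise
level. These sizes keep Monte-Carlo error comfortably inside the asserted
tolerances.

## Known limitations

* Thresholds for "abnormally low" AP/jAP must come from the user or a
  reference cohort; the package ships none, because none is established.
* The postoperative Caton-Deschamps index is computed from whatever margin
  landmark the annotator supplies; its pre/post comparability is limited by
  resection thickness and implant design, and the package documents rather
  than corrects this.
* The IS index uses straight-segment tendon length, as drawn on lateral
  films; a curved tendon course on a deeply flexed knee is not modelled.
* All geometry is planar; out-of-plane rotation of the limb must be handled
  at acquisition (gross rotation is an exclusion criterion upstream of this
  package, and the schema simply records what was clicked).
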
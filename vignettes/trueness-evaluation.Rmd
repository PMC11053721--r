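---
title: "Evaluating the spatial trueness of 3D-printed dental models with truedent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating the spatial trueness of 3D-printed dental models with truedent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truedent)
```

## The measurement problem

Photo-curing 3D printers (stereolithography, digital light processing,
photopolymer jetting) are the standard route from a digital dental model to a
physical one.  Polymerization shrinkage and the layer-wise build introduce
systematic distortions — in-plane shrinkage or expansion, vertical (Z) error,
and bowl-like warpage of the model base — that differ between technologies and
devices.  *Trueness* (ISO 5725-1) is the closeness of the measured result to
the design value; evaluating it on anatomical models is unreliable because
repeatedly identifying landmarks on cusps and fissures can err by more than
the printer itself.

`truedent` implements the evaluation workflow around a *structurized dental
model*: a maxillary and a mandibular model in which each tooth is replaced by
a cuboid *simulated dental crown* (SDC) of published population crown
dimensions, standing on a horseshoe-shaped base.  Every measurement surface is
an exactly known plane, so

* linear dimensions become unambiguous caliper spans (96 feature sizes over
  both jaws: per jaw 14 mesiodistal diameters, 14 buccolingual diameters,
  14 crown heights, and 6 arch dimensions of L1–L12),
* form tolerances (flatness, parallelism, perpendicularity) are measured
  against best-fit planes of labeled regions, and
* the overall 3D deviation is the RMS of signed distances between the scanned
  and the designed surface after best-fit rigid registration.

The model frame is millimetres, occlusal plane parallel to X–Y (the printer
platform), occlusogingival direction along +Z.

## The reference model and its layout

Crown dimensions (MD × BL × CH per tooth type and jaw) are fixed by
`default_spec()`.  The arch layout is not part of the published dimension
table, so it is a documented default of this package — the trueness metrics
compare designed against measured values of the *same* schema, so they do not
depend on reproducing any particular arch:

* SDC centers lie on a parabolic arch `y = -0.035 x^2` (apex radius
  ≈ 14 mm), mesiodistal axis along the arch tangent, buccolingual axis along
  the outward normal;
* adjacent SDC footprints keep a minimal clearance of exactly 2 mm, found by
  bisection (near the incisors the arch turns quickly, so spacing along the
  arc alone would let rotated footprints touch on the lingual side);
* the left half-arch is the exact mirror image of the right, giving bilateral
  symmetry by construction;
* the base is the arch strip swept 5 mm thick, wide enough to carry every
  footprint with a 2.5 mm margin (no palatal plate, as is usual for printed
  models and deliberately sensitive to transverse deformation).

```{r}
mesh <- build_model(default_spec("maxillary"))
mesh
schema <- enumerate_feature_sizes()
table(schema$jaw, schema$axis_class)
```

Each SDC contributes six labeled face regions (`occlusal`, `buccal`,
`lingual`, `mesial`, `distal`, `gingival`); the gingival-contact face is
bookkeeping only and enters no metric.  Arch dimensions L1–L12 are derived
deterministically from the layout (supporting-plane spans between the named
faces), so the schema is self-consistent: on the generated reference mesh the
virtual caliper returns every designed value to better than 1e-9 mm.

## Metrics

**Registration.**  Point-to-plane ICP of points sampled on the test mesh
against the reference surface, restricted to the base upper surface and the
occlusal/buccal/lingual faces (the narrow interproximal mesial/distal faces
are excluded, since 3D scanners resolve them poorly), seeded by a
principal-axes pre-alignment.  Convergence is declared when the RMS residual
changes by less than 1e-7 mm; non-convergence is flagged, never silent.
Registration is rigid on purpose: a scale-adjusting fit would absorb exactly
the shrinkage the method is meant to measure.

**Overall 3D deviation.**  Signed point-to-surface distances (positive on the
outward-normal side: material excess/expansion; negative: contraction),
summarized as `RMS = sqrt(sum(d_i^2)/n)` per jaw.  The two jaw values are
combined by their arithmetic mean — the package's documented aggregation
rule.  The colour difference map uses 21 segments: the middle one spans the
nominal band ±0.05 mm, ten equal-width segments per side reach the critical
value ±0.50 mm, and values beyond clamp into the end segments (blue =
contraction, yellow–red = expansion).

**Form tolerances.**  Per jaw, best-fit (orthogonal least-squares) planes of
the 42 SDC faces (14 occlusal, 14 buccal, 14 lingual) and of the base upper
surface.  Flatness is `x_positive + x_negative`, the sum of the extreme
orthogonal distances on either side of a region's plane.  Parallelism is the
acute angle, in degrees, between an occlusal plane and the base plane;
perpendicularity is the absolute deviation of a buccal/lingual plane's angle
to the base plane from 90°.  Summaries are mean ± sample SD (n−1) over
42 / 14 / 28 values.

**Linear errors.**  The virtual caliper mimics rigid jaws: two parallel
supporting planes orthogonal to the feature's design direction, each
contacting the extreme point of its defining region; relative error is
`(x2 - x1)/x1 × 100 %` (positive = enlargement).  Mean ± SD over the 34
occlusal-plane features is the occlusal plane error (the printer's X–Y
error); over the 14 crown heights, the occlusogingival direction error (the
Z error).  `icc()` provides the two-way random-effects, absolute-agreement,
single-measure intraclass correlation, ICC(2,1), for repeated manual
measurements; the same estimator serves intra- and inter-examiner tables.

## The deformation generator

`apply_deformation()` produces test meshes with known ground truth, applied
in a fixed order about the mesh centroid: anisotropic scaling (`xy_scale`,
`z_scale`), base warp (`z += warp_k * r^2`), Gaussian noise along vertex
normals, then a small rigid jitter.  The default fixture grid spans the error
ranges reported for dental photopolymer printers — scale errors of 0.5–1 %
(tens of micrometres over a crown), warp coefficients giving ~40 µm of basal
bowing, and 20 µm surface noise matching the accuracy of a lab scanner.

```{r}
fix <- apply_deformation(mesh, deformation_params(xy_scale = 0.99, z_scale = 0.995))
cfg <- default_config()
cfg$densities <- list(registration = 1, deviation = 2, form = 2)
ev <- evaluate_model(mesh, fix, schema, "maxillary", config = cfg,
                     register = "none")
ev$linear_summary$occlusal_plane$mean     # -1.00 (% in-plane shrinkage)
ev$linear_summary$occlusogingival$mean    # -0.50 (% vertical shrinkage)
```

What the generator emulates — and what it does not: it reproduces the
*global* deformation modes (anisotropic shrinkage, symmetric basal bowing,
scanner-grade surface noise, arbitrary pose).  It does not model layer
staircase artifacts, local cure gradients, support marks, or scan-mesh
defects (holes, topological noise).  Passing closed-loop tests therefore
demonstrates that the *measurement pipeline* is unbiased and exact for the
modes it models, not that any physical printer behaves this way.

## Numerical choices and degenerate inputs

* **Sampling.**  Region surfaces are sampled area-weighted and uniformly at a
  seeded density (default 25 points/mm², ≈ a 0.2 mm grid; registration uses
  5 points/mm²).  All sampling, noise and jitter are deterministic given the
  seed, and the global RNG stream is left untouched.
* **Fixture evaluation frame.**  Fixtures generated without rigid jitter are
  already in the design frame; they are evaluated with `register = "none"`.
  Re-running a rigid ICP on an anisotropically *scaled* shape is a
  well-defined but slightly biased problem — the optimum rigid pose of a
  shrunken arch is not exactly the identity — and would perturb caliper spans
  at the 1e-3 % level, which is why the exactness checks bypass it while the
  rigid-recovery checks exercise it.
* **STL precision.**  Binary STL stores float32 (~2e-6 mm at this model's
  size); ASCII STL keeps more digits.  Exactness checks at the 1e-9 mm level
  are therefore run on in-memory meshes.
* **Label transfer.**  Test faces inherit the nearest reference face's region
  within a 0.5 mm cutoff; where back-to-back surfaces coincide (a crown's
  gingival face is coplanar with the base top), the nearest face with a
  compatible normal direction wins.
* **Degenerate inputs.**  Collinear point sets refuse a plane fit; meshes
  with degenerate principal axes fall back to centroid pre-alignment with a
  warning; empty region selections, unknown regions, non-positive densities
  and incomplete feature sets are errors; a negative caliper span (regions
  overlapping along the axis) is flagged as a measurement failure.
* **Ties and clamping.**  Colour bins are closed on the nominal band
  (|d| ≤ 0.05 mm is the middle bin) and clamp beyond ±0.50 mm; the bin
  assignment is monotone in the deviation.

## Known limitations

* **Extreme-point caliper bias under noise.**  Because the caliper's jaws
  contact the extreme point of each face, zero-mean surface noise biases
  every span upward by roughly twice the expected maximum of the contact
  displacements (≈ +0.024 mm at 0.02 mm noise on this tessellation, i.e.
  ≈ +0.26 % over the occlusal-plane features).  A physical caliper on a
  rough surface shares this behaviour.  Noisy closed-loop recoveries are
  therefore systematically smaller in magnitude than the true shrinkage;
  fitted-plane distances would remove the bias but would also ignore the
  warpage extremes a real caliper feels, so the extreme-point convention is
  kept and the bias documented.
* **Cuboid faces stay flat under smooth deformations.**  A quadratic warp
  moves the four corners of a rectangular face coplanarly, so SDC face
  flatness is exactly zero under pure warp and the flatness metrics respond
  only to noise-like deformation.  On real prints, flatness also reflects
  layer texture the generator does not model.
* **Rigid refits of scaled shapes are reproducible only to sampling fuzz**
  (~0.003 % on caliper spans at the densities used here), because individual
  sampled points can flip between triangles across otherwise identical runs.
* **The arch layout is a package default.**  Absolute arch dimensions
  (L1–L12) are self-consistent within the package but are not the dimensions
  of any published physical model.

## Problem sizes

The reference meshes have ~1000 triangles and ~530 vertices per jaw.  The
test suite and the worked examples run the pipeline at reduced sampling
densities (1–10 points/mm², i.e. 4 000–40 000 sampled points per jaw) chosen
so the closed-loop properties are established well below their tolerances;
report-quality runs use the 25 points/mm² default.  Closed-loop noise
statistics use 20 seeds.
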
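---
title: "Dual STN-SN trajectory planning: models, parameters and design choices"
author: "nigratarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual STN-SN trajectory planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigratarget)
```

## The problem and the pipeline

Deep brain stimulation of the subthalamic nucleus (STN) increasingly aims to
co-engage the substantia nigra (SN) — usually its pars reticulata (SNr) —
with the same electrode. Whether a standard STN trajectory also reaches the
SNr, the pars compacta (SNc), or neither depends on fine geometry: where the
trajectory crosses the axial plane of maximal red nucleus cross-section (the
max-RN plane), and at which angles it descends. `nigratarget` implements the
analysis that quantifies this: geometric feature extraction, atlas-based
engagement scoring with virtual lead extension, probabilistic targeting-rule
learning, and a logistic depth rule, together with a synthetic data generator
that makes the whole chain testable end to end.

All coordinates are millimetres in a right-handed RAS frame (x right, y
anterior, z dorsal). The native frame is built from the anterior and
posterior commissures (AC, PC) and a midline vertex point: y runs from PC to
AC, the midsagittal plane contains all three landmarks with its normal
oriented to the right, and z = x × y points dorsal. The AC-PC (axial) plane
contains the AC-PC line with normal along z.

## Trajectory geometry

The trajectory norm is the unit vector from the ventralmost to the dorsalmost
reconstructed contact — deliberately not a regression over all contacts,
because the two extreme contacts define the implantation axis in clinical
reconstructions and intermediate contacts add no information for a rigid
lead. For a direction $l$ and plane normal $n$, the angle
$\theta=\cos^{-1}(|l\cdot n|/\lVert l\rVert)$ is the line-to-*normal* angle;
the package reports the line-to-*plane* angle $90^\circ-\theta$, folded into
$[0^\circ, 90^\circ]$. This convention is the only one consistent with the
magnitudes clinicians quote for implantation angles (midsagittal angles near
20°, AC-PC angles near 50°); angles are reported unsigned.

The feature origin is the **Bejjani origin**. The construction is
operationalized as follows: in the max-RN axial slice (per hemisphere; ties
between equally large slices break toward the more ventral one), Bejjani's
line runs mediolaterally through the anterior-most ipsilateral red-nucleus
voxel center; the origin is the most medial STN voxel center lying within
±0.5 mm of the line's anterior-posterior coordinate. The ±0.5 mm band (two
voxels at the default resolution) makes the medial-border lookup robust to
rasterization; the published landmark description pairs the line with the
max-RN plane but does not give a voxel-level recipe, so this is the package's
own, deterministic one.

X (lateral) and Y (anterior) are the offsets of the trajectory's crossing of
the max-RN plane from this origin; left-hemisphere X is reflected so lateral
is positive in both hemispheres, which lets bilateral cohorts pool. Depth is
measured as *arc length along the trajectory* below the max-RN plane
(ventral-positive), not as a z-difference: a contact 2 mm below the plane on
a 60° trajectory is at depth 2/sin 60° ≈ 2.31 mm.

## Engagement model

- A contact engages a region when a **1 mm-radius sphere** around its center
  intersects the region; with overlap in both SN compartments the larger
  overlap wins, so a contact is SNr or SNc but never both. An exact non-zero
  tie is assigned to SNr with a warning — ties are measure-zero at fine voxel
  sizes, but the resolution must be deterministic and auditable.
- A trajectory engages every region some contact engages, so a trajectory
  *can* engage both compartments.
- **Virtual contacts** at 2, 4 and 6 mm of arc length beyond the implanted
  ventralmost contact emulate deeper implantation or larger array spans; the
  four scenarios (implanted only, +2, +4, +6 mm) are nested, so engagement is
  monotone across them by construction, and the tests verify it.
- Graded engagement uses **2 mm-radius VAT spheres** (the 1 mA
  approximation) and reports percent of VAT volume inside the region, binned
  by depth in half-open 2 mm bins $[c-1, c+1)$; empty bins are absent, not
  zero.
- The **central target (CT)** is built from the STN motor/associative
  boundary: STN voxels whose centers lie within 0.75 mm of any shared face of
  6-adjacent motor/associative voxel pairs, with the most ventral 50 % of
  that band removed. The retained set has exactly `ceiling(n/2)` voxels;
  voxels tied at the cut depth are admitted in linear-index order so the
  result is reproducible. The CT is stored as an overlay mask because its
  voxels already carry compartment labels.

Overlap volumes are estimated by **voxel-center inclusion** (count of region
voxel centers inside the sphere times the voxel volume) at the native atlas
resolution, 0.25 mm by default. This estimator is deterministic, fast, and
converges to the analytic volume as voxels shrink; the tests check sphere and
half-space cases at 0.5/0.25/0.125 mm. One caveat the tests make explicit:
for spheres whose center sits exactly on lattice symmetry points the counting
error is coherent and can reach ~4 % at r = 1 mm, 0.25 mm voxels, while for
generic (real-data-like) placements the mean error is well under 2 %.
Verification therefore uses generic placements.

## Targeting rules

Two **independent binary Gaussian process classifiers** are trained — one for
SNr engagement, one for SNc engagement — rather than a single SNr-vs-SNc
discriminator. The results this machinery emulates report separate accuracies
and separate confidence regions per compartment, which requires two models; a
mutually exclusive variant can be obtained by training on the SNr-vs-SNc
subset of trajectories, but it is not the default.

The classifier is written in this package: probit likelihood, anisotropic
squared-exponential kernel over the four z-scored features, and
**expectation-propagation (EP)** inference in the standard stable
`B = I + sqrt(S) K sqrt(S)` parameterization, run as damped parallel updates
(damping 0.7, site-parameter tolerance 1e-6, at most 80 sweeps, relative
kernel jitter 1e-6). The EP marginal likelihood and predictive probabilities
are validated in the tests against exact quadrature at tiny n, and the
predictive surface is cross-checked against an independent Laplace-type GP
classifier. Kernel hyperparameters (four log lengthscales, log signal sd)
maximize the EP marginal likelihood via Nelder-Mead with seeded restarts
(default 2 restarts, 40 iterations, warm-started EP between objective
evaluations). Because the features are z-scored, the fallback unit
lengthscale (`optimize = FALSE`) is already a sensible scale and is used in
quick tests.

Cross-validation is stratified 5-fold with pooled out-of-fold accuracy; the
confident subset comprises out-of-fold predictions with max-class probability
≥ 0.95. Hyperparameters are optimized once on the full training set and held
fixed across folds: this keeps the report deterministic and cheap, at the
cost of a mild optimism in fold accuracies (the folds still refit all EP site
parameters). The label-permutation null in the acceptance checks uses the
same fixed hyperparameters, so observed and null accuracies are compared
under the same procedure.

Probability maps evaluate a trained model on a grid with defaults X ∈ [-1, 3]
mm and Y ∈ [-2, 2] mm in 0.5 mm steps, MS ∈ [10°, 35°] and AC-PC ∈ [35°, 65°]
in 1° steps (configurable; the emulated analysis says only "a wide range").
Cells with probability ≥ 0.95 form the high-confidence region. Rule
extraction at a fixed (X, Y) panel returns the admissible angle cells plus
*conservative* threshold bounds: the largest axis-aligned angle box entirely
inside the region (exhaustive search over the panel grid), with bounds that
coincide with the grid edge dropped. Every angle pair satisfying the emitted
bounds is guaranteed confident; the converse is not attempted. Precision is
the fraction of held-out trajectories with predicted probability ≥ 0.95 that
truly engage the target; with none selected it is reported absent, never
zero.

Far from all training data a GP classifier reverts to its prior, probability
0.5 — a designed property (an unfamiliar trajectory yields "no
recommendation", not a confident extrapolation), verified at 10 and 100
lengthscales.

The **depth rule** is a logistic regression of in-SN status on arc-length
depth. By default each on-track trajectory (one whose infinite line meets the
SN at all, sampled at 0.1 mm steps) contributes its deepest implanted
contact: that is the quantity an implantation-depth rule prescribes, and it
avoids the non-monotonicity that all-contact observations introduce once
virtual contacts pass out the ventral side of the SN (an option retains the
all-contact variant). The 95 % depth is the closed form
`(logit(0.95) - intercept) / slope`; under perfect separation the slope gets
an L2 penalty of 1e-4 and the fit is flagged. Because the rule's depth
referent is ambiguous between contact center and contact lower border, both
are reported, the border 0.75 mm (half a standard 1.5 mm contact height)
deeper.

## The synthetic study generator

The generator defines the study conditions; it is not tuned per experiment.

**Anatomy.** Analytic ellipsoids rasterized at 0.25 mm isotropic voxels
(configurable): an STN (≈160 mm³) split by a posterodorsal oblique plane into
a motor compartment (35 % of voxels) and associative remainder; an SN
(≈370 mm³) ventral to the STN, split by a dorsomedial oblique plane (offset
1.2 mm from its center) into an SNc strip and the SNr remainder — so SNr and
SNc partition the SN and are disjoint by construction; a red nucleus
(≈230 mm³) medial and posterior, whose widest axial slice defines the max-RN
plane near z = -4.5. The left hemisphere is the mirror image of the right on
a grid symmetric about the midsagittal plane. Validity checks reject
anatomies with the RN not medial to the STN, the SN not ventral to it,
structures outside the volume, or an SNc split that empties either
compartment. No attempt is made at anatomical realism beyond this topology —
no deformable shapes, no MRI intensities, no inter-subject variability — so
passing tests demonstrate the *machinery*, not clinical performance.

**Cohorts.** Each lead draws an intent class (defaults: 55 % SNr-aimed, 32 %
SNc-aimed, 13 % off-target), features from per-class independent normals,
a lead model (uniform over the eight supported designs), a hemisphere, and an
implantation depth. SNr- and SNc-aimed feature means are the published cohort
means for engaging trajectories — (2.0 mm, 0.45 mm, 22.3°, 50.1°) and
(0.97 mm, -0.66 mm, 22.5°, 49.2°) — and the spreads are those means' standard
errors scaled back to population SDs using the class sizes a 612-trajectory
cohort implies (e.g. 0.07 × √373 ≈ 1.35 mm for X of SNr engagers). Only
per-feature SEMs are published, so features are sampled independently per
class; no covariance is emulated. The off-target class is displaced
anteriorly and, chiefly, implanted shallow — deepest contact ≈3 mm *above*
the max-RN plane — which reproduces the qualitative signature that complete
SN misses largely vanish under virtual extension. Per-class depth means are a
generator extension (the published material reports no depth distribution);
3.5 mm below the plane for SN-aimed classes is a typical ventral-STN
implantation in this geometry. Draws whose angle pair is geometrically
impossible (sin²MS + sin²AC-PC ≥ 0.98) are rejected and resampled with a log
message. Class intent is metadata only: ground-truth labels always come from
the engagement module.

Contact levels are modeled as points spaced by the catalog inter-level
spacing (0.5 or 1.5 mm; 4 or 6 levels); contact height is not modeled, which
understates physical array spans but preserves the standard/extended design
ordering the analysis stratifies on.

**Determinism.** A single integer seed drives everything; derived stage seeds
are computed from it. Identical seeds give byte-identical atlases, cohorts
and pipeline artifacts (no timestamps are written), which the tests verify.

## Numerical choices

- EP: damping 0.7, parallel sweeps, site precisions floored at 0, jitter
  `1e-6 * diag(K) + 1e-8`; cavity precisions floored at 1e-12.
- Hyperparameter search bounds: lengthscales in [0.05, 50] (standardized
  units), signal sd in [0.1, 20]; objective returns a large penalty outside.
- Ties: SNr/SNc overlap tie → SNr with warning; max-RN slice tie → ventral;
  CT median-depth tie → dorsal set in linear-index order.
- Degenerate inputs: zero-length directions, coincident extreme contacts,
  single-class labels, trajectories parallel to the max-RN plane, and
  Bejjani lines that miss the STN all raise errors with diagnostics rather
  than returning silently.
- Configuration files are YAML; a quirk worth knowing is that YAML 1.1
  resolves a bare key `y` to a boolean, so the reader maps such keys back to
  the `y` grid axis (quoting the key also works).

## Problem sizes

The test suite exercises the geometry oracles on 100 randomized instances
per operation, overlap convergence at 0.5/0.25/0.125 mm, and the full
study-scale properties on a 600-lead cohort at 0.25 mm (with a 1000-lead
held-out cohort for rule precision and a 19-permutation label null); the
packaged demo configuration runs 40 leads at 0.5 mm. These sizes were chosen
so the complete suite runs in minutes on a single CPU while keeping the
cohort at the scale of the clinical dataset the pipeline emulates.

## Limitations

- The synthetic anatomy is topologically, not morphometrically, faithful;
  absolute engagement rates and depth thresholds depend on the ellipsoid
  geometry and should not be read as clinical estimates. The clinical
  headline numbers came from a 306-patient cohort this package does not have.
- Overlap estimation ignores partial-volume effects at the atlas resolution.
- The VAT model is a single fixed 2 mm sphere (1 mA); no amplitude-radius
  curve, field model, or directional steering is implemented.
- Image registration, electrode artifact localization and brain-shift
  correction are upstream of this package: it consumes reconstructed
  coordinates.
- The GPC assumes smooth class boundaries in feature space; with very small
  or single-class cohorts training refuses rather than extrapolating.
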
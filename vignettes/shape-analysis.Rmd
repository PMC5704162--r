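---
title: "Statistical shape analysis of hippocampal contours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape analysis of hippocampal contours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoMorph)
```

This vignette is the package's own account of its science: the model each
stage implements, the assumptions behind it, the defaults and why they
were chosen, and what the synthetic validation does and does not
establish about real clinical data.

## Data model and coordinate conventions

A `ContourReading` is one hand-drawn closed outline of a hippocampus on a
coronal section: at least four planar points in y-up Cartesian
millimetres, closed implicitly (the first point is never repeated), with
K fiducial markers — anatomically defined anchor points on the formation,
fissure and temporal-horn boundaries — stored as indices into the point
list. Orientation is normalized to counter-clockwise on load, and every
contour must be a simple polygon; both properties are enforced by the S4
validity method, so invalid annotations fail at construction with the
record named. Ingestion from pixel coordinates multiplies by the isotropic
pixel spacing and flips the y axis, decoupling the analysis from
image-display conventions. The number of fiducials is not fixed by the
data model; the synthetic template and all defaults use K = 4.

## Contour regularization

Hand-placed points are too irregular to correspond across readings, so
each contour is re-expressed as N regularized control points:

* a periodic C² cubic interpolating spline (`stats::splinefun`,
  `method = "periodic"`) is fitted through the points, parameterized by
  cumulative chord length;
* the spline is re-sampled by arc length, per fiducial segment: the
  output point at each fiducial slot coincides with the spline position
  of that fiducial, and points between consecutive fiducials are equally
  spaced in arc length. Spacing points per segment rather than globally
  keeps the anatomically labelled stretches of the outline in
  correspondence even when readers sample them with very different
  densities.

Arc length is integrated from the spline speed with 16-node
Gauss–Legendre panels aligned with the spline knots, where the integrand
is smooth; panel alignment makes the fixed-order rule accurate to about
1e-14 relative, comfortably below the 1e-8 tolerance the pipeline
guarantees, and it vectorizes over a whole cohort. Inverting the
arc-length function uses safeguarded Newton iterations on the panel
cumulative sums, converging to 1e-13 of the total length. Exact duplicate
consecutive points are collapsed with a warning; fewer than four distinct
points is an error.

The default N = 20 (40 degrees of freedom per contour) matches the
delineation protocol the package targets. Fiducial slots are frozen once
per cohort at `1 + round(N * f_k)`, where `f_k` is the mean cumulative
arc-length fraction of fiducial k over all readings — correspondence
requires every shape to use identical slots, and the first-pass mean is
the natural cohort-level summary.

## Procrustes alignment

Generalized Procrustes analysis removes location, scale and orientation:
each shape is centred, scaled to unit centroid size (RMS distance of
points to centroid = 1), and rotated to the current mean; the mean is
recomputed and renormalized until it moves by less than `tol` (default
1e-10, at most 100 iterations). Scale is removed — not just rigid
motion — because overall size is exactly the nuisance the area-based
screening convention is criticized for; group differences are therefore
expressed purely through shape. Reflections are never permitted (the
closed-form planar rotation is constrained to determinant +1): left and
right hippocampi are genuinely chiral and are modelled separately, with
`mirrorShapes()` available for deliberate pooling experiments.

Two numerical conventions deserve a note:

* **Gauge.** A Procrustes solution is defined only up to one global
  rotation. The package fixes it from the converged mean itself —
  the mean's first fiducial (the most superior marker in the synthetic
  template's convention) is rotated onto the positive y axis. Because
  the gauge depends only on the mean's own geometry, the aligned set is
  invariant to any common similarity transform of the inputs and to
  their ordering; an anchor chosen from one input shape would not be.
* **Tangent space.** The models operate on raw aligned coordinates;
  `tangentProject()` offers the Kendall tangent-space correction but is
  off by default, matching the small shape variation regime where the
  two agree to high order.

## The Karhunen–Loève shape model

PCA of the aligned shape vectors about their mean gives the linear
point-distribution model x = x̄ + P_s b_s. The decomposition runs on the
n × 2N data matrix through the singular value decomposition (stable when
2N exceeds n), covariance divisor n − 1, retaining min(2N, n − 1) modes.
Eigenvector signs are fixed so each column's largest-magnitude component
is positive, making parameter signs reproducible across platforms. Mode
counts are always chosen through the explained-variance threshold
(default 0.95), never hard-coded: the number of modes a cohort needs is
an empirical property of that cohort. Mahalanobis distances between
parameter vectors exclude near-degenerate modes
(eigenvalue < 1e-12 × the leading one).

## Model-space consensus

Vertex-wise averaging of discordant readings can produce illegal,
self-intersecting contours: at the same position along the curve one
reader may be tracing the formation while another is already in the
fissure. Repeated readings are therefore projected onto the model,
averaged in parameter space, and back-projected, which confines the
consensus to the model's span of legal shapes. The average is two-stage —
repeats within each reader first, then across readers — so a reader who
repeated three times does not outweigh one who repeated twice; the
repeat counts are small and uneven by design of the delineation
protocol. Averaging uses a truncated parameter vector (the same M later
offered to the classifier, computed as the larger of the sweep limit and
the 95% mode count); because the basis is orthonormal, averaging then
truncating equals truncating then averaging, so the choice only affects
how much out-of-span detail the stored consensus shape retains.

## SVM discrimination and the mode sweep

A soft-margin SVM with the linear kernel K(s) = γs + β (γ = 1, β = 0)
discriminates the two groups from the first M consensus parameters,
control = −1 and early-AD subject = +1; a decision value of exactly zero
maps to control, so the degenerate tie never inflates patient calls. The
quadratic program is solved by libsvm (through `e1071`) at tolerance
1e-6; inputs are canonically sorted before training, making the fit
deterministic and order-independent. Parameters are standardized
(per-column mean and standard deviation, stored in the model and
re-applied at prediction) before the margin: aligned shapes live on the
unit-centroid-size scale, where raw parameters are of order 0.1 and an
unstandardized margin penalty at the default cost of 1 would dominate
the hinge loss and collapse the classifier to the majority class.
Standardization is also what mainstream SVM front ends do by default, so
"default parameters" retain their usual meaning. Cost stays at 1; no
higher-order kernels are provided — the parameter space is already the
span of the leading covariance directions, and a hyperplane there is the
model's entire point.

The sweep trains and evaluates at every M = 1..M_max (default 10) and
records the two-view confusion counts and metrics. Resubstitution is the
default evaluation protocol because it is the historical convention for
this analysis — it is flagged as optimistic wherever it surfaces, and a
seeded k-fold mode (k = 5) is the honest alternative for data without a
held-out set. `selectOptimum()` averages sensitivity, specificity,
precision, accuracy and F-measure over both class views and returns the
smallest maximizing M: when several model complexities explain the data
equally well, the simplest prevails.

## Evaluation conventions

Counts are reported per class view — controls as positives (view C) and
subjects as positives (view S) — under the mirrored convention
TN_v = TP_v, FP_C = FN_S, FP_S = FN_C. This is implemented as the
package's reporting convention because it is the only reading that
reproduces the published screening tables the package ships as reference
counts; a textbook mode (`mirror = FALSE`) exists for external
comparability. Overall statistics are percent correct, Cohen's kappa
from the reconstructed 2×2 contingency, the 0/1-loss identities
MAE = misclassified/total and RMSE = √MAE, and relative errors against a
prior-probability baseline predictor whose per-instance absolute error
is the prior of the wrong class (baseline MAE 2·p_C·p_S, baseline RMSE
√(p_C·p_S)). The published relative errors follow a tool-specific
convention that this documented baseline matches only approximately
(within ~0.01 of a percentage point), so those two numbers are
explicitly not reproduction targets. Ratios of 0/0 are reported as 1
with a warning; they occur only in degenerate fixtures.

The area benchmark reproduces the conventional single-measurement rule:
per-subject Cartesian mean of trapezoidal contour areas, a Gaussian fit
per group, and an overlap count — the subjects misclassified by the
unequal-variance Gaussian likelihood-ratio rule, i.e. those falling in
the ambiguous overlap of the two area histograms.

## The synthetic cohort generator

The generator exists so that every stage is testable without the
(non-public) clinical contours. It emulates the study's statistical
structure, not its images:

* **Template.** A star-shaped, comma-like outline built analytically
  from an ellipse (semi-axes 10 × 7 mm) with a smooth Gaussian
  indentation (depth 2 mm, angular half-width 0.35 rad) standing in for
  the choroid fissure; four fiducials at fixed parameter fractions
  partition it into formation, stem-side, fissure and temporal-horn
  segments. Star-shapedness guarantees simple polygons under all default
  deformations.
* **Group structure.** 30 controls vs 33 early-AD subjects; per-subject
  latent factors formation height (control mean 1.0, subject mean 0.85,
  sd 0.05) and fissure width (1.0 vs 1.20, sd 0.07), pulling the
  subject group toward a flatter formation and wider fissure. Both
  sides share the subject's latent values; the right side is the
  mirrored template with independent noise.
* **Readings.** 3 readers × 2–3 repeats; each reading hand-samples 7–10
  points per fiducial segment with jittered spacing, adds smooth reader
  noise — a 4-harmonic Fourier perturbation along the radial direction
  (sd 0.4 mm), because hand tracings err in correlated sweeps, not
  pointwise — and applies similarity pose jitter (translation sd 2 mm,
  rotation sd 0.1 rad, scale sd 0.05). The pose magnitudes are
  order-of-magnitude choices for re-fixated single-slice annotations;
  the true inter-reader variance of the original study is unreported,
  so the defaults are exposed in `simulationConfig()`.
* **Seeding.** All randomness flows from one base seed through
  documented integer substreams per subject, side, reader and repeat,
  so any part of a cohort regenerates stably.

What passing the synthetic suite shows — and what it does not: the
pipeline recovers known generative structure, calibrates to chance on
null cohorts, and reproduces published metric tables exactly. It does
not certify accuracy on real CT delineations, whose reader behaviour,
boundary ambiguity and pathology spectrum the template only caricatures.

One identifiability caveat worth stating explicitly: the two latent
deformation directions are not orthogonal in Procrustes shape space
(both change centroid size, and alignment re-mixes what remains), so PCA
can only recover their span, not the factors individually — no single
mode matches the fissure factor even at negligible noise.
`recoveryExperiment()` therefore reports both the best single-parameter
correlation and the multiple correlation of each latent factor on the
leading five parameters; the recovery validation asserts the latter, at
a low-noise condition (reader noise 0.05 mm) where the span is cleanly
estimable. At the default 0.4 mm reader noise the eight smooth noise
harmonics are comparable to the group effects, and the reading-level
model needs around eight modes for 95% variance — the same order as the
clinical cohort's nine to ten.

## Numerical choices, sizes and limitations

* Tolerances: spline arc-length 1e-8 relative (achieved ~1e-13); GPA
  mean change 1e-10; SVM QP 1e-6; model container round-trip at full
  double-text precision.
* Problem sizes in the tests and acceptance script: the default
  63-subject cohort (~950 bilateral readings, ~470 per side), one
  low-noise recovery run, one null cross-validation run; the whole suite
  and the acceptance script each complete in well under a minute of CPU
  on one core.
* Degenerate inputs: all-identical points are rejected in alignment;
  single-class training sets are rejected; empty cohorts read and write
  cleanly; 0/0 metrics warn and report 1.
* Known limitations: no outlier-reading rejection (consensus averages
  everything); no nonlinear shape models; no image processing of any
  kind — the package starts at annotated contours; resubstitution
  optimism is inherited from the historical protocol and must be kept
  in mind when quoting sweep accuracies.
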
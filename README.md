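# hippoMorph

Statistical shape analysis and linear-SVM discrimination of hand-drawn
hippocampal contours.

## The problem

Early Alzheimer's disease shows up in the medial temporal lobe as subtle
morphology changes — the hippocampal formation flattens and the choroid
fissure widens — long before they are obvious to a reader scoring single
measurements such as formation height or area. Where high-end MRI is not
available, screening has to work from a hand-drawn outline of each
hippocampus on a single coronal CT section, drawn by several readers who
disagree with each other and with themselves. `hippoMorph` provides the
full analysis chain for such data: it turns noisy, irregularly sampled
closed contours into a compact statistical shape model, collapses
repeated readings into one anatomically legal consensus per subject, and
discriminates patient from control groups with a linear support vector
machine over a handful of shape parameters.

## The model

Each delineation is a closed planar polyline with K fiducial markers
(anatomically defined anchor points). The pipeline is:

1. **Regularization** — a periodic C² cubic spline is fitted through the
   hand-placed points and re-sampled by arc length into N corresponding
   control points (default N = 20, i.e. 40 degrees of freedom), anchored
   so that fiducial k always lands on the same output slot. A shape is
   then the vector **x** = (x₁, y₁, …, x_N, y_N)ᵀ.
2. **Alignment** — generalized Procrustes analysis removes translation,
   scale and orientation (similarity superimposition, reflections
   disallowed; left and right sides are modelled separately).
3. **Shape model** — PCA of the aligned shapes gives the Karhunen–Loève
   point-distribution model **x** = x̄ + P_s **b**_s, truncated to the
   smallest M modes holding a target variance fraction (default 95%).
4. **Consensus** — repeated readings of one hippocampus are averaged in
   model-parameter space (repeats within reader first, then across
   readers) and back-projected, so the consensus is always inside the
   model's span of legal shapes — vertex-wise Cartesian averaging of
   discordant readings can self-intersect.
5. **Classification** — a soft-margin SVM with the linear kernel
   f(**x**) = sgn[Σᵢ αᵢyᵢ K(**x**ᵢ·**x**) + b], K(s) = γs + β, is
   trained on the first M shape parameters (control = −1, subject = +1);
   a sweep over M = 1..M_max locates the operating optimum by averaging
   sensitivity, specificity, precision, accuracy and F-measure over both
   class views.
6. **Evaluation** — confusion counts are kept in the two-view mirrored
   reporting convention used in the screening literature (TN_v = TP_v,
   FP_C = FN_S, FP_S = FN_C), with Cohen's kappa, 0/1-loss MAE/RMSE and
   prior-baseline relative errors; a trapezoidal-integration area
   benchmark reproduces the conventional single-measurement screening
   rule the shape model is compared against.

Because the clinical contours behind the shipped reference tables are not
public, the package includes a first-class synthetic cohort generator:
a comma-shaped template deformed by per-subject latent factors
(formation-height shrinkage, fissure widening), sampled per reading with
pose jitter and smooth correlated reader noise, for 30 controls vs 33
subjects, 3 readers × 2–3 repeats, both sides.

## Worked example

```r
library(hippoMorph)

gen  <- generateCohort(simulationConfig(seed = 1))
gen$cohort
#> ShapeCohort with 948 readings: 63 subjects, sides {left,right}, 3 readers

pipe <- runPipeline(gen$cohort, side = "left")
pipe$model
#> ShapeModel (left side): 40 modes from 473 shapes of 20 points
#>   95% of variance in 8 modes

pipe$optimumM
#> [1] 7

round(subset(pipe$sweep@table, M %in% c(1, 3, 7),
  select = c(M, TP_C, TP_S, FN_C, FN_S, percentCorrect, kappa)), 4)
#>  M TP_C TP_S FN_C FN_S percentCorrect  kappa
#>  1   28   28    2    5        88.8889 0.7783
#>  3   27   31    3    2        92.0635 0.8407
#>  7   30   33    0    0       100.0000 1.0000
```

Reading the output: 8 of 40 modes describe 95% of the delineation
variability across all 473 left-side readings; after model-space
consensus, the averaged-indices rule puts the operating point at M = 7
shape parameters, where every one of the 63 consensus hippocampi is
classified correctly at resubstitution (an optimistic protocol — pass
`evaluation = "k_fold"` for cross-validation). The metric conventions
themselves can be driven directly from published count tables:

```r
counts <- referenceSweepCounts()
i <- which(counts$side == "left" & counts$M == 3)
cc <- ConfusionCounts(counts$TP_C[i], counts$TN_C[i], counts$FP_C[i], counts$FN_C[i],
                      counts$TP_S[i], counts$TN_S[i], counts$FP_S[i], counts$FN_S[i])
str(overallMetrics(cc))
#> List of 6
#>  $ percentCorrect: num 95.2
#>  $ kappa         : num 0.905
#>  $ mae           : num 0.0476
#>  $ rmse          : num 0.218
#>  $ rae           : num 9.55
#>  $ rrse          : num 43.7
```

A thin command-line wrapper over the same stages lives in
`inst/scripts/hippomorph-cli.R` (subcommands `simulate`, `resample`,
`align`, `fit`, `consensus`, `sweep`, `evaluate`, `report`).

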
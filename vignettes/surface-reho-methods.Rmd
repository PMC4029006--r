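---
title: "Surface regional homogeneity: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface regional homogeneity: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReHoSurf)
```

This vignette is the package's own account of the statistics it
implements: the concordance model behind 2dReHo, the inference machinery
around it, what the synthetic-data generator does and does not emulate,
and the numerical and design decisions that were genuinely open.

## The statistic

Regional homogeneity asks how synchronously a small neighborhood of the
cortex fluctuates at rest. On a surface mesh the natural neighborhood is
the k-ring of the vertex graph; with `ring = 2` a regular (valence-6)
vertex contributes 19 time series — itself, its 6 first-ring and 12
second-ring neighbors. Their agreement is Kendall's coefficient of
concordance with midranks and the standard tie correction,

$$W \;=\; \frac{12\,\sum_t \bigl(R_t - m(n+1)/2\bigr)^2}
               {m^2(n^3-n) \;-\; m\sum_j T_j},
\qquad T_j = \sum_g \bigl(t_g^3 - t_g\bigr),$$

for $m$ series ranking $n$ timepoints. $W$ lives in $[0,1]$; for
independent series $E[W] = 1/m$ (so $\approx 0.053$ for 19 series), a
useful null anchor that the test suite checks by simulation. For
tie-free data $W$ is algebraically identical to
$((m-1)\,\bar r_s + 1)/m$, with $\bar r_s$ the mean pairwise Spearman
correlation; the suite uses that identity as an independent oracle
rather than as the implementation.

Two deliberate readings, where the neighborhood convention is not
uniquely determined by the field's usage:

* "Nearest neighbors" is taken as graph rings, not geodesic distance,
  and the 19-series count is center-inclusive (1 + 6 + 12). At the 12
  valence-5 apices of an icosphere the 2-ring has 16 members; the
  neighborhood is whatever the 2-ring yields rather than being forced to
  19, since graph rings are the natural surface construct and reproduce
  19 exactly at regular vertices.
* The global summary is the **unweighted** vertex mean; an area-weighted
  mean is available (`globalReHo(map, mesh, areaWeighted = TRUE)`) but is
  not the default.

Degenerate neighborhoods (all series fully tied) return 0 with a warning
instead of erroring, so a masked or flat vertex cannot abort a whole
cohort run.

## Preprocessing

The chain follows the conventional resting-state order — discard 5
equilibration volumes, normalize the grand mean to 10,000, regress 26
nuisance signals (the Friston-24 motion expansion: 6 parameters, their
one-sample lags, and both sets squared, zero-padded at $t=0$; plus two
tissue means), band-pass 0.01–0.1 Hz, then remove linear and quadratic
trends. Each stage is exposed separately and the composition is tested
against the hand-chained stages.

Numerical choices:

* The band-pass is an **ideal (hard) Fourier filter** with inclusive
  band edges: DFT bins with frequency strictly outside
  $[f_{low}, f_{high}]$ are zeroed. This gives a bit-exact, idempotent
  contract (`filter(filter(x)) == filter(x)`), at the cost of the usual
  ringing for components off the bin grid; no filter family is canonical
  for this step, and reproducibility was preferred.
* Framewise displacement uses absolute backward differences, rotations
  converted to millimetres on a 50 mm sphere, summarized as the root
  mean square over frames (the plain mean is behind
  `summary = "mean"`). The rigid-body-matrix formulation is a known
  alternative; the backward-difference form is implemented and labeled
  as the package's choice.
* Motion parameters and tissue signals are *inputs*: realignment,
  tissue segmentation and surface projection are out of scope.

## Group inference

Each vertex gets an OLS fit of ReHo on
`[intercept, group, gender, age, ICV, rmsFD, mcBBR, global ReHo, JAC(v)]`;
the group t statistic has $n - p$ degrees of freedom. With no covariates
this reduces exactly to the pooled two-sample t-test (tested to 1e-10).
Because the JAC column differs per vertex, the engine precomputes, per
vertex, an orthonormal basis of the design and a contrast weight vector;
all per-permutation work is then elementwise matrix algebra across
vertices, which is what makes hundreds of permutation nulls per cohort
affordable in pure R.

Cluster-extent correction thresholds the t map two-sided at
$p_{vertex} = 0.01$, separately for increases and decreases, and forms
edge-connected clusters. The null is built by **Freedman–Lane**
permutation: residualize the maps against the covariate-only model,
permute residual rows, add back the reduced fit, refit the full model,
and record the **maximum suprathreshold cluster area over both signs**.
Each observed cluster receives
$p = (1 + \#\{\text{null max} \ge \text{area}\})/(1 + n_{perm})$.
Distribution-free permutation was chosen over Monte-Carlo smoothness
simulation because no smoothness estimate is needed or available on
synthetic data; cluster *area* (not peak height) is the extent statistic.
Sign-separated clusters compared against the both-signs maximum control
the family-wise error jointly across increases and decreases. One mesh is
analysed at a time; pooling hemispheres is the caller's concern.

Calibration measured by the test suite: over 200 null cohorts
(642-vertex mesh, 10 + 10 subjects, 100 timepoints, 500 permutations)
the family-wise positive rate falls in the expected band around 0.05,
with the mild conservatism typical of residual-permutation schemes at
$n = 20$; on identical data the Freedman–Lane and simple row-permutation
nulls give nearly identical minimum corrected p distributions.

## Behavior and association

Conflict scoring implements the printed formulas literally: mean
correct-trial RT of incongruent minus congruent trials; the ratio uses
the mean RT over **all** correct trials of all 12 cue-by-target cells
(a per-conflict-condition denominator is behind
`denominator = "conflict"`); accuracy conflict uses all presented trials
of the two conditions. Training-block trials are never scored. Alerting
and orienting are computable but off by default.

Partial correlation residualizes both variables on the covariates (with
intercept; a binary covariate such as gender enters as a 0/1 regressor)
and correlates the residuals, $df = n - 2 - k$. Log transforms are
natural logs; the practice-hours outlier rule is an absolute threshold
defaulting to 30 h/week (a Tukey 3×IQR rule is behind `rule = "iqr"`),
and p-values are reported unadjusted by default with a
Benjamini–Hochberg option. The per-cluster summary feeding the
correlations is the cluster-mean ReHo.

## The synthetic generator

The generator emulates the cohort design the pipeline targets: 22
experts and 18 controls with group-matched demographics (ages
52.4 ± 6.8 / 54.8 ± 6.8, education ≈ 12 y, ICV ≈ 1.1 L), expert practice
history (14.6 ± 8.6 years, 11.9 ± 5.1 h/week) with one injected
≥ 30 h/week practitioner for the exclusion rule to find, 243 volumes at
TR = 2 s, and 642-vertex icosphere surfaces standing in for the
registered cortical meshes.

Local synchrony is planted by **signal mixing**, not smoothing: inside a
patch with weight $\lambda$, vertex $v$ emits
$\sqrt{1-\lambda}\,\varepsilon_v + \sqrt{\lambda}\,c_p$ with
$\varepsilon_v$ independent band-limited (0.005–0.15 Hz, pink-weighted)
noise and $c_p$ a patch-shared signal. Mixing maps monotonically to $W$,
which is what makes recovery tests meaningful; the noise band
deliberately exceeds the 0.01–0.1 Hz analysis band so the band-pass
stage does observable work. A patch of sign +1 is mixed into experts
only (homogeneity increase), sign −1 into controls only.

Each subject additionally draws a **global synchrony weight**
(mean 0.12, SD 0.05, truncated to [0, 0.35]) mixing one subject-specific
signal into every vertex. This reproduces the between-subject spread of
global homogeneity seen in real cohorts. It matters at desk scale: on a
642-vertex mesh a 19-vertex patch is ~3% of the surface (on a real
20,000-vertex hemisphere a comparable cluster is ~0.1%), so without
subject-level global variance any planted patch would make the global
group test spuriously significant and the global-ReHo covariate nearly
collinear with the group column.

Two tissue signals leak uniformly into all vertices (weight 0.3) and are
exactly removable by the nuisance stage; motion is a bounded random walk
whose step sizes put rmsFD near 0.13 mm; JAC maps are smooth fields near
1. ANT sessions are one 24-trial training block plus three 96-trial test
blocks, balanced over the 12 cells and shuffled within block;
RTs are shifted-lognormal with cue and target offsets, capped at the
1700 ms response window, and a subject's conflict effect is
`conflictMs + linkCoef × (group-centered patch ReHo)` plus noise — a
negative `linkCoef` (default −300 ms per unit ReHo) plants
"more homogeneous patch, faster conflict resolution" *within* each group
without shifting group means.

What the generator does **not** emulate: hemodynamic response shapes,
spatial autocorrelation of the noise floor (outside planted patches,
vertices are independent), scanner drift and physiological artifacts
beyond the two tissue signals, realistic cortical geometry, or
performance floors/ceilings in behavior. Passing recovery tests
therefore demonstrates that the estimator and inference chain do what
they claim on data satisfying their assumptions — not that those
assumptions hold in any particular empirical dataset.

## Problem sizes used by the simulation tests

The calibration and recovery suites run at deliberately modest sizes,
chosen once as the smallest designs that keep the Monte-Carlo error
useful: 200 null cohorts of 10 + 10 subjects × 100 timepoints with 500
permutations for family-wise error; 50 cohorts of 20 + 20 subjects with
one λ = 0.5 patch and 250 permutations for recovery (Dice ≥ 0.3 against
the planted patch); 2000 draws for the Kendall-W null mean; 200
replicates at n = 21 for partial-correlation calibration. Inside the
null/recovery loops the generator's series feed `rehoMap()` directly —
their noise is already band-limited and tissue-free there, and the
preprocessing contracts are tested separately — so the loops measure the
inference machinery, not the filter chain. The end-to-end test runs the
full chain at the study design scale (22 + 18 × 243 volumes, 500
permutations).

## Known limitations

* The ideal filter's hard band edges are not what FSL/AFNI butterworth
  or FIR filters do; results near the band edges will differ from those
  toolchains.
* Freedman–Lane with few subjects is mildly conservative; permutation
  counts below ~500 limit the resolution of corrected p-values.
* Graph rings approximate geodesic neighborhoods; on strongly
  anisotropic meshes the 2-ring is not isotropic in millimetres.
* The global-ReHo covariate competes with group when planted effects
  occupy a non-trivial fraction of the surface; this is a property of
  the model, and at realistic surface resolutions the fraction is tiny.
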
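---
title: "Connectome deviation analysis with idfc: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome deviation analysis with idfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idfc)
```

## The deviation statistic

`idfc` quantifies how far an individual's resting-state functional
connectome lies from a reference cohort. For subject $i$ and region $k$, the
connectivity profile $F_{ik}$ is row $k$ of the subject's ROI-by-ROI Pearson
correlation matrix — the correlations of region $k$ with the other regions.
The inter-individual deviation of functional connectivity (IDFC) is the mean
cosine distance to every reference subject $j$:

$$ V_{ik} \;=\; \frac{1}{n}\sum_{j=1}^{n}\left( 1 -
\frac{F_{ik} F_{jk}'}{\sqrt{(F_{ik}F_{ik}')(F_{jk}F_{jk}')}} \right). $$

Negative correlations are zeroed before profiles are formed (their
physiological interpretation at rest is contested), so profiles are
nonnegative and every deviation lies in $[0, 1]$. Cosine distance is
scale-invariant: a global scaling of a subject's connectivity leaves its
deviations unchanged, so the statistic reacts to the *shape* of a region's
connectivity profile rather than its overall magnitude. Region-level
deviations are averaged within networks to give a subjects-by-networks
matrix, the feature space for subtyping.

Two conventions here are genuinely open and are exposed as toggles:

* **Self-entry.** The profile of region $k$ excludes the self correlation by
  default (`drop_self = TRUE`). The constant diagonal carries no
  inter-subject information and would compress cosine distances toward
  zero; including it is supported for comparability.
* **Zero-norm profiles.** If every correlation of a region is negative,
  zeroing leaves a zero profile and the cosine distance is undefined. The
  default is an error naming the subject and region; the alternative policy
  (`zero_norm = "max"`) assigns the maximum distance 1. A silent convention
  either way would bias the mean, so the choice is explicit.
* **Negative correlations.** `keep_negatives = TRUE` runs the whole pipeline
  on raw matrices (distances then live in $[0, 2]$), the standard
  sensitivity re-analysis for the zeroing convention.

Within-group heterogeneity uses the same kernel with the group itself as
reference, omitting the self-pairing ($i \neq j$). Contrasting the
patient-group and control-group heterogeneity maps region by region asks
whether patients are more *dissimilar from one another* than controls are,
independently of any mean-level difference.

## Group comparisons

Edge-level, network-level, and whole-brain comparisons all run on Fisher
z-transformed matrices ($z = \operatorname{artanh} r$, variance-stabilizing),
computed from the raw matrix with negatives retained; the zeroing convention
belongs to the deviation path only, and the two paths are kept distinct. The
"two-sample t test with covariates" is implemented, per unit, as the t
statistic of the group coefficient in an ordinary least-squares model
(intercept + group indicator + encoded covariates) — the standard way to
combine a two-group contrast with nuisance adjustment; without covariates it
reduces exactly to the textbook pooled two-sample t, a property the test
suite checks at tolerance 1e-10. Region- and network-scale families are
controlled with Benjamini–Hochberg at $q = 0.05$ (the field default when
"FDR" is stated without a dependency adjustment); the three whole-brain
comparisons use Bonferroni, threshold $0.05/3$ stored at full precision and
conventionally displayed as 0.017. Network blocks average z over all edges
between two networks (within-network blocks: the block's upper triangle);
whole-brain is the mean over all upper-triangle z values. Covariate
encoding: continuous covariates standardized, categorical ones one-hot with
the first level dropped, intercept always included; a rank-deficient design
is an error naming the collinear columns, never a silent drop.

## Subtyping

Network-level deviations are first residualized against age, FIQ, mean
framewise displacement, handedness, eye status and site; residuals are
orthogonal to every regressor and the operation is idempotent. k-means
(Euclidean, best of `n_restarts = 100` random multi-restarts, up to 300
iterations) is scanned over $k = 2..20$ and scored by the mean silhouette;
the smallest $k$ attaining the maximum wins (parsimony tie-break). We use
stock multi-restart k-means rather than a greedy seeding scheme: with 100
restarts on a 60-to-105-subject, 11-feature problem the best-restart
solution is stable under the fixed seed, and the simpler procedure is easier
to audit. Labels are canonicalized by descending cluster size so "subtype 1"
is always the largest cluster. Subtype balance on demographics uses pooled
two-sample t tests (continuous) and chi-squared tests (categorical), with
the site-by-subtype table reported alongside its test; symptom scores are
tested only on subjects that have them.

## Brain–behavior prediction

A linear $\varepsilon$-insensitive support-vector regression
($\tfrac12\lVert w\rVert^2 + C\sum_i \max(0, |w x_i + b - y_i| -
\varepsilon)$) predicts a symptom subscore from the residualized network
deviations, with $C = 1$, $\varepsilon = 0.1$ and no inner tuning loop —
fixed defaults, surfaced as arguments, since nested model selection is not
part of the procedure. Evaluation is leave-one-out:
features are standardized on each training fold and the held-out subject is
transformed with the training statistics, so nothing leaks; $R$ is the
Pearson correlation between observed scores and the out-of-fold predictions,
and per-network weights are averaged over the $n$ fold models. Significance
comes from rerunning the entire LOOCV on shuffled targets: the reported $p$
is the literal exceedance ratio $\#(R_p > R)/n_\text{perm}$ with
$n_\text{perm} = 1000$ by default. That estimator can return exactly 0 (a
flag marks this), so the $(b+1)/(n+1)$ variant is emitted alongside for
anyone who prefers a strictly positive estimate. Subjects missing the score
are dropped, never imputed.

## The synthetic cohort generator

`generate_cohort()` builds the cohort every validation runs on: a base
block-structured correlation matrix (within-network 0.5, between-network
0.15 by default), a hypoconnected subtype shifting every off-diagonal entry
by $-\delta$ and a hyperconnected one by $+\delta$ ($\delta = 0.12$),
per-subject symmetric edgewise jitter (sd 0.06), and projection back to the
nearest valid correlation matrix (Higham-style alternating projections,
tolerance 1e-8). Default sizes mirror a two-site-matched childhood cohort:
47 + 58 patients, 102 controls, 264 ROIs in 10 functional networks plus an
uncertain-assignment network. A time-series mode draws multivariate normal
series from the target covariance instead, so the sample correlation
converges to the target as the series lengthens; the matrix mode is the
default because the analysis consumes correlations.

Choices worth explaining:

* **Per-subtype heterogeneity scale.** Each subject's shift is drawn around
  the subtype mean with sd `shift_sd = c(0.005, 0.05)`. The deviation metric
  responds very steeply on the hypo side — at $-\delta$ the between-network
  correlations approach the zeroing threshold, where small shift differences
  produce large angular changes — and shallowly on the hyper side. The two
  scales give both subtypes meaningful, recoverable subject-level variation:
  tight enough on the steep side that the subtypes remain separable
  (roughly a six-sigma gap in deviation space), wide enough on the shallow
  side that the behavior link has signal above the estimation noise.
* **Matched covariates.** Age, FIQ and mean FD are stratified draws per
  planted group (each group samples the same distribution with near-identical
  empirical moments); handedness, eye status and site use largest-remainder
  allocation of the same frequencies in every group. This emulates a
  demographically *matched* cohort — the study design the analysis assumes —
  and matters statistically: with covariates drawn independently, chance
  correlation between ~11 regressors and the latent subtype indicator at
  $n = 60$ absorbs a noticeable fraction of the between-subtype separation
  during residualization and re-injects it as within-cluster spread.
* **Planted behavior link.** Symptom scores are a linear map of the
  *standardized noise-free* network deviations of the driving subtype plus
  Gaussian noise (sd 0.5): communication severity is driven by the
  hypoconnected subtype, restricted/repetitive behavior by the
  hyperconnected one, and the social score carries no signal.
  Standardization keeps the planted signal-to-noise ratio interpretable and
  equal across subtypes despite the asymmetric deviation response. Scores
  exist for 82/105 of patients, mirroring typical ADOS availability.
* **What is not simulated.** No site batch effects beyond the site label, no
  motion artifacts, no negative-tail structure in connectivity, no
  developmental trends. Passing recovery tests therefore demonstrates that
  the pipeline's inferential machinery is correct and calibrated — not that
  the statistic will cleanly subtype any real cohort, where effect sizes are
  far smaller and nuisance structure far richer.

## Validation scales and numerical conventions

The test suite validates each vectorized computation against a brute-force
oracle (triple-loop IDFC at 8 subjects × 12 ROIs to 1e-12; per-edge pooled t
to 1e-10; per-point silhouette by definition), checks BH false-discovery
control and permutation-test calibration under the global null (200
repetitions each; the 49-permutation rejection rule `p < 0.05` rejects with
probability exactly 3/50 under exchangeability, the bar the calibration is
held to), and runs full-scale recovery on a 264-ROI, 30+30+60 cohort:
silhouette-selected $k = 2$, adjusted Rand index ≥ 0.9 against the planted
labels, > 95% sign-consistency of significant edges per subtype, and
recovery of the planted subtype-by-score dissociation (LOOCV $r > 0.5$,
permutation $p < 0.05$, 500 permutations) with the crossed pairs silent.
These sizes keep the full suite in the minutes range while leaving every
inferential path exercised at the scale the method targets.

Degenerate inputs fail loudly throughout: constant time series name the
offending ROI, perfectly correlated ROIs block the Fisher transform,
zero-variance targets make LOOCV $R$ undefined, empty clusters trigger a
restart and only persistent degeneracy errors out. The frame-flagging QC
rule marks frames with displacement above 0.5 mm plus two frames on each
side (clipped at run boundaries) and excludes a subject only when *more
than* half the frames are flagged — the boundary case is kept.

## Known limitations

Cosine deviation conflates amplitude and topology changes whenever zeroing
alters the support of a profile; alternative kernels are out of scope. The
permutation test reruns the full LOOCV per shuffle and is the pipeline's
main cost at scale. The silhouette criterion inherits k-means' bias toward
spherical clusters of similar size; stability-based model selection is not
implemented. Site effects are handled as a fixed covariate, not harmonized.
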
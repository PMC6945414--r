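---
title: "Concordant partial areas and the partial c statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordant partial areas and the partial c statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordROC)
```

## The model

An empirical ROC curve summarizes a scored test set with `P` actual
positives and `N` actual negatives: sweeping a threshold down through the
scores, each positive moves the curve up by `1/P`, each negative moves it
right by `1/N`, and a group of tied scores with `a` positives and `b`
negatives is a single diagonal segment of rise `a/P` and run `b/N`. With
that tie convention the trapezoidal area under the polyline equals the c
statistic

$$c = \frac{1}{PN}\sum_{j=1}^{P}\sum_{k=1}^{N} H\big(g(p_j) - g(n_k)\big),$$

where the Heaviside comparison scores a correctly ranked pair 1, a tie 0.5
and an inversion 0. The concordance matrix makes this equivalence
geometric: arranging positives as rows and negatives as columns, both by
descending score outward from the origin, the staircase separating
concordant from discordant cells (crossing tied blocks diagonally) is the
empirical ROC curve itself — `border_path(concordance_matrix(d))` returns
the same vertices as `empirical_roc(d)`, and `test-concordance.R` checks
this vertex-for-vertex over simulated data.

For a partial curve with FPR range $[x_1, x_2]$ and TPR range
$[y_1, y_2]$, the package computes the vertical partial area
$pAUC = \int_{x_1}^{x_2} r(x)\,dx$ (average sensitivity times range
width), the horizontal partial area
$pAUC_x = \int_{y_1}^{y_2} 1 - r^{-1}(y)\,dy$ (average specificity times
range height), and their concordant combination

$$pAUC_c = \tfrac12\,pAUC + \tfrac12\,pAUC_x.$$

The equal weighting is not a modelling choice: the partial c statistic
counts the vertical and horizontal stripes of the concordance matrix that a
partial curve selects, the overlap block is counted twice, and dividing by
two is what makes the area and ranking views coincide and the parts sum to
the whole. No other weighting preserves both properties.

## The partial c statistic and its normalization

The stripe count is implemented with per-instance weights $w^+_j, w^-_k
\in [0,1]$ (1 = the instance's step lies fully inside the partial curve):

$$c_\Delta = \frac{1}{2PN}\Big[\sum_{j,k} w^+_j H_{jk}
  + \sum_{j,k} w^-_k H_{jk}\Big].$$

A single $1/(2PN)$ normalization with the weights inside the sums is used
throughout. The per-stripe normalized alternative (dividing each stripe sum
by its own covered cells) is available as `normalize_partial_c()`, which
rescales a partial c onto the AUC-comparable scale
$2PN\,c_\Delta/(N\sum w^+ + P\sum w^-)$; only the $1/(2PN)$ form is
additive across a partition and equal to `pauc_concordant()`, which is why
it is the primary definition here.

The *local* c statistic (`local_c()`) — concordance restricted to the block
of positives and negatives inside one part — is provided for completeness
but is deliberately not used in reports' identities: the test suite
contains a two-part example where every local value is 1.0 while c = 0.75,
because local blocks never see the cross-part discordant pairs.

## Resolving ranges and interpolation

An FPR range alone does not pin down a partial curve on a staircase, so
`resolve_partition()` applies fixed rules: the leftmost part starts at the
most southwest point of its left boundary; every other endpoint takes the
most northeast point. Adjacent parts then share their boundary vertex, a
vertical run on a boundary belongs to the part on its left, and shared
vertices contribute zero area twice, which keeps the partition sums exact
without excluding endpoints.

When a boundary cuts through an instance's step, `range_to_weights()`
assigns the covered fraction as that instance's weight. Tied groups need
one extra convention, chosen here and validated by property test: a tied
group is an *atomic diagonal* — a boundary cutting it at parameter
$t \in (0,1)$ gives all of the group's positives and negatives the same
weight fraction. Assigning sub-steps to individual tied instances instead
would break the per-part equality $pAUC_c = c_\Delta$ (each stripe picks up
an error term proportional to $t(1-t)\,\Delta x_g \Delta y_g$); under the
uniform convention the vertical and horizontal error terms cancel exactly,
and the round-trip property test drives boundaries through tied diagonals
to confirm equality at $10^{-10}$.

## Numerical choices

* All integrals are computed segment-exactly on the polyline — no
  quadrature grid — so additivity and the summation identities hold to
  machine precision, and the identity tests can assert $10^{-10}$
  tolerances rather than discretization-limited ones.
* Curve evaluation uses the conventions $r(x)$ = maximal TPR at `x` and
  $r^{-1}(y)$ = minimal FPR at `y`, which make the two partial integrals of
  a partition additive on staircases.
* Query coordinates are matched to vertices with absolute tolerance 1e-9;
  an endpoint farther than that from the polyline is an off-curve error
  naming the offending endpoint.
* Scores must be finite; orientation is explicit (`lower_is_positive`
  negates at ingest) — no auto-detection, since a silently flipped score
  column would corrupt every measure downstream.
* Degenerate parts are allowed: a purely vertical partial curve has zero
  vertical area and positive horizontal area and still satisfies the
  equality with the partial c statistic; normalized cells whose
  denominator range is zero-width are reported as `NA` in reports and are
  errors when requested directly.

## Comparison measures

`auprc_pair()` reports average precision in both class orientations: the
usual positives-focused AP and the value after swapping class roles and
negating scores. Step (rectangle) interpolation over distinct-score
thresholds is used — the definition under which AUPRC *is* average
precision — so values agree with the common machine-learning
implementations and with the rank-enumeration oracle in the tests.
McClish's standardized partial area
$sPA = \tfrac12[1 + (pAUC - A_{dg})/(A_{max} - A_{dg})]$ removes the area
under the chance diagonal and rescales to $[0.5, 1]$; unlike $pAUC_c$ it
can go below 0.5 (even negative) on improper curves, which the test suite
exhibits.

## What the simulator emulates

`simulate_scores()` draws positives from
$\mathcal N(\Delta\mu, \sigma_+^2)$ and negatives from
$\mathcal N(0, \sigma_-^2)$ — the binormal ROC model, whose population AUC
$\Phi(\Delta\mu/\sqrt{\sigma_+^2+\sigma_-^2})$ (`binormal_auc()`) serves as
a calibration target: at $P = N = 2000$ the empirical c must fall within
three standard errors (Hanley–McNeil) of the closed form for
$\Delta\mu \in \{0, 1, 2\}$. An optional quantization step rounds scores
onto a grid to inject ties. Default problem sizes in the test and
acceptance runs — around 120 datasets with $P, N \in [2, 40]$ for the
identity suite, $P = N = 2000$ for calibration — were chosen to estimate
the identities and the calibration to well beyond the asserted tolerances
while keeping a full run in the order of seconds.

The simulator produces exchangeable, unimodal, single-feature scores. Real
classifier scores can be multimodal, heteroscedastic, calibrated or
clipped, and real data can carry label noise; none of that affects the
*identities* (which hold for any finite scored sample, and that is what the
tests demonstrate), but it does mean that passing calibration here says
nothing about the discrimination of any particular real classifier.

## Fixtures

Three deterministic staircases ship with the package: the classic balanced
10 + 10 example from the ROC literature (its AUC, 68%, is a familiar
benchmark value), a 5-positive/15-negative imbalanced variant, and a
`vertical_end` curve whose two top scores are negatives so that the
leftmost resolved part has zero vertical area — the degenerate geometry
that most implementations of partial areas get wrong. Instance scores are
fixture-defined values realizing the stated shapes.

## Known limitations

* Only empirical (staircase) curves are modelled; fitted binormal curves
  and ROC convex hulls are out of scope, as are confidence intervals and
  significance tests for the partial measures.
* Overlapping partial curves are rejected: every summation identity is
  stated for disjoint spanning partitions.
* The concordance matrix is materialized densely (P×N), which is fine for
  evaluation-sized data but not for millions of instances; the measures
  themselves only need the score groups.
* Concordance for censored (survival) outcomes is a different statistic
  and is not provided.
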
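---
title: "Visibility-graph analysis of parcellated fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visibility-graph analysis of parcellated fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgfc)
library(dplyr)
```

## The visibility graph of a BOLD time series

A univariate time series $x_1, \dots, x_T$ maps to an undirected graph with
one node per frame: nodes $i < j$ are joined when the straight line between
$(i, x_i)$ and $(j, x_j)$ passes strictly above every intermediate sample,

$$x_k < x_j + (x_i - x_j)\,\frac{j - k}{j - i} \qquad \text{for all } i < k < j.$$

The inequality is strict: a sample lying exactly on the sight line blocks
it, which gives the clean analytic anchor that a linear ramp maps to a path
graph while a strictly convex series maps to a complete graph. Adjacent
frames always see each other, so every visibility graph is connected and
contains the Hamiltonian path of consecutive frames. The binary edge set is
invariant under positive affine transforms of the amplitudes, which is what
lets graphs be compared across subjects regardless of scanner units.

Time is the integer frame index, not seconds. The repetition time is
carried as metadata (`tr_seconds`) but never enters the construction: with
a constant TR the index is an affine function of time, and using seconds
would only rescale the weighted-graph distances by an arbitrary constant.

The weighted variant keeps the same edge set and attaches the reciprocal
Euclidean distance in the (frame, amplitude) plane,
$w_{ij} = 1/\sqrt{(j-i)^2 + (x_j-x_i)^2}$. Because time is frame-indexed,
$|\Delta t| \ge 1$ and all weights lie in $(0, 1]$.

**Amplitude convention.** Weights mix time (frames) and amplitude
(arbitrary BOLD units) in one distance, so they are only comparable across
regions and subjects under a declared amplitude convention. The package
z-scores each region (mean 0, sd 1) before building weighted graphs;
`zscore = FALSE` disables this. Binary graphs are unaffected either way.

**Algorithmics.** The production builder is an $O(T^2)$ running-maximum-
slope sweep in C++: edge $(i,j)$ exists iff the chord slope from $i$ to $j$
strictly exceeds the slope from $i$ to every intermediate point, so a
single forward scan per $i$ decides all pairs. Its contract is exact
equality with the literal $O(T^3)$ triple-loop oracle (`vg_oracle()`),
which is kept in the package as an independent reference and exercised on
hundreds of random series in the test suite.

## Five global graph features

For each region's weighted visibility graph the package reports:

* **average weighted degree** — mean node strength;
* **average path length** — mean unweighted shortest-path hop count over
  all node pairs;
* **global clustering coefficient** — transitivity,
  $3 \times \text{triangles} / \text{connected triples}$, on the binary
  edge set;
* **number of communities** — groups found by Walktrap (random-walk length
  4) on the weighted graph, taking the partition that maximises modularity
  along the merge dendrogram;
* **modularity** — Newman–Girvan $Q$ of that partition, with weights.

Two conventions deserve comment. Path length uses hop counts even though
the graph carries weights: "shortest path" on a weighted graph needs a
weight-to-distance transform, and rather than invent one silently the
package defaults to hops and exposes `path_weighted = TRUE`
(distance $= 1/w$) as a sensitivity analysis. Clustering is the
triple-based transitivity, not the mean local coefficient: the former is
the direct formalisation of "the probability that two neighbours of a node
are themselves connected". Walktrap and $Q$ see the weighted graph, degree
is explicitly weighted, and path length and clustering use the binary
structure; this split is configurable but is the documented default.

Walktrap with a fixed walk length has no random component, so feature
extraction is deterministic given the graph.

## Power-law tails of degree distributions

Weighted-degree distributions of fMRI visibility graphs are heavy-tailed;
the package fits the tail model $P(k) \sim k^{-\alpha}$, $k \ge x_{min}$,
with the continuous maximum-likelihood estimator
$\hat\alpha = 1 + n\big/\sum \ln(k_i/x_{min})$, choosing $x_{min}$ by
minimising the Kolmogorov–Smirnov distance between the tail data and the
fitted law. The 95% interval is the large-sample
$\hat\alpha \pm 1.96(\hat\alpha-1)/\sqrt{n}$. Weighted degrees are
continuous, hence the continuous estimator; a discrete variant is behind a
flag for binary degrees. The candidate $x_{min}$ scan is thinned to at most
250 quantile-spaced values, which changes nothing statistically (the KS
objective is flat between order statistics at this resolution) and bounds
the scan cost. Validation is by parameter recovery: inverse-CDF samples
($k = x_{min} u^{-1/(\alpha-1)}$) with $\alpha = 2.5$ must be recovered
within $\pm 0.1$ at $n = 10{,}000$, and exponential data must push
$x_{min}$ deep into the tail. Bootstrap goodness-of-fit p-values are out of
scope; only the point estimate and CI are reported.

## Degree synchrony as functional connectivity

Stacking the regions' visibility graphs as layers of a multiplex network —
node $t$ is the same time point in every layer — makes the per-layer degree
sequences directly comparable time series. Degree synchrony is their
Pearson correlation, and the region-by-region matrix of synchronies is an
alternative functional-connectivity estimate that asks whether bursts of
visibility (large-amplitude excursions) co-occur across regions.

Binary degrees are the default: they inherit the affine invariance of the
edge set, so no amplitude convention is needed. Weighted strengths are
available behind a flag. Significance uses the $t$ approximation with
$T - 2$ degrees of freedom and, by default, Benjamini–Hochberg FDR at
$q = 0.05$ over the upper triangle; an absolute-$r$ cutoff and a
proportional-density rule are alternatives, since the exact thresholding
rule of the original connectivity maps is not fixed. Group maps average
the *unthresholded* correlations and are thresholded last; group-level
p-values, when requested, come from a one-sample $t$ test of the subjects'
Fisher-z correlations. A region whose degree sequence is constant (a
strictly convex or concave series, mapping to a complete graph) has
undefined synchrony and propagates as `NA` with a warning, never a silent
drop. Group connectivity maps in the pipeline are computed on the
low-motion subset of subjects, mirroring how such maps are produced for
motion-sensitive data.

## Motion: quantification, impact, and the cap sweep

Framewise displacement is the Power-style backward-difference summary,
$FD(t) = \sum_i |\Delta d_i| + 50\,\text{mm} \sum_i |\Delta\theta_i|$ with
rotations in radians on a 50 mm sphere and $FD(1) = 0$; the rotation unit
of a motion-parameter file is always declared by the caller, never
guessed. A frame is motion-corrupted when $FD > 0.2$ mm (strictly), and a
scan's motion burden is its percentage of corrupted frames.

The motion-impact analysis correlates each (region, feature) pair with the
subjects' corrupted-frame percentages, and the cap sweep repeats this on
nested low-motion subsets: caps from 10% to 40% in 0.5% steps (61 points),
retaining subjects strictly below the cap. No multiple-testing correction
is applied to these descriptive tables; subject counts are reported so
users can correct downstream. With roughly 40 subjects below a 10% cap,
the sampling noise floor of a correlation is about $0.8/\sqrt{n} \approx
0.13$ — weak per-feature trends along the sweep are not interpretable at
this scale, which is why the validation suite asserts the trend on the
composite curve of the three motion-sensitive features and on average
weighted degree individually, the one feature whose signal clears the
floor everywhere.

## Test-retest reliability

Reliability between the two sessions is the two-way absolute-agreement
single-measurement intraclass correlation, ICC(A,1):

$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

from the two-way ANOVA mean squares (subjects, sessions, residual), with
the McGraw–Wong F-based confidence interval (Satterthwaite degrees of
freedom). Absolute agreement charges a constant session offset against
reliability, unlike the consistency coefficient; the mixed- versus
random-effects reading of the session factor does not change the point
estimate. The implementation is validated against `stats::aov` mean
squares and by parameter recovery on $y_{sd} = u_s + e_{sd}$ designs with
known variance ratios.

The reliability report keeps subjects whose corrupted-frame percentage is
strictly below the cap (default 20%) in *both* sessions — the original
subsetting rule does not state per-session versus pooled screening, so the
stricter both-sessions rule is used and recorded here.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
any data download. It emulates a two-session resting-state cohort:
`n_subjects` subjects × 2 sessions × `n_regions` regions ×
`n_frames` frames (defaults 114 × 2400 at TR 0.72 s, i.e. two concatenated
1200-frame runs).

**Signal.** Region $r$ of subject $s$ is
$x_r = \sqrt{1-L}\,e_r + \sqrt{L}\,c_{g(r)} + \varepsilon$, where $e_r$ is
region-private AR(1) noise, $c_g$ is the AR(1) signal shared by region
$r$'s community block, $L$ is `community_loading`, and $\varepsilon$ is
white measurement noise with sd `session_noise_sd`, drawn independently
per session. All AR processes use the subject's coefficient
$a_s = \texttt{ar\_coefficient\_mean} + N(0, \texttt{subject\_sd})$,
clipped to $(-0.95, 0.95)$ — the *sole* stable subject trait, so any
test-retest reliability recovered downstream traces back to one knob.
Defaults: 4 communities, loading 0.3 (clean-signal inter-regional
synchrony stays well below 0.4), AR mean 0.4 (lightly smoothed BOLD at
sub-second TR), subject sd 0.15, session noise sd 0.2.

**Motion.** Each subject draws a latent prevalence
$p_s \sim \text{Beta}(2, 6)$ (mean 25%; in a 200-subject cohort some
subjects fall below 10% and some above 40% corrupted frames, covering the
sweep range). Three structural choices make the motion model behave like
motion in real scans rather than like iid noise, and all three were
required for the generator to reproduce the directional structure the
analyses are designed to detect:

1. *Events, not frames.* Movements span consecutive frames: events start
   at rate $q = p_s/(d(1-p_s))$ per clean frame and last $1 +
   \text{Geom}(1/d)$ frames with mean `motion_event_duration` $d = 3$
   (≈2.2 s), making the long-run corrupted fraction exactly $p_s$.
   Isolated one-frame spikes mostly *block* lines of sight and push mean
   visibility degree down; multi-frame elevated plateaus both see far and
   segment the series, which is what raises degree, community count and
   modularity together.
2. *Severity couples to prevalence.* Corrupted frames draw
   $FD = 0.2 + \text{Exp}(s_c)$ mm with scale $s_c = 0.05 + 0.6\,p_s$:
   subjects who move often also move harder, as motion QC of real cohorts
   shows. This makes the artifact's feature response convex in prevalence,
   which is exactly what produces the declining cap sweep — low-motion
   subsets show weak correlations while the full cohort shows strong ones.
3. *Transient plus slow recovery.* Each corrupted frame injects a global
   additive transient `artifact_gain` × (FD − 0.2 mm) into every region
   (gain 20 per mm of excess: a 0.4 mm frame gives a ≈4 sd transient, a
   barely-over-threshold frame almost none), decaying geometrically at
   `artifact_tail_rho` = 0.7 per frame (≈2 s time constant), standing in
   for spin-history and related recovery effects that persist beyond the
   movement itself.

Clean frames carry baseline FD jitter $|N(0, 0.04\,\text{mm})|$, far below
the 0.2 mm threshold.

**Determinism.** All randomness flows from one seed through a
subject-major splitting scheme (subject $s$ uses its own derived stream),
so identical specs give bitwise-identical cohorts and enlarging a cohort
never perturbs earlier subjects.

**What the generator does not emulate.** No haemodynamic response
convolution, physiological noise, scanner drift, or spatial structure
beyond block correlations; amplitudes are abstract units, not percent
signal change. Because the artifact is perfectly global, motion-driven
degree fluctuations are shared across all regions and inflate
degree-synchrony well above the low-to-moderate levels seen in cleaned
real data — the low-motion subset and the artifact-free control are the
right objects for connectivity-level claims, and the package's validation
uses them accordingly. Passing tests on this cohort demonstrate that the
pipeline's statistics recover planted structure of each kind (stable
traits → ICC; global transients → motion correlations; block correlations
→ synchrony contrast); they do not certify effect sizes on real fMRI.

## Validation scales and numerical choices

The validation suite runs the full pipeline at a reduced scale chosen to
keep the whole suite in the minutes range on one CPU: 200 subjects × 2
sessions × 20 regions × 600 frames for the cohort-level checks, with
oracle equivalence on 200 random series up to $T = 128$ and analytic
fixtures solved by hand. Degenerate inputs are rejected loudly
(non-finite samples, constant regions before z-scoring, constant degree
sequences, missing ICC cells); ties in the visibility criterion block
visibility by construction; and every pipeline output embeds a
configuration hash so reruns can be verified byte for byte.

## Worked example

```{r example, eval = FALSE}
library(vgfc)

spec <- cohort_spec(n_subjects = 20, n_regions = 10, n_frames = 300,
                    seed = 42)
cohort <- generate_cohort(spec)

features <- cohort_features(cohort)
motion <- cohort_motion(cohort)

motion_feature_correlation(dplyr::filter(features, session == 1),
                           dplyr::filter(motion, session == 1)) |>
  summarise_motion_impact()

reliability_report(dplyr::filter(features, session == 1),
                   dplyr::filter(features, session == 2),
                   motion, cap_percent = 40) |>
  summarise_reliability()
```

## Known limitations

* The AR(1)-plus-transient world is far simpler than BOLD; in particular
  community count and modularity of visibility graphs at $T = 600$ are
  intrinsically noisy statistics, and their per-feature motion trends sit
  near the sampling noise floor at 200 subjects.
* Horizontal and parametric visibility variants, frame scrubbing, and
  graph analysis of the thresholded connectivity network are out of scope.
* The weighted/binary split of the five features (weighted degree,
  Walktrap, $Q$; binary clustering and path length) is one defensible
  convention among several; both are exposed where ambiguity exists.
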
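---
title: "Methods: from ROI time series to rich clubs, response bias and Arc ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ROI time series to rich clubs, response bias and Arc ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratconnectome)
```

This vignette is the package's own account of its methods: the models and
rules each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data layer does and does
not emulate, and the numerical decisions taken where the underlying
procedures are conventionally underspecified.

## Signal conditioning

The imaging arm consumes ROI-by-time tables (`RoiTimeSeriesSet`): one
signal per labeled region, bilateral regions tagged `_L`/`_R`, and a
sampling interval `dt` in seconds (default 2 s; 300 volumes span 10 min).
An optional entry point, `extractRoiSeries()`, averages voxels sharing an
integer atlas label in a 4-D volume (NIfTI via `RNifti`), with an
optional Gaussian blur that is off by default at ROI level because ROI
averaging already pools voxels.

Conditioning is ordered detrend → nuisance regression → band-pass:

* `detrendNormalize()` removes a per-ROI least-squares fit of intercept +
  linear + quadratic time terms and rescales residuals to unit variance.
  A residual with zero variance is set to all zeros and flagged in
  `metadata()` instead of propagating NaN into correlations.
* `regressNuisance()` residualizes each ROI on an intercept plus the
  confound matrix (six motion-like regressors and two
  physiological-reference signals in the simulated data). A
  rank-deficient confound matrix triggers a warning and a pseudoinverse
  (SVD) projection, so duplicated regressors change nothing. Residuals
  are orthogonal to every confound by construction, and the tests assert
  this to 1e-8 on unit-normalized vectors.
* `bandpassFilter()` applies an order-4 Butterworth band-pass forward and
  backward (`signal::filtfilt`), i.e. zero phase and squared magnitude.
  Only the band (default 0.01–0.1 Hz) is conventionally reported for this
  kind of preprocessing; the filter family and order are this package's
  choice, standard in resting-state work, and are pinned by a testable
  gain contract instead of by authority: mid-band gain within [0.9, 1.1],
  gain ≤ 0.1 at twice the upper edge and below half the lower edge, DC
  attenuated below 1 % after transients.

Applying the band-pass twice changes a passband sine's amplitude by less
than 5 % away from the series edges, which is how "near-idempotent" is
made precise in the tests.

## Connectome construction and graph metrics

`correlationMatrix()` drops the first `nDrop = 9` volumes (equilibration
frames are excluded from cross-correlation), computes all pairwise
Pearson correlations, clips |r| at 1 − 1e-7 so perfectly correlated
synthetic inputs stay finite, and applies Fisher's z = atanh(r). Constant
ROIs yield `NA` rows that are flagged, never silently zeroed.

`thresholdDensity()` keeps the `floor(density · n(n−1)/2)` largest signed
z values (default density 0.15 retains 1,676 of the 11,175 pairs of a
150-ROI matrix) and divides by the largest retained z, so every subject's
graph has the same density and a maximum edge weight of exactly 1. Three
conventions are fixed explicitly because any of them could silently vary
between implementations: edge-count rounding is *floor*; the ranking is
of *signed* z (a negative correlation could in principle be retained,
though never at 15 % density on realistic input); ties break by ascending
(row, column) index. All three are recorded in the graph's `metadata()`.

Metrics on the weighted graph:

* strength `s_i = Σ_j w_ij`, degree `k_i = #{j : w_ij > 0}`; since
  weights ≤ 1, strength ≤ degree with equality exactly at unit weights;
* weighted clustering by the geometric-mean triangle-intensity formula
  `C_i = (k_i(k_i−1))^{-1} Σ_{jh} (w_ij w_ih w_jh)^{1/3}` with binary
  degree in the denominator — the convention of the standard brain-
  connectivity toolbox this analysis style descends from;
* characteristic path length with edge length 1/w; on disconnected
  graphs unreachable pairs are excluded from the mean and their fraction
  reported, which avoids infinite means at low density;
* small-worldness σ = (C/⟨C₀⟩)/(L/⟨L₀⟩) over `nNulls` Maslov–Sneppen
  degree-preserving rewirings (10 swap attempts per edge, seeded) with
  the observed weights shuffled onto the rewired topology.

`richClubCurve()` works on the binary skeleton: for each threshold k the
club is the node set with degree strictly greater than k and
φ(k) = 2E_club/(N_club(N_club−1)). φ is flagged undefined when fewer than
two nodes survive. The verbal definition of a rich club ("edges among
nodes of degree k or higher") describes an edge count; the implemented
quantity is the standard normalized density form, which is what bounded
per-k curves in [0, 1] require. Whether to normalize additionally by
degree-preserving nulls is genuinely open in this literature; the option
exists (`nNulls > 0`) but is off by default, as is a weighted variant.
Every metric is checked against independent brute-force enumerations
(triple loops, Floyd–Warshall, explicit club enumeration) on hundreds of
seeded random graphs of up to 12 nodes.

`seedConnectivity()` reports z(seed_L, target_L), z(seed_R, target_R)
and their mean; hemispheres are averaged because the design this package
emulates found no left/right difference. `highStrengthSubnetwork()`
selects nodes by strength (> 15 by default) and/or degree (> 40),
either on across-subject means (default) or per subject with the union
reported — the source procedure is ambiguous between the two readings,
so both are provided rather than guessing.

## Behavior

A `TrialLog` is an ordered record of attempted trials. A failed
alternation is a working-memory error: it is recorded, but it is *not* a
trial — it carries no object choice and never enters percent correct or
the response bias. The response bias of a session is |L − R| / T over
object-choice trials; it is invariant to trial order and to correctness,
and the first free-choice trial of a day is included in T (it is an
object-choice trial; the convention is stated rather than silently
assumed). Multi-day aggregates are means of daily values.

## Arc catFISH classification

Candidate cells carry per-plane foci counts and perimeter-coverage
fractions. Inclusion requires not being cut by the tissue edge and being
visible in the central window of `round(0.2 · nPlanes)` planes centered
on the stack midpoint (planes 9–12 of a 20-plane stack). "Visible within
the median 20 % of planes" is read as *intersecting* that window; the
stricter covering rule is available (`rule = "cover"`). Classification
follows the plane-based rules exactly: nuclear = foci count in {1, 2} on
≥ 4 consecutive planes (counts above 2 do not qualify under the literal
reading; `fociRule = "atLeast1"` relaxes this), cytoplasmic = coverage
≥ 1/3 on ≥ 2 adjacent planes, double = both, negative = neither.
Upstream image processing (focus detection, nucleus segmentation) is out
of scope; the module consumes measurements.

Aggregation is per rat × region — animals, not cells, are the unit of
inference — so duplicating all of one rat's images leaves that rat's
fractions unchanged (tested). Task attribution maps cytoplasmic labeling
to the first epoch's task and nuclear to the second epoch's (transcripts
need ~15–20 min to reach the cytoplasm), keyed by each rat's
counterbalanced task order; double-labeled cells count toward both tasks
by default (they were active in both epochs) or can be excluded, since
published treatments differ. The similarity score
(pAB − pA·pB)/(min(pA, pB) − pA·pB) uses pA = cytoplasmic + double,
pB = nuclear + double, pAB = double; it is 0 at independence, 1 at
maximal overlap, symmetric in (pA, pB), and flagged undefined when the
denominator is non-positive. The exact variant of this score used in the
original analyses is cited rather than printed there; the form here is
the standard overlap normalization with that event algebra.

## Group statistics

`withinGroupZscore()` standardizes within each group before pooling —
the guard against between-group offsets masquerading as correlations —
and `pooledCorrelation()` reports Pearson R with F = R²(n−2)/(1−R²) on
(1, n−2) df. `mixedAnova()` is the classical one-between ×
one-within decomposition, fitted through `stats::aov` with an
`Error(subject)` stratum and verified in the tests against a fully
hand-computed sums-of-squares oracle. Design rules are strict: every
subject must appear in every session and in exactly one group; anything
else is an explicit error rather than a silent fall-back to another SS
type. No sphericity correction is applied by default (uncorrected df are
reported, matching the analysis style emulated); Greenhouse–Geisser is a
flag. Subject-level permutation p values (group relabeling for
between/interaction, within-subject shuffling for the within effect) are
available as a cross-check and agree with the parametric values under
normal simulation.

`richclubGroupComparison()` applies this ANOVA independently at each k
and reports contiguous significant-k bands at uncorrected α = 0.05 —
the shaded-band presentation style — with optional FDR across k. A k
with undefined φ for any subject, or fewer than two subjects in a cell,
is flagged undefined and skipped. Under null simulation the per-k
rejection rate for each effect stays within [0.03, 0.07] at 1,000
replicates (part of the acceptance suite).

## The synthetic-data layer

The generators exist so that every downstream stage has inputs with a
known answer; their defaults are the study conditions of the emulated
design, not free dials.

* **Time series.** A target correlation matrix is built from
  block-constant modules, hub rows (a planted club: hub–nonhub coupling
  `hubR`, hub–hub coupling `hubClubR`), and optionally pinned seed pairs,
  then projected to the nearest positive-semidefinite correlation matrix
  by eigenvalue clipping with diagonal renormalization — the projection
  guarantees a sampleable model at the cost of moving targets slightly
  when the requested structure is not exactly attainable. Draws use the
  symmetric matrix square root, so degenerate targets (r = 1) are
  reproduced exactly. On top of the unit-variance latent signal the
  generator adds per-ROI linear + quadratic drift, shared nuisance
  components (two sinusoids below 0.01 Hz standing in for
  ventricular/white-matter signals plus six smoothed random-walk
  "motion-like" regressors, all mixed with random ROI loadings), and
  white noise. One consequence worth stating explicitly: additive white
  noise of standard deviation σ attenuates *observed* correlations by a
  factor 1/(1 + σ²) relative to the planted latent targets, and because
  filtering acts identically on signal and noise the attenuation
  survives preprocessing. Tests therefore compare against the attenuated
  value where noise is on, and against the planted value where it is
  off. The empirical noise spectrum of real acquisitions is not
  characterized by any source available here, so the noise scales are
  honest free knobs; nothing downstream depends on their exact values.
* **Trial logs.** Each day starts with a free-choice turn; subsequent
  attempts fail to alternate with probability `pWme` (producing a WME
  row) and otherwise log an object choice on the animal's fixed
  preferred side with probability `sideBias` (a per-animal lateral
  preference; a per-day trajectory is accepted for drifting biases) and
  correct with that day's `pCorrect`. Expected bias converges to
  |2·sideBias − 1|, which the tests check against the binomial
  expectation.
* **Cells.** Planted nuclear/cytoplasmic/double/negative populations
  conform exactly to the classification rules, including boundary decoys
  among the negatives (three-plane foci runs, isolated over-threshold
  coverage planes, foci counts above 2). The classifier must recover
  planted labels with 100 % accuracy — by construction of the rules,
  not as an empirical claim about real tissue.

What passing tests do *not* show: that real BOLD noise (scanner drift
families, physiological spectra, motion artifacts beyond smooth
regressors), real learning dynamics, or real fluorescence measurement
noise are handled. The synthetic layer validates the *algebra* of the
pipeline — thresholds, formulas, accounting rules, inference machinery —
not the biology.

## Numerical choices and degenerate inputs

* Fisher-z clipping at |r| = 1 − 1e-7; constant ROIs flagged, never
  zeroed; thresholding refuses matrices containing undefined ROIs.
* Edge-count floor rounding and (row, column) tie-break, recorded in
  metadata.
* Path length on disconnected graphs: unreachable pairs excluded,
  fraction reported.
* φ(k) undefined below two club members; undefined k values propagate as
  flags, not zeros.
* Zero-variance groups or single-member groups in z-scoring: `NA` plus a
  warning.
* All generators and null ensembles are seeded; identical seeds give
  bit-identical outputs, and the pipeline's per-subject seeds derive
  deterministically from one master seed.

## Problem sizes used by the test suite

The suite exercises full-scale geometry (150 ROIs, 300 volumes) where the
quantity checked is an identity, and reduced geometry where replication
matters: the planted-effect recovery study runs 100 replicates of a
2-group × 5-subject × 3-session design at 60 ROIs, and the type-I
calibration runs 1,000 null replicates on a reduced k grid. These sizes
are the package's chosen trade-off between statistical resolution and a
test suite that runs in minutes on a laptop.

## Known limitations

* No voxel-level analyses: no seed maps, cluster-extent correction, or
  3-D rendering; the volume path stops at ROI extraction.
* No linear mixed-effects (REML) machinery; the ANOVA is the classical
  balanced decomposition, and unbalanced designs are rejected rather
  than approximated.
* No modeling of anesthesia, learning dynamics, or image segmentation.
* The rich-club normalization question (raw vs null-normalized φ) is
  surfaced as an option rather than resolved; published curves are not
  always explicit about it, and the two choices are not interchangeable
  at low k.
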
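---
title: "Mining acupoint–pattern associations from curated case records"
author: "acumine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining acupoint–pattern associations from curated case records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acumine)
```

## The data model

A *case record* is one treatment entry from a curated classical-medicine
corpus: the acupoints prescribed for a disorder together with the
diagnostic patterns implicated for it. Acupoints are identified by
WHO-style meridian codes (`CV4`, `ST36`, ...); validation is by code shape
(`^[A-Z]{2,3}[0-9]{1,2}$`) only — the package does not carry a lookup
table of the classical point list, because curated corpora identify points
by these codes and nothing in the analysis depends on anatomy.

Pattern terms come in raw form ("sovereign fire", "heat", ...) and are
mapped by a *taxonomy* onto canonical patterns, each belonging to one of
three pattern-identification categories. The packaged default taxonomy has
25 canonical patterns: 5 essential components of the body (essence, qi,
spirit, blood, phlegm), 12 viscera and bowels (liver, heart, pericardium,
spleen, lung, kidney, gallbladder, stomach, small intestine, large
intestine, bladder, triple energizers) and 8 internal/external causes
(food, overwork, sexual activity, wind, cold, dampness, dryness, fire).
All canonical profiles therefore live in a 25-dimensional pattern space.

Canonicalization (`canonicalize_corpus()`) replaces raw terms by canonical
patterns and collapses within-case duplicates — both duplicates present in
the raw data and duplicates created by the mapping. Duplicate acupoints
are collapsed at the same step. The rationale is that all downstream
frequencies are *case-level*: "point X used 16 times" means 16 cases, and
keeping per-case multiplicity would silently change every count. Raw
files may contain duplicates (the loader warns); the mention counts of
`summarize_corpus()` always describe the corpus as stored. Terms missing
from the taxonomy are an error by default (`unknown_policy = "error"`);
dropping them is possible but explicit, because silent drops corrupt
frequencies. Concepts that resist stable canonicalization (yin/yang,
deficiency/excess readings that flip with context) are deliberately not in
the default taxonomy; records using only such terms cannot be analyzed
without extending it.

## The weighting scheme

Let the co-occurrence cell `n(a, p)` be the number of cases containing
both acupoint `a` and canonical pattern `p` (`build_cooccurrence()`). The
analysis weights this table by tf-idf in both directions:

* **patterns as terms** (documents = acupoints): `w(a, p) = n(a, p) ·
  log(N_a / df(p))`, with `df(p)` the number of acupoint documents whose
  cell for `p` is positive and `N_a` the number of acupoint documents.
  Each acupoint becomes a weight vector over the 25 patterns — its
  *profile*.
* **acupoints as terms** (documents = patterns): the transpose
  construction, ranking the acupoints most specific to each pattern.

A pattern that co-occurs with every acupoint has `df = N` and weight
exactly zero everywhere: ubiquity is treated as zero information. Weights
vanish exactly when `tf = 0` or `df = N`, increase with tf at fixed df,
and decrease with df at fixed tf.

Each document vector is then cosine-normalized to unit Euclidean length
(`cosine_normalize()`), making acupoints of very different total usage
comparable in the same space. All-zero rows (every pattern of that
acupoint ubiquitous) are left at zero with a warning rather than producing
NaNs.

### Parameter choices

* **Minimum frequency** (`filter_min_count()`, default `min_count = 3`
  cases): sparse corpora contain many points used once or twice whose
  profiles are noise; the conventional cut keeps points appearing in at
  least 3 cases. The filter removes acupoint rows only — pattern columns
  and the retained rows' original case-level margins are kept.
* **Document universe** (`compute_tfidf()`): after filtering, `df` and `N`
  can be taken over the retained acupoints (`"filtered"`) or the full
  pre-filter matrix (`"all"`). The default is `"filtered"` for the
  pattern-as-term direction (profiles of the analyzable points, mirroring
  the ~43-point analysis set) and `"all"` for the acupoint-as-term
  direction (patterns as vectors over every recorded acupoint, mirroring
  the full 114-point feature space). Both are exposed because the choice
  is substantive when many rows are dropped.
* **Logarithm base** (`log_base`, default natural log, `"10"` available):
  the base multiplies every weight by one constant, so rankings,
  normalized vectors, correlations and therefore the network are
  invariant to it; the option exists purely for numeric comparability
  with other software.
* **Ranking ties** (`top_k_ranked()`): weight descending, then term label
  ascending (C-locale radix order). Zero-weight terms are never reported —
  a zero weight means "no information", not "weak association".

## The association network

The profile distance is the correlation distance `d = 1 − r` with `r` the
Pearson correlation of two acupoints' profiles, ranging over [0, 2].
Because Pearson correlation is invariant under positive affine rescaling
of its arguments, the distances (and hence the network) are identical
whether computed from raw or cosine-normalized weights — a useful internal
consistency check that the test suite asserts. Constant (zero-variance)
profiles have no defined correlation; they are masked, kept as isolated
nodes, and excluded from thresholding.

Two acupoints are linked when `d` is **strictly** below the threshold
(`build_network()`). The threshold is either fixed (default 0.1) or an
empirical percentile of the off-diagonal distance distribution
(`select_threshold()`, each unordered pair counted once, linear
interpolation — `stats::quantile` type 7; the convention is documented
because small networks make the quantile method visible). The two modes
are calibrated to each other: in corpora of this scale the lower 1
percentile of pairwise distances falls near 0.1.

A *module* is a connected component with ≥ 2 members; singleton nodes are
not modules. No community-detection algorithm is applied: at thresholds
this strict, components are already tight clusters, and a simpler
construction is easier to reason about and to test (components are checked
against a brute-force transitive-closure oracle). The module *hub* is the
member of maximal degree, ties broken by the lexicographically smallest
label; modules are ordered by decreasing size, then smallest member. Each
module is summarized by its *mean profile* — the elementwise arithmetic
mean of the members' normalized weight vectors (`module_mean_profile()`)
— which is what the radar charts draw.

Raising the threshold can only add edges and merge components; this
monotone coarsening is asserted as a property test.

## The synthetic-corpus generator

The curated corpora this analysis targets are typically unpublished, so
validation uses `generate_corpus()`, which emulates the statistical
structure of one chapter of a classical text:

* 114 cases; per case, `1 + Poisson(2.0)` acupoint draws and
  `1 + Poisson(8.5)` pattern draws, giving ~341 acupoint and ~1082 pattern
  mentions before per-case deduplication (the scale reported for such a
  chapter). Pre-collapse totals are returned separately because corpus
  scale is conventionally quoted before deduplication, while the stored
  cases are deduplicated.
* 7 planted modules of 5 acupoints each, drawn at random from a
  114-point universe; each module prefers a random set of 3–5 canonical
  patterns. A case is module-driven with probability 0.6; its acupoint
  draws come from the module with probability 0.8 each, its pattern draws
  from the preferred set with probability `alpha = 0.7` each. Everything
  else is background: acupoints from a Zipf-like distribution
  (weight `rank^(-0.75)`) over the 79 non-module points, patterns uniform
  over the 25.
* The Zipf exponent is the calibration knob for the popularity skew. It
  was set by a coarse sweep (0.5–1.5 in steps of 0.25, 20 seeds each) so
  that the `min_count = 3` filter retains roughly 43 of the 114 acupoints
  — the retention observed in corpora of this kind — while keeping the
  most-used points near the observed 12–16 case range. At 0.75 the filter
  retains 43–53 points (mean 47.5) and the top point is used ~14–26
  times; a steeper exponent centers retention on 43 exactly but roughly
  doubles the top-point usage, which we judged the worse distortion.

With the default configuration the full pipeline (filter at 3, percentile
threshold at 1%) recovers the planted modules with mean adjusted Rand
index ≈ 0.95 over 20 seeds, and recovery increases monotonically in
`alpha`. The ARI is computed over the acupoints detected in *some* module;
undetected points are excluded, because a strict threshold is designed to
leave weakly associated points unassigned, and penalizing abstention would
conflate precision with coverage.

What the generator does **not** emulate: subchapter structure and
meridian anatomy (module membership is random, whereas real co-prescribed
points cluster anatomically); pattern co-occurrence structure beyond the
planted module preferences; scribal variation in raw terms (generated
corpora are born canonical); and any correlation between a point's
popularity and its module membership. Passing the recovery tests
therefore shows the pipeline can extract planted co-usage structure at
realistic scale and noise — not that any particular historical corpus has
such structure.

## Numerical conventions and degenerate inputs

* Empty corpora are valid for loading/summarizing (all-zero summary) but
  an error for co-occurrence; a filter that removes every acupoint is an
  error rather than an empty analysis.
* Single-row or single-column weight matrices cannot enter the network
  stage (a correlation needs ≥ 2 profiles of length ≥ 2); this is an
  explicit error.
* Distances are reported to full double precision; bounds are asserted to
  1e-9, unit norms to 1e-9, and oracle equivalence of the weighting to
  1e-12.
* All label ordering uses C-locale radix sort so results do not depend on
  the session locale.
* Figure output is SVG or PNG through the cairo devices; rendering is
  smoke-tested (file existence, axis/band counts, byte-determinism of PNG
  re-renders), not pixel-compared, since vector output embeds
  device-version-dependent structure.

## Problem sizes used by the test suite

The suite validates the weighting and component extraction against
brute-force oracles on 200 random corpora of ≤ 8 cases, runs the planted
recovery experiment at the default scale (114 cases) over 20 seeds, the
calibration check over 20 seeds, and the `alpha` monotonicity check at
four levels × 10 seeds — sizes at which the brute-force oracles are exact
and the whole suite runs in well under a minute.

## Limitations

* Case-level counting is a modeling decision, not a discovery: if a
  corpus encodes meaningful within-case repetition, that signal is
  discarded by design.
* Connected components are fragile to single spurious edges at loose
  thresholds; the strict default threshold mitigates this, but users
  raising it should expect chaining.
* The 25-pattern taxonomy is a fixed simplification; terms with
  context-dependent meanings are excluded, and folding fire-related
  variants into one pattern discards their distinctions.
* tf-idf with case-count tf has no smoothing; in very small corpora a
  single case can dominate a profile. The minimum-frequency filter is the
  only guard.
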
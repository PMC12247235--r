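---
title: "Measuring embedding bias with WEAT and SD-WEAT: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring embedding bias with WEAT and SD-WEAT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medbias)
```

## The statistics

WEAT compares how strongly two target word sets X and Y (e.g. male-linked
and female-linked medical conditions) associate with two attribute word
sets A and B (e.g. male and female gender terms) inside one embedding
space. Everything reduces to cosine similarity. The association of a word
`w` is `s(w,A,B) = mean_a cos(w,a) − mean_b cos(w,b)`; the test statistic
sums associations over X minus Y; the effect size `d` standardizes the
difference of mean associations by the standard deviation of `s` over
`X ∪ Y`. The permutation p-value asks how often an equal-size re-partition
of `X ∪ Y` would produce a larger statistic, one-sided.

SD-WEAT removes WEAT's two fixed, equal-status attribute sets. All
attribute words — from any number of labelled groups — are pooled. K times,
four distinct words are drawn from the pool, the first two used as A and
the next two as B, and the draw's WEAT effect size recorded. The score is
the population standard deviation of those K effect sizes. The intuition:
if attribute identity is irrelevant, draws are exchangeable and effect
sizes cluster; if some words systematically pull one target set, draws that
happen to contrast those words give effect sizes near ±2 while mixed draws
give ≈ 0, inflating the spread. The score is thus a *variance-based*
signal of attribute structure, defined for any pool of ≥ 4 words —
including three or more demographic groups at once, the multi-class case
binary WEAT cannot express.

### Assumptions worth stating

* Bias is treated as a geometric property of the embedding table alone; no
  downstream task is consulted.
* Cosine is the similarity; vectors are *not* pre-normalized before mean
  pooling, so a term vector is the plain mean of its token vectors and
  cosine handles norms once, at comparison time.
* The permutation test's exchangeability assumption is over target words
  only; attribute sets are held fixed.
* A high score is not automatically bad: a clinical model arguably *should*
  associate breast cancer with female terms. The package measures; the
  judgment belongs to the user.

## Conventions that pin numbers down

Several small conventions change third-decimal results, so they are fixed
here and tested:

* **σ in the effect size** is the population (divide-by-N) standard
  deviation over `X ∪ Y`. This matches the canonical WEAT implementation
  and gives the exact bound |d| ≤ 2 for equal-size targets (the bound is
  property-tested). A `sd_type = "sample"` switch exists for sensitivity
  checks only.
* **Strict inequality** in the permutation test: partitions tying the
  observed statistic count as "not greater". The tie mass is reported.
  With this convention `p(A,B) + p(B,A) = 1 − tie mass` exactly under
  exhaustive enumeration, which the suite asserts.
* **Exhaustive enumeration** is used whenever `choose(2n, n) ≤ 200000`;
  otherwise seeded Monte-Carlo with an unsmoothed proportion and the draw
  count reported. Exhaustive p-values are exactly reproducible and are
  checked against an independent brute-force enumerator.
* **SD-WEAT draw protocol**: four distinct words per draw, split 2 + 2,
  independent across the K tests (a word pair may recur). K = 100 by
  default; the importance analysis uses M = 500. Draws whose association
  scores are constant (zero variance — e.g. all four words embedded
  identically) have no defined effect size; they are **resampled**, not
  skipped, with a hard cap of 10·K retries before erroring, so degenerate
  geometry is loud rather than silently absorbed.

## The SD-WEAT p-value

The resampling p-value used here is the package's own documented choice:
R replicates shuffle target-set membership (an equal-size re-partition of
`X ∪ Y`), each recomputing the K-draw score with fresh attribute draws, and

    p = (#{SD_null ≥ SD_obs} + 1) / (R + 1).

The add-one correction keeps p in `[1/(R+1), 1]` and makes the test valid
at finite R. Under an isotropic null both the observed and replicate scores
are exchangeable draws from one distribution, so p is uniform up to
discreteness — the acceptance suite verifies a rejection rate in
[0.03, 0.07] at α = 0.05 over 500 null tables. This construction mirrors
WEAT's own permutation logic and explains how a visibly large score can
still be non-significant when the target sets have little internal
structure for the shuffle to destroy. It is isolated behind
`pvalue_method` so an alternative formula can be substituted without
touching score computation.

## Embedding layer

Static tables load from glove-text or word2vec-text files (dimension from
the first row or the header; duplicate tokens: last wins, warned). A
multi-word term ("prostate cancer") embeds as the arithmetic mean of its
whitespace-token vectors — the static-table analogue of the sub-word mean
pooling used for transformer vocabularies, and consistent with the
membership rule that a term is representable iff every token is in
vocabulary. Hyphens are kept by default ("sickle-cell" is one token), with
a `split_hyphens` switch. Case policy `exact-then-lower` retries failed
exact lookups in lowercase, accommodating cased reference tables and
uncased models in one default.

Out-of-vocabulary handling is role-dependent by default: target terms are
skipped with a warning (mirroring construction-time exclusion of
unrecognized condition terms), attribute terms are errors, because the
attribute lists are the measuring instrument. Contextual models plug in as
a function `term -> matrix of sub-word vectors`; the core mean-pools the
rows and never imports a model library. Which hidden layer constitutes
"the embedding" is the backend's explicit decision, not the core's.

## The synthetic generator: what a green test establishes

`generate_table()` produces unit-norm vectors
`normalize(g + β·u_k)`, `g ~ N(0, I_dim)`, with `u_k` the group's latent
direction (orthonormal canonical basis vectors) and β the planted-bias
strength; β = 0 is an isotropic null. Defaults: dim = 50 — small enough
for fast CI, large enough that cosine noise (≈ 1/√dim) is mild. In
`exact-geometry` mode vectors equal their direction exactly, realizing the
analytic extremes (s-values ±1, d = ±2) that the suite asserts
*identically*, not approximately.

`synth_table_for_benchmark()` maps a benchmark onto the generator: targets
1 and 2 get directions 1 and 2; in the binary case attribute groups share
those directions (so bias is recoverable), in the multi-class case each
group gets its own. One rule is this package's own: benchmark terms are
tokenized exactly as the embedding layer will tokenize them, and a token
appearing in several groups — "cancer" occurs in both target sets of G-1 —
is left **neutral** (no direction) rather than arbitrarily assigned to one.
Consequently planted-bias runs on fixtures with shared tokens do not reach
the analytic extremes; tests that need exact extremes use single-token
synthetic benchmarks.

What the generator does *not* emulate: the anisotropy of transformer
embedding spaces, frequency effects, lexical semantics. A green
calibration test establishes that the statistics behave correctly on a
stated geometric world — not that any particular real model is or is not
biased, and not the published scores of real models, which require
downloading pretrained weights and are deliberately outside the test
suite.

### Calibration design

`calibration_experiment()` pairs seeds across the β grid (table j of every
β cell uses seed `seed + j`): common random numbers, the standard variance
reduction for comparing means across a grid. With 20 seeds per cell the
mean score is strictly increasing over β ∈ {0, 0.2, ..., 1.6} with
Spearman ρ = 1 at the default seed; unpaired designs need an order of
magnitude more replicates for a stable ordering, because between-table
noise (SD ≈ 0.1) is large relative to adjacent-β differences at small β.

## Benchmarks and fixtures

A benchmark couples exactly two equal-size target sets with ≥ 1 labelled
attribute groups; targets must be disjoint, groups pairwise disjoint, and
every term unique within its set — a term with a real double status
(breast cancer occurs in men) is still listed once, in the set where its
prevalence overwhelmingly sits. Multi-class benchmarks (E-2, H-1) store
three labelled groups of four that pool to the canonical 12-word list:
pooling is an operation, so the same file serves pooled SD-WEAT and
pairwise WEAT.

The published summary table prints only two example terms per set. The
bundled fixtures therefore carry those example terms plus clearly-labelled
synthetic placeholders (`g1-t1-term3`, ...) sized to the documented counts,
and validate against the built-in manifest; users with the complete
published word lists can drop in files of the same shape. The WEAT-7
gender attribute lists (8 terms per group) are complete and verbatim.
Fixture casing follows the published table; the `exact-then-lower` policy
absorbs the difference for uncased models.

## Importance analysis

To ask *which* attribute words drive a score, the pooled list is augmented
with 16 inanimate noise words (rock, dirt, ..., laptop — chosen to have no
plausible interaction with medical conditions), M = 500 draws are run, and
each word's effect sizes are averaged by the slot it occupied: tests where
the word sat in attribute set A contribute to its "Target 1" cell, B to
"Target 2". Cells a word never occupied stay missing — zero-filling would
disguise sparse occupancy as neutrality. Occupancy counts are reported and
must sum to 2M per slot, which the suite checks exactly. Under planted
gender-style bias the planted attribute words outrank the noise words in
their aligned slot; under the null the two populations are statistically
indistinguishable — both are fixed-seed simulation tests.

## Numerical notes and edge cases

* Zero-norm vectors are rejected at table construction, lookup and
  pooling ("degenerate-embedding"); opposite vectors that mean-pool to
  zero are caught at embed time.
* `σ = 0` in the effect size raises "zero-variance-association" rather
  than returning NaN; the permutation p remains defined (all partitions
  tie, p = 0 under strict inequality) and is documented as a degenerate
  edge.
* Tie detection in the permutation test uses a relative 1e-12 band;
  continuous random inputs never approach it, and constructed ties are
  tested explicitly.
* All randomness is seeded through R's RNG; every result object echoes
  its seed, and same-seed runs are bit-identical at the level of reported
  numbers. Functions that take a seed restore the caller's RNG state.
* SD-WEAT effect sizes for the K draws are computed from one precomputed
  target × pool cosine matrix; this is an evaluation-order optimization
  only and is tested equal (to 1e-12) against per-draw brute force.

## Known limitations

* The bundled fixtures are structurally faithful but lexically incomplete
  (placeholder slots), so absolute scores on them are not comparable to
  published model scores; shapes, counts and operating characteristics
  are.
* The SD-WEAT p-value is this package's construction; the original
  formula was not published in reprintable form, and no claim of
  equivalence is made.
* Scores from K random draws carry Monte-Carlo noise of order
  `score/√(2K)`; K = 100 gives roughly ±7% relative noise. Raise K for
  ranking models that are close.
* Contextual backends embed bare terms with no sentence template;
  context-sensitivity of bias is out of scope.
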
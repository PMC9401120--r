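---
title: "Copy-number fractioning and similarity indices: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number fractioning and similarity indices: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repfrac)
```

## The analytical problem

A T-cell response against a large cellular antigen involves clones of so many
specificities that the responding receptors share no detectable sequence
motif. Immunization nevertheless changes *population characteristics* of the
repertoire: expanding antigen-specific private clones displace the public
clonotypes that normally dominate parts of the copy-number spectrum. Public
clonotypes carry a recognizable statistical signature — considerably higher
copy number, shorter CDR3β, restricted VJ segment usage, convergent
nucleotide coding, and CDR3-similar satellite clonotypes — so their
displacement is measurable even when the displacing clones themselves share
nothing. `repfrac` measures this displacement per copy-number fraction, which
localizes *where in the clone-size spectrum* the response sits and when.

## Preprocessing model

The package consumes clonotype tables produced by an upstream read processor
(nucleotide CDR3β sequence, read count, amino-acid sequence, V/J calls) and
assumes error correction and removal of nonfunctional sequences happened
there; a safety filter drops rows whose amino-acid sequence contains `*` or
`_`. The preprocessing order is fixed:

1. optional depth normalization by **downsampling** nucleotide-sequence read
   counts without replacement (multivariate hypergeometric, seeded) to a
   common total — before merging, so clonotype composition reflects the
   normalized depth;
2. **merging** all nucleotide sequences with identical amino-acid sequence
   into one clonotype; the clonotype inherits the V/J calls of the variant
   with the highest read count. The source material does not say how ties are
   resolved; this implementation deterministically takes the
   lexicographically smallest nucleotide sequence, a documented convention
   rather than anyone's intent;
3. **exclusion of copy-number-1 clonotypes** (likely polymerase artefacts),
   applied at the clonotype level after merging. CN = 2 is therefore the
   smallest observable clone size.

Merged repertoires are canonically ordered (decreasing CN, then CDR3), which
makes write → read → merge round trips exact.

## The indices

With `R` a reflexive, symmetric relation on clonotypes (`relation_ld()`,
`relation_vj()`, `relation_identity()`, `relation_nc_count()`, or any
user-supplied predicate via `relation_custom()`):

* `rhi()` is the fraction of similar unordered clonotype pairs,
  `Σ_{i<j} 1(x_i R x_j) / C(m,2)` — a Simpson-type pair-sampling probability.
  It deliberately ignores copy numbers, because it is applied to fractions
  that are already defined by copy number.
* `cdi()` averages `D_NC(x) = 1 − Σ (c_i/ν)²` over clonotypes, where `c_i`
  are the read counts of the nucleotide variants of `x`.
* `rsi()` compares two repertoires; its self-similarity sums run over all
  ordered pairs *including* the diagonal, exactly as the double index in its
  definition dictates. Under clonotype identity it equals the Sørensen index;
  it can exceed 1 for non-transitive relations, which is why the combined
  dissimilarity `d = 1 − Σ α_i min(RSI_i, 1)` caps each term.
* `dissimilarity()` with `spec_vj` (V-identity and J-identity, weights ½/½)
  or `spec_nc` (similar nucleotide-coding counts) yields the `d_VJ` and
  `d_NC` matrices used for classification.

**Degenerate inputs.** An index that is undefined — RHI on fewer than two
clonotypes, CDI/RSI on an empty fraction, Jaccard of two empty sets — returns
`NA` rather than 0. Silent zeros would systematically bias the rank tests in
sparse fractions; `NA` values are instead dropped per animal and a fraction
is skipped (marked, not tested) when fewer than two defined values remain in
a group.

**The NC relation's threshold.** Two clonotypes are coding-similar when their
nucleotide-variant counts coincide or both "exceed 5"; this implementation
reads that strictly (both ≥ 6) and exposes the threshold as a parameter.

**Computation.** Equivalence-type relations (VJ, identity, coding-count
classes) are counted via class sizes rather than explicit pair loops; the
Levenshtein relation buckets sequences by length and only compares buckets
whose lengths differ by at most the distance cap. Both are pure
optimizations: the test suite gates them against full brute-force pair
matrices on hundreds of random instances.

### The copy-number-weighted variants

The weighted RSI replaces counts with relative copy numbers
`p_i = ν_i / Σν`:
`RSI^w = 2 Σ 1(x_i R y_j) p_i q_j / (Σ 1(x_i R x_j) p_i p_j + Σ 1(y_i R y_j) q_i q_j)`.
Under clonotype identity this is exactly the Morisita–Horn index, and with
uniform copy numbers it reduces to the unweighted RSI.

For the weighted RHI several analogous formulas are conceivable and their
desirable limiting behaviours conflict: a version that includes
same-clonotype read pairs reproduces the classical Simpson index under
identity but is dominated by any single large clone, while a version over
distinct clonotype pairs collapses to the unweighted RHI for uniform copy
numbers and lets a dominant but isolated clone's contribution vanish. This
package chooses the latter —
`RHI^w = Σ_{i<j} 1(x_i R x_j) ν_i ν_j / Σ_{i<j} ν_i ν_j` —
because both of its limits are properties one wants when screening fractions
for homogeneity shifts, and because it is the form consistent with the
weighted RSI above. Under the identity relation it is identically 0 on a
duplicate-free repertoire, so it is only meaningful for non-trivial
relations.

## Fraction schemes

The log2 scheme uses half-open integer intervals: fraction 1 is CN = 2,
fraction `k` (2..9) is `2^(k−1) < CN ≤ 2^k`, fraction 10 is CN > 512. All
boundary arithmetic is integer (`findInterval` on precomputed lower bounds),
so no floating-point log is ever compared against a boundary. Empty fractions
are retained, giving downstream statistics a fixed 10-column layout. The
coarse tripartition (CN = 2; 2 < CN ≤ 500; CN > 500) is implemented exactly
as printed; note the deliberate asymmetry that clonotypes with
500 < CN ≤ 512 belong to the high tripartition class but to log2 fraction 9
— both definitions are kept as stated, and a test pins the asymmetry down.
Custom schemes (e.g. a modified high-CN region starting at `log2(CN) > 8`)
are available through `fraction_scheme("custom", lower = ...)` and the
`cn_min`/`cn_max` arguments of `sub_repertoire()`.

## Group statistics

Per index and fraction, treated animals are compared to controls with the
Mann–Whitney U test; the default alternative is `"less"` (the displacement
mechanism predicts index *decreases*). Exact p-values are used whenever both
groups have fewer than 50 observations and no ties occur — which covers the
10-vs-20 design — with the tie/continuity-corrected normal approximation as
fallback. The 10 p-values of one index row are Holm-corrected independently
of other rows; skipped fractions are excluded from the correction so they do
not pay penalties for untestable hypotheses. The Jaccard index is reported
descriptively only (`pairwise_jaccard()`): each animal takes part in many
pairs, so the values are mutually dependent and p-values would be invalid.

## Classification

`dissimilarity_matrix()` builds `d_VJ` or `d_NC` over all sample pairs
(symmetric, zero diagonal, entries in [0, 1]; empty sub-repertoires are
excluded with a warning). Unsupervised structure comes from K-medoids
(`cluster::pam`, BUILD + SWAP); because SWAP is a local search, `kmedoids()`
additionally runs a seeded set of random-initialization restarts (default 10)
and keeps the lowest-cost solution — on small instances this reproducibly
attains the exhaustive-search optimum that the test suite checks against.
`mds_embed()` (classical metric MDS) is used for visualization only; tests
compare embedded distances, never raw coordinates, since orientation is
arbitrary.

Supervised classification is leave-one-out nearest-medoid: for each held-out
sample, one medoid per label group is computed on the remaining samples (the
training sample minimizing the summed within-group dissimilarity, i.e. PAM
with k = 1 per group) and the held-out sample takes the nearer medoid's
label. Distance ties go to the first factor level — the control/reference
class, conservative toward the null — and are logged per sample. The
confusion table is evaluated with a two-sided Fisher exact test. Time points
known to carry no effect in the analyzed region can be excluded from the
supervised step (`exclude =`), mirroring the practice of restricting the
late-effect classification to the affected groups. One caveat is inherited
from the procedure itself: when sub-repertoires and criteria are chosen after
inspecting the same data that are then classified, discriminatory power can
be overestimated; the package reproduces the procedure and documents the
caveat rather than correcting for it.

## The synthetic cohort generator

No sequencing data are distributed with the method, so every claim the
package makes is validated on synthetic cohorts whose *architecture* encodes
the public/private mechanism:

* a shared pool of public prototypes: CDR3 length shifted −2 relative to the
  private length law (discretized normal, mode 14, range 8–20), VJ pairs
  drawn from a concentrated usage distribution (Dirichlet with parameter
  1/concentration; default concentration 50 ≈ 6 effective pairs out of 240),
  2–8 distinct nucleotide codings each (uniform synonymous codons, standard
  genetic code, distinctness by rejection), plus 3 Levenshtein-distance-1
  satellites per prototype sharing its VJ pair;
* per animal: each pool clonotype present independently with probability 0.8;
  prototype copy numbers are the base law times a ×40 multiplier, satellites
  straddle the spectrum (half base, half multiplied) so cluster structure
  exists in both the low- and the high-CN region;
* private clonotypes unique to the animal: uniform VJ usage, single
  nucleotide coding with probability 0.92, copy numbers from the base law —
  a discrete power law with exponent 2.5 truncated to [2, 20000], which
  reproduces the monotone decaying fraction occupancy of real repertoires;
* an injectable effect: `effect_config()` places new private, singly coded
  clonotypes into a chosen log2 fraction range. The early-response preset
  injects 60 clonotypes into fractions 7–10; the late-response preset
  (`effect_late()`) injects 400 into fractions 1–2, reflecting that the late
  accumulation involves many distinct low-copy clones. A `"public"` regime
  expands pool clonotypes instead, for tracing analyses of known public sets.

Cohort sizes default to 20 control vs 10 treated — the design of one
immunization time point against pooled controls — at a desk scale of 2000
clonotypes per animal; the calibration suites run 8 vs 8 animals at 600
clonotypes, since type-I calibration is a property of the test machinery,
not of effect sizes. Where the emulated system fixes no quantity (pool size,
share probability, multipliers, injection counts), values were set once from
an a-priori power sketch of the index shifts they produce and are exposed as
free `cohort_config()` parameters.

All randomness flows from one root seed: `generate_cohort()` derives one
substream seed for the pool, one per animal, and one per injection
(`sample.int` on the root seed, kept below `2^31`), so cohorts are
bit-identical across runs and insertion of further animals does not perturb
earlier ones.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: V(D)J recombination mechanics and generation
probabilities (public CDR3s are random strings, not high-probability
rearrangements), sequencing error and PCR amplification noise, length-
dependent VJ correlations, clonal covariance structure between animals
beyond the shared pool, and TCRα pairing. The generator demonstrates that
the indices detect the displacement signature *when the assumed architecture
holds*; it cannot demonstrate that real repertoires satisfy the
architecture.

## Validation strategy

The test suite is organized around independent oracles: brute-force pair
matrices for RHI/RSI (all four relations, hundreds of random instances up to
300 clonotypes), naive recursion for the Levenshtein distance, full 2×2
enumeration for the Fisher test, hand step-down for Holm, exhaustive medoid
search for PAM on n ≤ 8, closed forms (Sørensen, Morisita–Horn, 1 − 1/k) for
the index collapses, and `Biostrings::translate` for the generator's reverse
translation. Null calibration uses ≥ 500 simulated no-effect comparison rows
(Holm-adjusted rejection rate must stay within binomial slack of the nominal
level) and 200 no-effect leave-one-out runs (mean accuracy within two
standard errors of 50%, which holds exactly under exchangeability because
medoid selection never sees the held-out sample's row). Effect recovery
checks the qualitative headline: injections into fractions 7–10 produce
Holm-significant decreases of RHI_VJ and CDI there and nowhere in the middle
fractions 5–6; injections into fractions 1–2 produce the late low-CN
pattern; and `d_VJ` leave-one-out classification of `X^top` beats random
labeling.

## Known limitations

* Non-transitive relations (Levenshtein) cost O(m²) pair evaluations within
  each length bucket; repertoires of 10⁵ clonotypes are feasible per fraction
  but slow for the full unfractioned repertoire.
* The weighted RHI is informative only for non-trivial relations (see above).
* `d_NC` compares coding-count *distributions* compositionally; it carries no
  information at all when every clonotype in a region is singly coded.
* The LOO evaluation inherits the optimistic bias of post-hoc region/criterion
  selection noted above.
* Downsampling treats reads as exchangeable tokens; it does not model
  amplification bias.
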
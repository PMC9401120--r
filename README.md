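# repfrac

Copy-number fractioning and similarity indices for T-cell receptor (TCRβ)
repertoires.

## The problem

After immunization with a large, complex antigen (many epitopes), the
responding T-cell clones are so diverse that they leave no single common motif
in the repertoire. Standard analyses that watch only the highest-copy clones
see an effect for a day or two and then lose it, although proliferation
continues. `repfrac` implements an analysis strategy that localizes such
diffuse immune responses *within* the repertoire instead: the repertoire is
split into standardized copy-number (CN) fractions, and each fraction is
monitored with similarity indices that respond to the *displacement of public
clonotypes by expanding private clones* — a signature that is largely
independent of the antigen.

It is written for immunologists and bioinformaticians working with bulk CDR3β
clonotype tables (MiTCR- or AIRR-rearrangement-style TSV files): one row per
nucleotide sequence with read count, CDR3β amino-acid sequence and V/J calls.

## The statistics

A repertoire is a set of clonotypes `X = {(x_i, ν(x_i))}` where a clonotype
is one CDR3β amino-acid sequence with an assigned V and J segment and copy
number ν (summed reads of all nucleotide sequences coding for it). For an
arbitrary reflexive, symmetric similarity relation `R` on clonotypes:

* **RHI (Repertoire Homogeneity Index)** — a generalized Simpson index:
  the probability that a random pair of distinct clonotypes is similar,
  `RHI_R(X) = Σ_{i<j} 1(x_i R x_j) / C(m,2)`.
  Relations used: `R_LD` (CDR3β Levenshtein distance ≤ 1) and `R_VJ`
  (equal V and J segment).
* **CDI (Coding Diversity Index)** — mean over clonotypes of
  `D_NC(x) = 1 − Σ_i (c_i/ν)²`, the Simpson-type diversity of a clonotype's
  nucleotide-variant read counts `c_i`. Near 0: one dominant coding;
  near 1: balanced convergent coding.
* **RSI (Repertoire Similarity Index)** — the cross-repertoire analogue,
  `RSI_R(X,Y) = 2·(Σ 1(x_i R y_j)/nm) / (Σ 1(x_i R x_j)/m² + Σ 1(y_i R y_j)/n²)`,
  which collapses to the Sørensen index under clonotype identity (and to
  Morisita–Horn in its CN-weighted form).
* **Dissimilarity** `d_{α,R1..Rk}(X,Y) = 1 − Σ α_i · min(RSI_{R_i}, 1)` —
  used as `d_VJ` (identity of V and of J, weights ½/½) and `d_NC`
  (similar nucleotide-coding counts) for K-medoid clustering, metric MDS and
  leave-one-out nearest-medoid classification with Fisher-exact evaluation.

Repertoires are split on the log2 CN grid into 10 fractions — fraction 1 is
CN = 2 (singletons are removed in preprocessing), fractions k = 2..9 are
`2^(k−1) < CN ≤ 2^k`, fraction 10 is CN > 512 — and each fraction is compared
between cohorts with one-tailed Mann–Whitney U tests, Holm-corrected per
index row. Two regions matter downstream: `X^top` (CN > 64), where effects
appear early, and `X^bottom` (CN ≤ 4), where they appear late.

Because no public sequencing data accompany the method, the package ships a
synthetic cohort generator (`generate_cohort()`) that emulates the
public/private architecture the indices exploit — shared high-CN public
clonotypes with short CDR3s, restricted VJ usage, convergent nucleotide
coding and LD-1 satellite clusters, plus animal-unique private clonotypes —
with injectable immunization effects for validation end to end.

## Worked example

```r
library(repfrac)

cfg <- cohort_config(n_control = 8, n_treated = 6, n_clonotypes_target = 1200,
                     public_pool_size = 100, seed = 42)
cohort <- generate_cohort(cfg)
summary(cohort$repertoires[[1]])
#> Repertoire 'C01': 1192 clonotypes, 41592 reads
#>   mean CDR3 length: 13.38
#>   clonotypes per log2 copy-number fraction:
#>   1   2   3   4   5   6   7   8   9  10
#> 500 279 138  56  12   4 145  29  21   8

ctl <- cohort$repertoires[cohort$labels == "control"]
imm <- cohort$repertoires[cohort$labels == "immunized"]
compare_cohorts(ctl, imm)
#> Fraction-wise cohort comparison (less Mann-Whitney U, Holm-corrected per index row)
#> scheme: log2; 8 control vs 6 treated animals
#>
#>        1    2    3    4    5    6    7    8    9    10
#> rhi_ld                                **
#> rhi_vj                                **   *    *    *
#> cdi                                   **   **   **   **
#>
#> (adjusted p: *** <0.001, ** <0.01, * <0.05, '.' not testable)

classify_cohort(cohort$repertoires, labels = cohort$labels,
                sub = "top", criterion = "vj", seed = 1)
#> Repertoire classification (criterion: d_VJ)
#> K-medoids (k = 2) cluster sizes: 8 / 6; cost = 0.07586
#> Leave-one-out nearest-medoid classification
#>            predicted
#> true        control immunized
#>   control         8         0
#>   immunized       0         6
#> accuracy: 100.0%  (Fisher exact p = 0.000333)
```

The cohort here carries a simulated early immunization effect (60 private
clonotypes expanded into log2 fractions 7–10 of each treated animal). The
comparison localizes the effect exactly there — homogeneity (RHI) and coding
diversity (CDI) drop in the targeted high-CN fractions, the untargeted middle
fractions stay silent — and the d_VJ-based leave-one-out classification of
the CN > 64 sub-repertoire separates the groups perfectly.

Real data enter through `read_clonotype_table()` /
`preprocess_table()` (dialects `"mitcr"`, `"airr"`, `"simple"`), and the
whole pipeline can be driven from one YAML config via `run_study()` or the
CLI at `inst/cli/repfrac.R` (subcommands `simulate`, `preprocess`,
`fractions`, `indices`, `compare`, `classify`, `distribute`, `run`).

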
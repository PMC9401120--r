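#' Repertoire Homogeneity Index (RHI)
#'
#' The probability that a randomly sampled pair of distinct clonotypes within
#' a repertoire (or repertoire fraction) is similar under the relation `R`:
#' \deqn{RHI_R(X) = \sum_{i<j} 1(x_i R x_j) / \binom{m}{2}.}
#' This is a Simpson-type index generalized from clonotype identity to an
#' arbitrary reflexive, symmetric similarity criterion; an increase reflects
#' homogenization of the repertoire with respect to `R`. Copy numbers are not
#' taken into account, which is intentional when the index is applied to
#' fractions already defined by copy number (see [rhi_weighted()] for the
#' copy-number-weighted variant).
#'
#' @param x repertoire, sub-repertoire or clonotype data.frame.
#' @param relation a [similarity relation][relations].
#' @return numeric in `[0, 1]`; `NA` when fewer than two clonotypes are
#'   present (the index is undefined, not zero).
#' @examples
#' cl <- data.frame(cdr3_aa = c("CASSLG", "CASSLA", "CATT"),
#'                  v_segment = "TRBV1", j_segment = "TRBJ1",
#'                  copy_number = c(5L, 3L, 2L))
#' rhi(cl, relation_ld())   # only (CASSLG, CASSLA) is within distance 1
#' rhi(cl, relation_vj())
#' @export
rhi <- function(x, relation) {
  df <- as_clonotype_df(x)
  m <- nrow(df)
  if (m < 2L) return(NA_real_)
  pairs_within(relation, df) / choose(m, 2)
}

#' Copy-number-weighted Repertoire Homogeneity Index
#'
#' Weighted variant of [rhi()] in which clonotype pairs are sampled with
#' probability proportional to the product of their copy numbers (pairs of
#' distinct clonotypes only):
#' \deqn{RHI^w_R(X) = \sum_{i<j} 1(x_i R x_j)\,\nu_i \nu_j \big/
#'   \sum_{i<j} \nu_i \nu_j.}
#' With equal copy numbers this reduces to the unweighted RHI, and the
#' contribution of a single dominant clonotype that is similar to nothing but
#' itself vanishes as its copy number grows.
#'
#' @inheritParams rhi
#' @return numeric in `[0, 1]`, `NA` when fewer than two clonotypes.
#' @export
rhi_weighted <- function(x, relation) {
  df <- as_clonotype_df(x)
  m <- nrow(df)
  if (m < 2L) return(NA_real_)
  w <- as.numeric(df$copy_number)
  denom <- (sum(w)^2 - sum(w^2)) / 2
  if (denom <= 0) return(NA_real_)
  pairs_within(relation, df, w = w) / denom
}

#' Nucleotide-coding diversity of one clonotype
#'
#' Degeneracy of the genetic code lets several nucleotide sequences code for
#' one CDR3beta amino-acid sequence. The coding diversity of a clonotype is a
#' Simpson-type index on its variant read counts \eqn{c_1, ..., c_k} (summing
#' to the copy number \eqn{\nu}):
#' \deqn{D_{NC} = 1 - \sum_i (c_i/\nu)^2 .}
#' A value near 0 reflects predominant coding by a single nucleotide sequence;
#' values near 1 reflect balanced coding by many variants.
#'
#' @param read_counts positive integer vector of variant read counts.
#' @return numeric in `[0, 1)`.
#' @examples
#' coding_diversity(10)        # single variant: 0
#' coding_diversity(c(1, 1))   # two balanced variants: 0.5
#' coding_diversity(c(3, 1))   # 0.375
#' @export
coding_diversity <- function(read_counts) {
  if (!length(read_counts) || any(read_counts < 1))
    stop("read_counts must be a non-empty vector of positive counts")
  tot <- sum(as.numeric(read_counts))
  1 - sum((as.numeric(read_counts) / tot)^2)
}

#' Coding Diversity Index (CDI)
#'
#' The mean [coding_diversity()] over all clonotypes of a repertoire or
#' fraction; a decrease indicates that expanding clonotypes are coded by few
#' dominant nucleotide sequences.
#'
#' @param x repertoire, sub-repertoire or clonotype data.frame (needs the
#'   per-clonotype `d_nc` column maintained by [merge_to_clonotypes()] and the
#'   synthetic generator).
#' @return numeric in `[0, 1)`; `NA` for an empty input.
#' @export
cdi <- function(x) {
  df <- as_clonotype_df(x)
  if (!nrow(df)) return(NA_real_)
  if (is.null(df$d_nc)) stop("clonotype table lacks 'd_nc'")
  mean(df$d_nc)
}

#' Jaccard index of clonal overlap
#'
#' `|A intersect B| / |A union B|` over the CDR3beta amino-acid sets of two
#' repertoires (fractions), quantifying clonal overlap between animals. With
#' `strict = TRUE` clonotypes must also agree in V and J segment.
#'
#' @param a,b repertoires, sub-repertoires or clonotype data.frames.
#' @param strict compare `(cdr3_aa, V, J)` instead of `cdr3_aa` alone.
#' @return numeric in `[0, 1]`; `NA` when both sets are empty.
#' @export
jaccard <- function(a, b, strict = FALSE) {
  da <- as_clonotype_df(a); db <- as_clonotype_df(b)
  ka <- if (strict) paste(da$cdr3_aa, da$v_segment, da$j_segment, sep = "\r") else da$cdr3_aa
  kb <- if (strict) paste(db$cdr3_aa, db$v_segment, db$j_segment, sep = "\r") else db$cdr3_aa
  ka <- unique(ka); kb <- unique(kb)
  u <- length(union(ka, kb))
  if (!u) return(NA_real_)
  length(intersect(ka, kb)) / u
}

#' Repertoire Similarity Index (RSI)
#'
#' Cross-repertoire generalization of the RHI, comparing clonotypes of `X`
#' with clonotypes of another repertoire `Y`:
#' \deqn{RSI_R(X,Y) = \frac{2 \sum_{i,j} 1(x_i R y_j) / (nm)}
#'   {\sum_{i,j=1}^{m} 1(x_i R x_j)/m^2 + \sum_{i,j=1}^{n} 1(y_i R y_j)/n^2}}
#' where the self-similarity sums run over all ordered pairs including the
#' diagonal (`R` is reflexive). Under the identity relation on duplicate-free
#' sets the RSI coincides with the Sorensen index. The index is symmetric and
#' non-negative; it can exceed 1 for non-transitive relations.
#'
#' @param x,y repertoires, sub-repertoires or clonotype data.frames.
#' @inheritParams rhi
#' @return numeric `>= 0`; `NA` when either side is empty.
#' @export
rsi <- function(x, y, relation) {
  dx <- as_clonotype_df(x); dy <- as_clonotype_df(y)
  m <- nrow(dx); n <- nrow(dy)
  if (!m || !n) return(NA_real_)
  cross <- pairs_between(relation, dx, dy)
  sx <- 2 * pairs_within(relation, dx) + m   # ordered pairs incl. diagonal
  sy <- 2 * pairs_within(relation, dy) + n
  2 * (cross / (n * m)) / (sx / m^2 + sy / n^2)
}

#' Copy-number-weighted Repertoire Similarity Index
#'
#' Weighted variant of [rsi()] in which every clonotype enters with its
#' relative copy number \eqn{p_i = \nu_i / \sum_k \nu_k}:
#' \deqn{RSI^w_R(X,Y) = \frac{2 \sum_{i,j} 1(x_i R y_j)\, p_i q_j}
#'   {\sum_{i,j} 1(x_i R x_j)\, p_i p_j + \sum_{i,j} 1(y_i R y_j)\, q_i q_j}.}
#' Under the identity relation this is exactly the Morisita-Horn index of the
#' two copy-number vectors, and with uniform copy numbers it reduces to the
#' unweighted RSI.
#'
#' @inheritParams rsi
#' @return numeric `>= 0`; `NA` when either side is empty.
#' @export
rsi_weighted <- function(x, y, relation) {
  dx <- as_clonotype_df(x); dy <- as_clonotype_df(y)
  m <- nrow(dx); n <- nrow(dy)
  if (!m || !n) return(NA_real_)
  p <- as.numeric(dx$copy_number); p <- p / sum(p)
  q <- as.numeric(dy$copy_number); q <- q / sum(q)
  cross <- pairs_between(relation, dx, dy, wx = p, wy = q)
  sx <- 2 * pairs_within(relation, dx, w = p) + sum(p^2)
  sy <- 2 * pairs_within(relation, dy, w = q) + sum(q^2)
  2 * cross / (sx + sy)
}

#' Weighted dissimilarity between repertoires
#'
#' A dissimilarity specification combines `k` similarity relations
#' `R_1, ..., R_k` with non-negative weights summing to 1; the dissimilarity
#' of two repertoires is
#' \deqn{d_{\alpha,R_1..R_k}(X,Y) = 1 - \sum_i \alpha_i\,
#'   \min(RSI_{R_i}(X,Y), 1) \in [0, 1],}
#' which is symmetric and zero for `X = Y`. The two criteria used for
#' classification are `d_VJ` (identity of V and of J segment as two equally
#' weighted criteria) and `d_NC` (the nucleotide-coding count relation as the
#' single criterion).
#'
#' @param relations list of [similarity relations][relations].
#' @param weights numeric weights, non-negative, summing to 1.
#' @param weighted use the copy-number-weighted [rsi_weighted()] instead of
#'   the unweighted [rsi()].
#' @return `dissimilarity_spec` constructs the specification;
#'   `dissimilarity` returns a numeric in `[0, 1]` (`NA` when any RSI is
#'   undefined).
#' @export
dissimilarity_spec <- function(relations, weights = NULL, weighted = FALSE) {
  if (inherits(relations, "similarity_relation")) relations <- list(relations)
  k <- length(relations)
  weights <- weights %||% rep(1 / k, k)
  if (length(weights) != k) stop("weights and relations lengths differ")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  structure(list(relations = relations, weights = weights, weighted = weighted),
            class = "dissimilarity_spec")
}

#' @rdname dissimilarity_spec
#' @param x,y repertoires, sub-repertoires or clonotype data.frames.
#' @param spec a `dissimilarity_spec`.
#' @export
dissimilarity <- function(x, y, spec) {
  stopifnot(inherits(spec, "dissimilarity_spec"))
  fun <- if (spec$weighted) rsi_weighted else rsi
  vals <- vapply(spec$relations, function(r) fun(x, y, r), numeric(1))
  if (anyNA(vals)) return(NA_real_)
  1 - sum(spec$weights * pmin(vals, 1))
}

# The two dissimilarity criteria used throughout classification.
spec_vj <- function(weighted = FALSE)
  dissimilarity_spec(list(relation_v(), relation_j()), c(0.5, 0.5), weighted)

spec_nc <- function(threshold = 5L, weighted = FALSE)
  dissimilarity_spec(list(relation_nc_count(threshold)), 1, weighted)
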
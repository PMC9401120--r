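#' Levenshtein distance
#'
#' Unit-cost edit distance (substitutions, insertions and deletions each cost
#' 1) between CDR3 amino-acid sequences, computed elementwise with recycling.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @examples
#' levenshtein("CASSLG", c("CASSLG", "CASSLA", "CATT"))
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- utils::adist(a[i], b[i])[1L, 1L]
  out
}

# A similarity relation is a named reflexive, symmetric predicate over
# clonotype pairs. For equivalence relations ('key' type) pair counts are
# computed from class sizes; the Levenshtein relation ('ld') is computed with
# length-bucketed distance matrices; user-supplied predicates fall back to an
# explicit pairwise loop.
new_relation <- function(name, type, key = NULL, predicate, max_d = NULL) {
  structure(list(name = name, type = type, key = key,
                 predicate = predicate, max_d = max_d),
            class = "similarity_relation")
}

#' @export
print.similarity_relation <- function(x, ...) {
  cat("similarity relation '", x$name, "' (", x$type, ")\n", sep = "")
  invisible(x)
}

#' Similarity relations on clonotypes
#'
#' Constructors for the reflexive, symmetric relations used by the homogeneity
#' and similarity indices:
#' \describe{
#'   \item{`relation_vj()`}{equal V segment and equal J segment.}
#'   \item{`relation_v()`, `relation_j()`}{equal V (resp. J) segment only;
#'     these are the two equally weighted criteria of the VJ dissimilarity.}
#'   \item{`relation_ld(max_d)`}{Levenshtein distance of the CDR3beta
#'     amino-acid sequences at most `max_d` (default 1).}
#'   \item{`relation_identity(strict)`}{equal CDR3beta sequence; with
#'     `strict = TRUE` the V and J segments must match too.}
#'   \item{`relation_nc_count(threshold)`}{the numbers of distinct nucleotide
#'     sequences coding for the two clonotypes either coincide or exceed
#'     `threshold` (default 5, i.e. both at least 6) for both.}
#'   \item{`relation_custom(name, predicate)`}{arbitrary predicate
#'     `function(a, b)` over one-row clonotype data.frames; evaluated pairwise,
#'     so only suitable for small inputs.}
#' }
#'
#' @param max_d maximal Levenshtein distance still counted as similar.
#' @param strict for `relation_identity`: also require equal V and J.
#' @param threshold for `relation_nc_count`: variant-count value that both
#'   clonotypes must strictly exceed to be similar without coinciding.
#' @param name,predicate for `relation_custom`.
#' @return a `similarity_relation`.
#' @name relations
NULL

#' @rdname relations
#' @export
relation_vj <- function() {
  new_relation("VJ", "key",
               key = function(df) paste(df$v_segment, df$j_segment, sep = "\r"),
               predicate = function(a, b)
                 a$v_segment == b$v_segment && a$j_segment == b$j_segment)
}

#' @rdname relations
#' @export
relation_v <- function() {
  new_relation("V", "key", key = function(df) df$v_segment,
               predicate = function(a, b) a$v_segment == b$v_segment)
}

#' @rdname relations
#' @export
relation_j <- function() {
  new_relation("J", "key", key = function(df) df$j_segment,
               predicate = function(a, b) a$j_segment == b$j_segment)
}

#' @rdname relations
#' @export
relation_identity <- function(strict = FALSE) {
  if (strict)
    new_relation("identity(aa+VJ)", "key",
                 key = function(df) paste(df$cdr3_aa, df$v_segment, df$j_segment,
                                          sep = "\r"),
                 predicate = function(a, b)
                   a$cdr3_aa == b$cdr3_aa && a$v_segment == b$v_segment &&
                   a$j_segment == b$j_segment)
  else
    new_relation("identity", "key", key = function(df) df$cdr3_aa,
                 predicate = function(a, b) a$cdr3_aa == b$cdr3_aa)
}

#' @rdname relations
#' @export
relation_nc_count <- function(threshold = 5L) {
  force(threshold)
  new_relation(paste0("NC(>", threshold, ")"), "key",
               key = function(df) {
                 nv <- df$n_variants
                 if (is.null(nv)) stop("clonotype table lacks 'n_variants'")
                 ifelse(nv > threshold, "many", as.character(nv))
               },
               predicate = function(a, b)
                 a$n_variants == b$n_variants ||
                 (a$n_variants > threshold && b$n_variants > threshold))
}

#' @rdname relations
#' @export
relation_ld <- function(max_d = 1L) {
  force(max_d)
  new_relation(paste0("LD<=", max_d), "ld",
               predicate = function(a, b)
                 levenshtein(a$cdr3_aa, b$cdr3_aa) <= max_d,
               max_d = max_d)
}

#' @rdname relations
#' @export
relation_custom <- function(name, predicate) {
  stopifnot(is.function(predicate))
  new_relation(name, "predicate", predicate = predicate)
}

## ---- internal pair counting -------------------------------------------------

# Number of unordered pairs i < j with x_i R x_j; optionally weighted by
# products of clonotype weights w_i w_j.
pairs_within <- function(rel, df, w = NULL) {
  m <- nrow(df)
  if (m < 2L) return(0)
  switch(rel$type,
    key = {
      k <- rel$key(df)
      if (is.null(w)) {
        tab <- table(k)
        sum(choose(tab, 2))
      } else {
        s1 <- rowsum(w, k)[, 1L]
        s2 <- rowsum(w^2, k)[, 1L]
        sum(s1^2 - s2) / 2
      }
    },
    ld = ld_pairs_within(df$cdr3_aa, rel$max_d, w),
    predicate = {
      acc <- 0
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
        if (isTRUE(rel$predicate(df[i, , drop = FALSE], df[j, , drop = FALSE])))
          acc <- acc + if (is.null(w)) 1 else w[i] * w[j]
      acc
    })
}

# Sum over all ordered cross pairs (i, j) of 1(x_i R y_j), optionally
# weighted by w_x[i] * w_y[j].
pairs_between <- function(rel, dfx, dfy, wx = NULL, wy = NULL) {
  m <- nrow(dfx); n <- nrow(dfy)
  if (!m || !n) return(0)
  switch(rel$type,
    key = {
      kx <- rel$key(dfx); ky <- rel$key(dfy)
      if (is.null(wx)) {
        tx <- table(kx); ty <- table(ky)
        shared <- intersect(names(tx), names(ty))
        sum(as.numeric(tx[shared]) * as.numeric(ty[shared]))
      } else {
        sx <- rowsum(wx, kx); sy <- rowsum(wy, ky)
        shared <- intersect(rownames(sx), rownames(sy))
        sum(sx[shared, 1L] * sy[shared, 1L])
      }
    },
    ld = ld_pairs_between(dfx$cdr3_aa, dfy$cdr3_aa, rel$max_d, wx, wy),
    predicate = {
      acc <- 0
      for (i in seq_len(m)) for (j in seq_len(n))
        if (isTRUE(rel$predicate(dfx[i, , drop = FALSE], dfy[j, , drop = FALSE])))
          acc <- acc + if (is.null(wx)) 1 else wx[i] * wy[j]
      acc
    })
}

# Length-bucketed Levenshtein pair counting: sequences whose lengths differ by
# more than max_d cannot be within distance max_d, so only neighbouring length
# buckets are compared (pure optimization; oracle-checked in the test suite).
ld_pairs_within <- function(seqs, max_d, w = NULL) {
  len <- nchar(seqs)
  buckets <- split(seq_along(seqs), len)
  lens <- as.integer(names(buckets))
  acc <- 0
  for (bi in seq_along(buckets)) {
    ii <- buckets[[bi]]
    if (length(ii) > 1L) {
      d <- utils::adist(seqs[ii])
      hit <- d <= max_d
      if (is.null(w)) acc <- acc + (sum(hit) - length(ii)) / 2
      else {
        ww <- outer(w[ii], w[ii])
        acc <- acc + (sum(ww[hit]) - sum(w[ii]^2)) / 2
      }
    }
    for (bj in seq_along(buckets)) {
      if (bj <= bi) next
      if (abs(lens[bj] - lens[bi]) > max_d) next
      jj <- buckets[[bj]]
      d <- utils::adist(seqs[ii], seqs[jj])
      hit <- d <= max_d
      if (is.null(w)) acc <- acc + sum(hit)
      else acc <- acc + sum(outer(w[ii], w[jj])[hit])
    }
  }
  acc
}

ld_pairs_between <- function(sx, sy, max_d, wx = NULL, wy = NULL) {
  lx <- nchar(sx); ly <- nchar(sy)
  bx <- split(seq_along(sx), lx)
  by <- split(seq_along(sy), ly)
  lenx <- as.integer(names(bx)); leny <- as.integer(names(by))
  acc <- 0
  for (i in seq_along(bx)) for (j in seq_along(by)) {
    if (abs(lenx[i] - leny[j]) > max_d) next
    ii <- bx[[i]]; jj <- by[[j]]
    d <- utils::adist(sx[ii], sy[jj])
    hit <- d <= max_d
    if (is.null(wx)) acc <- acc + sum(hit)
    else acc <- acc + sum(outer(wx[ii], wy[jj])[hit])
  }
  acc
}
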
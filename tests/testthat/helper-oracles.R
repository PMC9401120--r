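# Independent brute-force oracles. These deliberately avoid the package's
# class-counting / length-bucketing code paths: every pair is materialized in
# a full similarity matrix (or evaluated by naive recursion) and the index is
# assembled directly from its definition.

# full m x n logical similarity matrix under a named relation
oracle_pair_matrix <- function(rel, dfx, dfy = dfx) {
  switch(rel,
    vj = outer(paste(dfx$v_segment, dfx$j_segment),
               paste(dfy$v_segment, dfy$j_segment), "=="),
    v = outer(dfx$v_segment, dfy$v_segment, "=="),
    j = outer(dfx$j_segment, dfy$j_segment, "=="),
    identity = outer(dfx$cdr3_aa, dfy$cdr3_aa, "=="),
    nc = outer(dfx$n_variants, dfy$n_variants, "==") |
         outer(dfx$n_variants > 5, dfy$n_variants > 5, "&"),
    ld = utils::adist(dfx$cdr3_aa, dfy$cdr3_aa) <= 1,
    stop("unknown relation ", rel))
}

oracle_rhi <- function(df, rel) {
  m <- nrow(df)
  if (m < 2) return(NA_real_)
  M <- oracle_pair_matrix(rel, df)
  sum(M[upper.tri(M)]) / choose(m, 2)
}

oracle_rhi_weighted <- function(df, rel) {
  m <- nrow(df)
  if (m < 2) return(NA_real_)
  M <- oracle_pair_matrix(rel, df)
  W <- outer(df$copy_number, df$copy_number)
  up <- upper.tri(M)
  sum(W[up & M]) / sum(W[up])
}

oracle_rsi <- function(dfx, dfy, rel) {
  m <- nrow(dfx); n <- nrow(dfy)
  if (!m || !n) return(NA_real_)
  cross <- sum(oracle_pair_matrix(rel, dfx, dfy))
  sx <- sum(oracle_pair_matrix(rel, dfx))       # ordered pairs incl. diagonal
  sy <- sum(oracle_pair_matrix(rel, dfy))
  2 * (cross / (n * m)) / (sx / m^2 + sy / n^2)
}

oracle_rsi_weighted <- function(dfx, dfy, rel) {
  m <- nrow(dfx); n <- nrow(dfy)
  if (!m || !n) return(NA_real_)
  p <- dfx$copy_number / sum(dfx$copy_number)
  q <- dfy$copy_number / sum(dfy$copy_number)
  cross <- sum(oracle_pair_matrix(rel, dfx, dfy) * outer(p, q))
  sx <- sum(oracle_pair_matrix(rel, dfx) * outer(p, p))
  sy <- sum(oracle_pair_matrix(rel, dfy) * outer(q, q))
  2 * cross / (sx + sy)
}

# naive exponential-time Levenshtein recursion (strings <= 8)
naive_lev <- function(a, b) {
  if (!nchar(a)) return(nchar(b))
  if (!nchar(b)) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
  min(naive_lev(ta, b) + 1L, naive_lev(a, tb) + 1L, naive_lev(ta, tb) + cost)
}

# two-sided Fisher p by full enumeration of 2x2 tables with fixed margins
fisher_enum <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(ks, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Holm step-down by hand
holm_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin((n - seq_len(n) + 1) * p[o], 1)
  adj <- cummax(adj)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive 2-medoid search: minimal sum of dissimilarities to nearer medoid
pam_exhaustive_cost <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(m[, i], m[, j]))
    if (cost < best) best <- cost
  }
  best
}

# random clonotype tables over a deliberately small alphabet so that identity,
# Levenshtein and VJ coincidences all occur with useful frequency
random_clonotype_df <- function(m, lmin = 3, lmax = 6) {
  len <- sample(lmin:lmax, m, replace = TRUE)
  aa <- vapply(len, function(l)
    paste0(sample(c("C", "A", "S", "T"), l, replace = TRUE), collapse = ""), "")
  data.frame(cdr3_aa = aa,
             v_segment = sample(paste0("TRBV", 1:3), m, replace = TRUE),
             j_segment = sample(paste0("TRBJ", 1:2), m, replace = TRUE),
             copy_number = sample(2:50, m, replace = TRUE),
             n_variants = sample(1:8, m, replace = TRUE),
             d_nc = stats::runif(m, 0, 0.8),
             stringsAsFactors = FALSE)
}

make_clonotypes <- function(aa, v = "TRBV1", j = "TRBJ1", cn = 2L, nv = 1L) {
  data.frame(cdr3_aa = aa,
             v_segment = rep_len(v, length(aa)),
             j_segment = rep_len(j, length(aa)),
             copy_number = as.integer(rep_len(cn, length(aa))),
             n_variants = as.integer(rep_len(nv, length(aa))),
             d_nc = rep_len(0, length(aa)), stringsAsFactors = FALSE)
}
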
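test_that("levenshtein distance matches hand-worked examples", {
  expect_equal(levenshtein("CASS", "CASS"), 0L)
  expect_equal(levenshtein("CASS", "CAST"), 1L)
  # two substitutions plus two deletions; cross-checked by naive recursion
  expect_equal(levenshtein("CASSLG", "CATT"), naive_lev("CASSLG", "CATT"))
  expect_equal(levenshtein("CASSLG", "CATT"), 4L)
  expect_equal(levenshtein("", "CAT"), 3L)
})

test_that("relations evaluate their stated criteria", {
  a <- make_clonotypes("CASSLG", v = "TRBV1", j = "TRBJ2")
  b <- make_clonotypes("CASSLA", v = "TRBV1", j = "TRBJ2")
  c_ <- make_clonotypes("CATT", v = "TRBV2", j = "TRBJ2")
  expect_true(relation_vj()$predicate(a, b))
  expect_false(relation_vj()$predicate(a, c_))
  expect_true(relation_ld()$predicate(a, b))      # distance 1
  expect_false(relation_ld()$predicate(a, c_))    # distance 3
  nc <- relation_nc_count(5L)
  expect_true(nc$predicate(make_clonotypes("X", nv = 3L), make_clonotypes("Y", nv = 3L)))
  expect_true(nc$predicate(make_clonotypes("X", nv = 6L), make_clonotypes("Y", nv = 8L)))
  expect_false(nc$predicate(make_clonotypes("X", nv = 2L), make_clonotypes("Y", nv = 4L)))
  expect_false(nc$predicate(make_clonotypes("X", nv = 5L), make_clonotypes("Y", nv = 6L)))
})

test_that("all relations are reflexive and symmetric on random clonotype pairs", {
  set.seed(21)
  rels <- list(relation_vj(), relation_v(), relation_j(), relation_ld(),
               relation_identity(), relation_identity(strict = TRUE),
               relation_nc_count())
  for (i in 1:40) {
    df <- random_clonotype_df(2)
    a <- df[1, , drop = FALSE]; b <- df[2, , drop = FALSE]
    for (rel in rels) {
      expect_true(rel$predicate(a, a), info = rel$name)
      expect_identical(rel$predicate(a, b), rel$predicate(b, a), info = rel$name)
    }
  }
})

test_that("RHI matches its definition on worked examples and flags undefined input", {
  dis <- make_clonotypes(c("CAAAF", "CTTTF", "CGGGF"),
                         v = c("TRBV1", "TRBV2", "TRBV3"),
                         j = c("TRBJ1", "TRBJ2", "TRBJ1"))
  expect_equal(rhi(dis, relation_vj()), 0)
  expect_equal(rhi(dis, relation_ld()), 0)

  same <- make_clonotypes(c("CAF", "CCF", "CGF", "CTF"))   # all share V and J
  expect_equal(rhi(same, relation_vj()), 1)

  tri <- make_clonotypes(c("CASSLG", "CASSLA", "CATT"))
  expect_equal(rhi(tri, relation_ld()), 1 / 3)

  expect_true(is.na(rhi(make_clonotypes("CAF"), relation_vj())))
  expect_true(is.na(rhi(make_clonotypes(character()), relation_vj())))
})

test_that("weighted RHI collapses to RHI for uniform CN and damps a dominant singleton", {
  set.seed(31)
  for (i in 1:10) {
    df <- random_clonotype_df(40)
    df$copy_number <- 7L
    expect_equal(rhi_weighted(df, relation_vj()), rhi(df, relation_vj()))
    expect_equal(rhi_weighted(df, relation_ld()), rhi(df, relation_ld()))
  }
  # one dominant clonotype similar only to itself: contribution vanishes
  df <- make_clonotypes(c("CAAAAAF", "CWWF", "CWWWWF"),
                        v = c("TRBV9", "TRBV1", "TRBV1"),
                        j = c("TRBJ9", "TRBJ1", "TRBJ1"))
  vals <- vapply(c(10L, 1000L, 100000L), function(big) {
    df$copy_number <- c(big, 2L, 2L)
    rhi_weighted(df, relation_vj())
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 1e-4)   # ~ 1/CN decay of the dominant pair weight
})

test_that("weighted RHI equals the brute-force pair-weight oracle", {
  set.seed(32)
  for (i in 1:25) {
    df <- random_clonotype_df(50)
    for (rel in c("vj", "ld", "identity", "nc"))
      expect_equal(rhi_weighted(df, switch(rel, vj = relation_vj(),
                                           ld = relation_ld(),
                                           identity = relation_identity(),
                                           nc = relation_nc_count())),
                   oracle_rhi_weighted(df, rel), info = rel)
  }
})

test_that("coding diversity follows the Simpson form on variant read counts", {
  expect_equal(coding_diversity(10L), 0)
  for (k in 2:6) expect_equal(coding_diversity(rep(3L, k)), 1 - 1 / k)
  expect_equal(coding_diversity(c(3L, 1L)), 0.375)
  expect_error(coding_diversity(integer()))
})

test_that("CDI is the clonotype mean of coding diversities", {
  singles <- make_clonotypes(c("CAF", "CCF"))
  expect_equal(cdi(singles), 0)
  two <- singles; two$d_nc <- c(0, 0.5)
  expect_equal(cdi(two), 0.25)
  expect_true(is.na(cdi(make_clonotypes(character()))))
  # oracle: recompute from the variant table of a merged repertoire
  tab <- data.frame(nt_sequence = c("TGTAAA", "TGCAAA", "TGTCCC", "TGTGGG"),
                    read_count = c(3L, 1L, 6L, 2L),
                    cdr3_aa = c("CK", "CK", "CP", "CG"),
                    v_segment = "V", j_segment = "J")
  rep <- merge_to_clonotypes(tab)
  by_hand <- mean(c(1 - (36 / 36), 1 - (4 / 4), 1 - (9 + 1) / 16))
  expect_equal(cdi(rep), by_hand)
})

test_that("jaccard overlap counts CDR3 sets", {
  A <- make_clonotypes(c("Ca", "Cb", "Cc"))
  B <- make_clonotypes(c("Cb", "Cc", "Cd"))
  expect_equal(jaccard(A, A), 1)
  expect_equal(jaccard(A, make_clonotypes(c("Cx", "Cy"))), 0)
  expect_equal(jaccard(A, B), 0.5)
  expect_true(is.na(jaccard(make_clonotypes(character()), make_clonotypes(character()))))
  # strict mode distinguishes equal CDR3 with different segments
  A2 <- make_clonotypes("Ca", v = "TRBV1"); B2 <- make_clonotypes("Ca", v = "TRBV2")
  expect_equal(jaccard(A2, B2), 1)
  expect_equal(jaccard(A2, B2, strict = TRUE), 0)
})

test_that("RSI reduces to the Sorensen index under clonotype identity", {
  X <- make_clonotypes(c("Ca", "Cb", "Cc"))
  Y <- make_clonotypes(c("Cb", "Cc", "Cd"))
  expect_equal(rsi(X, Y, relation_identity()), 2 / 3)
  expect_equal(rsi(X, X, relation_identity()), 1)
  expect_true(is.na(rsi(X, make_clonotypes(character()), relation_identity())))
  set.seed(41)
  for (i in 1:20) {
    dx <- random_clonotype_df(30); dx <- dx[!duplicated(dx$cdr3_aa), ]
    dy <- random_clonotype_df(30); dy <- dy[!duplicated(dy$cdr3_aa), ]
    sor <- 2 * length(intersect(dx$cdr3_aa, dy$cdr3_aa)) / (nrow(dx) + nrow(dy))
    expect_equal(rsi(dx, dy, relation_identity()), sor)
  }
})

test_that("weighted RSI equals the Morisita-Horn index under identity", {
  X <- make_clonotypes(c("Ca", "Cb"), cn = c(5L, 3L))
  expect_equal(rsi_weighted(X, X, relation_identity()), 1)
  set.seed(42)
  for (i in 1:20) {
    dx <- random_clonotype_df(25); dx <- dx[!duplicated(dx$cdr3_aa), ]
    dy <- random_clonotype_df(25); dy <- dy[!duplicated(dy$cdr3_aa), ]
    # textbook Morisita-Horn on the aligned count vectors
    aa <- union(dx$cdr3_aa, dy$cdr3_aa)
    x <- dx$copy_number[match(aa, dx$cdr3_aa)]; x[is.na(x)] <- 0
    y <- dy$copy_number[match(aa, dy$cdr3_aa)]; y[is.na(y)] <- 0
    p <- x / sum(x); q <- y / sum(y)
    mh <- 2 * sum(p * q) / (sum(p^2) + sum(q^2))
    expect_equal(rsi_weighted(dx, dy, relation_identity()), mh)
    # uniform counts collapse to the unweighted index
    du <- dx; du$copy_number <- 4L
    dv <- dy; dv$copy_number <- 4L
    expect_equal(rsi_weighted(du, dv, relation_ld()), rsi(du, dv, relation_ld()))
  }
})

test_that("dissimilarity composes weighted capped RSI terms", {
  X <- make_clonotypes(c("Ca", "Cb", "Cc"))
  expect_equal(dissimilarity(X, X, dissimilarity_spec(relation_identity())), 0)
  Y <- make_clonotypes(c("Cx", "Cy"), v = "TRBV7", j = "TRBJ7")
  spec <- dissimilarity_spec(list(relation_v(), relation_j()), c(0.5, 0.5))
  expect_equal(dissimilarity(X, Y, spec), 1)   # both RSI terms are 0
  set.seed(43)
  for (i in 1:10) {
    dx <- random_clonotype_df(20); dy <- random_clonotype_df(25)
    d <- dissimilarity(dx, dy, spec)
    hand <- 1 - 0.5 * (min(oracle_rsi(dx, dy, "v"), 1) +
                       min(oracle_rsi(dx, dy, "j"), 1))
    expect_equal(d, hand)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  expect_error(dissimilarity_spec(list(relation_v()), 0.7), "sum to 1")
})

test_that("index values are invariant under clonotype permutation", {
  set.seed(44)
  df <- random_clonotype_df(60)
  perm <- df[sample(nrow(df)), ]
  for (rel in list(relation_vj(), relation_ld(), relation_nc_count())) {
    expect_equal(rhi(perm, rel), rhi(df, rel))
    expect_equal(rhi_weighted(perm, rel), rhi_weighted(df, rel))
  }
  dy <- random_clonotype_df(30)
  expect_equal(rsi(perm, dy, relation_ld()), rsi(df, dy, relation_ld()))
  expect_equal(cdi(perm), cdi(df))
})

test_that("repertoire statistics report count and unweighted mean CDR3 length", {
  st <- repertoire_stats(make_clonotypes(c("CASS", "CASSLG")))
  expect_equal(st$n_clonotypes, 2L)
  expect_equal(st$mean_cdr3_length, 5)
  empty <- repertoire_stats(make_clonotypes(character()))
  expect_equal(empty$n_clonotypes, 0L)
  expect_true(is.na(empty$mean_cdr3_length))
  set.seed(45)
  df <- random_clonotype_df(500)
  expect_equal(repertoire_stats(df)$mean_cdr3_length, sum(nchar(df$cdr3_aa)) / 500)
})

test_that("custom predicate relations run through the generic pairwise path", {
  same_len <- relation_custom("same-length", function(a, b)
    nchar(a$cdr3_aa) == nchar(b$cdr3_aa))
  df <- make_clonotypes(c("CAF", "CCF", "CAAAF"))
  expect_equal(rhi(df, same_len), 1 / 3)
  dy <- make_clonotypes(c("CTF", "CAAAAF"))
  expect_equal(rsi(df, dy, same_len),
               2 * (2 / 6) / ((2 * 1 + 3) / 9 + (2 * 0 + 2) / 4))
})
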
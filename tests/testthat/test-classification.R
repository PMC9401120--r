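# crafted repertoires with controllable V/J usage
vj_repertoire <- function(id, v_pool, j_pool, n = 30) {
  set.seed(sum(utf8ToInt(id)))
  repertoire(data.frame(cdr3_aa = paste0("C", id, seq_len(n), "F"),
                        v_segment = sample(v_pool, n, replace = TRUE),
                        j_segment = sample(j_pool, n, replace = TRUE),
                        copy_number = 2L, n_variants = 1L, d_nc = 0),
             sample_id = id)
}

test_that("dissimilarity matrices are symmetric, zero-diagonal and oracle-consistent", {
  reps <- c(lapply(c("a1", "a2", "a3"), vj_repertoire,
                   v_pool = paste0("TRBV", 1:3), j_pool = paste0("TRBJ", 1:2)),
            lapply(c("b1", "b2", "b3"), vj_repertoire,
                   v_pool = paste0("TRBV", 11:13), j_pool = paste0("TRBJ", 11:12)))
  m <- dissimilarity_matrix(reps, "vj")
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_true(all(m >= 0 & m <= 1))
  # disjoint V and J usage between the blocks: both RSI terms 0, distance 1
  expect_equal(unname(m[1:3, 4:6]), matrix(1, 3, 3))
  # every entry equals the oracle composition of RSI_V and RSI_J
  for (i in 1:5) for (j in (i + 1):6) {
    dx <- reps[[i]]$clonotypes; dy <- reps[[j]]$clonotypes
    expect_equal(m[i, j], 1 - 0.5 * (min(oracle_rsi(dx, dy, "v"), 1) +
                                     min(oracle_rsi(dx, dy, "j"), 1)))
  }
  # identical samples are at distance zero
  same <- replicate(3, vj_repertoire("z", "TRBV1", "TRBJ1"), simplify = FALSE)
  for (k in seq_along(same)) same[[k]]$sample_id <- paste0("z", k)
  m2 <- dissimilarity_matrix(same, "vj")
  expect_equal(unname(m2), matrix(0, 3, 3))
})

test_that("empty sub-repertoires are excluded with a warning", {
  reps <- c(lapply(c("a1", "a2", "a3"), vj_repertoire,
                   v_pool = "TRBV1", j_pool = "TRBJ1"),
            list(repertoire(make_clonotypes(character()), sample_id = "empty")))
  expect_warning(m <- dissimilarity_matrix(reps, "vj"), "empty")
  expect_equal(nrow(m), 3L)
})

test_that("k-medoids recovers planted blobs and matches exhaustive search on small n", {
  set.seed(61)
  blob <- function(n, center) abs(center + matrix(rnorm(n * n, sd = 0.02), n, n))
  d_within <- 0.05; d_between <- 0.9
  n <- 10
  m <- matrix(d_between, n, n)
  m[1:5, 1:5] <- d_within; m[6:10, 6:10] <- d_within
  m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:n)
  km <- kmedoids(m, 2)
  expect_equal(length(unique(km$assignments[1:5])), 1L)
  expect_equal(length(unique(km$assignments[6:10])), 1L)
  expect_true(km$assignments[1] != km$assignments[6])

  expect_equal(kmedoids(m, n)$cost, 0)
  expect_error(kmedoids(m, n + 1), "exceeds")

  for (rep_i in 1:30) {
    nn <- sample(4:8, 1)
    r <- matrix(runif(nn * nn), nn, nn)
    r <- (r + t(r)) / 2; diag(r) <- 0
    rownames(r) <- colnames(r) <- paste0("s", 1:nn)
    expect_equal(kmedoids(r, 2)$cost, pam_exhaustive_cost(r),
                 tolerance = 1e-12)
  }
})

test_that("metric MDS preserves distances of embeddable configurations", {
  # three equidistant samples form an equilateral triangle
  m <- matrix(0.6, 3, 3); diag(m) <- 0
  rownames(m) <- colnames(m) <- letters[1:3]
  xy <- mds_embed(m)
  d <- as.matrix(dist(xy))
  expect_equal(unname(d[upper.tri(d)]), rep(0.6, 3), tolerance = 1e-8)

  # points on a line: exactly recoverable
  x <- c(0, 0.1, 0.35, 0.7, 1)
  m2 <- as.matrix(dist(x))
  rownames(m2) <- colnames(m2) <- paste0("p", 1:5)
  xy2 <- mds_embed(m2)
  expect_equal(unname(as.matrix(dist(xy2))), unname(m2), tolerance = 1e-6)

  z <- matrix(0, 3, 3); rownames(z) <- colnames(z) <- letters[1:3]
  expect_warning(at0 <- mds_embed(z), "degenerate")
  expect_equal(unname(at0), matrix(0, 3, 2))
})

test_that("leave-one-out nearest-medoid classification separates planted cohorts", {
  n <- 12
  m <- matrix(0.9, n, n)
  m[1:6, 1:6] <- 0.05; m[7:12, 7:12] <- 0.05
  set.seed(62)
  noise <- matrix(runif(n * n, 0, 0.01), n, n); noise <- (noise + t(noise)) / 2
  m <- m + noise; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:n)
  labels <- factor(rep(c("control", "immunized"), each = 6),
                   levels = c("control", "immunized"))
  res <- loo_classify(m, labels)
  expect_equal(res$accuracy, 1)
  expect_lt(res$fisher_p, 0.05)
  expect_equal(sum(res$confusion), n)
})

test_that("a four-sample dissimilarity matrix is classified as in the hand derivation", {
  # groups {s1, s2} and {s3, s4}; holding out s1 leaves s2 as its group medoid
  m <- matrix(c(0.00, 0.10, 0.80, 0.90,
                0.10, 0.00, 0.70, 0.85,
                0.80, 0.70, 0.00, 0.15,
                0.90, 0.85, 0.15, 0.00), 4, 4)
  rownames(m) <- colnames(m) <- paste0("s", 1:4)
  labels <- factor(c("A", "A", "B", "B"))
  res <- loo_classify(m, labels)
  # hand trace: each held-out sample is nearer its own group's remaining member
  expect_equal(as.character(res$predicted), c("A", "A", "B", "B"))
  expect_error(loo_classify(m, factor(c("A", "B", "B", "B"))), "at least 2")
})

test_that("the held-out label never influences medoid selection", {
  set.seed(63)
  n <- 10
  m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:n)
  labels <- factor(rep(c("control", "immunized"), each = 5))
  base <- loo_classify(m, labels)
  for (i in seq_len(n)) {
    poisoned <- labels
    poisoned[i] <- if (labels[i] == "control") "immunized" else "control"
    res <- loo_classify(m, poisoned)
    expect_identical(as.character(res$predicted[i]),
                     as.character(base$predicted[i]))
  }
})

test_that("fisher_exact equals full 2x2 enumeration", {
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10))
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2)), 1)
  set.seed(64)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_exact(tab), fisher_enum(tab), tolerance = 1e-9)
  }
})

test_that("classify_cohort ties the pipeline together on a planted cohort", {
  reps <- c(lapply(paste0("c", 1:4), vj_repertoire,
                   v_pool = paste0("TRBV", 1:3), j_pool = paste0("TRBJ", 1:2)),
            lapply(paste0("t", 1:4), vj_repertoire,
                   v_pool = paste0("TRBV", 11:13), j_pool = paste0("TRBJ", 11:12)))
  reps <- lapply(reps, function(r) { r$clonotypes$copy_number <- 100L; r })
  labels <- factor(rep(c("control", "immunized"), each = 4),
                   levels = c("control", "immunized"))
  cls <- classify_cohort(reps, labels = labels, sub = "top", criterion = "vj")
  expect_equal(cls$loo$accuracy, 1)
  expect_equal(dim(cls$mds), c(8L, 2L))
  expect_output(print(cls), "K-medoids")
})
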
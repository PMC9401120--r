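#' Dissimilarity matrix over a cohort
#'
#' Computes all pairwise dissimilarities `d(X, Y)` between (sub-)repertoires
#' under one of the two classification criteria: `"vj"` uses identity of the V
#' segment and of the J segment as two equally weighted similarity relations
#' (`d_VJ`), `"nc"` uses the nucleotide-coding-count relation as single
#' criterion (`d_NC`). Empty sub-repertoires are excluded with a warning. The
#' result is symmetric with an exactly zero diagonal and entries in `[0, 1]`.
#'
#' @param reps list of repertoires or sub-repertoires.
#' @param criterion `"vj"` or `"nc"`.
#' @param weighted use copy-number-weighted similarity ([rsi_weighted()]).
#' @param threshold variant-count threshold of the NC relation.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
dissimilarity_matrix <- function(reps, criterion = c("vj", "nc"),
                                 weighted = FALSE, threshold = 5L) {
  criterion <- match.arg(criterion)
  sizes <- vapply(reps, n_clonotypes, 0L)
  if (any(sizes == 0L)) {
    warning("excluding ", sum(sizes == 0L), " sample(s) with empty sub-repertoire")
    reps <- reps[sizes > 0L]
  }
  n <- length(reps)
  if (n < 2L) stop("need at least two non-empty samples")
  spec <- if (criterion == "vj") spec_vj(weighted) else spec_nc(threshold, weighted)
  ids <- vapply(reps, function(r) r$sample_id, "")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- dissimilarity(reps[[i]], reps[[j]], spec)
  m
}

#' K-medoids clustering of repertoires
#'
#' Partitioning around medoids (PAM: greedy BUILD initialization followed by
#' SWAP steps until no single medoid exchange lowers the total within-cluster
#' dissimilarity) on a precomputed dissimilarity matrix, via
#' [cluster::pam()]. Because the SWAP phase is a local search, a configurable
#' number of additional random-initialization runs is performed and the
#' lowest-cost solution returned; the result is deterministic given `seed`.
#'
#' @param m symmetric dissimilarity matrix.
#' @param k number of clusters, `k <= nrow(m)`.
#' @param seed seed for the random restarts.
#' @param restarts additional random-start PAM runs beyond the BUILD start.
#' @return list with `assignments` (named integer vector), `medoids`
#'   (sample ids) and `cost` (sum of dissimilarities to the assigned medoid).
#' @export
kmedoids <- function(m, k, seed = NULL, restarts = 10L) {
  n <- nrow(m)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  if (k == n)  # degenerate: every sample is its own medoid at zero cost
    return(list(assignments = stats::setNames(seq_len(n), rownames(m)),
                medoids = rownames(m), cost = 0))
  with_preserved_seed(seed, {
    fits <- c(list(cluster::pam(m, k = k, diss = TRUE, keep.diss = FALSE)),
              lapply(seq_len(restarts), function(i)
                cluster::pam(m, k = k, diss = TRUE, keep.diss = FALSE,
                             medoids = sample.int(n, k), do.swap = TRUE)))
    cost <- function(fit)
      sum(m[cbind(seq_len(n), match(fit$medoids[fit$clustering], rownames(m)))])
    costs <- vapply(fits, cost, numeric(1))
    fit <- fits[[which.min(costs)]]
    list(assignments = fit$clustering, medoids = fit$medoids,
         cost = min(costs))
  })
}

#' Metric multidimensional scaling embedding
#'
#' Classical metric MDS ([stats::cmdscale()]) of a dissimilarity matrix, used
#' to visualize cluster structure: pairwise distances of the embedded points
#' approximate the input dissimilarities. Orientation and sign of the axes are
#' arbitrary.
#'
#' @param m symmetric dissimilarity matrix.
#' @param dims embedding dimension (default 2).
#' @return numeric matrix `n x dims` of coordinates.
#' @export
mds_embed <- function(m, dims = 2L) {
  n <- nrow(m)
  if (n < dims + 1L) stop("need at least dims + 1 samples")
  if (all(m == 0)) {
    warning("degenerate (all-zero) dissimilarity matrix; all points at origin")
    return(matrix(0, n, dims, dimnames = list(rownames(m), NULL)))
  }
  xy <- stats::cmdscale(m, k = dims)
  if (ncol(xy) < dims)  # rank-deficient configurations pad with zeros
    xy <- cbind(xy, matrix(0, n, dims - ncol(xy)))
  rownames(xy) <- rownames(m)
  xy
}

#' Leave-one-out nearest-medoid classification
#'
#' Supervised classification of repertoires from their dissimilarity matrix:
#' each sample is held out in turn; within each label group of the remaining
#' samples one medoid is determined (the training sample minimizing the summed
#' dissimilarity to its group members, i.e. K-medoids with k = 1 per group);
#' the held-out sample receives the label of the nearer medoid. Distance ties
#' are resolved toward the first factor level (conservative toward the
#' reference/control label) and logged. The resulting confusion table is
#' evaluated with Fisher's exact test: a significant result implies the
#' predicted labels are associated with the true status rather than random.
#'
#' @param m symmetric dissimilarity matrix.
#' @param labels factor (or vector) of two classes aligned with the rows of
#'   `m`; the first level is the reference ("control") class.
#' @return object of class `loo_classification` with `true`, `predicted`,
#'   `confusion` (2x2 table), `accuracy`, `fisher_p`, `ties`.
#' @export
loo_classify <- function(m, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  n <- nrow(m)
  stopifnot(length(labels) == n)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 samples to allow a holdout")
  lev <- levels(labels)
  pred <- character(n)
  ties <- logical(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    d_to_medoid <- vapply(lev, function(lv) {
      grp <- train[labels[train] == lv]
      sums <- colSums(m[grp, grp, drop = FALSE])
      medoid <- grp[which.min(sums)]
      m[i, medoid]
    }, numeric(1))
    if (d_to_medoid[1L] == d_to_medoid[2L]) {
      ties[i] <- TRUE
      pred[i] <- lev[1L]
    } else pred[i] <- lev[which.min(d_to_medoid)]
  }
  pred <- factor(pred, levels = lev)
  confusion <- table(true = labels, predicted = pred)
  structure(list(true = labels, predicted = pred,
                 confusion = confusion,
                 accuracy = mean(pred == labels),
                 fisher_p = fisher_exact(confusion),
                 ties = ties,
                 sample_ids = rownames(m)),
            class = "loo_classification")
}

#' @export
print.loo_classification <- function(x, ...) {
  cat("Leave-one-out nearest-medoid classification\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.1f%%  (Fisher exact p = %.3g)\n",
              100 * x$accuracy, x$fisher_p))
  if (any(x$ties))
    cat("distance ties resolved to '", levels(x$true)[1L], "' for: ",
        paste(x$sample_ids[x$ties], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fisher's exact test on a 2x2 confusion table
#'
#' Two-sided exact hypergeometric test of association between true and
#' predicted labels.
#'
#' @param confusion 2x2 table or matrix of non-negative integer counts.
#' @return the p-value.
#' @export
fisher_exact <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == 2L), all(confusion >= 0),
            is_count(as.vector(confusion)))
  stats::fisher.test(confusion)$p.value
}

#' Cluster and classify a cohort in one call
#'
#' Convenience wrapper around the classification pipeline: restrict each
#' repertoire to a copy-number region, build the dissimilarity matrix, run
#' unsupervised K-medoids (k = 2), embed with metric MDS, and (when labels are
#' given) run the leave-one-out supervised classification.
#'
#' @param reps list of repertoires.
#' @param labels optional two-class labels aligned with `reps`.
#' @param sub `"top"`, `"bottom"`, or `"all"`; or use `cn_min`/`cn_max`.
#' @param criterion `"vj"` or `"nc"` (see [dissimilarity_matrix()]).
#' @param weighted copy-number-weighted similarity.
#' @param cn_min,cn_max custom copy-number region (half-open `(cn_min, cn_max]`).
#' @param exclude optional character vector of `group_label`/`timepoint` values
#'   whose samples are dropped before the supervised step (e.g. time points at
#'   which no effect is present in the analyzed region).
#' @param seed passed to [kmedoids()].
#' @return object of class `repertoire_classification` with the matrix,
#'   cluster assignments, MDS coordinates and (if labels given) the
#'   `loo_classification`.
#' @export
classify_cohort <- function(reps, labels = NULL,
                            sub = c("top", "bottom", "all"),
                            criterion = c("vj", "nc"), weighted = FALSE,
                            cn_min = NULL, cn_max = NULL,
                            exclude = NULL, seed = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(cn_min) && is.null(cn_max)) {
    sub <- match.arg(sub)
    subs <- switch(sub,
                   top = lapply(reps, sub_repertoire, which = "top"),
                   bottom = lapply(reps, sub_repertoire, which = "bottom"),
                   all = reps)
  } else subs <- lapply(reps, sub_repertoire, cn_min = cn_min, cn_max = cn_max)
  if (!is.null(exclude)) {
    drop <- vapply(reps, function(r)
      (r$timepoint %in% exclude) || (r$group_label %in% exclude), NA)
    subs <- subs[!drop]
    if (!is.null(labels)) labels <- labels[!drop]
  }
  m <- dissimilarity_matrix(subs, criterion = criterion, weighted = weighted)
  kept <- match(rownames(m), vapply(subs, function(r) r$sample_id, ""))
  km <- kmedoids(m, k = 2L, seed = seed)
  xy <- mds_embed(m, dims = 2L)
  loo <- NULL
  if (!is.null(labels)) loo <- loo_classify(m, labels[kept])
  structure(list(matrix = m, clusters = km, mds = xy, loo = loo,
                 criterion = criterion, weighted = weighted),
            class = "repertoire_classification")
}

#' @export
print.repertoire_classification <- function(x, ...) {
  cat("Repertoire classification (criterion: d_", toupper(x$criterion),
      if (x$weighted) ", CN-weighted" else "", ")\n", sep = "")
  cat("K-medoids (k = 2) cluster sizes: ",
      paste(table(x$clusters$assignments), collapse = " / "),
      "; cost = ", format(x$clusters$cost, digits = 4), "\n", sep = "")
  if (!is.null(x$loo)) print(x$loo)
  invisible(x)
}

#' @export
plot.repertoire_classification <- function(x, ...) {
  pch <- c(1, 2)[x$clusters$assignments]
  col <- if (!is.null(x$loo)) c("grey30", "red3")[as.integer(x$loo$true)] else "grey30"
  graphics::plot(x$mds, pch = pch, col = col, asp = 1,
                 xlab = "MDS 1", ylab = "MDS 2",
                 main = paste0("metric MDS (d_", toupper(x$criterion), ")"), ...)
  invisible(x)
}
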
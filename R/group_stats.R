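#' Mann-Whitney U test p-value
#'
#' Rank-sum comparison of per-animal index values between two groups. Exact
#' p-values are used whenever both groups have fewer than 50 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction applies. `alternative = "less"` tests for a decrease
#' in the first group.
#'
#' @param a,b numeric vectors (NA values, i.e. undefined index values, are
#'   dropped).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return the p-value; `NA` if either group is empty after NA removal.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, correct = TRUE)$p.value)
}

#' Holm step-down correction
#'
#' Holm's sequentially rejective adjustment of a vector of p-values, with
#' monotonicity enforcement and capping at 1. NA entries (skipped tests) are
#' preserved and the correction is applied over the non-missing entries only,
#' so untestable fractions do not inflate the penalty for the others.
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, elementwise `>=` the input.
#' @export
holm_correct <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- p
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "holm")
  out
}

# Per-fraction index evaluators used by compare_cohorts.
.index_funs <- list(
  rhi_ld = function(sub) rhi(sub, relation_ld(1L)),
  rhi_vj = function(sub) rhi(sub, relation_vj()),
  cdi = function(sub) cdi(sub),
  n_clonotypes = function(sub) n_clonotypes(sub),
  mean_length = function(sub) repertoire_stats(sub)$mean_cdr3_length
)

#' Fraction-wise cohort comparison
#'
#' The core group analysis: each animal's repertoire is split into
#' copy-number fractions, the requested indices are evaluated per fraction,
#' and for every index and fraction the treated group is compared to the
#' control group with a Mann-Whitney U test. The row of p-values of each index
#' (one per fraction) is then independently corrected with Holm's method —
#' yielding the heat-map layout index x fraction.
#'
#' Fractions in which an index is undefined (fewer than two clonotypes for an
#' RHI, empty fraction for the CDI) are dropped per animal; a fraction is
#' skipped entirely (p = NA) when fewer than `min_per_group` defined values
#' remain in either group. The Jaccard index is deliberately absent here: as a
#' pairwise overlap it violates the independence assumptions of the rank test
#' and is reported descriptively via [pairwise_jaccard()].
#'
#' @param control,treated lists of preprocessed [repertoire] objects.
#' @param indices character subset of
#'   `c("rhi_ld", "rhi_vj", "cdi", "n_clonotypes", "mean_length")`.
#' @param scheme a [fraction_scheme] or its name (default the log2 scheme).
#' @param alternative passed to [mann_whitney()]; `"less"` tests for a
#'   decrease of the index in the treated group.
#' @param min_per_group minimal number of defined per-animal values per group
#'   for a fraction to be tested.
#' @return object of class `cohort_comparison` with elements `values`
#'   (3-d array animal x fraction x index), `p_raw`, `p_holm`,
#'   `median_control`, `median_treated` (index x fraction matrices),
#'   `n_control`, `n_treated`, `scheme`, `alternative`.
#' @export
compare_cohorts <- function(control, treated,
                            indices = c("rhi_ld", "rhi_vj", "cdi"),
                            scheme = fraction_scheme("log2"),
                            alternative = "less",
                            min_per_group = 2L) {
  if (is.character(scheme)) scheme <- fraction_scheme(scheme)
  indices <- match.arg(indices, names(.index_funs), several.ok = TRUE)
  if (length(control) < 2L || length(treated) < 2L)
    stop("need at least two repertoires per group")
  reps <- c(control, treated)
  grp <- rep(c("control", "treated"), c(length(control), length(treated)))
  nf <- length(scheme$lower)

  vals <- array(NA_real_,
                dim = c(length(reps), nf, length(indices)),
                dimnames = list(vapply(reps, `[[`, "", "sample_id"),
                                scheme$labels, indices))
  for (i in seq_along(reps)) {
    subs <- split_by_scheme(reps[[i]], scheme)
    for (k in seq_len(nf)) for (ix in seq_along(indices))
      vals[i, k, ix] <- .index_funs[[indices[ix]]](subs[[k]])
  }

  p_raw <- matrix(NA_real_, length(indices), nf,
                  dimnames = list(indices, scheme$labels))
  n_ctl <- n_trt <- matrix(0L, length(indices), nf,
                           dimnames = dimnames(p_raw))
  med_c <- med_t <- p_raw
  for (ix in seq_along(indices)) for (k in seq_len(nf)) {
    a <- vals[grp == "treated", k, ix]
    b <- vals[grp == "control", k, ix]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n_trt[ix, k] <- length(a); n_ctl[ix, k] <- length(b)
    if (length(a)) med_t[ix, k] <- stats::median(a)
    if (length(b)) med_c[ix, k] <- stats::median(b)
    if (length(a) >= min_per_group && length(b) >= min_per_group)
      p_raw[ix, k] <- mann_whitney(a, b, alternative = alternative)
  }
  p_holm <- t(apply(p_raw, 1L, holm_correct))
  dimnames(p_holm) <- dimnames(p_raw)

  structure(list(values = vals, group = grp,
                 p_raw = p_raw, p_holm = p_holm,
                 median_control = med_c, median_treated = med_t,
                 n_control = n_ctl, n_treated = n_trt,
                 scheme = scheme, alternative = alternative),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Fraction-wise cohort comparison (", x$alternative,
      " Mann-Whitney U, Holm-corrected per index row)\n", sep = "")
  cat("scheme: ", x$scheme$name, "; ", sum(x$group == "control"), " control vs ",
      sum(x$group == "treated"), " treated animals\n\n", sep = "")
  stars <- function(p) ifelse(is.na(p), "  . ",
                       ifelse(p < 0.001, " ***",
                       ifelse(p < 0.01, " ** ",
                       ifelse(p < 0.05, " *  ", "    "))))
  tab <- matrix(stars(x$p_holm), nrow = nrow(x$p_holm),
                dimnames = dimnames(x$p_holm))
  print(as.data.frame(tab), right = FALSE)
  cat("\n(adjusted p: *** <0.001, ** <0.01, * <0.05, '.' not testable)\n")
  invisible(x)
}

#' @export
summary.cohort_comparison <- function(object, alpha = 0.05, ...) {
  sig <- !is.na(object$p_holm) & object$p_holm < alpha
  out <- data.frame(index = rep(rownames(sig), ncol(sig)),
                    fraction = rep(colnames(sig), each = nrow(sig)),
                    p_raw = as.vector(object$p_raw),
                    p_holm = as.vector(object$p_holm),
                    median_control = as.vector(object$median_control),
                    median_treated = as.vector(object$median_treated),
                    significant = as.vector(sig))
  out
}

#' @export
plot.cohort_comparison <- function(x, ...) {
  p <- x$p_holm
  z <- -log10(pmax(p, 1e-16))
  z[is.na(p)] <- 0
  graphics::image(x = seq_len(ncol(p)), y = seq_len(nrow(p)), z = t(z),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "copy-number fraction", ylab = "", axes = FALSE,
                  main = "-log10 adjusted p", ...)
  graphics::axis(1, at = seq_len(ncol(p)), labels = colnames(p))
  graphics::axis(2, at = seq_len(nrow(p)), labels = rownames(p), las = 1)
  graphics::box()
  invisible(x)
}

#' Pairwise Jaccard overlap within a cohort
#'
#' All pairwise [jaccard()] values between repertoires (optionally restricted
#' to a copy-number region first). Because every animal takes part in many
#' pairs, these values are mutually dependent and are reported descriptively
#' rather than tested.
#'
#' @param reps list of repertoires (or sub-repertoires).
#' @return symmetric matrix of Jaccard indices with `NA` diagonal.
#' @export
pairwise_jaccard <- function(reps) {
  n <- length(reps)
  ids <- vapply(reps, function(r) r$sample_id, "")
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- jaccard(reps[[i]], reps[[j]])
  m
}
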
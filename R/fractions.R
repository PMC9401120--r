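# Lower bounds of the 10 half-open log2 copy-number intervals:
# fraction k (k = 1..9) holds 2^(k-1) < CN <= 2^k, fraction 10 holds CN > 512.
.log2_lower <- c(2L, 3L, 5L, 9L, 17L, 33L, 65L, 129L, 257L, 513L)

#' Log2 copy-number fraction of a clonotype
#'
#' Maps a copy number to its fraction on the log2 grid: fraction 1 is
#' `CN = 2` (the lowest copy number after singleton removal), fractions
#' `k = 2..9` are the half-open intervals `2^(k-1) < CN <= 2^k`, and fraction
#' 10 collects `CN > 512`. Integer arithmetic only, so interval boundaries are
#' exact.
#'
#' @param cn integer vector of copy numbers, all `>= 2`.
#' @return integer vector of fraction indices in `1..10`.
#' @examples
#' log2_fraction_index(c(2, 3, 4, 64, 65, 512, 513))
#' @export
log2_fraction_index <- function(cn) {
  if (!is_count(cn)) stop("copy numbers must be integers")
  if (any(cn < 2)) stop("copy number < 2: singletons must be removed first")
  findInterval(cn, .log2_lower)
}

#' Copy-number fraction schemes
#'
#' A fraction scheme is an ordered list of disjoint half-open copy-number
#' intervals covering all `CN >= 2`. `"log2"` is the systematic 10-fraction
#' scheme; `"tripartition"` is the coarse split into `CN = 2` (low),
#' `2 < CN <= 500` (med) and `CN > 500` (high). A custom scheme is defined by
#' its interval lower bounds (first element must be 2; the last interval is
#' unbounded above).
#'
#' @param name `"log2"`, `"tripartition"` or `"custom"`.
#' @param lower for `"custom"`: increasing integer vector of interval lower
#'   bounds starting at 2.
#' @param labels optional fraction labels.
#' @return object of class `fraction_scheme`.
#' @export
fraction_scheme <- function(name = c("log2", "tripartition", "custom"),
                            lower = NULL, labels = NULL) {
  name <- match.arg(name)
  if (name == "log2") {
    lower <- .log2_lower
    labels <- labels %||% as.character(1:10)
  } else if (name == "tripartition") {
    lower <- c(2L, 3L, 501L)
    labels <- labels %||% c("low", "med", "high")
  } else {
    if (is.null(lower) || lower[1] != 2L || is.unsorted(lower, strictly = TRUE))
      stop("custom scheme needs strictly increasing lower bounds starting at 2")
    lower <- as.integer(lower)
    labels <- labels %||% as.character(seq_along(lower))
  }
  structure(list(name = name, lower = lower, labels = labels),
            class = "fraction_scheme")
}

#' @export
print.fraction_scheme <- function(x, ...) {
  up <- c(x$lower[-1] - 1L, Inf)
  cat("fraction scheme '", x$name, "' (", length(x$lower), " fractions)\n", sep = "")
  for (i in seq_along(x$lower))
    cat(sprintf("  %-5s CN in [%d, %s]\n", x$labels[i], x$lower[i],
                if (is.finite(up[i])) format(up[i]) else "Inf"))
  invisible(x)
}

scheme_index <- function(cn, scheme) {
  if (!is_count(cn)) stop("copy numbers must be integers")
  if (any(cn < 2)) stop("copy number < 2: singletons must be removed first")
  findInterval(cn, scheme$lower)
}

#' Split a repertoire into copy-number fractions
#'
#' Partitions a preprocessed repertoire (`CN >= 2`) into the sub-repertoires of
#' a fraction scheme. Every clonotype falls into exactly one fraction; empty
#' fractions are retained so downstream statistics keep a fixed layout.
#'
#' @param rep a repertoire.
#' @param scheme a [fraction_scheme] (or its name).
#' @return named list of sub-repertoires, one per fraction.
#' @export
split_by_scheme <- function(rep, scheme = fraction_scheme("log2")) {
  if (is.character(scheme)) scheme <- fraction_scheme(scheme)
  idx <- scheme_index(rep$clonotypes$copy_number, scheme)
  up <- c(scheme$lower[-1] - 1L, Inf)
  out <- vector("list", length(scheme$lower))
  names(out) <- scheme$labels
  for (k in seq_along(out)) {
    sub <- subset_repertoire(rep, idx == k)
    attr(sub, "cn_range") <- c(scheme$lower[k] - 1L, up[k])  # half-open (lo, hi]
    attr(sub, "parent_id") <- rep$sample_id
    class(sub) <- c("sub_repertoire", class(sub))
    out[[k]] <- sub
  }
  out
}

#' @rdname split_by_scheme
#' @export
split_log2 <- function(rep) split_by_scheme(rep, fraction_scheme("log2"))

#' @rdname split_by_scheme
#' @export
split_tripartition <- function(rep) split_by_scheme(rep, fraction_scheme("tripartition"))

#' Top / bottom sub-repertoires
#'
#' The two copy-number regions where immunization effects localize:
#' `X^top` keeps clonotypes with `CN > 64` (`log2(CN) > 6`) and `X^bottom`
#' keeps `CN <= 4` (`log2(CN) <= 2`; the lower limit 2 comes from singleton
#' removal). A custom region is available through `cn_min`/`cn_max`.
#'
#' @param rep a repertoire.
#' @param which `"top"` or `"bottom"`; ignored when `cn_min`/`cn_max` given.
#' @param cn_min,cn_max optional custom half-open bounds: keeps
#'   `cn_min < CN <= cn_max`.
#' @return a sub-repertoire.
#' @export
sub_repertoire <- function(rep, which = c("top", "bottom"),
                           cn_min = NULL, cn_max = NULL) {
  if (is.null(cn_min) && is.null(cn_max)) {
    which <- match.arg(which)
    if (which == "top") { cn_min <- 64L; cn_max <- Inf }
    else { cn_min <- 1L; cn_max <- 4L }
  } else {
    cn_min <- cn_min %||% 1L
    cn_max <- cn_max %||% Inf
  }
  cn <- rep$clonotypes$copy_number
  sub <- subset_repertoire(rep, cn > cn_min & cn <= cn_max)
  attr(sub, "cn_range") <- c(cn_min, cn_max)
  attr(sub, "parent_id") <- rep$sample_id
  class(sub) <- c("sub_repertoire", class(sub))
  sub
}

#' Distribution of a clonotype set over log2 fractions
#'
#' Counts how many members of an externally supplied CDR3beta amino-acid set
#' (for example previously identified antigen-specific public clonotypes) fall
#' into each log2 copy-number fraction of a repertoire. Set members absent
#' from the repertoire contribute nothing.
#'
#' @param rep a repertoire.
#' @param aa_set character vector of CDR3beta amino-acid sequences.
#' @return named integer vector of length 10 (fractions 1..10).
#' @export
distribute_clonotype_set <- function(rep, aa_set) {
  cl <- rep$clonotypes
  hit <- cl$cdr3_aa %in% aa_set
  counts <- integer(10)
  if (any(hit))
    counts <- tabulate(log2_fraction_index(cl$copy_number[hit]), nbins = 10)
  names(counts) <- as.character(1:10)
  counts
}
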
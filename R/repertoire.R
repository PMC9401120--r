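#' Construct a repertoire object
#'
#' A repertoire is one animal's set of clonotypes. A clonotype is the set of
#' T cells sharing an identical CDR3beta amino-acid sequence; it carries one
#' assigned V and J segment, a copy number (summed read count of all nucleotide
#' sequences coding for it), and optionally the underlying nucleotide variants.
#'
#' @param clonotypes data.frame with columns `cdr3_aa`, `v_segment`,
#'   `j_segment`, `copy_number`, and optionally `n_variants` and `d_nc`
#'   (per-clonotype nucleotide-coding diversity). Missing `n_variants`/`d_nc`
#'   are computed from `variants` when given, otherwise set to single coding.
#' @param variants optional data.frame with columns `cdr3_aa`, `nt_sequence`,
#'   `read_count`: the nucleotide sequences coding for each clonotype.
#' @param sample_id sample label.
#' @param group_label,timepoint optional experimental annotations.
#' @param validate check invariants (unique CDR3, positive copy numbers,
#'   variant read counts summing to the clonotype copy number).
#' @return An object of class `repertoire`.
#' @examples
#' cl <- data.frame(cdr3_aa = c("CASSLG", "CATT"),
#'                  v_segment = c("TRBV1", "TRBV2"),
#'                  j_segment = c("TRBJ1", "TRBJ1"),
#'                  copy_number = c(4L, 2L))
#' rep <- repertoire(cl, sample_id = "m1")
#' n_clonotypes(rep)
#' @export
repertoire <- function(clonotypes, variants = NULL, sample_id = "sample",
                       group_label = NA_character_, timepoint = NA_character_,
                       validate = TRUE) {
  clonotypes <- as.data.frame(clonotypes)
  needed <- c("cdr3_aa", "v_segment", "j_segment", "copy_number")
  miss <- setdiff(needed, names(clonotypes))
  if (length(miss)) stop("clonotype table lacks column(s): ", paste(miss, collapse = ", "))
  clonotypes$copy_number <- as.integer(clonotypes$copy_number)

  if (!is.null(variants)) {
    variants <- as.data.frame(variants)
    vneed <- c("cdr3_aa", "nt_sequence", "read_count")
    vmiss <- setdiff(vneed, names(variants))
    if (length(vmiss)) stop("variant table lacks column(s): ", paste(vmiss, collapse = ", "))
    variants$read_count <- as.integer(variants$read_count)
  }

  if (is.null(clonotypes$n_variants) || is.null(clonotypes$d_nc)) {
    if (!is.null(variants) && nrow(clonotypes)) {
      key <- factor(variants$cdr3_aa, levels = clonotypes$cdr3_aa)
      clonotypes$n_variants <- as.integer(tabulate(key, nbins = nrow(clonotypes)))
      ssq <- rowsum(as.numeric(variants$read_count)^2, key)[, 1L]
      tot <- rowsum(as.numeric(variants$read_count), key)[, 1L]
      clonotypes$d_nc <- 1 - ssq / tot^2
    } else {
      clonotypes$n_variants <- rep.int(1L, nrow(clonotypes))
      clonotypes$d_nc <- rep.int(0, nrow(clonotypes))
    }
  }
  rownames(clonotypes) <- NULL

  x <- structure(list(sample_id = sample_id,
                      group_label = group_label,
                      timepoint = timepoint,
                      clonotypes = clonotypes,
                      variants = variants),
                 class = "repertoire")
  if (validate) validate_repertoire(x)
  x
}

validate_repertoire <- function(x) {
  cl <- x$clonotypes
  if (anyDuplicated(cl$cdr3_aa))
    stop("duplicate cdr3_aa within repertoire '", x$sample_id, "'")
  if (nrow(cl) && any(cl$copy_number < 1L))
    stop("copy_number must be >= 1")
  if (!is.null(x$variants) && nrow(cl)) {
    v <- x$variants
    if (any(v$read_count < 1L)) stop("variant read_count must be >= 1")
    if (any(!grepl("^[ACGT]+$", v$nt_sequence)))
      stop("nt_sequence must be non-empty over the alphabet {A,C,G,T}")
    tot <- rowsum(as.numeric(v$read_count), factor(v$cdr3_aa, levels = cl$cdr3_aa))[, 1L]
    tot[is.na(tot)] <- 0
    if (any(tot != cl$copy_number))
      stop("copy_number must equal the sum of variant read counts")
  }
  invisible(x)
}

#' @rdname repertoire
#' @param x a repertoire.
#' @export
n_clonotypes <- function(x) nrow(as_clonotype_df(x))

#' @rdname repertoire
#' @export
total_reads <- function(x) sum(as_clonotype_df(x)$copy_number)

# Accept either a repertoire object or a bare clonotype data.frame.
as_clonotype_df <- function(x) {
  if (inherits(x, "repertoire")) x$clonotypes
  else if (is.data.frame(x)) x
  else stop("expected a repertoire or a clonotype data.frame")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("TCR repertoire '", x$sample_id, "'", sep = "")
  if (!is.na(x$group_label)) cat(" [", x$group_label, "]", sep = "")
  if (!is.na(x$timepoint)) cat(" @", x$timepoint, sep = "")
  cat("\n  clonotypes: ", nrow(x$clonotypes),
      ", total reads: ", sum(x$clonotypes$copy_number), "\n", sep = "")
  rng <- attr(x, "cn_range")
  if (!is.null(rng))
    cat("  copy-number condition: (", rng[1], ", ",
        if (is.finite(rng[2])) rng[2] else "Inf", "]\n", sep = "")
  invisible(x)
}

#' @export
summary.repertoire <- function(object, ...) {
  st <- repertoire_stats(object)
  cl <- object$clonotypes
  out <- list(sample_id = object$sample_id,
              n_clonotypes = st$n_clonotypes,
              total_reads = st$total_reads,
              mean_cdr3_length = st$mean_cdr3_length,
              cn_range = if (nrow(cl)) range(cl$copy_number) else c(NA, NA),
              fraction_sizes = if (nrow(cl))
                table(factor(log2_fraction_index(cl$copy_number), levels = 1:10))
              else table(factor(integer(), levels = 1:10)))
  class(out) <- "summary.repertoire"
  out
}

#' @export
print.summary.repertoire <- function(x, ...) {
  cat("Repertoire '", x$sample_id, "': ", x$n_clonotypes, " clonotypes, ",
      x$total_reads, " reads\n", sep = "")
  cat("  mean CDR3 length:", format(x$mean_cdr3_length, digits = 4), "\n")
  cat("  clonotypes per log2 copy-number fraction:\n")
  print(x$fraction_sizes)
  invisible(x)
}

#' Basic repertoire statistics
#'
#' Number of clonotypes and unweighted mean CDR3 amino-acid length,
#' the descriptive parameters reported alongside the similarity indices.
#'
#' @param x repertoire or clonotype data.frame.
#' @return list with `n_clonotypes`, `mean_cdr3_length` (NA for an empty
#'   repertoire) and `total_reads`.
#' @export
repertoire_stats <- function(x) {
  df <- as_clonotype_df(x)
  list(n_clonotypes = nrow(df),
       mean_cdr3_length = if (nrow(df)) mean(nchar(df$cdr3_aa)) else NA_real_,
       total_reads = if (nrow(df)) sum(df$copy_number) else 0L)
}
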
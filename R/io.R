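# Column maps for the supported tab-separated clonotype table dialects.
# Unknown extra columns in an input file are ignored.
.dialects <- list(
  mitcr = c(read_count = "Read count",
            nt_sequence = "CDR3 nucleotide sequence",
            cdr3_aa = "CDR3 amino acid sequence",
            v_segment = "V segments",
            j_segment = "J segments"),
  airr = c(read_count = "duplicate_count",
           nt_sequence = "junction",
           cdr3_aa = "junction_aa",
           v_segment = "v_call",
           j_segment = "j_call"),
  simple = c(read_count = "count",
             nt_sequence = "nt",
             cdr3_aa = "aa",
             v_segment = "v",
             j_segment = "j"))

match_dialect <- function(dialect) {
  dialect <- sub("-tsv$", "", tolower(dialect))
  if (!dialect %in% names(.dialects))
    stop("unknown dialect '", dialect, "'; use one of: ",
         paste(names(.dialects), collapse = ", "))
  dialect
}

#' Read a clonotype table
#'
#' Reads one tab-separated table of CDR3beta nucleotide sequences with read
#' counts, amino-acid sequences and V/J segment calls, as produced by
#' MiTCR-style or AIRR-rearrangement-style pipelines. Rows sharing the same
#' nucleotide sequence are merged by summing read counts.
#'
#' @param path file path.
#' @param dialect one of `"mitcr"`, `"airr"`, `"simple"` (alias
#'   `"simple-tsv"`); selects the expected column names.
#' @param drop_nonfunctional drop rows whose amino-acid sequence contains a
#'   stop (`*`) or frameshift (`_`) marker. Upstream read processing normally
#'   removes these already; this is a safety filter.
#' @return data.frame with canonical columns `nt_sequence`, `read_count`,
#'   `cdr3_aa`, `v_segment`, `j_segment` (one row per nucleotide sequence).
#' @seealso [merge_to_clonotypes()], [write_repertoire()]
#' @export
read_clonotype_table <- function(path, dialect = "simple", drop_nonfunctional = TRUE) {
  dialect <- match_dialect(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  map <- .dialects[[dialect]]
  miss <- setdiff(unname(map), names(raw))
  if (length(miss))
    stop("file '", path, "' (dialect ", dialect, ") is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(raw)) stop("empty clonotype table: ", path)
  tab <- data.frame(nt_sequence = as.character(raw[[map["nt_sequence"]]]),
                    read_count = as.integer(raw[[map["read_count"]]]),
                    cdr3_aa = as.character(raw[[map["cdr3_aa"]]]),
                    v_segment = as.character(raw[[map["v_segment"]]]),
                    j_segment = as.character(raw[[map["j_segment"]]]),
                    stringsAsFactors = FALSE)
  if (any(tab$read_count < 1L)) stop("read_count must be >= 1 in ", path)
  if (drop_nonfunctional) {
    bad <- grepl("[*_]", tab$cdr3_aa)
    if (any(bad)) tab <- tab[!bad, , drop = FALSE]
    if (!nrow(tab)) stop("no functional sequences left in ", path)
  }
  if (anyDuplicated(tab$nt_sequence)) {
    key <- factor(tab$nt_sequence, levels = unique(tab$nt_sequence))
    cnt <- rowsum(tab$read_count, key)[, 1L]
    first <- tab[!duplicated(tab$nt_sequence), , drop = FALSE]
    first$read_count <- as.integer(cnt[first$nt_sequence])
    tab <- first
  }
  rownames(tab) <- NULL
  tab
}

#' Downsample a raw sequence table to a target read depth
#'
#' Draws `target_reads` reads without replacement from the pooled reads of the
#' table (multivariate hypergeometric sampling over nucleotide sequences),
#' emulating depth normalization of unequally sequenced samples. Sampling is
#' performed before merging to clonotypes, on nucleotide-sequence read counts.
#' Sequences reduced to zero reads are dropped.
#'
#' @param table raw sequence table as returned by [read_clonotype_table()].
#' @param target_reads total read count after downsampling; must not exceed
#'   the current total.
#' @param seed integer seed; the result is reproducible given the seed and the
#'   caller's RNG state is left untouched.
#' @return the table with reduced `read_count`s summing exactly to
#'   `target_reads`.
#' @export
downsample_reads <- function(table, target_reads, seed = NULL) {
  stopifnot(is_count(target_reads), length(target_reads) == 1L)
  n <- as.numeric(table$read_count)
  total <- sum(n)
  if (target_reads > total)
    stop("target_reads (", target_reads, ") exceeds total reads (", total, ")")
  if (target_reads == total) return(table)
  out <- with_preserved_seed(seed, {
    kept <- numeric(length(n))
    remaining_target <- target_reads
    remaining_total <- total
    for (i in seq_along(n)) {
      # conditional draw: reads of sequence i are 'white balls' in the pool
      kept[i] <- stats::rhyper(1L, n[i], remaining_total - n[i], remaining_target)
      remaining_target <- remaining_target - kept[i]
      remaining_total <- remaining_total - n[i]
    }
    kept
  })
  table$read_count <- as.integer(out)
  table <- table[table$read_count > 0L, , drop = FALSE]
  rownames(table) <- NULL
  table
}

#' Merge nucleotide sequences into clonotypes
#'
#' All nucleotide sequences coding for an identical CDR3beta amino-acid
#' sequence are merged into one clonotype whose copy number is the summed read
#' count. The clonotype inherits the V and J segments of the member nucleotide
#' sequence with the highest read count; ties are broken deterministically by
#' the lexicographically smallest nucleotide sequence. Clonotypes are ordered
#' by decreasing copy number (ties by CDR3 sequence) so that write/read round
#' trips are exact.
#'
#' @param table raw sequence table (see [read_clonotype_table()]).
#' @param sample_id,group_label,timepoint metadata for the resulting
#'   repertoire.
#' @return a [repertoire] whose `variants` slot preserves the nucleotide
#'   composition of every clonotype.
#' @export
merge_to_clonotypes <- function(table, sample_id = "sample",
                                group_label = NA_character_,
                                timepoint = NA_character_) {
  if (!nrow(table)) stop("cannot merge an empty table")
  ord <- order(table$cdr3_aa, -table$read_count, table$nt_sequence)
  tab <- table[ord, , drop = FALSE]
  top <- tab[!duplicated(tab$cdr3_aa), , drop = FALSE]
  key <- factor(tab$cdr3_aa, levels = top$cdr3_aa)
  cn <- rowsum(as.numeric(tab$read_count), key)[, 1L]
  cl <- data.frame(cdr3_aa = top$cdr3_aa,
                   v_segment = top$v_segment,
                   j_segment = top$j_segment,
                   copy_number = as.integer(cn),
                   stringsAsFactors = FALSE)
  cl_ord <- order(-cl$copy_number, cl$cdr3_aa)
  cl <- cl[cl_ord, , drop = FALSE]
  vr <- data.frame(cdr3_aa = tab$cdr3_aa,
                   nt_sequence = tab$nt_sequence,
                   read_count = tab$read_count,
                   stringsAsFactors = FALSE)
  vr <- vr[order(match(vr$cdr3_aa, cl$cdr3_aa), -vr$read_count, vr$nt_sequence), ,
           drop = FALSE]
  rownames(cl) <- rownames(vr) <- NULL
  repertoire(cl, variants = vr, sample_id = sample_id,
             group_label = group_label, timepoint = timepoint)
}

#' Remove copy-number-1 clonotypes
#'
#' Clonotypes supported by a single read are likely polymerase/sequencing
#' artefacts and are excluded before any index is computed, so `CN = 2` is the
#' lowest copy number in a preprocessed repertoire. Order is preserved and the
#' operation is idempotent.
#'
#' @param rep a repertoire.
#' @return the repertoire restricted to clonotypes with `copy_number >= 2`.
#' @export
remove_singletons <- function(rep) {
  keep <- rep$clonotypes$copy_number >= 2L
  if (all(keep)) return(rep)
  out <- subset_repertoire(rep, keep)
  if (!nrow(out$clonotypes))
    message("repertoire '", rep$sample_id, "' is empty after singleton removal")
  out
}

# Restrict a repertoire to a logical/integer clonotype selection,
# keeping variants consistent.
subset_repertoire <- function(rep, keep) {
  cl <- rep$clonotypes[keep, , drop = FALSE]
  rownames(cl) <- NULL
  vr <- rep$variants
  if (!is.null(vr)) {
    vr <- vr[vr$cdr3_aa %in% cl$cdr3_aa, , drop = FALSE]
    rownames(vr) <- NULL
  }
  out <- rep
  out$clonotypes <- cl
  out$variants <- vr
  out
}

#' Write a repertoire to a clonotype table
#'
#' Writes one row per nucleotide variant (clonotype-level V/J replicated), so
#' that reading the file back and re-merging reproduces the repertoire exactly.
#'
#' @param rep repertoire to write.
#' @param path output file path.
#' @param dialect output dialect, see [read_clonotype_table()].
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path, dialect = "simple") {
  dialect <- match_dialect(dialect)
  map <- .dialects[[dialect]]
  cl <- rep$clonotypes
  if (is.null(rep$variants)) {
    vr <- data.frame(cdr3_aa = cl$cdr3_aa,
                     nt_sequence = cl$cdr3_aa,  # no nucleotide data recorded
                     read_count = cl$copy_number, stringsAsFactors = FALSE)
  } else vr <- rep$variants
  idx <- match(vr$cdr3_aa, cl$cdr3_aa)
  out <- data.frame(vr$read_count, vr$nt_sequence, vr$cdr3_aa,
                    cl$v_segment[idx], cl$j_segment[idx],
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unname(map[c("read_count", "nt_sequence", "cdr3_aa",
                             "v_segment", "j_segment")])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("failed writing '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Preprocess a raw sequence table into an analysis-ready repertoire
#'
#' Applies the standard preprocessing order: (optional) removal of
#' nonfunctional sequences happens at read time, then (optional) downsampling
#' of nucleotide-sequence read counts to a common depth, merging to
#' clonotypes, and exclusion of copy-number-1 clonotypes.
#'
#' @param table raw sequence table.
#' @param downsample_to optional target read total (see [downsample_reads()]).
#' @param seed seed for the downsampling draw.
#' @inheritParams merge_to_clonotypes
#' @return a preprocessed [repertoire] (all `copy_number >= 2`).
#' @export
preprocess_table <- function(table, downsample_to = NULL, seed = NULL,
                             sample_id = "sample", group_label = NA_character_,
                             timepoint = NA_character_) {
  if (!is.null(downsample_to))
    table <- downsample_reads(table, downsample_to, seed = seed)
  rep <- merge_to_clonotypes(table, sample_id = sample_id,
                             group_label = group_label, timepoint = timepoint)
  remove_singletons(rep)
}
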
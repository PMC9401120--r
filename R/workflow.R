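#' Run the end-to-end repertoire study analogue
#'
#' Orchestrates the full analysis under one configuration: obtain repertoires
#' (simulated cohort or clonotype-table files), preprocess, compute
#' per-sample per-fraction indices, compare cohorts fraction-wise, classify
#' the configured sub-repertoire, and (optionally) distribute an externally
#' supplied clonotype set over the log2 fractions. All outputs are plain TSV
#' and JSON for diff-ability, plus a run manifest (config echo, seeds,
#' package version).
#'
#' @param config either a `study_config` list (see Details) or the path of a
#'   YAML file holding one.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress per-stage log lines.
#'
#' @details The configuration is a named list with (all optional unless
#' noted): `simulate` — arguments for [cohort_config()] (used when no `input`
#' files are given); `input` — list with `control`/`treated` character vectors
#' of file paths and `dialect`; `downsample_to` — common read depth;
#' `indices` — index names for [compare_cohorts()]; `alternative`; `scheme`;
#' `classify` — list with `sub`, `criterion`, `weighted`, `exclude`;
#' `clonotype_set` — path of a text file with one CDR3 amino-acid sequence
#' per line (distribution analysis); `seed`.
#'
#' @return (invisibly) list with the `cohort_comparison`, the
#'   `repertoire_classification`, the per-sample index table, the distribution
#'   table, and the manifest.
#' @export
run_study <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed %||% 1L

  # -- stage: obtain repertoires ---------------------------------------------
  if (!is.null(config$input)) {
    dial <- config$input$dialect %||% "simple"
    read_group <- function(paths, label) lapply(seq_along(paths), function(i) {
      tab <- read_clonotype_table(paths[i], dialect = dial)
      preprocess_table(tab, downsample_to = config$downsample_to,
                       seed = seed + i,
                       sample_id = tools::file_path_sans_ext(basename(paths[i])),
                       group_label = label)
    })
    control <- read_group(config$input$control, "control")
    treated <- read_group(config$input$treated, "immunized")
    labels <- factor(rep(c("control", "immunized"),
                         c(length(control), length(treated))),
                     levels = c("control", "immunized"))
    reps <- c(control, treated)
    say("stage=input n_control=%d n_treated=%d", length(control), length(treated))
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    if (!is.null(sim_args$effect) && !inherits(sim_args$effect, "effect_config"))
      sim_args$effect <- do.call(effect_config, sim_args$effect)
    cohort <- do.call(cohort_config, sim_args)
    cohort <- generate_cohort(cohort)
    reps <- cohort$repertoires
    labels <- cohort$labels
    control <- reps[labels == "control"]
    treated <- reps[labels == "immunized"]
    utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("stage=simulate n_control=%d n_treated=%d", length(control), length(treated))
  }

  # -- stage: per-sample per-fraction indices --------------------------------
  scheme <- fraction_scheme(config$scheme %||% "log2")
  indices <- config$indices %||% c("rhi_ld", "rhi_vj", "cdi")
  cmp <- compare_cohorts(control, treated, indices = indices, scheme = scheme,
                         alternative = config$alternative %||% "less")
  vals <- cmp$values
  idx_tab <- data.frame(sample_id = rep(dimnames(vals)[[1]], times = prod(dim(vals)[2:3])),
                        fraction = rep(rep(dimnames(vals)[[2]], each = dim(vals)[1]),
                                       times = dim(vals)[3]),
                        index = rep(dimnames(vals)[[3]], each = prod(dim(vals)[1:2])),
                        value = as.vector(vals))
  utils::write.table(idx_tab, file.path(out_dir, "indices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary(cmp), file.path(out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("stage=compare indices=%s", paste(indices, collapse = ","))

  # -- stage: classification -------------------------------------------------
  cls_cfg <- config$classify %||% list()
  cls <- classify_cohort(reps, labels = labels,
                         sub = cls_cfg$sub %||% "top",
                         criterion = cls_cfg$criterion %||% "vj",
                         weighted = isTRUE(cls_cfg$weighted),
                         exclude = cls_cfg$exclude,
                         seed = seed)
  utils::write.table(cls$matrix, file.path(out_dir, "dissimilarity.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(data.frame(sample_id = rownames(cls$mds),
                                mds1 = cls$mds[, 1], mds2 = cls$mds[, 2],
                                cluster = cls$clusters$assignments),
                     file.path(out_dir, "mds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(confusion = as.vector(cls$loo$confusion),
                            accuracy = cls$loo$accuracy,
                            fisher_p = cls$loo$fisher_p),
                       file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)
  say("stage=classify accuracy=%.2f fisher_p=%.3g", cls$loo$accuracy, cls$loo$fisher_p)

  # -- stage: clonotype-set distribution -------------------------------------
  dist_tab <- NULL
  if (!is.null(config$clonotype_set)) {
    aa_set <- readLines(config$clonotype_set, warn = FALSE)
    aa_set <- aa_set[nzchar(aa_set)]
    dist_tab <- t(vapply(reps, distribute_clonotype_set, integer(10), aa_set = aa_set))
    dist_tab <- data.frame(sample_id = vapply(reps, `[[`, "", "sample_id"),
                           group = labels, dist_tab, check.names = FALSE)
    utils::write.table(dist_tab, file.path(out_dir, "set_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("stage=distribute set_size=%d", length(aa_set))
  }

  manifest <- list(package = "repfrac",
                   version = as.character(utils::packageVersion("repfrac")),
                   seed = seed,
                   config = config,
                   n_samples = length(reps))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(comparison = cmp, classification = cls,
                 indices = idx_tab, distribution = dist_tab,
                 manifest = manifest))
}
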
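# Amino-acid alphabet for CDR3 generation. Generated CDR3s keep the canonical
# C...F frame; satellite mutations only touch interior positions.
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.codon_cache <- new.env(parent = emptyenv())

# aa letter -> standard codons, built from the genetic code.
reverse_codon_table <- function() {
  if (is.null(.codon_cache$rev)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[gc != "*"]
    .codon_cache$rev <- split(names(gc), unname(gc))
  }
  .codon_cache$rev
}

# One random nucleotide coding per amino-acid sequence (uniform synonymous
# codon choice), vectorized over sequences.
random_coding <- function(aa_vec) {
  if (!length(aa_vec)) return(character())
  rev <- reverse_codon_table()
  chars <- strsplit(aa_vec, "", fixed = TRUE)
  gid <- rep.int(seq_along(aa_vec), lengths(chars))
  letters_all <- unlist(chars, use.names = FALSE)
  codons <- character(length(letters_all))
  for (a in unique(letters_all)) {
    ii <- which(letters_all == a)
    opts <- rev[[a]]
    codons[ii] <- opts[sample.int(length(opts), length(ii), replace = TRUE)]
  }
  vapply(split(codons, gid), paste0, "", collapse = "")
}

# k distinct nucleotide codings for one amino-acid sequence (rejection on
# duplicates; guaranteed possible for the >= 6-residue CDR3s generated here).
distinct_codings <- function(aa, k) {
  out <- unique(random_coding(rep.int(aa, k)))
  tries <- 0L
  while (length(out) < k && tries < 50L) {
    out <- unique(c(out, random_coding(rep.int(aa, k - length(out)))))
    tries <- tries + 1L
  }
  out[seq_len(k)]
}

random_cdr3 <- function(n, len) {
  # fixed C...F frame with random interior
  if (!n) return(character())
  inner <- len - 2L
  chars <- sample(.AA, sum(inner), replace = TRUE)
  gid <- rep.int(seq_len(n), inner)
  paste0("C", vapply(split(chars, gid), paste0, "", collapse = ""), "F")
}

draw_lengths <- function(n, cfg, shift = 0L) {
  len <- round(stats::rnorm(n, mean = cfg$mean + shift, sd = cfg$sd))
  pmin(pmax(len, cfg$min), cfg$max)
}

#' Synthetic cohort configuration
#'
#' All distributions and effect sizes of the synthetic TCRbeta repertoire
#' generator. The architecture mirrors what distinguishes public from private
#' clonotypes in murine spleen: public clonotypes are shared between animals,
#' reach considerably higher copy numbers, have shorter CDR3 regions,
#' restricted VJ segment usage, several nucleotide codings (convergent
#' recombination), and come with CDR3-similar low-copy satellite clonotypes
#' forming Levenshtein-distance-1 clusters; private clonotypes are unique to
#' an animal, mostly singly coded, with unrestricted VJ usage.
#'
#' @param n_control,n_treated cohort sizes (defaults 20 and 10, the study
#'   design of one immunization time point versus the pooled controls).
#' @param n_clonotypes_target approximate clonotypes per animal after
#'   preprocessing (desk-scale default 2000).
#' @param cn_distribution list: `type = "power_law"` with `exponent`, `min`,
#'   `max` — the base copy-number law (monotone decaying fraction occupancy).
#' @param public_pool_size number of public prototype clonotypes.
#' @param public_share_prob probability that a given public pool clonotype is
#'   present in a given animal.
#' @param public_cn_multiplier copy-number multiplier of public prototypes
#'   relative to the base law (satellites stay on the base law).
#' @param public_cdr3_length_shift additive shift (<= 0) of public CDR3
#'   lengths.
#' @param public_vj_concentration restriction of public VJ usage: pair
#'   frequencies are drawn from a Dirichlet with parameter
#'   `1/public_vj_concentration`; larger values concentrate the usage on
#'   fewer pairs (`Inf` collapses everything onto a single pair).
#' @param public_nc_variants list `min`, `mean_extra`: nucleotide codings per
#'   public clonotype are `min + Poisson(mean_extra)`, capped at 8.
#' @param private_nc_variants list `p_multi`: probability that a private
#'   clonotype carries a second coding (otherwise singly coded).
#' @param cluster_neighbors_per_public Levenshtein-distance-1 satellite
#'   clonotypes per public prototype.
#' @param v_segments,j_segments gene-segment label pools.
#' @param cdr3_length list `mean`, `sd`, `min`, `max` of the discretized
#'   normal CDR3 length law (private clonotypes).
#' @param effect an [effect_config()] describing the injected immunization
#'   effect for treated animals.
#' @param seed root seed; every animal and the pool get derived substreams.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 20L, n_treated = 10L,
                          n_clonotypes_target = 2000L,
                          cn_distribution = list(type = "power_law",
                                                 exponent = 2.5,
                                                 min = 2L, max = 20000L),
                          public_pool_size = 150L,
                          public_share_prob = 0.8,
                          public_cn_multiplier = 40,
                          public_cdr3_length_shift = -2L,
                          public_vj_concentration = 50,
                          public_nc_variants = list(min = 2L, mean_extra = 1.5),
                          private_nc_variants = list(p_multi = 0.08),
                          cluster_neighbors_per_public = 3L,
                          v_segments = paste0("TRBV", 1:20),
                          j_segments = paste0("TRBJ", 1:12),
                          cdr3_length = list(mean = 14, sd = 2, min = 8L, max = 20L),
                          effect = effect_config(),
                          seed = 1L) {
  stopifnot(public_share_prob >= 0, public_share_prob <= 1,
            public_cn_multiplier >= 1,
            public_cdr3_length_shift <= 0,
            cn_distribution$type == "power_law")
  structure(as.list(environment()), class = "cohort_config")
}

#' Immunization-effect configuration
#'
#' Describes the injected effect applied to treated animals: antigen-specific
#' clonotypes placed into a chosen region of log2 copy-number fractions. The
#' default emulates the early response (expansion into the high-copy fractions
#' 7-10); `effect_late()` emulates the late response (accumulation of many
#' specific clones in the lowest-copy fractions 1-2).
#'
#' @param target_fractions integer interval `c(lo, hi)` of log2 fractions the
#'   injected clonotypes land in.
#' @param n_specific_per_animal number of injected specific clonotypes.
#' @param expansion_multiplier multiplier (>= 1) applied to the drawn copy
#'   numbers before clamping back into the target region; values > 1 bias the
#'   injected clones toward the top of the region.
#' @param specific_type `"private"` (new animal-unique, singly coded
#'   clonotypes — the regime of the SRBC response) or `"public"` (expansion of
#'   clonotypes from the shared pool).
#' @param timepoint label attached to treated repertoires.
#' @return object of class `effect_config`.
#' @export
effect_config <- function(target_fractions = c(7L, 10L),
                          n_specific_per_animal = 60L,
                          expansion_multiplier = 1,
                          specific_type = c("private", "public"),
                          timepoint = "d3") {
  specific_type <- match.arg(specific_type)
  stopifnot(length(target_fractions) == 2L,
            target_fractions[1] >= 1L, target_fractions[2] <= 10L,
            target_fractions[1] <= target_fractions[2],
            expansion_multiplier >= 1)
  structure(list(target_fractions = as.integer(target_fractions),
                 n_specific_per_animal = as.integer(n_specific_per_animal),
                 expansion_multiplier = expansion_multiplier,
                 specific_type = specific_type,
                 timepoint = timepoint),
            class = "effect_config")
}

#' @rdname effect_config
#' @export
effect_late <- function(n_specific_per_animal = 400L) {
  effect_config(target_fractions = c(1L, 2L),
                n_specific_per_animal = n_specific_per_animal,
                timepoint = "d7")
}

draw_base_cn <- function(n, dist) {
  support <- dist$min:dist$max
  # power law with monotone decaying fraction occupancy
  probs <- as.numeric(support)^(-dist$exponent)
  sample(support, n, replace = TRUE, prob = probs)
}

#' Generate the public clonotype pool
#'
#' Draws the shared pool of public prototypes (shortened CDR3, VJ pairs from a
#' concentrated usage distribution, multiple fixed nucleotide codings) plus
#' their Levenshtein-distance-1 satellite clonotypes (same VJ pair as the
#' prototype, one interior residue substituted).
#'
#' @param config a [cohort_config()].
#' @param seed seed for the pool substream.
#' @return data.frame with columns `cdr3_aa`, `v_segment`, `j_segment`,
#'   `role` (`"prototype"`/`"satellite"`), `prototype_id`, `n_codings`, and a
#'   list column `codings` of distinct nucleotide sequences.
#' @export
make_public_pool <- function(config, seed = NULL) {
  with_preserved_seed(seed, {
    np <- config$public_pool_size
    nV <- length(config$v_segments); nJ <- length(config$j_segments)
    K <- nV * nJ

    conc <- config$public_vj_concentration
    if (is.infinite(conc)) {
      probs <- numeric(K); probs[sample.int(K, 1L)] <- 1
    } else {
      w <- stats::rgamma(K, shape = 1 / conc)
      if (sum(w) == 0) { w <- numeric(K); w[sample.int(K, 1L)] <- 1 }
      probs <- w / sum(w)
    }
    pair <- sample.int(K, np, replace = TRUE, prob = probs)
    v <- config$v_segments[(pair - 1L) %/% nJ + 1L]
    j <- config$j_segments[(pair - 1L) %% nJ + 1L]

    len <- draw_lengths(np, config$cdr3_length, shift = config$public_cdr3_length_shift)
    aa <- random_cdr3(np, len)
    while (anyDuplicated(aa)) {
      dup <- which(duplicated(aa))
      aa[dup] <- random_cdr3(length(dup), len[dup])
    }

    k <- pmin(config$public_nc_variants$min +
                stats::rpois(np, config$public_nc_variants$mean_extra), 8L)

    nsat <- config$cluster_neighbors_per_public
    if (nsat > 0L) {
      proto_id <- rep(seq_len(np), each = nsat)
      sat_aa <- vapply(proto_id, function(p) {
        s <- aa[p]
        pos <- sample(2:(nchar(s) - 1L), 1L)  # keep the C...F frame
        old <- substr(s, pos, pos)
        repl <- sample(setdiff(.AA, old), 1L)
        paste0(substr(s, 1L, pos - 1L), repl, substr(s, pos + 1L, nchar(s)))
      }, "")
      sat_k <- pmin(config$public_nc_variants$min +
                      stats::rpois(length(sat_aa), config$public_nc_variants$mean_extra), 8L)
      pool <- data.frame(cdr3_aa = c(aa, sat_aa),
                         v_segment = c(v, v[proto_id]),
                         j_segment = c(j, j[proto_id]),
                         role = rep(c("prototype", "satellite"), c(np, length(sat_aa))),
                         prototype_id = c(seq_len(np), proto_id),
                         n_codings = c(k, sat_k),
                         stringsAsFactors = FALSE)
    } else {
      pool <- data.frame(cdr3_aa = aa, v_segment = v, j_segment = j,
                         role = "prototype", prototype_id = seq_len(np),
                         n_codings = k, stringsAsFactors = FALSE)
    }
    keep <- !duplicated(pool$cdr3_aa)  # rare satellite collisions
    pool <- pool[keep, , drop = FALSE]
    pool$codings <- I(mapply(distinct_codings, pool$cdr3_aa, pool$n_codings,
                             SIMPLIFY = FALSE))
    rownames(pool) <- NULL
    pool
  })
}

# Assemble clonotype + variant tables from per-clonotype coding lists.
assemble_repertoire <- function(aa, v, j, cn, codings, sample_id,
                                group_label, timepoint) {
  k <- pmin(lengths(codings), cn)  # cannot carry more codings than reads
  n <- length(aa)
  counts <- vector("list", n)
  d_nc <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] == 1L) {
      counts[[i]] <- cn[i]
    } else {
      cts <- as.vector(stats::rmultinom(1L, cn[i] - k[i], rep.int(1, k[i]))) + 1L
      counts[[i]] <- cts
      d_nc[i] <- 1 - sum((cts / cn[i])^2)
    }
  }
  cl <- data.frame(cdr3_aa = aa, v_segment = v, j_segment = j,
                   copy_number = as.integer(cn),
                   n_variants = as.integer(k), d_nc = d_nc,
                   stringsAsFactors = FALSE)
  vr <- data.frame(cdr3_aa = rep.int(aa, k),
                   nt_sequence = unlist(mapply(function(cc, kk) cc[seq_len(kk)],
                                               codings, k, SIMPLIFY = FALSE),
                                        use.names = FALSE),
                   read_count = as.integer(unlist(counts, use.names = FALSE)),
                   stringsAsFactors = FALSE)
  repertoire(cl, variants = vr, sample_id = sample_id,
             group_label = group_label, timepoint = timepoint)
}

#' Generate one synthetic repertoire
#'
#' Composes an animal's repertoire from the shared public pool (each pool
#' clonotype present independently with `public_share_prob`; prototypes on the
#' multiplied copy-number law, satellites on the base law) and animal-unique
#' private clonotypes (unshifted CDR3 lengths, uniform VJ usage, mostly single
#' nucleotide coding). All copy numbers are >= 2, i.e. the repertoire is
#' already in preprocessed form.
#'
#' @param config a [cohort_config()].
#' @param pool result of [make_public_pool()].
#' @param animal_id sample id.
#' @param seed per-animal substream seed.
#' @param group_label,timepoint metadata attached to the repertoire.
#' @return a [repertoire].
#' @export
generate_repertoire <- function(config, pool, animal_id, seed = NULL,
                                group_label = "control", timepoint = "d0") {
  with_preserved_seed(seed, {
    present <- stats::runif(nrow(pool)) < config$public_share_prob
    pub <- pool[present, , drop = FALSE]
    base <- draw_base_cn(nrow(pub), config$cn_distribution)
    # prototypes are always expanded; satellites straddle the copy-number
    # range (half on the base law, half expanded), so public cluster
    # structures exist in the low- as well as the high-copy region
    expanded <- pub$role == "prototype" | stats::runif(nrow(pub)) < 0.5
    mult <- ifelse(expanded, config$public_cn_multiplier, 1)
    pub_cn <- pmin(round(base * mult), config$cn_distribution$max)

    n_priv <- max(0L, round(config$n_clonotypes_target -
                              nrow(pool) * config$public_share_prob))
    priv_len <- draw_lengths(n_priv, config$cdr3_length)
    priv_aa <- random_cdr3(n_priv, priv_len)
    bad <- duplicated(priv_aa) | priv_aa %in% pub$cdr3_aa
    while (any(bad)) {
      priv_aa[bad] <- random_cdr3(sum(bad), priv_len[bad])
      bad <- duplicated(priv_aa) | priv_aa %in% pub$cdr3_aa
    }
    priv_cn <- draw_base_cn(n_priv, config$cn_distribution)
    priv_v <- sample(config$v_segments, n_priv, replace = TRUE)
    priv_j <- sample(config$j_segments, n_priv, replace = TRUE)
    priv_k <- 1L + (stats::runif(n_priv) < config$private_nc_variants$p_multi)
    priv_codings <- vector("list", n_priv)
    single <- priv_k == 1L
    priv_codings[single] <- as.list(random_coding(priv_aa[single]))
    if (any(!single))
      priv_codings[!single] <- mapply(distinct_codings, priv_aa[!single],
                                      priv_k[!single], SIMPLIFY = FALSE)

    assemble_repertoire(aa = c(pub$cdr3_aa, priv_aa),
                        v = c(pub$v_segment, priv_v),
                        j = c(pub$j_segment, priv_j),
                        cn = c(pub_cn, priv_cn),
                        codings = c(pub$codings, priv_codings),
                        sample_id = animal_id,
                        group_label = group_label, timepoint = timepoint)
  })
}

#' Inject an immunization effect into a repertoire
#'
#' Adds `n_specific_per_animal` antigen-specific clonotypes whose copy numbers
#' are drawn to land in the configured log2 fraction region. In the
#' `"private"` regime (the default) these are new, animal-unique, singly coded
#' clonotypes with unrestricted VJ usage — the displacement signature observed
#' after immunization with a complex antigen. In the `"public"` regime,
#' clonotypes sampled from the public pool are expanded into the target region
#' instead.
#'
#' @param rep a repertoire of a treated animal.
#' @param effect an [effect_config()].
#' @param config the generating [cohort_config()].
#' @param seed substream seed.
#' @param pool the public pool (needed for `specific_type = "public"`).
#' @return list with elements `repertoire` (modified) and `truth`
#'   (data.frame `sample_id`, `cdr3_aa`, `copy_number`, `fraction` of the
#'   injected/expanded clonotypes).
#' @export
inject_effect <- function(rep, effect, config, seed = NULL, pool = NULL) {
  n <- effect$n_specific_per_animal
  empty_truth <- data.frame(sample_id = character(), cdr3_aa = character(),
                            copy_number = integer(), fraction = integer())
  if (n == 0L) return(list(repertoire = rep, truth = empty_truth))
  with_preserved_seed(seed, {
    frs <- seq.int(effect$target_fractions[1], effect$target_fractions[2])
    fr <- sample(rep.int(frs, 2L), n, replace = TRUE)  # rep.int guards length-1 ranges
    lo <- .log2_lower[fr]
    hi <- ifelse(fr < 10L, 2L^fr, 1024L)
    cn <- lo + floor(stats::runif(n) * (hi - lo + 1L))
    cn <- pmin(pmax(round(cn * effect$expansion_multiplier), lo), hi)

    if (effect$specific_type == "private") {
      len <- draw_lengths(n, config$cdr3_length)
      aa <- random_cdr3(n, len)
      bad <- duplicated(aa) | aa %in% rep$clonotypes$cdr3_aa
      while (any(bad)) {
        aa[bad] <- random_cdr3(sum(bad), len[bad])
        bad <- duplicated(aa) | aa %in% rep$clonotypes$cdr3_aa
      }
      v <- sample(config$v_segments, n, replace = TRUE)
      j <- sample(config$j_segments, n, replace = TRUE)
      nt <- random_coding(aa)
      cl_new <- data.frame(cdr3_aa = aa, v_segment = v, j_segment = j,
                           copy_number = as.integer(cn),
                           n_variants = 1L, d_nc = 0,
                           stringsAsFactors = FALSE)
      vr_new <- data.frame(cdr3_aa = aa, nt_sequence = nt,
                           read_count = as.integer(cn),
                           stringsAsFactors = FALSE)
      out <- rep
      out$clonotypes <- rbind(rep$clonotypes, cl_new)
      out$variants <- rbind(rep$variants, vr_new)
      rownames(out$clonotypes) <- rownames(out$variants) <- NULL
      validate_repertoire(out)
      truth <- data.frame(sample_id = rep$sample_id, cdr3_aa = aa,
                          copy_number = as.integer(cn), fraction = fr,
                          stringsAsFactors = FALSE)
    } else {
      if (is.null(pool)) stop("specific_type = 'public' requires the pool")
      idx <- match(sample(pool$cdr3_aa[pool$role == "prototype"],
                          min(n, sum(pool$role == "prototype"))),
                   rep$clonotypes$cdr3_aa)
      idx <- idx[!is.na(idx)]
      cn <- cn[seq_along(idx)]; fr <- fr[seq_along(idx)]
      out <- rep
      out$clonotypes$copy_number[idx] <- as.integer(cn)
      # rescale variant read counts of the expanded clonotypes
      for (q in seq_along(idx)) {
        i <- idx[q]
        sel <- out$variants$cdr3_aa == out$clonotypes$cdr3_aa[i]
        k <- sum(sel)
        cts <- as.vector(stats::rmultinom(1L, cn[q] - k, rep.int(1, k))) + 1L
        out$variants$read_count[sel] <- as.integer(cts)
        out$clonotypes$n_variants[i] <- k
        out$clonotypes$d_nc[i] <- 1 - sum((cts / cn[q])^2)
      }
      validate_repertoire(out)
      truth <- data.frame(sample_id = rep$sample_id,
                          cdr3_aa = out$clonotypes$cdr3_aa[idx],
                          copy_number = as.integer(cn), fraction = fr,
                          stringsAsFactors = FALSE)
    }
    list(repertoire = out, truth = truth)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Draws the public pool once, then `n_control` unmodified and `n_treated`
#' effect-injected repertoires. All randomness flows from `config$seed`
#' through derived substreams (pool; one per animal; one per injection), so
#' the cohort is bit-identical across runs for a given configuration.
#'
#' @param config a [cohort_config()].
#' @return object of class `labeled_cohort`: list with `repertoires`,
#'   `labels` (factor, levels `control`/`immunized`), `truth` (row-bound
#'   injection records), `pool`, `config`.
#' @export
generate_cohort <- function(config) {
  n_tot <- config$n_control + config$n_treated
  seeds <- derive_seeds(config$seed, 1L + n_tot + config$n_treated)
  pool <- make_public_pool(config, seed = seeds[1L])
  reps <- vector("list", n_tot)
  truths <- list()
  for (i in seq_len(config$n_control)) {
    reps[[i]] <- generate_repertoire(config, pool,
                                     animal_id = sprintf("C%02d", i),
                                     seed = seeds[1L + i],
                                     group_label = "control", timepoint = "d0")
  }
  for (t in seq_len(config$n_treated)) {
    i <- config$n_control + t
    r <- generate_repertoire(config, pool,
                             animal_id = sprintf("T%02d", t),
                             seed = seeds[1L + i],
                             group_label = "immunized",
                             timepoint = config$effect$timepoint)
    inj <- inject_effect(r, config$effect, config,
                         seed = seeds[1L + n_tot + t], pool = pool)
    reps[[i]] <- inj$repertoire
    truths[[t]] <- inj$truth
  }
  structure(list(repertoires = reps,
                 labels = factor(rep(c("control", "immunized"),
                                     c(config$n_control, config$n_treated)),
                                 levels = c("control", "immunized")),
                 truth = do.call(rbind, truths) %||%
                   data.frame(sample_id = character(), cdr3_aa = character(),
                              copy_number = integer(), fraction = integer()),
                 pool = pool, config = config),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("Synthetic labeled cohort: ", sum(x$labels == "control"), " control + ",
      sum(x$labels == "immunized"), " immunized animals\n", sep = "")
  sz <- vapply(x$repertoires, n_clonotypes, 0L)
  cat("  clonotypes per animal: ", min(sz), "-", max(sz),
      " (median ", stats::median(sz), ")\n", sep = "")
  ef <- x$config$effect
  cat("  effect: ", ef$n_specific_per_animal, " ", ef$specific_type,
      " clonotypes into log2 fractions ", ef$target_fractions[1], "-",
      ef$target_fractions[2], " (", ef$timepoint, ")\n", sep = "")
  invisible(x)
}
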
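#' Configuration for a synthetic miRNA-overexpression experiment
#'
#' Bundles and validates all generator parameters.  The defaults emulate
#' the statistical structure of a miRNA transfection microarray study on
#' a human gene universe: log-normal region lengths, genome-like AT-rich
#' base composition (41\% GC), a fraction of genes carrying effective
#' planted seed sites whose expression shifts down by a per-category
#' effect, nonfunctional background seed sites in other genes, replicate
#' noise, a global additive logFC displacement, and (optionally) a
#' transcription-factor regulon with planted promoter motifs and a
#' coordinated expression shift.
#'
#' @param n_genes Number of genes (default 2000).
#' @param seed RNG seed for full determinism (default NULL).
#' @param composition Per-base probabilities A,C,G,T; default
#'   `c(0.295, 0.205, 0.205, 0.295)`.
#' @param utr3_len,cds_len,utr5_len Log-normal length models,
#'   `list(meanlog, sdlog)`; defaults give median 1000 / 1300 / 200 nt.
#' @param promoter_len Fixed promoter length (default 2000 nt upstream of
#'   the TSS).
#' @param target_fraction Fraction of genes designated miRNA targets
#'   (default 0.15).
#' @param site_spec Per-category probability that a target receives one
#'   planted site of that category (`site8`, `site7m8`, `site7a1`,
#'   `site6`).  A target that draws none receives a 7mer-m8.
#' @param effects Per-category logFC shift contributed by a planted site;
#'   default `c(site8 = -0.6, site7m8 = -0.4, site7a1 = -0.3,
#'   site6 = -0.1)`, ordered by the canonical site-efficacy hierarchy.
#' @param background_prob Probability that a non-target gene carries one
#'   nonfunctional (no expression effect) seed site (default 0.1).
#' @param noise_sd Replicate noise standard deviation in log2 units
#'   (default 0.25).
#' @param global_shift Additive logFC displacement applied to every gene
#'   (default 0.226), emulating the array-wide technical displacement such
#'   experiments show.
#' @param n_replicates Replicates per condition,
#'   `c(treated = 4, control = 4)`; set control to 3 to emulate removal of
#'   one mock array.
#' @param regulon Optional transcription-factor regulon:
#'   `list(motif = <count_matrix>, member_fraction, plant_prob_members,
#'   plant_prob_background, regulon_shift)`.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, seed = NULL,
                              composition = c(A = 0.295, C = 0.205,
                                              G = 0.205, T = 0.295),
                              utr3_len = list(meanlog = log(1000),
                                              sdlog = 0.6),
                              cds_len = list(meanlog = log(1300),
                                             sdlog = 0.4),
                              utr5_len = list(meanlog = log(200),
                                              sdlog = 0.5),
                              promoter_len = 2000L,
                              target_fraction = 0.15,
                              site_spec = c(site8 = 0.3, site7m8 = 0.5,
                                            site7a1 = 0.35, site6 = 0.25),
                              effects = c(site8 = -0.6, site7m8 = -0.4,
                                          site7a1 = -0.3, site6 = -0.1),
                              background_prob = 0.1,
                              noise_sd = 0.25,
                              global_shift = 0.226,
                              n_replicates = c(treated = 4L, control = 4L),
                              regulon = NULL) {
  check_scalar_number(n_genes, "n_genes", 2)
  check_scalar_number(target_fraction, "target_fraction", 0, 1)
  check_scalar_number(background_prob, "background_prob", 0, 1)
  check_scalar_number(noise_sd, "noise_sd", 0)
  check_scalar_number(promoter_len, "promoter_len", 1)
  if (length(composition) != 4 || any(composition < 0)) {
    abort("`composition` must be 4 non-negative base probabilities")
  }
  if (!all(SITE_CATEGORIES %in% names(site_spec)) ||
      any(site_spec < 0 | site_spec > 1)) {
    abort("`site_spec` needs probabilities in [0,1] for site8, site7m8, site7a1, site6")
  }
  if (!all(SITE_CATEGORIES %in% names(effects))) {
    abort("`effects` needs values for site8, site7m8, site7a1, site6")
  }
  if (length(n_replicates) != 2 || any(n_replicates < 2)) {
    abort("`n_replicates` must give at least 2 replicates per condition")
  }
  if (!is.null(regulon)) {
    req <- c("motif", "member_fraction", "plant_prob_members",
             "plant_prob_background", "regulon_shift")
    if (!all(req %in% names(regulon))) {
      abort(sprintf("`regulon` needs elements: %s", paste(req, collapse = ", ")))
    }
    if (!inherits(regulon$motif, "count_matrix")) {
      abort("`regulon$motif` must be a count_matrix")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), seed = seed,
         composition = composition, utr3_len = utr3_len, cds_len = cds_len,
         utr5_len = utr5_len, promoter_len = as.integer(promoter_len),
         target_fraction = target_fraction, site_spec = site_spec,
         effects = effects, background_prob = background_prob,
         noise_sd = noise_sd, global_shift = global_shift,
         n_replicates = n_replicates, regulon = regulon),
    class = "simulation_config"
  )
}

#' Random DNA sequences
#'
#' @param n Number of sequences.
#' @param lengths Sequence length(s), recycled to `n`.
#' @param composition Per-base probabilities A,C,G,T.
#' @param seed Optional RNG seed.
#' @return Character vector of sequences.
#' @export
random_dna <- function(n, lengths,
                       composition = c(0.25, 0.25, 0.25, 0.25),
                       seed = NULL) {
  lens <- as.integer(rep_len(lengths, n))
  with_seed_if(seed, cpp_random_dna(lens, as.numeric(composition)))
}

#' Consensus sequence of a motif
#'
#' @param x A [count_matrix()] or [build_pssm()] object.
#' @return The consensus string (highest count/weight per column; ties go
#'   to the alphabetically first base).
#' @export
consensus_sequence <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts
       else if (inherits(x, "pssm")) x$weights
       else abort("`x` must be a count_matrix or pssm")
  paste(DNA_BASES[apply(m, 2, which.max)], collapse = "")
}

#' Plant a word into a sequence
#'
#' Overwrites a window of the sequence with `word`, either at a fixed
#' 0-based offset or at a random position.  With a seed lexicon supplied,
#' random placement rejection-samples (up to 100 tries) positions where
#' the planting would create an unintended seed-core occurrence spanning
#' the planted window's boundary, and positions overlapping `avoid`
#' windows (e.g. previously planted sites).
#'
#' @param sequence A DNA string.
#' @param word The DNA word to plant.
#' @param position 0-based offset, or `"random"`.
#' @param seed Optional RNG seed.
#' @param lexicon Optional [seed_words()] lexicon whose core 6mer must not
#'   gain boundary-spanning occurrences.
#' @param avoid Optional two-column matrix of 0-based half-open windows
#'   that the planted word must not overlap.
#' @return The modified sequence; the attribute `position` records the
#'   0-based offset used.
#' @export
plant_word <- function(sequence, word, position = "random", seed = NULL,
                       lexicon = NULL, avoid = NULL) {
  L <- nchar(sequence)
  w <- nchar(word)
  if (w > L) abort("word is longer than the sequence")
  overwrite <- function(pos0) {
    paste0(substr(sequence, 1, pos0), word,
           substr(sequence, pos0 + w + 1L, L))
  }
  # 0-based starts of every (overlapping) occurrence of `core`
  core_starts <- function(s, core) {
    ns <- nchar(s)
    kc <- nchar(core)
    if (ns < kc) return(integer(0))
    starts <- seq_len(ns - kc + 1L)
    starts[substring(s, starts, starts + kc - 1L) == core] - 1L
  }
  if (!identical(position, "random")) {
    check_scalar_number(position, "position", 0, L - w)
    out <- overwrite(as.integer(position))
    attr(out, "position") <- as.integer(position)
    return(out)
  }
  with_seed_if(seed, {
    for (try in seq_len(100L)) {
      pos0 <- sample.int(L - w + 1L, 1L) - 1L
      if (!is.null(avoid) && nrow(avoid) > 0 &&
          any(pos0 < avoid[, 2] & pos0 + w > avoid[, 1])) next
      cand <- overwrite(pos0)
      if (!is.null(lexicon)) {
        # an occurrence of the seed core is unintended iff it straddles the
        # planted window's boundary; occurrences wholly inside are the
        # plant itself, wholly outside ones existed before
        core <- lexicon$word6
        occ <- core_starts(cand, core)
        straddles <- any((occ < pos0 | occ + nchar(core) > pos0 + w) &
                         (occ + nchar(core) > pos0 & occ < pos0 + w))
        if (straddles) next
      }
      attr(cand, "position") <- pos0
      return(cand)
    }
    abort("plant_word() rejection budget exhausted (100 tries)")
  })
}

# Destroy every occurrence of the seed core in a sequence by rewriting one
# base per occurrence, iterating until clean.
scrub_seed_cores <- function(sequences, lexicon) {
  core <- lexicon$word6
  mid <- 3L  # base within the core to rewrite
  for (pass in seq_len(10L)) {
    dss <- Biostrings::DNAStringSet(sequences)
    hits <- Biostrings::vmatchPattern(core, dss, fixed = TRUE)
    starts <- Biostrings::startIndex(hits)
    dirty <- which(lengths(starts) > 0)
    if (length(dirty) == 0) return(sequences)
    for (i in dirty) {
      for (s in starts[[i]]) {
        at <- s + mid - 1L
        cur <- substr(sequences[i], at, at)
        repl <- sample(setdiff(DNA_BASES, cur), 1L)
        substr(sequences[i], at, at) <- repl
      }
    }
  }
  abort("failed to scrub seed cores after 10 passes")
}

# Per-category plant strings with controlled flanks so the planted site
# classifies as exactly its intended category.
plant_strings <- function(lexicon) {
  m8 <- substr(lexicon$word7m8, 1, 1)
  not_a <- "C"
  not_m8 <- if (m8 == "C") "G" else "C"
  c(site8 = lexicon$word8,
    site7m8 = paste0(lexicon$word7m8, not_a),
    site7a1 = paste0(not_m8, lexicon$word7a1),
    site6 = paste0(not_m8, lexicon$word6, not_a))
}

#' Simulate a miRNA overexpression experiment with ground truth
#'
#' Generates region sequences, plants seed sites into the 3'UTRs of a
#' designated target fraction (effective sites, shifting expression down
#' by per-category effects) and of a background fraction (nonfunctional
#' sites, no effect), simulates replicate-level expression with a global
#' logFC displacement, computes the differential table with
#' [differential_stats()], and optionally plants a transcription-factor
#' motif into regulon promoters with a coordinated shift.  Generated
#' 3'UTRs are first scrubbed of chance seed-core occurrences so the
#' planted sites are exactly the sites present.
#'
#' @param config A [simulation_config()].
#' @param lexicon A [seed_words()] lexicon.
#' @return An object of class `synthetic_experiment`: a list with
#'   `sequences` (tibble with `region` column), `expression`,
#'   `conditions`, `diff`, `truth`, `config`, `lexicon`.
#' @export
simulate_experiment <- function(config, lexicon) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config()")
  }
  if (!inherits(lexicon, "seed_lexicon")) {
    abort("`lexicon` must come from seed_words()")
  }
  plants <- plant_strings(lexicon)
  min_len <- 50L
  with_seed_if(config$seed, {
    n <- config$n_genes
    ids <- sprintf("g%05d", seq_len(n))
    draw_len <- function(model) {
      pmax(as.integer(round(rlnorm(n, model$meanlog, model$sdlog))), min_len)
    }
    utr3 <- cpp_random_dna(draw_len(config$utr3_len),
                           as.numeric(config$composition))
    utr5 <- cpp_random_dna(draw_len(config$utr5_len),
                           as.numeric(config$composition))
    cds <- cpp_random_dna(draw_len(config$cds_len),
                          as.numeric(config$composition))
    prom <- cpp_random_dna(rep(config$promoter_len, n),
                           as.numeric(config$composition))
    if (max(nchar(plants)) > min_len) {
      abort("planted site longer than the minimum UTR length")
    }
    utr3 <- scrub_seed_cores(utr3, lexicon)

    n_targets <- floor(config$target_fraction * n)
    is_target <- logical(n)
    is_target[sample.int(n, n_targets)] <- TRUE

    planted <- matrix(0L, nrow = n, ncol = 4,
                      dimnames = list(NULL, SITE_CATEGORIES))
    background_sites <- integer(n)
    plant_into <- function(seq, cats) {
      occupied <- matrix(numeric(0), ncol = 2)
      for (cat in cats) {
        seq2 <- plant_word(seq, plants[[cat]], lexicon = lexicon,
                           avoid = occupied)
        occupied <- rbind(occupied,
                          c(attr(seq2, "position"),
                            attr(seq2, "position") + nchar(plants[[cat]])))
        seq <- as.character(seq2)
      }
      seq
    }
    for (i in which(is_target)) {
      cats <- SITE_CATEGORIES[runif(4) < config$site_spec[SITE_CATEGORIES]]
      if (length(cats) == 0) cats <- "site7m8"
      utr3[i] <- plant_into(utr3[i], cats)
      planted[i, cats] <- 1L
    }
    bg <- which(!is_target & runif(n) < config$background_prob)
    cat_probs <- config$site_spec[SITE_CATEGORIES] /
      sum(config$site_spec[SITE_CATEGORIES])
    for (i in bg) {
      cat <- sample(SITE_CATEGORIES, 1L, prob = cat_probs)
      utr3[i] <- plant_into(utr3[i], cat)
      background_sites[i] <- 1L
    }

    regulon_member <- logical(n)
    if (!is.null(config$regulon)) {
      rg <- config$regulon
      regulon_member[sample.int(n, floor(rg$member_fraction * n))] <- TRUE
      motif_word <- consensus_sequence(rg$motif)
      p_plant <- ifelse(regulon_member, rg$plant_prob_members,
                        rg$plant_prob_background)
      do_plant <- runif(n) < p_plant
      for (i in which(do_plant)) {
        prom[i] <- as.character(plant_word(prom[i], motif_word))
      }
    }

    true_shift <- as.numeric(planted %*% config$effects[SITE_CATEGORIES])
    if (!is.null(config$regulon)) {
      true_shift <- true_shift +
        config$regulon$regulon_shift * regulon_member
    }

    nt <- config$n_replicates[["treated"]]
    nc <- config$n_replicates[["control"]]
    baseline <- rnorm(n, mean = 7, sd = 1.5)
    treated <- baseline + true_shift + config$global_shift +
      matrix(rnorm(n * nt, sd = config$noise_sd), n, nt)
    control <- baseline + matrix(rnorm(n * nc, sd = config$noise_sd), n, nc)
    sample_ids <- c(sprintf("trt_%d", seq_len(nt)),
                    sprintf("ctl_%d", seq_len(nc)))
    vals <- cbind(treated, control)
    colnames(vals) <- sample_ids
    expression <- dplyr::bind_cols(tibble::tibble(gene_id = ids),
                                   tibble::as_tibble(vals))
    conditions <- stats::setNames(rep(c("treated", "control"), c(nt, nc)),
                                  sample_ids)
    diff <- differential_stats(expression, conditions)

    sequences <- dplyr::bind_rows(
      tibble::tibble(seq_id = ids, region = "utr3", sequence = utr3),
      tibble::tibble(seq_id = ids, region = "utr5", sequence = utr5),
      tibble::tibble(seq_id = ids, region = "cds", sequence = cds),
      tibble::tibble(seq_id = ids, region = "promoter", sequence = prom)
    )
    truth <- tibble::tibble(
      gene_id = ids, is_target = is_target,
      planted8 = planted[, "site8"], planted7m8 = planted[, "site7m8"],
      planted7a1 = planted[, "site7a1"], planted6 = planted[, "site6"],
      background_sites = background_sites,
      regulon_member = regulon_member, true_shift = true_shift
    )
    structure(list(sequences = sequences, expression = expression,
                   conditions = conditions, diff = diff, truth = truth,
                   config = config, lexicon = lexicon),
              class = "synthetic_experiment")
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_experiment> %d genes, %d targets, ",
                     "%d+%d replicates\n"),
              x$config$n_genes, sum(x$truth$is_target),
              x$config$n_replicates[["treated"]],
              x$config$n_replicates[["control"]]))
  invisible(x)
}

#' Export a synthetic experiment to disk
#'
#' Writes one FASTA per region, the differential table and the ground
#' truth as TSV, and a YAML provenance record of the full configuration.
#' All files re-ingest losslessly through [read_fasta()] and
#' [read_diff_table()].
#'
#' @param exp A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_experiment <- function(exp, dir) {
  if (!inherits(exp, "synthetic_experiment")) {
    abort("`exp` must come from simulate_experiment()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rg in unique(exp$sequences$region)) {
    write_fasta(exp$sequences[exp$sequences$region == rg, ],
                file.path(dir, paste0(rg, ".fa")))
  }
  readr::write_tsv(exp$diff, file.path(dir, "diff.tsv"), progress = FALSE)
  readr::write_tsv(exp$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  cfg <- exp$config
  class(cfg) <- NULL
  if (!is.null(cfg$regulon)) {
    cfg$regulon$motif <- list(motif_id = cfg$regulon$motif$motif_id,
                              name = cfg$regulon$motif$name,
                              counts = apply(cfg$regulon$motif$counts, 1,
                                             identity, simplify = FALSE))
  }
  cfg$lexicon <- list(mirna_id = exp$lexicon$mirna_id,
                      mature = exp$lexicon$mature)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
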
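MIR145_MATURE <- "GUCCAGUUUUCCCAGGAAUCCCU"

usage_error <- function(msg) {
  abort(msg, class = "seedwords_usage_error")
}

check_config_keys <- function(config, allowed, required = character(0)) {
  if (!is.list(config)) usage_error("config must be a named list")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    usage_error(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0) {
    usage_error(sprintf("missing required config key(s): %s",
                        paste(missing_keys, collapse = ", ")))
  }
  invisible(config)
}

# Run a command body with pipeline exit-code semantics:
# 0 success, 2 usage error, 1 runtime error.
run_command <- function(expr) {
  tryCatch({
    force(expr)
    invisible(0L)
  },
  seedwords_usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    invisible(2L)
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(1L)
  })
}

write_provenance <- function(path, params, inputs = character(0)) {
  sums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else NULL
  yaml::write_yaml(list(parameters = params, input_md5 = sums,
                        package = "seedwords",
                        version = as.character(utils::packageVersion("seedwords"))),
                   path)
  invisible(path)
}

#' Pipeline command: simulate a synthetic experiment
#'
#' Thin orchestration wrapper around [simulation_config()],
#' [simulate_experiment()] and [export_experiment()].  The output
#' directory receives one FASTA per region, the differential and truth
#' tables, and a YAML provenance record.
#'
#' @param config Named list: `out_dir` (required), `mirna` (mature miRNA,
#'   default the miR-145 sequence), `mirna_id`, `seed`, plus any
#'   [simulation_config()] argument.
#' @return Exit status, invisibly: 0 success, 2 usage error, 1 runtime
#'   error.
#' @export
cmd_simulate <- function(config = list()) {
  run_command({
    sim_keys <- setdiff(names(formals(simulation_config)), "")
    check_config_keys(config, c("out_dir", "mirna", "mirna_id", sim_keys),
                      required = "out_dir")
    lex <- seed_words(config$mirna %||% MIR145_MATURE,
                      config$mirna_id %||% "hsa-miR-145")
    cfg <- do.call(simulation_config,
                   config[intersect(names(config), sim_keys)])
    if (is.null(cfg$seed)) {
      cfg$seed <- 1L
      inform("no seed given; using recorded default seed 1")
    }
    exp <- simulate_experiment(cfg, lex)
    export_experiment(exp, config$out_dir)
    inform(sprintf("simulated %d genes into %s", cfg$n_genes,
                   config$out_dir))
  })
}

read_region_fastas <- function(fasta) {
  if (is.character(fasta)) fasta <- list(utr3 = fasta)
  rows <- purrr::imap(fasta, function(path, rg) {
    if (!rg %in% REGIONS) usage_error(sprintf("unknown region '%s'", rg))
    if (!file.exists(path)) {
      abort(sprintf("missing FASTA for region '%s': %s", rg, path))
    }
    collapse_isoforms(read_fasta(path, rg))
  })
  dplyr::bind_rows(rows)
}

#' Pipeline command: seed-site enrichment
#'
#' Reads region FASTA file(s) and a differential table, partitions genes
#' with [assign_sets()], runs [seed_enrichment()] (or [region_sweep()]
#' when several regions are given) and writes the result TSV plus a
#' provenance record.
#'
#' @param config Named list: `fasta` (path, or named list region = path;
#'   required), `diff` (TSV path, required), `out` (required), `mirna`,
#'   `mirna_id`, `metric`, `seed`, `fdr_regulated`, `fdr_nochange`,
#'   `regions`.
#' @return Exit status, invisibly.
#' @export
cmd_seedscan <- function(config = list()) {
  run_command({
    check_config_keys(config, c("fasta", "diff", "out", "mirna", "mirna_id",
                                "metric", "seed", "fdr_regulated",
                                "fdr_nochange", "regions"),
                      required = c("fasta", "diff", "out"))
    lex <- seed_words(config$mirna %||% MIR145_MATURE,
                      config$mirna_id %||% "hsa-miR-145")
    seqs <- read_region_fastas(config$fasta)
    diff <- read_diff_table(config$diff)
    sets <- assign_sets(diff,
                        fdr_regulated = config$fdr_regulated %||% 0.25,
                        fdr_nochange = config$fdr_nochange %||% 0.8)
    inform(sprintf("sets: %s", paste(names(table(sets$set)),
                                     table(sets$set), collapse = ", ")))
    metric <- config$metric %||% "percent_of_genes"
    seed <- config$seed
    if (metric == "downscaled_counts" && is.null(seed)) {
      warn("downscaled metric without a seed; using recorded default seed 1")
      seed <- 1L
    }
    regions <- config$regions %||% unique(seqs$region)
    res <- if (length(regions) > 1) {
      region_sweep(sets, seqs, lex, regions = regions)
    } else {
      seed_enrichment(sets, seqs[seqs$region == regions, ], lex,
                      metric = metric, seed = seed)
    }
    write_enrichment_table(res, config$out)
    write_provenance(paste0(config$out, ".provenance.yaml"),
                     list(command = "seedscan", metric = metric,
                          seed = seed, regions = regions,
                          mirna_id = lex$mirna_id),
                     c(unlist(config$fasta), config$diff))
  })
}

#' Pipeline command: unbiased word analysis
#'
#' Reads a 3'UTR FASTA and a differential table, ranks sequences by
#' ascending logFC and runs [word_analysis()]; optionally writes
#' running-sum profiles for selected words.
#'
#' @param config Named list: `fasta`, `diff`, `out` (required); `k`
#'   (default 7), `B` (default 5000), `P` (default 100), `top` (rows to
#'   write; default all), `seed`, `mirna`, `mirna_id`, `profile_words`
#'   (character vector), `profile_out` (directory for profile TSVs).
#' @return Exit status, invisibly.
#' @export
cmd_wordscan <- function(config = list()) {
  run_command({
    check_config_keys(config, c("fasta", "diff", "out", "k", "B", "P",
                                "top", "seed", "mirna", "mirna_id",
                                "profile_words", "profile_out"),
                      required = c("fasta", "diff", "out"))
    lex <- seed_words(config$mirna %||% MIR145_MATURE,
                      config$mirna_id %||% "hsa-miR-145")
    k <- config$k %||% 7L
    if (k < 4 || k > 8) usage_error("k must be between 4 and 8")
    seqs <- collapse_isoforms(read_fasta(config$fasta, "utr3"))
    diff <- read_diff_table(config$diff)
    seqs <- dplyr::inner_join(seqs, diff[, c("gene_id", "logFC")],
                              by = c(seq_id = "gene_id"))
    inform(sprintf("%d sequences with logFC ranking", nrow(seqs)))
    seed <- config$seed %||% 1L
    wsm <- with_seed_if(seed, word_score_matrix(seqs, k = k,
                                                B = config$B %||% 5000L))
    res <- word_analysis(wsm, P = config$P %||% 100L, seed = seed + 1L,
                         lexicon = lex)
    out_tbl <- if (!is.null(config$top)) head(res, config$top) else res
    attributes(out_tbl)[c("k", "B", "P", "seed")] <-
      attributes(res)[c("k", "B", "P", "seed")]
    write_enrichment_table(out_tbl, config$out)
    for (wd in config$profile_words %||% character(0)) {
      prof <- word_profile(wsm, wd)
      dir.create(config$profile_out %||% dirname(config$out),
                 showWarnings = FALSE, recursive = TRUE)
      readr::write_tsv(prof, file.path(config$profile_out %||%
                                         dirname(config$out),
                                       paste0("profile_", wd, ".tsv")),
                       progress = FALSE)
    }
    write_provenance(paste0(config$out, ".provenance.yaml"),
                     list(command = "wordscan", k = k,
                          B = config$B %||% 5000L, P = config$P %||% 100L,
                          seed = seed, mirna_id = lex$mirna_id),
                     c(config$fasta, config$diff))
  })
}

#' Pipeline command: promoter TFBS enrichment
#'
#' Reads promoter FASTA, a differential table and a JASPAR matrix file,
#' and writes a motif enrichment table; optionally repeats the analysis
#' with column-shuffled control matrices.
#'
#' @param config Named list: `fasta` (promoters), `diff`, `jaspar`, `out`
#'   (required); `threshold` (default 0.8), `strands` (default "both"),
#'   `shuffle_control` (number of shuffled-control replicates per motif),
#'   `control_out`, `seed`, `fdr_regulated`, `fdr_nochange`.
#' @return Exit status, invisibly.
#' @export
cmd_tfbs <- function(config = list()) {
  run_command({
    check_config_keys(config, c("fasta", "diff", "jaspar", "out",
                                "threshold", "strands", "shuffle_control",
                                "control_out", "seed", "fdr_regulated",
                                "fdr_nochange"),
                      required = c("fasta", "diff", "jaspar", "out"))
    cms <- read_jaspar(config$jaspar)
    if (length(cms) == 0) abort("empty JASPAR file")
    proms <- collapse_isoforms(read_fasta(config$fasta, "promoter"))
    diff <- read_diff_table(config$diff)
    sets <- assign_sets(diff,
                        fdr_regulated = config$fdr_regulated %||% 0.25,
                        fdr_nochange = config$fdr_nochange %||% 0.8)
    threshold <- config$threshold %||% 0.8
    strands <- config$strands %||% "both"
    pssms <- purrr::map(cms, build_pssm)
    res <- promoter_enrichment(sets, proms, pssms, threshold = threshold,
                               strands = strands)
    res <- dplyr::arrange(res, .data$p_dn_vs_nc)
    write_enrichment_table(res, config$out)
    n_ctrl <- config$shuffle_control %||% 0L
    if (n_ctrl > 0) {
      seed <- config$seed %||% 1L
      ctrl <- purrr::map(seq_len(n_ctrl), function(r) {
        shuffled <- purrr::map(cms, shuffle_matrix, seed = seed + r)
        out <- promoter_enrichment(sets, proms,
                                   purrr::map(shuffled, build_pssm),
                                   threshold = threshold, strands = strands)
        dplyr::mutate(out, control_rep = r, control_seed = seed + r)
      })
      ctrl_tbl <- dplyr::bind_rows(ctrl)
      attr(ctrl_tbl, "threshold") <- threshold
      attr(ctrl_tbl, "strands") <- strands
      write_enrichment_table(ctrl_tbl,
                             config$control_out %||%
                               paste0(config$out, ".control.tsv"))
    }
    write_provenance(paste0(config$out, ".provenance.yaml"),
                     list(command = "tfbs", threshold = threshold,
                          strands = strands, shuffle_control = n_ctrl,
                          seed = config$seed),
                     c(config$fasta, config$diff, config$jaspar))
  })
}
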
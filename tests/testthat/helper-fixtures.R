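# Shared synthetic fixtures built in code at test time.

# Three regulation sets with per-set 7mer-m8 prevalence planted into
# otherwise core-free random sequences.
make_prevalence_fixture <- function(n_per_set, prev, lens = 400) {
  withr::local_seed(31, .local_envir = parent.frame())
  sets <- make_sets(sprintf("u%d", seq_len(n_per_set[1])),
                    sprintf("d%d", seq_len(n_per_set[2])),
                    sprintf("n%d", seq_len(n_per_set[3])))
  seqs <- oracle_random_dna(nrow(sets), lens, probs = c(0.4, 0.2, 0.1, 0.3))
  seqs <- gsub("ACTGGA", "ACTGCA", seqs, fixed = TRUE)
  prev_of <- prev[as.character(sets$set)]
  for (i in seq_len(nrow(sets))) {
    if (runif(1) < prev_of[i]) {
      pos <- sample(nchar(seqs[i]) - 8, 1)
      substr(seqs[i], pos, pos + 7) <- "AACTGGAC"  # 7mer-m8 site
    }
  }
  list(sets = sets, seqs = tibble::tibble(seq_id = sets$gene_id,
                                          sequence = seqs))
}

# logFC-ranked sequence list with a word planted at high prevalence among
# the most down-regulated entries.
plant_ranked_fixture <- function(n, len, word, top_n, prev_top, prev_bg,
                                 seed) {
  withr::local_seed(seed, .local_envir = parent.frame())
  seqs <- oracle_random_dna(n, len)
  seqs <- gsub(substr(word, 2, 7), "ACGCAT", seqs, fixed = TRUE)
  prev <- c(rep(prev_top, top_n), rep(prev_bg, n - top_n))
  for (i in seq_len(n)) {
    if (runif(1) < prev[i]) {
      pos <- sample(len - nchar(word), 1)
      substr(seqs[i], pos, pos + nchar(word) - 1) <- word
    }
  }
  tibble::tibble(seq_id = sprintf("s%04d", seq_len(n)), sequence = seqs,
                 logFC = seq(-3, 3, length.out = n))
}

# Promoter sets with a motif consensus planted at per-set probabilities
# into random promoters (genome-like AT-rich composition by default).
make_promoter_fixture <- function(n_per_set, plant_down, plant_nc, motif,
                                  len = 600,
                                  composition = c(0.295, 0.205, 0.205,
                                                  0.295)) {
  sets <- make_sets(sprintf("u%d", seq_len(n_per_set)),
                    sprintf("d%d", seq_len(n_per_set)),
                    sprintf("n%d", seq_len(n_per_set)))
  word <- consensus_sequence(motif)
  seqs <- oracle_random_dna(nrow(sets), len, probs = composition)
  plant_p <- c(up = plant_nc, down = plant_down, no_change = plant_nc)
  pp <- plant_p[as.character(sets$set)]
  for (i in seq_len(nrow(sets))) {
    if (runif(1) < pp[i]) {
      pos <- sample(len - nchar(word), 1)
      substr(seqs[i], pos, pos + nchar(word) - 1) <- word
    }
  }
  list(sets = sets,
       proms = tibble::tibble(seq_id = sets$gene_id, sequence = seqs))
}

shipped_motif <- function(id) {
  read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                          package = "seedwords"))[[id]]
}

synthetic_gc_motif <- function() shipped_motif("SYN_GCRICH")
synthetic_mixed_motif <- function() shipped_motif("SYN_MIXED")
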
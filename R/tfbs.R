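#' Build a position-specific scoring matrix from counts
#'
#' Converts a motif count matrix into log2-ratio weights with Laplace
#' smoothing: for column j with total n_j,
#' `weight(b, j) = log2(((count(b, j) + pseudocount) / (n_j + 4 * pseudocount)) / background(b))`.
#' The minimum and maximum achievable window scores are precomputed for
#' relative-score thresholding.
#'
#' @param cm A [count_matrix()].
#' @param background Background nucleotide frequency: a single value
#'   (default 0.25) or a length-4 vector for A,C,G,T.  Must lie strictly
#'   between 0 and 1.
#' @param pseudocount Per-cell pseudocount (default 1).
#' @return An object of class `pssm` with elements `motif_id`, `name`,
#'   `weights` (4 x L), `s_min`, `s_max`.
#' @export
build_pssm <- function(cm, background = 0.25, pseudocount = 1) {
  if (!inherits(cm, "count_matrix")) abort("`cm` must be a count_matrix")
  if (length(background) == 1) background <- rep(background, 4)
  if (length(background) != 4 || any(background <= 0) ||
      any(background >= 1)) {
    abort("`background` frequencies must lie strictly between 0 and 1")
  }
  counts <- cm$counts
  totals <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2, totals + 4 * pseudocount, "/")
  weights <- log2(freq / background)
  rownames(weights) <- DNA_BASES
  structure(list(motif_id = cm$motif_id, name = cm$name, weights = weights,
                 s_min = sum(apply(weights, 2, min)),
                 s_max = sum(apply(weights, 2, max))),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s (%s), %d positions, score range [%.3f, %.3f]\n",
              x$motif_id, x$name, ncol(x$weights), x$s_min, x$s_max))
  invisible(x)
}

#' Scan sequences for motif hits
#'
#' Scores every window of motif length on the requested strand(s) and
#' returns hits whose relative score,
#' `(score - s_min) / (s_max - s_min)`, reaches the threshold.  Windows
#' containing `N` are skipped.  Minus-strand hits are scored with the
#' reverse-complemented matrix and reported in the input sequence's
#' coordinate frame, as 0-based half-open intervals.
#'
#' @param seqs Sequence table (`seq_id`, `sequence`).
#' @param pssm A [build_pssm()] object.
#' @param threshold Relative-score cutoff in \[0, 1\] (default 0.8).
#' @param strands `"both"` (default) or `"plus"`.
#' @return A tibble of hits: `seq_id`, `start`, `end`, `motif_id`,
#'   `strand`, `abs_score`, `rel_score`, in coordinate order per sequence.
#' @export
scan_pssm <- function(seqs, pssm, threshold = 0.8,
                      strands = c("both", "plus")) {
  strands <- match.arg(strands)
  check_seq_tbl(seqs)
  if (!inherits(pssm, "pssm")) abort("`pssm` must come from build_pssm()")
  check_scalar_number(threshold, "threshold", 0, 1)
  L <- ncol(pssm$weights)
  hits <- purrr::map(seq_len(nrow(seqs)), function(i) {
    df <- cpp_scan_pssm(normalize_sequence(seqs$sequence[i]), pssm$weights,
                        threshold, strands == "both")
    tibble::tibble(seq_id = rep(seqs$seq_id[i], nrow(df)),
                   start = df$start, end = df$start + L,
                   motif_id = rep(pssm$motif_id, nrow(df)),
                   strand = df$strand, abs_score = df$abs_score,
                   rel_score = df$rel_score)
  })
  dplyr::bind_rows(hits)
}

#' Transcription-factor binding-site enrichment in promoters
#'
#' For each motif, scans the promoters of the down-, up- and no-change
#' gene sets, records the percentage of promoters in each set with at
#' least one hit (presence/absence; overlapping hits collapse), and tests
#' the down and up sets against the no-change background with
#' [two_proportion_test()].
#'
#' @param sets A `regulation_sets` table (or data frame with `gene_id`,
#'   `set`).
#' @param promoters Sequence table of promoter sequences keyed by gene id
#'   (genes without a promoter are dropped with a message).
#' @param pssms A list of [build_pssm()] objects (or a single one).
#' @param threshold Relative-score cutoff (default 0.8).
#' @param strands `"both"` (default) or `"plus"`.
#' @return A `tfbs_enrichment` tibble with one row per motif:
#'   `motif_id`, `percent_down`, `percent_up`, `percent_nochange`,
#'   `p_dn_vs_nc`, `p_up_vs_nc`.
#' @export
promoter_enrichment <- function(sets, promoters, pssms, threshold = 0.8,
                                strands = c("both", "plus")) {
  strands <- match.arg(strands)
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  if (length(pssms) == 0) abort("no PSSMs supplied")
  if (!all(c("gene_id", "set") %in% names(sets))) {
    abort("`sets` needs columns gene_id and set")
  }
  members <- dplyr::filter(sets, .data$set %in% c("up", "down", "no_change"))
  sizes <- table(factor(members$set, levels = c("up", "down", "no_change")))
  if (any(sizes == 0)) {
    abort(sprintf("empty regulation set(s): %s",
                  paste(names(sizes)[sizes == 0], collapse = ", ")))
  }
  have_seq <- members$gene_id %in% promoters$seq_id
  if (any(!have_seq)) {
    inform(sprintf("dropping %d gene(s) without a promoter sequence",
                   sum(!have_seq)))
    members <- members[have_seq, , drop = FALSE]
  }
  proms <- promoters[match(members$gene_id, promoters$seq_id), , drop = FALSE]
  set_of <- as.character(members$set)
  n_dn <- sum(set_of == "down")
  n_up <- sum(set_of == "up")
  n_nc <- sum(set_of == "no_change")

  rows <- purrr::map(pssms, function(pssm) {
    hits <- scan_pssm(proms, pssm, threshold = threshold, strands = strands)
    with_hit <- proms$seq_id %in% hits$seq_id
    k_dn <- sum(with_hit[set_of == "down"])
    k_up <- sum(with_hit[set_of == "up"])
    k_nc <- sum(with_hit[set_of == "no_change"])
    tibble::tibble(
      motif_id = pssm$motif_id,
      percent_down = 100 * k_dn / n_dn,
      percent_up = 100 * k_up / n_up,
      percent_nochange = 100 * k_nc / n_nc,
      p_dn_vs_nc = two_proportion_test(k_dn, n_dn, k_nc, n_nc),
      p_up_vs_nc = two_proportion_test(k_up, n_up, k_nc, n_nc)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "strands") <- strands
  attr(out, "set_sizes") <- c(down = n_dn, up = n_up, no_change = n_nc)
  class(out) <- c("tfbs_enrichment", class(out))
  out
}

#' Column-shuffled control matrix
#'
#' Produces a negative-control motif by permuting the columns of a count
#' matrix uniformly at random, guaranteed different from the identity
#' permutation; when the matrix has duplicated columns, permutations that
#' happen to reproduce the original matrix are also resampled (up to 100
#' tries) so the control genuinely differs.  Column contents (hence total
#' information content) are preserved.
#'
#' @param cm A [count_matrix()] with at least 2 columns.
#' @param seed Optional RNG seed.
#' @return A [count_matrix()] with permuted columns and motif id suffixed
#'   `"_shuffled"`.
#' @export
shuffle_matrix <- function(cm, seed = NULL) {
  if (!inherits(cm, "count_matrix")) abort("`cm` must be a count_matrix")
  L <- ncol(cm$counts)
  if (L < 2) abort("matrix must have at least 2 columns to shuffle")
  perm <- with_seed_if(seed, {
    p <- sample.int(L)
    tries <- 0L
    while ((all(p == seq_len(L)) ||
            identical(cm$counts[, p, drop = FALSE], cm$counts)) &&
           tries < 100L) {
      p <- sample.int(L)
      tries <- tries + 1L
    }
    if (all(p == seq_len(L))) p <- rev(seq_len(L))
    p
  })
  count_matrix(paste0(cm$motif_id, "_shuffled"), cm$name,
               cm$counts[, perm, drop = FALSE])
}
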
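#' Mononucleotide shuffle of a sequence
#'
#' Returns a uniform random permutation (Fisher-Yates) of the sequence's
#' characters, preserving single-nucleotide composition.  `N` characters
#' are permuted along with the rest.
#'
#' @param sequence A DNA string.
#' @param seed Optional RNG seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return The shuffled string.
#' @export
mononucleotide_shuffle <- function(sequence, seed = NULL) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  with_seed_if(seed, paste(sample(chars), collapse = ""))
}

#' Shuffle-null tail counts for the words of one sequence
#'
#' For every k-mer observed in the sequence (overlapping occurrences;
#' windows containing `N` never match), estimates the null tail
#' N(m) = number of mononucleotide shuffles in which the word occurred at
#' least as often as observed.  Words absent from the sequence score zero
#' by convention and are not materialized.
#'
#' @param sequence A DNA string.
#' @param k Word length.
#' @param B Number of shuffles (default 5000).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `word`, `m_obs`, `tail`; `B` is stored as
#'   an attribute.  Empty when the sequence is shorter than `k`.
#' @export
null_tails <- function(sequence, k, B = 5000L, seed = NULL) {
  check_scalar_number(k, "k", 1, 15)
  check_scalar_number(B, "B", 1)
  res <- with_seed_if(seed, cpp_shuffle_tails(normalize_sequence(sequence),
                                              as.integer(k), as.integer(B)))
  out <- tibble::tibble(
    word = if (length(res$word_index)) decode_kmer(res$word_index, k)
           else character(0),
    m_obs = res$m_obs, tail = res$tail
  )
  attr(out, "B") <- as.integer(B)
  out
}

#' Word overrepresentation score
#'
#' Converts a shuffle-null tail count into a non-negative log-odds score,
#' `-log10((N(m) + 1) / (B + 1))`.  The +1 corrects crudely for sampling
#' uncertainty and avoids `log(0)`.  A word that occurs no more often than
#' in every shuffle (N(m) = B), and in particular any absent word, scores
#' zero.
#'
#' @param tail Tail count(s) N(m).
#' @param B Number of shuffles.
#' @return Score(s) in `[0, log10(B + 1)]`.
#' @export
overrep_score <- function(tail, B) {
  if (any(tail < 0) || any(tail > B)) abort("tail counts must lie in [0, B]")
  -log10((tail + 1) / (B + 1))
}

#' Running sum of overrepresentation scores along a ranked list
#'
#' Centers the per-sequence scores of one word by their mean and
#' accumulates them along the ranked list (most down-regulated sequence
#' first).  The word's enrichment statistic is the maximum of the running
#' sum; enrichment near the top of the ranking produces an early peak.
#'
#' @param scores Numeric vector of per-sequence scores in ranked order
#'   (length at least 2).
#' @return A `running_sum_profile` tibble with columns `index` and `S`;
#'   the maximum, `max(S)`, is stored in the `statistic` attribute.
#' @export
running_sum <- function(scores) {
  if (length(scores) < 2) abort("running_sum() needs at least 2 sequences")
  s <- cumsum(scores - mean(scores))
  out <- tibble::tibble(index = seq_along(s), S = s)
  # S_n = 0 in exact arithmetic, so the maximum is non-negative; clamp
  # away summation noise
  attr(out, "statistic") <- max(s, 0)
  class(out) <- c("running_sum_profile", class(out))
  out
}

#' Per-sequence, per-word overrepresentation score matrix
#'
#' Builds the score matrix underlying [word_analysis()]: for each sequence
#' in ranked order and every k-mer, the shuffle-null overrepresentation
#' score.  Duplicate sequences share one null estimation, so scores depend
#' only on sequence content and the seed, not on labels.
#'
#' @param seqs Sequence table; if a `logFC` column is present the rows are
#'   ranked by ascending logFC (most down-regulated first), otherwise the
#'   given order is taken as the ranking.
#' @param k Word length.
#' @param B Shuffles per sequence (default 5000).
#' @param seed Optional RNG seed.
#' @return An object of class `word_score_matrix`: a list with the
#'   `scores` matrix (sequences x 4^k words), `seq_ids`, `k`, `B`, `seed`.
#' @export
word_score_matrix <- function(seqs, k, B = 5000L, seed = NULL) {
  check_seq_tbl(seqs)
  check_scalar_number(k, "k", 1, 15)
  if ("logFC" %in% names(seqs)) {
    seqs <- dplyr::arrange(seqs, .data$logFC)
  }
  sequences <- normalize_sequence(seqs$sequence)
  n <- length(sequences)
  W <- as.integer(4^k)
  scores <- matrix(0, nrow = n, ncol = W)
  with_seed_if(seed, {
    uniq <- unique(sequences)
    cache_idx <- match(sequences, uniq)
    for (u in seq_along(uniq)) {
      res <- cpp_shuffle_tails(uniq[u], as.integer(k), as.integer(B))
      if (length(res$word_index) > 0) {
        sc <- overrep_score(res$tail, B)
        for (i in which(cache_idx == u)) {
          scores[i, res$word_index + 1L] <- sc
        }
      }
    }
  })
  structure(list(scores = scores, seq_ids = seqs$seq_id, k = as.integer(k),
                 B = as.integer(B), seed = seed),
            class = "word_score_matrix")
}

#' @export
print.word_score_matrix <- function(x, ...) {
  cat(sprintf("<word_score_matrix> %d sequences x %d words (k=%d, B=%d)\n",
              nrow(x$scores), ncol(x$scores), x$k, x$B))
  invisible(x)
}

#' Extract a word's running-sum profile
#'
#' @param wsm A [word_score_matrix()].
#' @param word A k-mer (DNA).
#' @return A [running_sum()] profile for that word.
#' @export
word_profile <- function(wsm, word) {
  if (!inherits(wsm, "word_score_matrix")) {
    abort("`wsm` must be a word_score_matrix")
  }
  word <- normalize_sequence(word)
  if (nchar(word) != wsm$k) abort(sprintf("word must have length k = %d",
                                          wsm$k))
  prof <- running_sum(wsm$scores[, encode_kmer(word) + 1L])
  attr(prof, "word") <- word
  prof
}

#' Unbiased word enrichment over a ranked sequence list
#'
#' Scores every k-mer for overrepresentation in each sequence against a
#' mononucleotide-shuffle null, accumulates a running sum of the
#' (mean-centered) scores along the logFC-ranked sequence list, and
#' standardizes each word's maximum running sum against `P` random
#' permutations of the ranking.  False discovery rates come from the
#' pooled permutation null: the fraction of all permutation z-values at or
#' above a word's z, divided by the fraction of observed z-values at or
#' above it, clipped to \[0, 1\] and made monotone in z.  Words matching
#' the supplied seed lexicon completely, or sharing at least 5 consecutive
#' bases with the 8mer seed word, are annotated.
#'
#' @param seqs A sequence table (ranked by ascending `logFC` if that
#'   column is present), or a prebuilt [word_score_matrix()].
#' @param k Word length (guarded to 4-8 by default; see `k_range`).
#' @param B Shuffles per sequence (default 5000).
#' @param P Number of ranked-list permutations (at least 2; at least 20
#'   recommended for usable FDR resolution).
#' @param seed Optional RNG seed; fixing it makes the whole table
#'   reproducible.
#' @param lexicon Optional [seed_words()] lexicon for annotation.
#' @param k_range Allowed word-length range (resource guard).
#' @return A `word_enrichment` tibble sorted by descending z-score with
#'   columns `rank`, `word`, `statistic`, `z_score`, `fdr`, `annotation`.
#'   `k`, `B`, `P` and `seed` are stored as attributes.
#' @export
word_analysis <- function(seqs, k = NULL, B = 5000L, P = 100L, seed = NULL,
                          lexicon = NULL, k_range = c(4L, 8L)) {
  if (P < 2) abort("P must be at least 2 ranked-list permutations")
  if (P < 20) inform("P < 20 gives coarse FDR resolution")
  prebuilt <- inherits(seqs, "word_score_matrix")
  if (prebuilt) {
    k <- seqs$k
  } else {
    if (is.null(k)) abort("`k` must be given when `seqs` is a sequence table")
    check_scalar_number(k, "k", 1, 15)
  }
  if (k < k_range[1] || k > k_range[2]) {
    abort(sprintf("k = %d outside the allowed range [%d, %d]", k,
                  k_range[1], k_range[2]))
  }
  # one seeded stream covers both the per-sequence shuffles and the
  # ranked-list permutations, so a single seed reproduces the whole table
  built <- with_seed_if(seed, {
    wsm <- if (prebuilt) seqs else word_score_matrix(seqs, k = k, B = B)
    n <- nrow(wsm$scores)
    if (n < 2) abort("word_analysis() needs at least 2 sequences")
    list(wsm = wsm,
         orders = cbind(seq_len(n), replicate(P, sample.int(n))))
  })
  wsm <- built$wsm
  orders <- built$orders
  W <- ncol(wsm$scores)
  stats <- cpp_max_running_sums(wsm$scores, orders)
  obs <- stats[1, ]
  perm <- stats[-1, , drop = FALSE]
  mu <- colMeans(perm)
  sdev <- sqrt(pmax(colMeans(perm^2) - mu^2, 0) * P / (P - 1))
  z <- ifelse(sdev > 0, (obs - mu) / sdev, 0)
  zperm <- sweep(perm, 2, mu)
  zperm <- sweep(zperm, 2, ifelse(sdev > 0, sdev, 1), FUN = "/")
  zperm[, sdev == 0] <- 0

  sorted_perm <- sort(as.numeric(zperm))
  sorted_obs <- sort(z)
  n_perm_ge <- length(sorted_perm) -
    findInterval(z, sorted_perm, left.open = TRUE)
  n_obs_ge <- length(sorted_obs) - findInterval(z, sorted_obs,
                                                left.open = TRUE)
  fdr_raw <- pmin((n_perm_ge / length(sorted_perm)) / (n_obs_ge / W), 1)

  ord <- order(z, decreasing = TRUE)
  fdr <- numeric(W)
  fdr[ord] <- cummax(fdr_raw[ord])  # monotone non-increasing in z

  words <- all_kmers(k)
  annotation <- annotate_words(words, lexicon)
  out <- tibble::tibble(rank = seq_len(W), word = words[ord],
                        statistic = obs[ord], z_score = z[ord],
                        fdr = fdr[ord], annotation = annotation[ord])
  attr(out, "k") <- k
  attr(out, "B") <- wsm$B
  attr(out, "P") <- as.integer(P)
  attr(out, "seed") <- seed
  class(out) <- c("word_enrichment", class(out))
  out
}

# Annotate words against a seed lexicon: exact category matches, or a
# shared substring of >= 5 nt with the 8mer seed word (partial match).
annotate_words <- function(words, lexicon) {
  ann <- rep("", length(words))
  if (is.null(lexicon)) return(ann)
  exact <- c(stats::setNames("8mer", lexicon$word8),
             stats::setNames("7mer-m8", lexicon$word7m8),
             stats::setNames("7mer-1A", lexicon$word7a1),
             stats::setNames("6mer", lexicon$word6))
  hit <- match(words, names(exact))
  ann[!is.na(hit)] <- paste(lexicon$mirna_id, exact[hit[!is.na(hit)]])
  w8 <- lexicon$word8
  subs <- unique(unlist(lapply(5:nchar(w8), function(len) {
    substring(w8, seq_len(nchar(w8) - len + 1L),
              seq_len(nchar(w8) - len + 1L) + len - 1L)
  })))
  partial <- Reduce(`|`, lapply(subs, function(s) {
    grepl(s, words, fixed = TRUE)
  }))
  ann[partial & ann == ""] <- paste(lexicon$mirna_id, "partial")
  ann
}
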
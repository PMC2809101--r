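# Independent oracles used across the suite.  Everything here is written
# with plain base R (no package internals) so implementation and oracle
# never share a code path.

mir145 <- seed_words("GUCCAGUUUUCCCAGGAAUCCCU", "hsa-miR-145")

# Overlapping substring count by direct window comparison.
oracle_count_word <- function(seq, word) {
  L <- nchar(seq)
  k <- nchar(word)
  if (L < k) return(0L)
  starts <- seq_len(L - k + 1L)
  sum(substring(seq, starts, starts + k - 1L) == word)
}

# Hierarchical seed classification by containment-exclusion: raw counts of
# the four words combined with inclusion-exclusion, so longer sites are
# never double-counted as shorter ones.
oracle_seed_counts <- function(seq, lex) {
  r8 <- oracle_count_word(seq, lex$word8)
  r7m8 <- oracle_count_word(seq, lex$word7m8)
  r7a1 <- oracle_count_word(seq, lex$word7a1)
  r6 <- oracle_count_word(seq, lex$word6)
  c(n8 = r8, n7m8 = r7m8 - r8, n7a1 = r7a1 - r8,
    n6 = r6 - r7m8 - r7a1 + r8)
}

# Per-window classifier returning 0-based site positions per category.
oracle_seed_positions <- function(seq, lex) {
  k <- nchar(lex$word6)
  L <- nchar(seq)
  out <- list(site8 = integer(0), site7m8 = integer(0),
              site7a1 = integer(0), site6 = integer(0))
  if (L < k) return(out)
  m8 <- substr(lex$word7m8, 1, 1)
  starts <- seq_len(L - k + 1L)
  core_hits <- starts[substring(seq, starts, starts + k - 1L) == lex$word6]
  for (s in core_hits) {
    pre <- if (s > 1) substring(seq, s - 1L, s - 1L) else ""
    post <- if (s + k <= L) substring(seq, s + k, s + k) else ""
    if (pre == m8 && post == "A") {
      out$site8 <- c(out$site8, s - 2L)
    } else if (pre == m8) {
      out$site7m8 <- c(out$site7m8, s - 2L)
    } else if (post == "A") {
      out$site7a1 <- c(out$site7a1, s - 1L)
    } else {
      out$site6 <- c(out$site6, s - 1L)
    }
  }
  out
}

oracle_random_dna <- function(n, lens, probs = rep(0.25, 4)) {
  vapply(rep_len(lens, n), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

# All distinct arrangements of a character multiset (each equally likely
# under a uniform permutation).
enumerate_arrangements <- function(chars) {
  recurse <- function(remaining) {
    if (length(remaining) == 0) return(list(character(0)))
    out <- list()
    for (b in unique(remaining)) {
      rest <- remaining[-match(b, remaining)]
      for (tail in recurse(rest)) out <- c(out, list(c(b, tail)))
    }
    out
  }
  vapply(recurse(chars), paste, character(1), collapse = "")
}

# Brute-force PSSM window scorer (both strands, input-frame coordinates).
oracle_scan_pssm <- function(seq, weights, threshold, both = TRUE) {
  L <- ncol(weights)
  n <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  smin <- sum(apply(weights, 2, min))
  smax <- sum(apply(weights, 2, max))
  hits <- data.frame(start = integer(0), strand = character(0),
                     abs_score = numeric(0), rel_score = numeric(0))
  if (n < L) return(hits)
  for (i in seq_len(n - L + 1L)) {
    win <- strsplit(substring(seq, i, i + L - 1L), "")[[1]]
    if (any(!win %in% names(comp))) next
    fwd <- sum(weights[cbind(match(win, rownames(weights)), seq_len(L))])
    rel <- if (smax > smin) (fwd - smin) / (smax - smin) else 1
    if (rel >= threshold) {
      hits <- rbind(hits, data.frame(start = i - 1L, strand = "+",
                                     abs_score = fwd, rel_score = rel))
    }
    if (both) {
      rcwin <- rev(comp[win])
      rc <- sum(weights[cbind(match(rcwin, rownames(weights)), seq_len(L))])
      rel <- if (smax > smin) (rc - smin) / (smax - smin) else 1
      if (rel >= threshold) {
        hits <- rbind(hits, data.frame(start = i - 1L, strand = "-",
                                       abs_score = rc, rel_score = rel))
      }
    }
  }
  hits
}

oracle_chisq_prop <- function(k1, n1, k2, n2) {
  suppressWarnings(stats::chisq.test(
    matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE),
    correct = FALSE
  )$p.value)
}

# Small random count matrix with a unique consensus per column.
random_count_matrix <- function(id = "M_RAND", L = 8, total = 20) {
  counts <- sapply(seq_len(L), function(j) {
    top <- sample(4, 1)
    v <- rep(1, 4)
    v[top] <- total - 3
    v
  })
  count_matrix(id, id, counts)
}

# Regulation sets by direct construction (no assign_sets involvement).
make_sets <- function(up, down, nochange) {
  tibble::tibble(
    gene_id = c(up, down, nochange),
    set = rep(c("up", "down", "no_change"),
              c(length(up), length(down), length(nochange)))
  )
}
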
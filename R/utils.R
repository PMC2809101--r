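DNA_BASES <- c("A", "C", "G", "T")
REGIONS <- c("utr3", "utr5", "cds", "cdna", "promoter")

# Uppercase, RNA -> DNA.  All internal matching is on the DNA alphabet.
normalize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T,N} (first offender: %s)",
      what, x[which(bad)[1]]
    ))
  }
  invisible(x)
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# k-mer <-> integer index (A=0, C=1, G=2, T=3; big-endian), matching the
# encoding used by the compiled counting routines.
decode_kmer <- function(idx, k) {
  out <- character(length(idx))
  rem <- as.integer(idx)
  chars <- matrix("", nrow = length(idx), ncol = k)
  for (j in seq(k, 1L)) {
    chars[, j] <- DNA_BASES[rem %% 4L + 1L]
    rem <- rem %/% 4L
  }
  apply(chars, 1L, paste, collapse = "")
}

encode_kmer <- function(words) {
  k <- nchar(words[1])
  m <- vapply(strsplit(words, "", fixed = TRUE), function(ch) {
    sum((match(ch, DNA_BASES) - 1L) * 4^(rev(seq_len(k)) - 1L))
  }, numeric(1))
  as.integer(m)
}

all_kmers <- function(k) {
  decode_kmer(seq_len(4^k) - 1L, k)
}

# Validate a sequence table (tibble with seq_id / sequence, optional region).
check_seq_tbl <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs)) {
    abort(sprintf("`%s` must be a data frame of sequences", arg))
  }
  missing_cols <- setdiff(c("seq_id", "sequence"), names(seqs))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  invisible(seqs)
}

as_dna_stringset <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs$sequence)
  names(x) <- seqs$seq_id
  x
}

# Run `expr` under a fixed seed when one is supplied, leaving the caller's
# RNG state untouched; otherwise use (and advance) the current RNG.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}
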
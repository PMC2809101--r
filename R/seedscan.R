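#' Derive canonical seed-match words from a mature miRNA
#'
#' Builds the four target-strand DNA words complementary to a miRNA's seed
#' region: the 6mer (reverse complement of miRNA positions 2-7), the
#' 7mer-m8 (reverse complement of positions 2-8), the 7mer-1A (6mer
#' followed by an `A` opposite miRNA position 1) and the 8mer (7mer-m8
#' followed by the `A`).
#'
#' @param mature Mature miRNA sequence, 5' to 3', RNA alphabet
#'   (`A`,`C`,`G`,`U`; `T` is also accepted).  Must be at least 8 nt.
#' @param mirna_id Identifier used in annotations.
#' @return An object of class `seed_lexicon` with elements `mirna_id`,
#'   `mature`, `word6`, `word7m8`, `word7a1`, `word8`.
#' @export
#' @examples
#' seed_words("GUCCAGUUUUCCCAGGAAUCCCU", "hsa-miR-145")
seed_words <- function(mature, mirna_id = "miRNA") {
  mature <- toupper(mature)
  if (grepl("[^ACGUT]", mature)) {
    abort("mature miRNA sequence must use the RNA alphabet {A,C,G,U}")
  }
  if (nchar(mature) < 8) {
    abort("mature miRNA must be at least 8 nt to define seed words")
  }
  dna <- normalize_sequence(mature)
  word6 <- reverse_complement(substr(dna, 2, 7))
  word7m8 <- reverse_complement(substr(dna, 2, 8))
  structure(
    list(mirna_id = mirna_id, mature = mature, word6 = word6,
         word7m8 = word7m8, word7a1 = paste0(word6, "A"),
         word8 = paste0(word7m8, "A")),
    class = "seed_lexicon"
  )
}

#' @export
print.seed_lexicon <- function(x, ...) {
  cat(sprintf("<seed_lexicon> %s (%s)\n", x$mirna_id, x$mature))
  cat(sprintf("  6mer:    %s\n  7mer-m8: %s\n  7mer-1A: %s\n  8mer:    %s\n",
              x$word6, x$word7m8, x$word7a1, x$word8))
  invisible(x)
}

SITE_CATEGORIES <- c("site8", "site7m8", "site7a1", "site6")

# Core scanner: classify every raw occurrence of the 6mer core by its
# flanking bases.  A preceding base matching the 7mer-m8 extension and a
# following A make an 8mer; one of them alone makes a 7mer-m8 / 7mer-1A;
# neither makes a plain 6mer.  Sequence ends and N count as non-matching
# flanks, so the four categories are mutually exclusive and sum to the raw
# 6mer occurrence count.
scan_seed_sites <- function(seqs, lexicon) {
  check_seq_tbl(seqs)
  if (!inherits(lexicon, "seed_lexicon")) {
    abort("`lexicon` must come from seed_words()")
  }
  dss <- as_dna_stringset(seqs)
  hits <- Biostrings::vmatchPattern(lexicon$word6, dss, fixed = TRUE)
  starts <- lapply(Biostrings::startIndex(hits), function(s) s %||% integer(0))
  n_hits <- lengths(starts)
  idx <- rep.int(seq_len(nrow(seqs)), n_hits)
  start1 <- unlist(starts, use.names = FALSE)  # 1-based core start
  if (length(start1) == 0) {
    return(tibble::tibble(seq_id = character(), category = character(),
                          start = integer(), end = integer()))
  }
  sq <- seqs$sequence[idx]
  m8_base <- substr(lexicon$word7m8, 1, 1)
  prev <- substr(sq, start1 - 1L, start1 - 1L)        # "" at sequence start
  nxt <- substr(sq, start1 + 6L, start1 + 6L)         # "" at sequence end
  has_m8 <- prev == m8_base
  has_a1 <- nxt == "A"
  category <- dplyr::case_when(
    has_m8 & has_a1 ~ "site8",
    has_m8 ~ "site7m8",
    has_a1 ~ "site7a1",
    TRUE ~ "site6"
  )
  # full site extent, 0-based half-open on the input sequence
  site_start <- start1 - 1L - ifelse(has_m8, 1L, 0L)
  site_end <- start1 + 5L + ifelse(has_a1, 1L, 0L)
  tibble::tibble(seq_id = seqs$seq_id[idx], category = category,
                 start = site_start, end = site_end)
}

#' Locate seed sites in sequences
#'
#' Returns every hierarchical (mutually exclusive) seed site found on the
#' sense strand of each sequence, as BED-like 0-based half-open intervals
#' covering the full site extent.
#'
#' @param seqs Sequence table (`seq_id`, `sequence`).
#' @param lexicon A [seed_words()] lexicon.
#' @return A tibble with columns `seq_id`, `category` (one of `site8`,
#'   `site7m8`, `site7a1`, `site6`), `start`, `end`.
#' @export
seed_sites <- function(seqs, lexicon) {
  scan_seed_sites(seqs, lexicon)
}

#' Count hierarchical seed sites per sequence
#'
#' Counts 8mer, 7mer-m8, 7mer-1A and 6mer seed matches in every sequence.
#' Categories are mutually exclusive: each raw occurrence of the 6mer core
#' is assigned to exactly one class based on its flanking bases, so longer
#' sites are never double-counted as shorter ones, and
#' `n8 + n7m8 + n7a1 + n6` equals the raw (overlapping) substring count of
#' the 6mer core.  Windows containing `N` never match.
#'
#' @inheritParams seed_sites
#' @return A tibble with one row per input sequence: `seq_id`, `length`,
#'   `n8`, `n7m8`, `n7a1`, `n6`.
#' @export
count_seed_sites <- function(seqs, lexicon) {
  sites <- scan_seed_sites(seqs, lexicon)
  base <- tibble::tibble(seq_id = seqs$seq_id,
                         length = nchar(seqs$sequence))
  wide <- sites |>
    dplyr::count(.data$seq_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cat in SITE_CATEGORIES) {
    if (!cat %in% names(wide)) wide[[cat]] <- 0L
  }
  out <- dplyr::left_join(base, wide, by = "seq_id")
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(SITE_CATEGORIES),
                                          ~ tidyr::replace_na(.x, 0L)))
  out <- dplyr::rename(out, n8 = "site8", n7m8 = "site7m8",
                       n7a1 = "site7a1", n6 = "site6")
  out[, c("seq_id", "length", "n8", "n7m8", "n7a1", "n6")]
}

#' Two-sample proportion test
#'
#' Two-sided z-test of equal proportions using the pooled estimate, without
#' continuity correction.  Degenerate pooled proportions (0 or 1) give
#' p = 1.  Vectorized over its arguments.
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @return Two-sided p-value(s).
#' @export
#' @examples
#' two_proportion_test(30, 100, 10, 100)
two_proportion_test <- function(k1, n1, k2, n2) {
  if (any(n1 < 1) || any(n2 < 1)) abort("trial counts must be at least 1")
  if (any(k1 < 0) || any(k2 < 0) || any(k1 > n1) || any(k2 > n2)) {
    abort("successes must lie between 0 and the number of trials")
  }
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (k1 / n1 - k2 / n2) / se, 0)
  ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
}

# Word length backing each site category; the pooled category combines the
# three 7/8-nt classes and uses the 7mer denominator for rate metrics.
category_word_length <- function(category) {
  c(site8 = 8L, site7m8 = 7L, site7a1 = 7L, site6 = 6L, pooled = 7L)[category]
}

#' Seed-site enrichment across regulation sets
#'
#' Compares seed-site occurrence between the down-regulated set and the
#' up-regulated / no-change sets, per site category plus a pooled category
#' combining 7mer-m8, 7mer-1A and 8mer sites.  Three metrics are
#' available: the percentage of genes in each set with at least one site
#' (`percent_of_genes`); sites per kilobase of scanned sequence
#' (`per_kb`, denominators use valid start positions, `len - k + 1`); and
#' raw site counts after subsampling every set without replacement to the
#' size of the smallest (`downscaled_counts`).  All comparisons use
#' [two_proportion_test()].
#'
#' @param sets A `regulation_sets` table from [assign_sets()], or any data
#'   frame with `gene_id` and `set` columns.
#' @param seqs Sequence table covering the genes in `sets` (genes without a
#'   sequence are dropped with a message).
#' @param lexicon A [seed_words()] lexicon.
#' @param metric One of `"percent_of_genes"`, `"per_kb"`,
#'   `"downscaled_counts"`.
#' @param seed RNG seed for the subsampling metric.
#' @param alternative `"two.sided"` (default) or `"greater"` for a
#'   one-sided test of enrichment in the down set.
#' @return A `seed_enrichment` tibble with one row per category: the
#'   per-set values, `p_dn_vs_up` and `p_dn_vs_nc`.  Set sizes, the metric
#'   and the seed are stored as attributes.
#' @export
seed_enrichment <- function(sets, seqs, lexicon,
                            metric = c("percent_of_genes", "per_kb",
                                       "downscaled_counts"),
                            seed = NULL,
                            alternative = c("two.sided", "greater")) {
  metric <- match.arg(metric)
  alternative <- match.arg(alternative)
  if (!all(c("gene_id", "set") %in% names(sets))) {
    abort("`sets` needs columns gene_id and set")
  }
  members <- dplyr::filter(sets, .data$set %in% c("up", "down", "no_change"))
  members$set <- as.character(members$set)
  sizes <- table(factor(members$set, levels = c("up", "down", "no_change")))
  if (any(sizes == 0)) {
    abort(sprintf("empty regulation set(s): %s",
                  paste(names(sizes)[sizes == 0], collapse = ", ")))
  }
  have_seq <- members$gene_id %in% seqs$seq_id
  if (any(!have_seq)) {
    inform(sprintf("dropping %d gene(s) without a sequence", sum(!have_seq)))
    members <- members[have_seq, , drop = FALSE]
  }
  counts <- count_seed_sites(seqs[match(members$gene_id, seqs$seq_id), ,
                                  drop = FALSE], lexicon)
  counts$set <- members$set
  counts$pooled <- counts$n8 + counts$n7m8 + counts$n7a1
  cat_col <- c(site8 = "n8", site7m8 = "n7m8", site7a1 = "n7a1",
               site6 = "n6", pooled = "pooled")

  if (metric == "downscaled_counts") {
    n_min <- min(table(counts$set))
    counts <- with_seed_if(seed, {
      counts |>
        dplyr::group_by(.data$set) |>
        dplyr::slice_sample(n = n_min) |>
        dplyr::ungroup()
    })
  }

  per_set <- function(set_name, category) {
    sub <- counts[counts$set == set_name, , drop = FALSE]
    x <- sub[[cat_col[category]]]
    klen <- category_word_length(category)
    positions <- sum(pmax(sub$length - klen + 1L, 0L))
    switch(metric,
      percent_of_genes = list(value = 100 * mean(x > 0),
                              k = sum(x > 0), n = nrow(sub)),
      per_kb = list(value = 1000 * sum(x) / positions,
                    k = sum(x), n = positions),
      downscaled_counts = list(value = sum(x), k = sum(x), n = positions)
    )
  }

  categories <- c(SITE_CATEGORIES, "pooled")
  rows <- purrr::map(categories, function(cat) {
    up <- per_set("up", cat)
    dn <- per_set("down", cat)
    nc <- per_set("no_change", cat)
    p_up <- two_proportion_test(dn$k, dn$n, up$k, up$n)
    p_nc <- two_proportion_test(dn$k, dn$n, nc$k, nc$n)
    if (alternative == "greater") {
      # halve the two-sided p when the down set is the enriched one
      p_up <- ifelse(dn$k / dn$n >= up$k / up$n, p_up / 2, 1 - p_up / 2)
      p_nc <- ifelse(dn$k / dn$n >= nc$k / nc$n, p_nc / 2, 1 - p_nc / 2)
    }
    tibble::tibble(category = cat, up = up$value, down = dn$value,
                   no_change = nc$value, p_dn_vs_up = p_up,
                   p_dn_vs_nc = p_nc)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metric") <- metric
  attr(out, "set_sizes") <- as.integer(table(counts$set))
  names(attr(out, "set_sizes")) <- names(table(counts$set))
  attr(out, "seed") <- seed
  attr(out, "mirna_id") <- lexicon$mirna_id
  class(out) <- c("seed_enrichment", class(out))
  out
}

#' Seed-site enrichment across transcript regions
#'
#' Runs the percent-of-genes seed enrichment separately for each supplied
#' transcript region.  If `"cdna"` is requested but absent from `seqs`, it
#' is synthesized by concatenating each gene's 5'UTR, CDS and 3'UTR into a
#' single sequence.
#'
#' @inheritParams seed_enrichment
#' @param seqs Sequence table with a `region` column.
#' @param regions Regions to analyse; defaults to the regions present.
#' @return A tibble of per-region [seed_enrichment()] rows with a leading
#'   `region` column.
#' @export
region_sweep <- function(sets, seqs, lexicon, regions = NULL) {
  check_seq_tbl(seqs)
  if (!"region" %in% names(seqs)) {
    abort("`seqs` needs a region column for region_sweep()")
  }
  present <- unique(seqs$region)
  if (is.null(regions)) regions <- present
  if (length(regions) == 0) abort("no regions to analyse")
  rows <- purrr::map(regions, function(rg) {
    if (rg == "cdna" && !"cdna" %in% present) {
      parts <- seqs[seqs$region %in% c("utr5", "cds", "utr3"), , drop = FALSE]
      parts$region <- factor(parts$region, levels = c("utr5", "cds", "utr3"))
      rseqs <- parts |>
        dplyr::arrange(.data$seq_id, .data$region) |>
        dplyr::group_by(.data$seq_id) |>
        dplyr::summarise(sequence = paste(.data$sequence, collapse = ""),
                         .groups = "drop") |>
        dplyr::mutate(region = "cdna")
    } else {
      rseqs <- seqs[seqs$region == rg, , drop = FALSE]
    }
    if (nrow(rseqs) == 0) abort(sprintf("no sequences for region '%s'", rg))
    res <- seed_enrichment(sets, rseqs, lexicon, metric = "percent_of_genes")
    dplyr::bind_cols(tibble::tibble(region = rg), res)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metric") <- "percent_of_genes"
  class(out) <- c("region_sweep", class(out))
  out
}
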
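test_that("seed words derive correctly from the mature miRNA", {
  lex <- seed_words("GUCCAGUUUUCCCAGGAAUCCCU", "hsa-miR-145")
  expect_equal(lex$word7m8, "AACTGGA")
  expect_equal(lex$word7a1, "ACTGGAA")
  expect_equal(lex$word6, "ACTGGA")
  expect_equal(lex$word8, "AACTGGAA")
  # structural invariants
  expect_equal(substr(lex$word7m8, 2, 7), lex$word6)
  expect_equal(lex$word7a1, paste0(lex$word6, "A"))
  expect_equal(lex$word8, paste0(lex$word7m8, "A"))

  expect_error(seed_words("GUCCAGU"), "at least 8")
  expect_error(seed_words("GUCCAGXU"), "RNA alphabet")
})

test_that("count_seed_sites classifies published oligo and primer sequences", {
  seqs <- tibble::tibble(
    seq_id = c("word8", "as_oligo", "stat1_mut", "yes_mut", "two6"),
    sequence = c(
      "AACTGGAA",
      "CTAGTAGGGATTCCTGGGAAAACTGGACGCTCAGCA",
      "CTTGATGGCCCTAAAGGAACTCCATATATCAAGACTGAGTTGAT",
      "TCTTCTTTACTCTGCATGTTTTTAATGGTAAAGAGGAATCCCAGATATGGT",
      "ACTGGACTGGA"
    )
  )
  counts <- count_seed_sites(seqs, mir145)
  expect_equal(unlist(counts[1, c("n8", "n7m8", "n7a1", "n6")],
                      use.names = FALSE), c(1, 0, 0, 0))
  expect_equal(unlist(counts[2, c("n8", "n7m8", "n7a1", "n6")],
                      use.names = FALSE), c(0, 1, 0, 0))
  expect_equal(sum(counts[3, c("n8", "n7m8", "n7a1", "n6")]), 0)
  expect_equal(sum(counts[4, c("n8", "n7m8", "n7a1", "n6")]), 0)
  # overlapping core occurrences are each counted
  expect_equal(unlist(counts[5, c("n8", "n7m8", "n7a1", "n6")],
                      use.names = FALSE), c(0, 0, 0, 2))
})

test_that("N windows and sequence ends behave as non-matches", {
  seqs <- tibble::tibble(
    seq_id = c("n_core", "n_flank", "start_edge", "end_edge"),
    sequence = c("ACTNGA", "NACTGGAN", "ACTGGATTT", "TTTAACTGGA")
  )
  counts <- count_seed_sites(seqs, mir145)
  expect_equal(sum(counts[1, c("n8", "n7m8", "n7a1", "n6")]), 0)
  # N flanks make a bare 6mer
  expect_equal(counts$n6[2], 1)
  expect_equal(sum(counts[2, c("n8", "n7m8", "n7a1")]), 0)
  # missing upstream base cannot complete a 7mer-m8
  expect_equal(counts$n6[3], 1)
  # 7mer-m8 at the very end (no downstream A possible)
  expect_equal(counts$n7m8[4], 1)
})

test_that("hierarchical counts and positions agree with the brute-force oracle", {
  withr::local_seed(99)
  # AT-rich composition plus planted fragments to enrich for seed cores
  n <- 300
  seqs <- oracle_random_dna(n, sample(30:400, n, replace = TRUE),
                            probs = c(0.35, 0.15, 0.15, 0.35))
  frag <- c("AACTGGAA", "AACTGGAC", "CACTGGAA", "ACTGGA", "AACTGG")
  for (i in seq_len(n)) {
    if (runif(1) < 0.7) {
      f <- sample(frag, 1)
      pos <- sample(nchar(seqs[i]) - nchar(f) + 1, 1)
      substr(seqs[i], pos, pos + nchar(f) - 1) <- f
    }
  }
  tbl <- tibble::tibble(seq_id = sprintf("s%d", seq_len(n)), sequence = seqs)
  counts <- count_seed_sites(tbl, mir145)
  sites <- seed_sites(tbl, mir145)
  expect_gt(sum(counts$n8 + counts$n7m8 + counts$n7a1 + counts$n6), 50)
  for (i in seq_len(n)) {
    oc <- oracle_seed_counts(seqs[i], mir145)
    expect_equal(unlist(counts[i, c("n8", "n7m8", "n7a1", "n6")],
                        use.names = FALSE), unname(oc))
    # conservation: categories sum to the raw core count
    expect_equal(sum(oc), oracle_count_word(seqs[i], mir145$word6))
    op <- oracle_seed_positions(seqs[i], mir145)
    ssub <- sites[sites$seq_id == sprintf("s%d", i), ]
    for (cat in names(op)) {
      expect_equal(sort(ssub$start[ssub$category == cat]),
                   sort(op[[cat]]))
    }
  }
})

test_that("scanning is sense-strand specific", {
  fwd <- "TTTAACTGGATTT"
  rev <- paste(rev(strsplit(fwd, "")[[1]]), collapse = "")
  tbl <- tibble::tibble(seq_id = c("f", "r"), sequence = c(fwd, rev))
  counts <- count_seed_sites(tbl, mir145)
  expect_equal(counts$n7m8[1], 1)
  expect_equal(sum(counts[2, c("n8", "n7m8", "n7a1", "n6")]), 0)
})

test_that("two_proportion_test matches published-style examples and edge cases", {
  expect_equal(two_proportion_test(50, 100, 50, 100), 1)
  expect_equal(two_proportion_test(0, 10, 0, 20), 1)
  expect_equal(two_proportion_test(10, 10, 20, 20), 1)
  expect_equal(two_proportion_test(30, 100, 10, 100), 4.07e-4,
               tolerance = 1e-2)
  expect_error(two_proportion_test(5, 3, 1, 10), "between 0")
  expect_error(two_proportion_test(1, 0, 1, 10), "at least 1")
})

test_that("two_proportion_test is symmetric and agrees with the chi-square oracle", {
  withr::local_seed(17)
  for (rep in 1:500) {
    n1 <- sample(2:200, 1)
    n2 <- sample(2:200, 1)
    k1 <- sample(0:n1, 1)
    k2 <- sample(0:n2, 1)
    p <- two_proportion_test(k1, n1, k2, n2)
    expect_equal(p, two_proportion_test(k2, n2, k1, n1), tolerance = 0)
    pool <- (k1 + k2) / (n1 + n2)
    if (pool > 0 && pool < 1) {
      expect_equal(p, oracle_chisq_prop(k1, n1, k2, n2),
                   tolerance = 1e-10)
    }
  }
})


test_that("percent-of-genes enrichment detects a planted prevalence contrast", {
  fx <- make_prevalence_fixture(c(150, 200, 200),
                                c(up = 0.1, down = 0.6, no_change = 0.1))
  res <- seed_enrichment(fx$sets, fx$seqs, mir145)
  pooled <- res[res$category == "pooled", ]
  expect_lt(pooled$p_dn_vs_nc, 1e-15)
  expect_lt(pooled$p_dn_vs_up, 1e-15)
  expect_gt(pooled$down, pooled$no_change)
  expect_true(all(res$up >= 0 & res$up <= 100))
  g <- glance(res)
  expect_equal(g$n_down, 200)
  expect_equal(g$pooled_p_dn_vs_nc, pooled$p_dn_vs_nc)
})

test_that("identical sequences across sets give p = 1 under the per-kb metric", {
  sets <- make_sets(sprintf("u%d", 1:5), sprintf("d%d", 1:5),
                    sprintf("n%d", 1:5))
  seqs <- tibble::tibble(seq_id = sets$gene_id,
                         sequence = strrep("TAACTGGA", 10))
  res <- seed_enrichment(sets, seqs, mir145, metric = "per_kb")
  expect_equal(res$p_dn_vs_nc, rep(1, 5))
  expect_equal(res$down, res$no_change)
})

test_that("downscaled metric subsamples deterministically under a seed", {
  fx <- make_prevalence_fixture(c(60, 100, 150),
                                c(up = 0.1, down = 0.7, no_change = 0.1))
  r1 <- seed_enrichment(fx$sets, fx$seqs, mir145,
                        metric = "downscaled_counts", seed = 7)
  r2 <- seed_enrichment(fx$sets, fx$seqs, mir145,
                        metric = "downscaled_counts", seed = 7)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_equal(attr(r1, "set_sizes"), c(down = 60L, no_change = 60L,
                                        up = 60L)[names(attr(r1, "set_sizes"))])
  expect_lt(r1[r1$category == "pooled", ]$p_dn_vs_nc, 1e-4)
})

test_that("seed_enrichment validates sets and reports dropped genes", {
  fx <- make_prevalence_fixture(c(10, 10, 10),
                                c(up = 0, down = 0.5, no_change = 0))
  empty <- fx$sets[fx$sets$set != "up", ]
  expect_error(seed_enrichment(empty, fx$seqs, mir145), "empty")
  expect_message(
    seed_enrichment(fx$sets, fx$seqs[-1, ], mir145),
    "without a sequence"
  )
})

test_that("region_sweep isolates enrichment to the region carrying sites", {
  withr::local_seed(12)
  n <- 120
  ids <- sprintf("g%d", seq_len(n))
  sets <- make_sets(ids[1:40], ids[41:80], ids[81:120])
  utr3 <- oracle_random_dna(n, 300, probs = c(0.4, 0.2, 0.1, 0.3))
  utr3 <- gsub("ACTGGA", "ACTGCA", utr3, fixed = TRUE)
  for (i in 41:80) substr(utr3[i], 10, 17) <- "AACTGGAC"
  utr5 <- oracle_random_dna(n, 150)
  seqs <- dplyr::bind_rows(
    tibble::tibble(seq_id = ids, region = "utr3", sequence = utr3),
    tibble::tibble(seq_id = ids, region = "utr5", sequence = utr5)
  )
  sweep <- region_sweep(sets, seqs, mir145)
  p3 <- sweep[sweep$region == "utr3" & sweep$category == "pooled", ]
  p5 <- sweep[sweep$region == "utr5" & sweep$category == "pooled", ]
  expect_lt(p3$p_dn_vs_nc, 1e-10)
  expect_gt(p5$p_dn_vs_nc, 0.05)

  # cdna synthesis concatenates regions, so planted 3'UTR sites remain
  sweep2 <- region_sweep(sets, seqs, mir145, regions = "cdna")
  expect_equal(nrow(sweep2), 5)
  expect_lt(sweep2[sweep2$category == "pooled", ]$p_dn_vs_nc, 1e-10)
})
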
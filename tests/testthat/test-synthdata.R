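test_that("plant_word overwrites at fixed and random positions", {
  out <- plant_word("TTTTTTTTTT", "ACGT", position = 0)
  expect_equal(as.character(out), "ACGTTTTTTT")
  expect_equal(attr(out, "position"), 0L)

  out2 <- plant_word("TTTTTTTTTT", "ACGT", position = 6)
  expect_equal(as.character(out2), "TTTTTTACGT")

  expect_error(plant_word("ACG", "ACGT"), "longer")

  withr::local_seed(61)
  s <- oracle_random_dna(1, 50)
  out3 <- plant_word(s, "ACGT")
  pos <- attr(out3, "position")
  expect_equal(as.character(substr(out3, pos + 1, pos + 4)), "ACGT")
  expect_equal(nchar(out3), 50)
})

test_that("planting an 8mer into a core-free sequence yields exactly one 8mer site", {
  withr::local_seed(67)
  for (rep in 1:20) {
    # G/C/T alphabet: no A means no seed core and no chance flank-A
    s <- oracle_random_dna(1, 120, probs = c(0, 0.4, 0.3, 0.3))
    planted <- plant_word(s, mir145$word8, lexicon = mir145)
    counts <- count_seed_sites(
      tibble::tibble(seq_id = "x", sequence = as.character(planted)), mir145)
    expect_equal(unlist(counts[, c("n8", "n7m8", "n7a1", "n6")],
                        use.names = FALSE), c(1, 0, 0, 0))
  }
})

test_that("simulation_config validates its inputs", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(target_fraction = 1.5), "target_fraction")
  expect_error(simulation_config(n_replicates = c(treated = 1, control = 4)),
               "at least 2")
  expect_error(simulation_config(regulon = list(motif = "x")), "regulon")
})

small_exp <- function(seed = 101, n = 250, ...) {
  cfg <- simulation_config(n_genes = n, seed = seed,
                           utr3_len = list(meanlog = log(400), sdlog = 0.4),
                           cds_len = list(meanlog = log(300), sdlog = 0.3),
                           utr5_len = list(meanlog = log(120), sdlog = 0.3),
                           promoter_len = 300L, ...)
  simulate_experiment(cfg, mir145)
}

test_that("emitted 3'UTR site content matches the recorded ground truth", {
  exp <- small_exp()
  utr3 <- exp$sequences[exp$sequences$region == "utr3", ]
  counts <- count_seed_sites(utr3, mir145)
  tr <- exp$truth
  expect_equal(counts$seq_id, tr$gene_id)
  total_planted <- tr$planted8 + tr$planted7m8 + tr$planted7a1 +
    tr$planted6 + tr$background_sites
  total_found <- counts$n8 + counts$n7m8 + counts$n7a1 + counts$n6
  expect_equal(total_found, total_planted)
  # per-category agreement for targets (background genes plant one site of
  # an unrecorded category, so only totals are pinned there)
  tg <- tr$is_target
  expect_equal(counts$n8[tg], tr$planted8[tg])
  expect_equal(counts$n7m8[tg], tr$planted7m8[tg])
  expect_equal(counts$n7a1[tg], tr$planted7a1[tg])
  expect_equal(counts$n6[tg], tr$planted6[tg])
  expect_true(all(tr$background_sites[tg] == 0))
  # every target carries at least one effective site
  expect_true(all(total_planted[tg] >= 1))
})

test_that("simulation is fully deterministic given the seed", {
  e1 <- small_exp(seed = 33, n = 80)
  e2 <- small_exp(seed = 33, n = 80)
  expect_identical(e1$sequences, e2$sequences)
  expect_identical(e1$expression, e2$expression)
  expect_identical(e1$diff, e2$diff)
  e3 <- small_exp(seed = 34, n = 80)
  expect_false(identical(e1$sequences$sequence, e3$sequences$sequence))
})

test_that("the global logFC displacement is reproduced in the null model", {
  exp <- simulate_experiment(
    simulation_config(n_genes = 3000, seed = 71,
                      effects = c(site8 = 0, site7m8 = 0, site7a1 = 0,
                                  site6 = 0),
                      utr3_len = list(meanlog = log(300), sdlog = 0.3),
                      cds_len = list(meanlog = log(100), sdlog = 0.2),
                      utr5_len = list(meanlog = log(80), sdlog = 0.2),
                      promoter_len = 100L,
                      global_shift = 0.226),
    mir145
  )
  expect_equal(mean(exp$diff$logFC), 0.226, tolerance = 0.03 / 0.226)
})

test_that("per-category expression effects are recoverable by regression", {
  exp <- simulate_experiment(
    simulation_config(n_genes = 3000, seed = 73,
                      utr3_len = list(meanlog = log(300), sdlog = 0.3),
                      cds_len = list(meanlog = log(100), sdlog = 0.2),
                      utr5_len = list(meanlog = log(80), sdlog = 0.2),
                      promoter_len = 100L),
    mir145
  )
  dat <- dplyr::inner_join(exp$diff, exp$truth, by = "gene_id")
  fit <- lm(logFC ~ planted8 + planted7m8 + planted7a1 + planted6,
            data = dat)
  est <- coef(summary(fit))
  cfg_eff <- exp$config$effects
  for (cat in c("planted8", "planted7m8", "planted7a1", "planted6")) {
    eff <- cfg_eff[sub("planted", "site", cat)]
    expect_lt(abs(est[cat, "Estimate"] - eff), 2 * est[cat, "Std. Error"])
  }
  expect_equal(est["(Intercept)", "Estimate"], exp$config$global_shift,
               tolerance = 0.1)
})

test_that("stronger effects give monotonically stronger enrichment", {
  # fixed-size sets from the logFC ranking keep set sizes comparable
  # across effect magnitudes, isolating the effect-size dose response
  med_p <- vapply(c(0.08, 0.2, 0.5), function(mag) {
    ps <- vapply(1:7, function(s) {
      exp <- simulate_experiment(
        simulation_config(n_genes = 500, seed = 1000 + s,
                          effects = c(site8 = -1.5 * mag,
                                      site7m8 = -mag,
                                      site7a1 = -0.75 * mag,
                                      site6 = -0.25 * mag),
                          global_shift = 0, noise_sd = 0.2,
                          utr3_len = list(meanlog = log(300), sdlog = 0.3),
                          cds_len = list(meanlog = log(100), sdlog = 0.2),
                          utr5_len = list(meanlog = log(80), sdlog = 0.2),
                          promoter_len = 100L),
        mir145
      )
      d <- dplyr::arrange(exp$diff, logFC)
      sets <- tibble::tibble(
        gene_id = d$gene_id,
        set = rep(c("down", "unassigned", "no_change", "unassigned", "up"),
                  c(100, 150, 100, 50, 100))
      )
      utr3 <- exp$sequences[exp$sequences$region == "utr3", ]
      res <- seed_enrichment(sets, utr3, mir145)
      res$p_dn_vs_nc[res$category == "pooled"]
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) < 0))
})

test_that("regulon planting shifts members and their promoter content", {
  gcbox <- read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                                   package = "seedwords"))$SYN_GCRICH
  exp <- small_exp(seed = 79, n = 400,
                   regulon = list(motif = gcbox, member_fraction = 0.2,
                                  plant_prob_members = 0.9,
                                  plant_prob_background = 0.1,
                                  regulon_shift = -0.5))
  tr <- exp$truth
  expect_equal(sum(tr$regulon_member), 80)
  proms <- exp$sequences[exp$sequences$region == "promoter", ]
  hits <- scan_pssm(proms, build_pssm(exp$config$regulon$motif))
  has_hit <- proms$seq_id %in% hits$seq_id
  expect_gt(mean(has_hit[tr$regulon_member]),
            mean(has_hit[!tr$regulon_member]) + 0.3)
  # members' expression shift includes the regulon effect
  non_target_members <- tr$regulon_member & !tr$is_target
  expect_true(all(tr$true_shift[non_target_members] == -0.5))
})

test_that("export then re-ingest reproduces the experiment losslessly", {
  exp <- small_exp(seed = 83, n = 60)
  dir <- withr::local_tempdir()
  export_experiment(exp, dir)
  expect_setequal(list.files(dir),
                  c("utr3.fa", "utr5.fa", "cds.fa", "promoter.fa",
                    "diff.tsv", "truth.tsv", "config.yaml"))
  diff_back <- read_diff_table(file.path(dir, "diff.tsv"))
  expect_equal(diff_back$gene_id, exp$diff$gene_id)
  expect_equal(diff_back$logFC, exp$diff$logFC, tolerance = 1e-12)
  utr3_back <- read_fasta(file.path(dir, "utr3.fa"), "utr3")
  expect_equal(utr3_back,
               exp$sequences[exp$sequences$region == "utr3", ])
  truth_back <- readr::read_tsv(file.path(dir, "truth.tsv"),
                                show_col_types = FALSE)
  expect_equal(nrow(truth_back), 60)
  # byte-identical re-export under the same seed
  dir2 <- withr::local_tempdir()
  export_experiment(small_exp(seed = 83, n = 60), dir2)
  expect_identical(readLines(file.path(dir, "utr3.fa")),
                   readLines(file.path(dir2, "utr3.fa")))
})

test_that("random set labels give calibrated enrichment p-values", {
  withr::local_seed(89)
  reps <- 200
  pvals <- vapply(seq_len(reps), function(r) {
    n <- 600
    seqs <- random_dna(n, 500, composition = c(0.295, 0.205, 0.205, 0.295))
    tbl <- tibble::tibble(seq_id = sprintf("g%d", seq_len(n)),
                          sequence = seqs)
    sets <- make_sets(tbl$seq_id[1:200], tbl$seq_id[201:400],
                      tbl$seq_id[401:600])
    res <- seed_enrichment(sets, tbl, mir145)
    res$p_dn_vs_nc[res$category == "site6"]
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})
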
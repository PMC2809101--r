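#' Collapse probesets to genes
#'
#' Applies the standard array pre-processing rules for many-to-many
#' probeset/gene maps: probesets mapping to more than two genes are
#' discarded as non-specific; a probeset mapping to two genes contributes
#' to both; and when several probesets survive for one gene, the probeset
#' with the largest inter-quartile range (IQR) of expression across all
#' samples is kept as that gene's measurement.
#'
#' @param exprs Expression table: a data frame whose first column is
#'   `probeset_id` and whose remaining columns are per-sample normalized
#'   log-intensities.
#' @param probe_map Long-format map: a data frame with columns
#'   `probeset_id` and `gene_id` (one row per mapping).
#' @return A gene-keyed expression tibble (`gene_id` + sample columns).
#' @export
collapse_probesets <- function(exprs, probe_map) {
  if (!is.data.frame(exprs) || names(exprs)[1] != "probeset_id") {
    abort("`exprs` must be a data frame with first column `probeset_id`")
  }
  if (!all(c("probeset_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` must have columns probeset_id and gene_id")
  }
  unmapped <- setdiff(exprs$probeset_id, probe_map$probeset_id)
  if (length(unmapped) > 0) {
    abort(sprintf("probeset(s) absent from map: %s",
                  paste(unmapped, collapse = ", ")))
  }
  sample_cols <- names(exprs)[-1]
  n_per_probe <- probe_map |>
    dplyr::distinct(.data$probeset_id, .data$gene_id) |>
    dplyr::count(.data$probeset_id, name = "n_genes")
  ambiguous <- n_per_probe$probeset_id[n_per_probe$n_genes > 2]
  if (length(ambiguous) > 0) {
    inform(sprintf("dropping %d probeset(s) mapping to more than two genes",
                   length(ambiguous)))
  }
  vals <- as.matrix(exprs[, sample_cols, drop = FALSE])
  iqr <- apply(vals, 1L, stats::IQR)
  keyed <- exprs |>
    dplyr::mutate(.iqr = iqr) |>
    dplyr::filter(!(.data$probeset_id %in% ambiguous)) |>
    dplyr::inner_join(
      dplyr::distinct(probe_map, .data$probeset_id, .data$gene_id),
      by = "probeset_id", relationship = "many-to-many"
    ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$.iqr), .data$probeset_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id)
  keyed[, c("gene_id", sample_cols)]
}

#' Non-specific variance filter
#'
#' Removes genes whose across-sample variance (unbiased, n-1 denominator)
#' falls strictly below `cutoff`.  Genes at exactly the cutoff are kept.
#'
#' @param exprs Gene-keyed expression table (`gene_id` + sample columns).
#' @param cutoff Variance threshold; default 0.25.
#' @return The filtered expression tibble; the number of removed genes is
#'   reported as a message.
#' @export
variance_filter <- function(exprs, cutoff = 0.25) {
  if (!is.data.frame(exprs) || names(exprs)[1] != "gene_id") {
    abort("`exprs` must be a gene-keyed expression table")
  }
  vals <- as.matrix(exprs[, -1, drop = FALSE])
  if (ncol(vals) < 2) abort("variance filter needs at least 2 samples")
  v <- apply(vals, 1L, var)
  keep <- v >= cutoff
  inform(sprintf("variance filter removed %d of %d genes (cutoff %g)",
                 sum(!keep), length(keep), cutoff))
  exprs[keep, , drop = FALSE]
}

#' Per-gene differential statistics
#'
#' Computes, for every gene, the log2 fold-change (mean of treated minus
#' mean of control samples), a two-sided Welch t-test p-value, and
#' Benjamini-Hochberg adjusted FDR values over all tested genes.
#'
#' @param exprs Gene-keyed expression table (`gene_id` + sample columns) of
#'   log2-scale intensities.
#' @param conditions Named character vector mapping each sample column to
#'   `"treated"` or `"control"`, or a data frame with columns `sample_id`
#'   and `condition`.
#' @return A differential tibble with columns `gene_id`, `logFC`, `p`,
#'   `fdr`.
#' @export
differential_stats <- function(exprs, conditions) {
  if (!is.data.frame(exprs) || names(exprs)[1] != "gene_id") {
    abort("`exprs` must be a gene-keyed expression table")
  }
  if (is.data.frame(conditions)) {
    conditions <- stats::setNames(conditions$condition, conditions$sample_id)
  }
  sample_cols <- names(exprs)[-1]
  missing_cond <- setdiff(sample_cols, names(conditions))
  if (length(missing_cond) > 0) {
    abort(sprintf("no condition given for sample(s): %s",
                  paste(missing_cond, collapse = ", ")))
  }
  cond <- conditions[sample_cols]
  if (!all(cond %in% c("treated", "control"))) {
    abort("conditions must be 'treated' or 'control'")
  }
  nt <- sum(cond == "treated")
  nc <- sum(cond == "control")
  if (nt < 2 || nc < 2) {
    abort("each condition needs at least 2 samples for the t-test")
  }
  m <- as.matrix(exprs[, -1, drop = FALSE])
  tm <- m[, cond == "treated", drop = FALSE]
  cm <- m[, cond == "control", drop = FALSE]
  mt <- rowMeans(tm)
  mc <- rowMeans(cm)
  vt <- rowSums((tm - mt)^2) / (nt - 1)
  vc <- rowSums((cm - mc)^2) / (nc - 1)
  logfc <- mt - mc
  se2 <- vt / nt + vc / nc
  tstat <- ifelse(se2 > 0, logfc / sqrt(se2), ifelse(logfc == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((vt / nt)^2 / (nt - 1) + (vc / nc)^2 / (nc - 1)),
               nt + nc - 2)
  p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df), 0)
  p[tstat == 0] <- 1
  tibble::tibble(gene_id = exprs$gene_id, logFC = logfc, p = p,
                 fdr = p.adjust(p, method = "BH"))
}

#' Partition genes into up, down and no-change sets
#'
#' Genes with `fdr < fdr_regulated` are called up- or down-regulated by the
#' sign of their log2 fold-change; genes with `fdr > fdr_nochange` form the
#' no-change background set.  Genes in the middle FDR band (and the
#' measure-zero case `fdr < fdr_regulated` with `logFC == 0`) remain
#' unassigned rather than being silently dropped.
#'
#' @param diff A differential table (`gene_id`, `logFC`, `fdr`, and
#'   typically `p`), e.g. from [differential_stats()] or
#'   [read_diff_table()].
#' @param fdr_regulated FDR threshold below which genes are regulated
#'   (default 0.25).
#' @param fdr_nochange FDR threshold above which genes count as unchanged
#'   (default 0.8).
#' @return The input tibble with an added factor column `set` taking values
#'   `up`, `down`, `no_change`, `unassigned`; thresholds are recorded as
#'   attributes.  Class `regulation_sets`.
#' @export
assign_sets <- function(diff, fdr_regulated = 0.25, fdr_nochange = 0.8) {
  if (!is.data.frame(diff) || nrow(diff) == 0) {
    abort("`diff` must be a non-empty differential table")
  }
  if (!all(c("gene_id", "logFC", "fdr") %in% names(diff))) {
    abort("`diff` needs columns gene_id, logFC, fdr")
  }
  check_scalar_number(fdr_regulated, "fdr_regulated", 0, 1)
  check_scalar_number(fdr_nochange, "fdr_nochange", 0, 1)
  set <- dplyr::case_when(
    diff$fdr < fdr_regulated & diff$logFC > 0 ~ "up",
    diff$fdr < fdr_regulated & diff$logFC < 0 ~ "down",
    diff$fdr > fdr_nochange ~ "no_change",
    TRUE ~ "unassigned"
  )
  out <- tibble::as_tibble(diff)
  out$set <- factor(set, levels = c("up", "down", "no_change", "unassigned"))
  attr(out, "fdr_regulated") <- fdr_regulated
  attr(out, "fdr_nochange") <- fdr_nochange
  class(out) <- c("regulation_sets", class(out))
  out
}

#' Select strongly responsive genes for annotation export
#'
#' Returns the genes whose absolute log2 fold-change exceeds `cutoff`, as a
#' plain id table suitable for export to external functional-annotation
#' tools.  The default cutoff `log2(1.1)` reads the selection as a 1.1-fold
#' change; pass `cutoff = 1.1` for a literal log2-unit threshold.
#'
#' @param diff A differential table with `gene_id` and `logFC`.
#' @param cutoff Absolute logFC cutoff (default `log2(1.1)`).
#' @return A tibble with columns `gene_id` and `logFC`.
#' @export
functional_set <- function(diff, cutoff = log2(1.1)) {
  if (!all(c("gene_id", "logFC") %in% names(diff))) {
    abort("`diff` needs columns gene_id and logFC")
  }
  diff |>
    dplyr::filter(abs(.data$logFC) > cutoff) |>
    dplyr::select("gene_id", "logFC") |>
    tibble::as_tibble()
}

#' Write regulation sets as a three-column TSV
#'
#' @param sets A `regulation_sets` table from [assign_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulation_sets <- function(sets, path) {
  if (!inherits(sets, "regulation_sets")) {
    abort("`sets` must come from assign_sets()")
  }
  readr::write_tsv(sets[, c("gene_id", "set", "logFC")], path,
                   progress = FALSE)
  invisible(path)
}
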
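#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a word-enrichment table
#'
#' @param x A [word_analysis()] result.
#' @param ... Unused.
#' @return A plain tibble of per-word results.
#' @export
tidy.word_enrichment <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a word analysis
#'
#' @param x A [word_analysis()] result.
#' @param ... Unused.
#' @return A one-row tibble: word length `k`, shuffles `B`, permutations
#'   `P`, number of words, the top word with its z-score and FDR, and the
#'   number of words at FDR below 0.05.
#' @export
glance.word_enrichment <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"), B = attr(x, "B"), P = attr(x, "P"),
    n_words = nrow(x), top_word = x$word[1], top_z = x$z_score[1],
    top_fdr = x$fdr[1], n_fdr_05 = sum(x$fdr < 0.05)
  )
}

#' Tidy a seed-enrichment result
#'
#' @param x A [seed_enrichment()] result.
#' @param ... Unused.
#' @return A long tibble with one row per category and set.
#' @export
tidy.seed_enrichment <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("up", "down", "no_change"), names_to = "set",
                        values_to = "value")
}

#' One-row summary of a seed-enrichment result
#'
#' @param x A [seed_enrichment()] result.
#' @param ... Unused.
#' @return A one-row tibble with the metric, set sizes and the pooled
#'   category's p-values.
#' @export
glance.seed_enrichment <- function(x, ...) {
  pooled <- x[x$category == "pooled", ]
  sizes <- attr(x, "set_sizes")
  tibble::tibble(
    metric = attr(x, "metric"),
    n_up = unname(sizes["up"]), n_down = unname(sizes["down"]),
    n_nochange = unname(sizes["no_change"]),
    pooled_p_dn_vs_up = pooled$p_dn_vs_up,
    pooled_p_dn_vs_nc = pooled$p_dn_vs_nc
  )
}

#' Tidy a regulation-sets table
#'
#' @param x An [assign_sets()] result.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.regulation_sets <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a regulation-sets table
#'
#' @param x An [assign_sets()] result.
#' @param ... Unused.
#' @return A one-row tibble of set sizes, thresholds and mean logFC.
#' @export
glance.regulation_sets <- function(x, ...) {
  tab <- table(x$set)
  tibble::tibble(
    n_genes = nrow(x), n_up = unname(tab["up"]), n_down = unname(tab["down"]),
    n_nochange = unname(tab["no_change"]),
    n_unassigned = unname(tab["unassigned"]),
    fdr_regulated = attr(x, "fdr_regulated"),
    fdr_nochange = attr(x, "fdr_nochange"),
    mean_logFC = mean(x$logFC)
  )
}
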
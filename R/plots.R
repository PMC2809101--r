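#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_col
#'   geom_point labs facet_wrap position_dodge scale_y_log10 theme_minimal
NULL

#' Plot a running-sum profile
#'
#' Draws the cumulative mean-centered overrepresentation score along the
#' ranked sequence list; an early peak indicates enrichment among the
#' most down-regulated sequences.
#'
#' @param object A [running_sum()] / [word_profile()] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.running_sum_profile <- function(object, ...) {
  word <- attr(object, "word")
  ggplot(object, aes(x = .data$index, y = .data$S)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "black") +
    labs(x = "rank in sequence list (most down-regulated first)",
         y = "running sum of centered scores",
         title = if (!is.null(word)) {
           sprintf("Running-sum profile for %s", word)
         } else "Running-sum profile",
         subtitle = sprintf("max statistic = %.3f",
                            attr(object, "statistic"))) +
    theme_minimal()
}

#' Plot word-enrichment z-scores
#'
#' @param object A [word_analysis()] table.
#' @param top Number of top-ranked words to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.word_enrichment <- function(object, top = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$word <- factor(df$word, levels = rev(df$word))
  df$match <- ifelse(df$annotation == "", "other", "seed match")
  ggplot(df, aes(x = .data$z_score, y = .data$word, fill = .data$match)) +
    geom_col() +
    labs(x = "z-score", y = NULL, fill = NULL,
         title = sprintf("Top %d enriched %d-mers", nrow(df),
                         attr(object, "k"))) +
    theme_minimal()
}

#' Plot seed-site enrichment across sets
#'
#' @param object A [seed_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seed_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("up", "down", "no_change"), names_to = "set",
                        values_to = "value")
  df$set <- factor(df$set, levels = c("up", "down", "no_change"))
  ylab <- switch(attr(object, "metric"),
                 percent_of_genes = "% of genes with a site",
                 per_kb = "sites per kb",
                 downscaled_counts = "site count (downscaled sets)")
  ggplot(df, aes(x = .data$category, y = .data$value, fill = .data$set)) +
    geom_col(position = position_dodge()) +
    labs(x = "seed-site category", y = ylab, fill = "gene set") +
    theme_minimal()
}

#' Plot promoter motif enrichment
#'
#' @param object A [promoter_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfbs_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::starts_with("percent_"), names_to = "set",
                        values_to = "percent",
                        names_prefix = "percent_")
  ggplot(df, aes(x = .data$motif_id, y = .data$percent, fill = .data$set)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "% promoters with a hit", fill = "gene set") +
    theme_minimal()
}
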
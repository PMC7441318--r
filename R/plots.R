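#' Plot the Monte-Carlo coincidence distribution
#'
#' Histogram of the replicate coincidence counts for the affected set with
#' the observed count marked, the usual way the randomization null is
#' displayed.
#'
#' @param object an `mc_overlap` result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mc_overlap <- function(object, ...) {
  df <- object$replicate_counts
  ggplot2::ggplot(df, ggplot2::aes(x = .data$affected)) +
    ggplot2::geom_bar(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$affected_observed,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "# coincidences (affected set, randomized)",
                  y = "replicates",
                  title = sprintf("observed %d, expected %.1f (joint p = %.3g)",
                                  object$affected_observed,
                                  object$affected_expected, object$p_joint)) +
    ggplot2::theme_minimal()
}

#' Plot the selection cascade of biallelic deletions
#'
#' Carrier rates in affected and unaffected individuals at each selection
#' stage.
#'
#' @param object a `cnv0_selection`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cnv0_selection <- function(object, ...) {
  df <- object$cascade %>%
    tidyr::pivot_longer(c("affected_rate_pct", "unaffected_rate_pct"),
                        names_to = "group", values_to = "rate_pct") %>%
    mutate(group = sub("_rate_pct", "", .data$group),
           stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$rate_pct,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% individuals with >= 1 event",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Distribution of per-sample autozygosity
#'
#' @param fractions tibble with an `autozygosity_pct` column (e.g. from
#'   [total_autozygosity()] or [autozygosity_summary()]).
#' @param threshold family-classification threshold to mark (default 2.5).
#' @return a ggplot.
#' @export
plot_autozygosity <- function(fractions, threshold = 2.5) {
  ggplot2::ggplot(fractions, ggplot2::aes(x = .data$autozygosity_pct)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "% of autosomal genetic map in runs >= 5 cM",
                  y = "individuals") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-profile joint p-values
#'
#' Displays the per-epigenome (or tissue-union) joint
#' enrichment/depletion p-values from [chromhmm_overlap()] as
#' `-log10(p)`.
#'
#' @param results tibble returned by [chromhmm_overlap()].
#' @return a ggplot.
#' @export
plot_enrichment_profiles <- function(results) {
  df <- results %>%
    mutate(neglog10_p = -log10(.data$p_joint),
           profile = stats::reorder(.data$profile, .data$neglog10_p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neglog10_p, y = .data$profile,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](joint~p)), y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
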
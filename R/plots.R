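#' Plot per-column conservation of a consensus profile
#'
#' Bars show each column's conservation fraction coloured by domain
#' region, with the consensus threshold as a dashed line.
#'
#' @param object A [consensus_profile][build_consensus].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_profile <- function(object, ...) {
  df <- tidy(object)
  df$region <- factor(df$region, levels = c("basic", "helix1", "loop", "helix2"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$fraction,
                                   fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "alignment column", y = "conservation fraction",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of binding categories per species
#'
#' @param table Family table from [tabulate_categories()] (the grand-total
#'   row is dropped).
#' @return A ggplot object.
#' @export
plot_binding_categories <- function(table) {
  df <- table |>
    dplyr::filter(.data$species != "Total") |>
    tidyr::pivot_longer(dplyr::all_of(BINDING_CATEGORIES),
                        names_to = "category", values_to = "count") |>
    dplyr::mutate(category = factor(.data$category, levels = BINDING_CATEGORIES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$count,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proteins", fill = "binding category") +
    ggplot2::theme_minimal()
}

#' Bar chart of intron-pattern frequencies per group
#'
#' @param distribution Tibble from [pattern_distribution()].
#' @return A ggplot object.
#' @export
plot_intron_patterns <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = stats::reorder(.data$label, -.data$count),
                               y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(x = "intron pattern", y = "genes") +
    ggplot2::theme_minimal()
}

#' Bar chart of domain- or loop-length frequencies
#'
#' @param distribution Tibble from [domain_length_distribution()] or
#'   [loop_length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(distribution) {
  key <- intersect(c("domain_length", "loop_length"), names(distribution))[1]
  if (is.na(key)) abort("expected a domain_length or loop_length column")
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data[[key]], y = .data$percentage)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = gsub("_", " ", key), y = "% of accepted domains") +
    ggplot2::theme_minimal()
}
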
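# ggplot2 views of the profile and quantity results.

#' Plot an intact occurrence profile
#'
#' Bar chart of per-category bioactive-fragment occurrence counts (or the
#' relative Y percentages) for each protein.
#'
#' @param object An `intact_profile` from [scan_intact()].
#' @param statistic `"count"`, `"freq_A"` or `"rel_Y"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot intact_profile
#' @export
autoplot.intact_profile <- function(object, statistic = c("count", "freq_A", "rel_Y"), ...) {
  statistic <- match.arg(statistic)
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data[[statistic]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$accession), scales = "free_y") +
    ggplot2::labs(
      x = "activity category",
      y = switch(statistic,
                 count = "occurrences in intact chain",
                 freq_A = "A (occurrences per 1000 residues)",
                 rel_Y = "Y (% of all occurrences)"),
      title = "Bioactive peptide occurrences in intact proteins"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a post-digestion profile
#'
#' Per-category released-peptide counts by protein and scenario.
#'
#' @param object A `scenario_profile` from [profile_digest()], or the
#'   combined `digest` tibble from [run_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_profile
#' @export
autoplot.scenario_profile <- function(object, ...) {
  dat <- if (inherits(object, "scenario_profile")) tidy(object) else as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$count,
                                    fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$accession), scales = "free_y") +
    ggplot2::labs(x = "activity category", y = "peptides released per molecule",
                  fill = "scenario",
                  title = "Bioactive peptides released by simulated digestion") +
    ggplot2::theme_minimal()
}

#' Plot a daily-quantity estimate
#'
#' @param object A `quantity_estimate` from [daily_total()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quantity_estimate
#' @export
autoplot.quantity_estimate <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$item, .data$mg_per_day),
                                    y = .data$mg_per_day)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bioactive peptide (mg/day)",
                  title = "Predicted daily bioactive peptide quantity by food item") +
    ggplot2::theme_minimal()
}
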
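#' Plot per-pattern signal fractions against their cutoffs
#'
#' @param object A `cbfb_fish_interp`.
#' @param cutoffs The [fish_cutoffs()] used for classification (drawn as
#'   per-pattern threshold ticks).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbfb_fish_interp
#' @export
autoplot.cbfb_fish_interp <- function(object, cutoffs = fish_cutoffs(), ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$pattern != "F2") |>
    dplyr::mutate(cutoff = unclass(cutoffs)[.data$pattern])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$percent,
                                   fill = .data$exceeded)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$cutoff,
                                        ymax = .data$cutoff),
                           linetype = 2, width = 0.6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "signal pattern", y = "% of scored nuclei",
                  fill = "at/above cutoff",
                  title = paste("Break-apart FISH:", object$category)) +
    ggplot2::theme_minimal()
}

#' Plot the result-category breakdown of a cohort
#'
#' @param object A `cbfb_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbfb_cohort_summary
#' @export
autoplot.cbfb_cohort_summary <- function(object, ...) {
  df <- dplyr::mutate(object$result_table,
                      category = factor(.data$category,
                                        levels = rev(CATEGORY_LEVELS)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$percent)),
                       hjust = -0.05, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(x = NULL, y = "patients",
                  title = "Reported CBFB break-apart FISH results") +
    ggplot2::theme_minimal()
}

#' Bar chart of discordance/atypicality causes in a called cohort
#'
#' @param calls Output of [call_cases()].
#' @return A ggplot object.
#' @export
plot_discordance_causes <- function(calls) {
  df <- calls |>
    dplyr::filter(!is.na(.data$discordance_cause),
                  .data$discordance_cause != "none") |>
    dplyr::count(.data$discordance_cause)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$discordance_cause,
                                                      .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#762a83") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cases",
                  title = "Causes of discordant or atypical results") +
    ggplot2::theme_minimal()
}
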
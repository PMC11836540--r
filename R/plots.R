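#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fan chart of projected speaker totals
#'
#' Median projected total speakers per year with the 80% projection
#' interval as a ribbon, facetted by language.
#'
#' @param object A `speaker_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot speaker_projection
#' @export
autoplot.speaker_projection <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(is.na(.data$age_lo))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue4") +
    ggplot2::facet_wrap(~language, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "speakers",
      title = "Projected speaker numbers",
      subtitle = "median and 80% projection interval"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot dormancy_summary
#' @export
autoplot.dormancy_summary <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$year, y = .data$risk, colour = .data$band)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(10, 50), linetype = "dotted") +
    ggplot2::labs(
      x = NULL, y = "dormancy risk (%)", colour = "age band",
      title = paste("Dormancy risk", attr(object, "language"))
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot speaker_baseline
#' @export
autoplot.speaker_baseline <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      sd = dplyr::case_when(
        .data$family == "nbinom" ~ sqrt(.data$mu + .data$mu^2 / .data$size),
        .data$family == "poisson" ~ sqrt(.data$mu),
        TRUE ~ 0
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_lo, y = .data$mu)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(0, .data$mu - 1.28 * .data$sd),
        ymax = .data$mu + 1.28 * .data$sd
      ),
      width = 2
    ) +
    ggplot2::labs(
      x = "age group (lower bound) in 2001", y = "speakers",
      title = paste("Baseline 2001 age structure:", object$language),
      subtitle = "cohort means with ~80% count bands"
    ) +
    ggplot2::theme_minimal()
}
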
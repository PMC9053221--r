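#' Plot a rate-difference posterior
#'
#' Normalized density curve with the reported tail shaded and a reference
#' line at zero.
#'
#' @param object A [delta_posterior()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot delta_posterior
#' @export
autoplot.delta_posterior <- function(object, ...) {
  if (!object$informative) stop("posterior is not normalizable; nothing to plot")
  grid <- seq(object$support[1], object$support[2], length.out = 400)
  df <- tibble::tibble(delta = grid, density = posterior_density(object, grid))
  tail_side <- if (object$expected_delta > 0) df$delta <= 0 else df$delta >= 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$density)) +
    ggplot2::geom_area(data = df[tail_side, , drop = FALSE],
                       fill = "grey60", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression(Delta * lambda ~ "(per person-year)"),
      y = "posterior density",
      subtitle = sprintf("E[Δλ] = %.3g, p = %.3g",
                         object$expected_delta, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot survival curves
#'
#' @param object A `survival_curve` tibble from [kaplan_meier()] or
#'   [mortality_curves()] (the latter stacks a `stratum` column).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1,
                   stratum = unique(object$stratum %||% "all")),
    tibble::as_tibble(object))
  if (!"stratum" %in% names(df)) df$stratum <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "survival") +
    ggplot2::theme_minimal()
}

#' Plot a chapter-level frequency comparison
#'
#' Dot-and-error display of the two groups' frequency posteriors per
#' chapter and care setting, shaded by significance grade.
#'
#' @param object A `chapter_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chapter_comparison
#' @export
autoplot.chapter_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("freq1_pct_py", "freq2_pct_py"),
    names_to = "side", values_to = "freq") |>
    dplyr::mutate(
      group = ifelse(.data$side == "freq1_pct_py", .data$group1, .data$group2),
      sd = ifelse(.data$side == "freq1_pct_py", .data$freq1_sd_pct_py,
                  .data$freq2_sd_pct_py))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chapter, y = .data$freq,
                                     colour = .data$group,
                                     alpha = .data$grade != "ns")) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$freq - 2 * .data$sd, 0),
                                          ymax = .data$freq + 2 * .data$sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~source, ncol = 1) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "ICD-10 chapter", y = "frequency (% per year)") +
    ggplot2::theme_minimal()
}

#' Plot person-year frequencies for a link
#'
#' @param object A `py_frequency` from [frequency_by_exposure()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot py_frequency
#' @export
autoplot.py_frequency <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$subgroup, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "events per person-year",
                  subtitle = paste(object$cause[1], "→",
                                   object$outcome[1])) +
    ggplot2::theme_minimal()
}
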
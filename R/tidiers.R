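#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an epsilon profile
#'
#' `tidy()` returns one row per history length with the estimate, its
#' harmonic weight and the maximizing word; `glance()` returns a one-row
#' summary with the weighted aggregate.
#'
#' @param x An [epsilon_profile()] object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @export
tidy.epsilon_profile <- function(x, ...) {
  hs <- 0:x$h_max
  w <- 1 / (hs + 1)
  tibble::tibble(
    h = hs,
    epsilon = unname(x$epsilons),
    weight = w / sum(w),
    argmax_word = unname(x$argmax_words)
  )
}

#' @rdname tidy.epsilon_profile
#' @export
glance.epsilon_profile <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    h_max = x$h_max,
    mode = x$mode,
    cyclic = x$cyclic,
    epsilon_min = min(x$epsilons),
    epsilon_max = max(x$epsilons),
    weighted_epsilon = x$weighted
  )
}

#' Plot an epsilon profile
#'
#' Draws the per-history estimates against history length, with the
#' harmonic-weighted aggregate as a dashed reference line.
#'
#' @param object An [epsilon_profile()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epsilon_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$epsilon)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = object$weighted, linetype = "dashed",
      colour = "firebrick"
    ) +
    ggplot2::scale_x_continuous(breaks = df$h) +
    ggplot2::labs(
      x = "history length h",
      y = expression(tilde(epsilon)[h]),
      title = sprintf(
        "Per-history bias estimates (n = %s, weighted = %.4f)",
        format(object$n, big.mark = ","), object$weighted
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot cohort epsilon summaries by sex and age decade
#'
#' Renders the output of [summarize_groups()] in the whisker-box convention
#' used for cohort comparisons: box from first to third quartile, middle
#' line at the median, whiskers at the group minimum and maximum, one panel
#' per sex.
#'
#' @param summary A tibble from [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_group_epsilons <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = factor(.data$decade))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q0, ymax = .data$q4),
      width = 0.25, colour = "grey40"
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$q2, ymin = .data$q1, ymax = .data$q3),
      fill = "grey90", width = 0.6
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(
      x = "age decade", y = expression(tilde(epsilon)),
      title = "Weighted epsilon by sex and age decade"
    ) +
    ggplot2::theme_minimal()
}
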
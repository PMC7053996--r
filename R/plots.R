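#' Plot a deprivation timecourse
#'
#' Group mean with SEM ribbon per session, with a dashed baseline
#' reference at 1.
#'
#' @param object A `spinedyn_timecourse` (see [timecourse()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spinedyn_timecourse <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session_index, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 2) +
    ggplot2::scale_x_continuous(breaks = df$session_index, labels = df$session) +
    ggplot2::labs(x = NULL, y = paste("normalized", object$value),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare per-spine CV distributions between groups
#'
#' Boxplots of per-spine coefficients of variation, one box per named
#' group (e.g. layers, or before/after deprivation).
#'
#' @param cv_list Named list of tibbles from [spine_cv()] (or numeric
#'   vectors of CVs).
#' @return A ggplot.
#' @export
plot_cv_comparison <- function(cv_list) {
  df <- purrr::imap_dfr(cv_list, function(x, name) {
    cv <- if (is.data.frame(x)) x$cv else x
    tibble(group = name, cv = cv[!is.na(cv)])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$cv)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "spine sGluA1 CV") +
    ggplot2::theme_minimal()
}

#' Plot a value against a spatial coordinate
#'
#' Scatter of per-unit values against relative depth or distance with a
#' least-squares trend line, the visual companion of
#' [coordinate_correlation()].
#'
#' @param tbl Table holding both columns.
#' @param value,coord Column names.
#' @return A ggplot.
#' @export
plot_coordinate <- function(tbl, value, coord) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data[[coord]], y = .data[[value]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = coord, y = value) +
    ggplot2::theme_minimal()
}

#' Plot decrease / no-decrease classification outcomes
#'
#' Per-unit values at the evaluated session, coloured by label, with the
#' threshold line.
#'
#' @param classification Tibble from [classify_response()].
#' @return A ggplot.
#' @export
plot_classification <- function(classification) {
  thr <- classification$threshold[1]
  ggplot2::ggplot(
    classification,
    ggplot2::aes(x = stats::reorder(.data$unit_id, .data$value),
                 y = .data$value, fill = .data$label)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1 - thr, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "normalized sGluA1 at VD1", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
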
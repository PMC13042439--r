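# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_segment geom_col labs scale_y_log10 facet_wrap arrow unit
#'   coord_polar theme_minimal position_dodge
NULL

#' Plot a MO-shift profile
#'
#' Gap-shift magnitude against distance from the guest, with the tolerance
#' line and (optionally) the detected convergence radius.
#'
#' @param object A `shift_profile`.
#' @param delta Tolerance line to draw, eV (default 0.01).
#' @param r_conv Optional convergence radius (number or
#'   [convergence_radius()] result) drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_profile <- function(object, delta = 0.01, r_conv = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$abs_eps <- abs(df$delta_eps)
  p <- ggplot(df, aes(x = .data$rmin, y = .data$abs_eps)) +
    geom_point(alpha = 0.7, colour = "#2c5f8a") +
    geom_hline(yintercept = delta, linetype = "dashed", colour = "grey40") +
    labs(x = expression(R[min] ~ "(Å)"),
         y = expression("|" * Delta * epsilon * "| (eV)"),
         title = "Binding-induced HOMO-LUMO gap shifts") +
    theme_minimal()
  if (!is.null(r_conv)) {
    if (inherits(r_conv, "convergence_radius")) r_conv <- r_conv$r_conv
    p <- p + geom_vline(xintercept = r_conv, colour = "#b5442a")
  }
  p
}

#' Plot a charge-flow network in radial layout
#'
#' Nodes on a polar layout (radius = log10 distance from the guest, angle =
#' fragment index), directed edges drawn as arrows with width proportional
#' to the transferred charge.
#'
#' @param object A `flow_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_graph <- function(object, ...) {
  nodes <- tibble::as_tibble(object$nodes)
  n <- nrow(nodes)
  nodes$angle <- 2 * pi * (seq_len(n) - 1) / max(1, n)
  r <- nodes$rmin
  if (all(is.na(r))) r <- rep(1, n)
  nodes$radius <- log10(pmax(r, 0.5) + 1)
  nodes$px <- nodes$radius * cos(nodes$angle)
  nodes$py <- nodes$radius * sin(nodes$angle)
  ed <- tibble::as_tibble(object$edges)
  if (nrow(ed) > 0) {
    m1 <- match(ed$source, nodes$fragment_id)
    m2 <- match(ed$target, nodes$fragment_id)
    ed$x <- nodes$px[m1]; ed$y <- nodes$py[m1]
    ed$xend <- nodes$px[m2]; ed$yend <- nodes$py[m2]
  }
  p <- ggplot(nodes, aes(x = .data$px, y = .data$py)) +
    geom_point(aes(size = abs(.data$delta_q)), colour = "black") +
    labs(title = "Charge-redistribution network",
         subtitle = sprintf("edge threshold %g e", object$threshold),
         x = NULL, y = NULL, size = expression("|" * Delta * q * "| (e)")) +
    theme_minimal()
  if (nrow(ed) > 0) {
    p <- p + geom_segment(
      data = ed,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
          linewidth = .data$weight),
      colour = "#b5442a", alpha = 0.6,
      arrow = arrow(length = unit(2, "mm"))) +
      ggplot2::scale_linewidth(range = c(0.2, 1.2))
  }
  p
}

#' Plot a deviation table
#'
#' Signed deviations from the reference model, one bar per model within each
#' label.
#'
#' @param object A `deviation_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deviation_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ref <- attr(object, "reference_model")
  df <- df[df$model != ref & !is.na(df$deviation), ]
  ggplot(df, aes(x = .data$label, y = .data$deviation, fill = .data$model)) +
    geom_col(position = position_dodge()) +
    geom_hline(yintercept = 0, colour = "grey30") +
    labs(x = NULL, y = paste0("deviation from ", ref),
         title = "Region-model deviations from the reference") +
    theme_minimal()
}

#' Scatter of computed energies against experimental activities
#'
#' @param series Activity series tibble (`label`, `activity`, `computed`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_activity_series <- function(series, ...) {
  df <- tibble::as_tibble(series)
  ggplot(df, aes(x = .data$activity, y = .data$computed)) +
    geom_point(size = 2, colour = "#b5442a") +
    ggplot2::geom_text(aes(label = .data$label), vjust = -0.8, size = 3) +
    labs(x = "experimental activity (pIC50)",
         y = "computed binding energy (kcal/mol)",
         title = "Rank agreement with experiment") +
    theme_minimal()
}
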
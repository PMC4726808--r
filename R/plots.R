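#' Plot a phase sweep
#'
#' Normalized probability of the tracked state as a function of the shared
#' phase difference, with the classical collapse point (pi/2) and the
#' minimum marked.
#'
#' @param object A `qlbn_sweep` from [sweep_phase()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.qlbn_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_theta,
                                       y = .data$p_target)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = pi / 2, linetype = "dashed",
                        color = "grey40") +
    ggplot2::annotate("point", x = attr(object, "argmin"),
                      y = attr(object, "minimum"), color = "firebrick") +
    ggplot2::labs(
      x = expression(Delta * theta ~ "(radians)"),
      y = sprintf("Pr(%s = %s)", attr(object, "target"),
                  attr(object, "state")),
      title = "Attainable probabilities over the interference phase",
      subtitle = "dashed: classical collapse at π/2; point: minimum"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a reproduction report
#'
#' Recomputed versus published cell values, colored by the registry's
#' self-consistency flag.
#'
#' @param object A `qlbn_report` from [reproduce_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.qlbn_report <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$reported))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reported, y = .data$value,
                                   color = .data$self_consistent)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$column), scales = "free") +
    ggplot2::labs(
      x = "published value", y = "recomputed value",
      color = "self-consistent",
      title = sprintf("Reproduction of comparison table %s",
                      attr(object, "table_id"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
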
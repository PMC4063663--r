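#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mechanism curves (q_segment versus Q)
#'
#' One panel per segment with the diagonal reference; a curve below the
#' diagonal at high Q marks a late-completing element.
#'
#' @param object a `mechanism_curves` tibble.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mechanism_curves <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Q_mid, y = .data$q_mean,
                                   colour = .data$segment)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$segment),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Q (fraction of native contacts)",
                  y = expression(q[segment]),
                  colour = "segment", fill = "segment") +
    ggplot2::theme_minimal()
}

#' Plot a specific-heat curve with the folding temperature marked
#'
#' @param object a `thermo_result`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.thermo_result <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$T, y = .data$Cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$Tf, linetype = "dotted") +
    ggplot2::annotate("text", x = object$Tf, y = max(object$cv$Cv),
                      label = paste0(" Tf = ", signif(object$Tf, 3)),
                      hjust = 0, vjust = 1) +
    ggplot2::labs(x = "T (epsilon)", y = "Cv") +
    ggplot2::theme_minimal()
}

#' Plot an NSD profile
#'
#' @param object an `nsd_profile`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.nsd_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$residue, y = .data$amplitude)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::labs(x = "residue", y = "slow-mode amplitude (A)") +
    ggplot2::theme_minimal()
}

#' Plot a reduced-minus-oxidized NSD comparison
#'
#' Bars for the two states, a line for the difference, shading over the
#' local bridge window.
#'
#' @param object an `nsd_difference`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.nsd_difference <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df, c("amplitude_red", "amplitude_ox"),
                              names_to = "state", values_to = "amplitude")
  long$state <- ifelse(long$state == "amplitude_red", "reduced", "oxidized")
  ggplot2::ggplot(long) +
    ggplot2::geom_col(ggplot2::aes(x = .data$residue, y = .data$amplitude,
                                   fill = .data$state),
                      position = "identity", alpha = 0.45, width = 1) +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(x = .data$residue, y = .data$delta),
                       colour = "goldenrod3", linewidth = 0.8) +
    ggplot2::scale_fill_manual(values = c(reduced = "steelblue",
                                          oxidized = "firebrick")) +
    ggplot2::labs(x = "residue", y = "amplitude (A); line: red - ox") +
    ggplot2::theme_minimal()
}

#' Plot the Q time series of a trajectory
#'
#' @param object a `plasso_traj`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.plasso_traj <- function(object, ...) {
  df <- as_tibble.plasso_traj(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$Q)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (reduced)", y = "Q") +
    ggplot2::theme_minimal()
}
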
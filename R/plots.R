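# ggplot2 views of trajectories and sweeps, styled after the published
# trajectory panels: site availability in gray, bound complex in gold, free
# site dotted blue.

#' Plot an occupancy trajectory
#'
#' @param object An `occu_sim` object.
#' @param ... Unused.
#' @return A ggplot: `B_total` (gray), bound complex `c` (gold), free site
#'   `B_free` (dotted blue) against dimensionless time.
#' @examples
#' autoplot(case_pcsk9("wt", 5.3))
#' @method autoplot occu_sim
#' @export
autoplot.occu_sim <- function(object, ...) {
  traj <- tidyr::pivot_longer(object$trajectory,
                              c("b_total", "c", "b_free"),
                              names_to = "series", values_to = "level")
  traj$series <- factor(traj$series, levels = c("b_total", "c", "b_free"),
                        labels = c("B[total]", "bound", "B[free]"))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$tau, y = .data$level,
                                     colour = .data$series,
                                     linetype = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c("grey50", "goldenrod3", "steelblue")) +
    ggplot2::scale_linetype_manual(values = c("solid", "solid", "dotted")) +
    ggplot2::labs(
      x = expression(tau == k[i] * t),
      y = expression("level (units of " * B[max] * ")"),
      colour = NULL, linetype = NULL,
      title = sprintf("Scenario %d: %s profile (peak c = %.2f)",
                      object$scenario, object$profile$label,
                      object$profile$c_peak)) +
    ggplot2::theme_minimal()
}

#' Plot a kon-sweep trajectory family
#'
#' @param sweep Result of [sweep_kon()].
#' @return A ggplot of bound-complex curves colored blue-to-red by
#'   increasing `kon`, over the gray site-availability curve.
#' @examples
#' plot_sweep(sweep_kon(10^(5:7), list(ki = 1e-4, k_minus_i = 1e-4,
#'                                     koff = 1e-4, L0 = 1e-9)))
#' @export
plot_sweep <- function(sweep) {
  traj <- sweep$trajectories
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$tau)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$b_total), colour = "grey60",
                       data = traj[traj$kon == traj$kon[1], ]) +
    ggplot2::geom_line(ggplot2::aes(y = .data$c, colour = factor(.data$kon),
                                    group = .data$kon), linewidth = 0.7) +
    ggplot2::scale_colour_viridis_d(option = "plasma", end = 0.9,
                                    name = expression(k[on])) +
    ggplot2::labs(x = expression(tau == k[i] * t),
                  y = "bound complex (units of site peak)") +
    ggplot2::theme_minimal()
}
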
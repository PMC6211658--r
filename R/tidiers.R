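# broom-style accessors for occu_sim objects.

#' Tidy an occupancy simulation into its trajectory
#'
#' @param x An `occu_sim` object.
#' @param ... Unused.
#' @return The trajectory tibble (`tau`, `time_s`, `b_total`, `b_free`, `c`,
#'   `f_occ`).
#' @examples
#' tidy(simulate_occupancy(1e5, 1e-4, 1e-4, 1e-4, 1e-9))
#' @method tidy occu_sim
#' @export
tidy.occu_sim <- function(x, ...) {
  x$trajectory
}

#' One-row summary of an occupancy simulation
#'
#' @param x An `occu_sim` object.
#' @param ... Unused.
#' @return One-row tibble combining the profile report with the dimensionless
#'   groups and input rates.
#' @examples
#' glance(simulate_occupancy(1e5, 1e-4, 1e-8, 1e-8, 1e-9))
#' @method glance occu_sim
#' @export
glance.occu_sim <- function(x, ...) {
  dplyr::bind_cols(
    x$profile,
    dplyr::select(x$groups, "kon", "koff", "ki", "k_minus_i", "L0",
                  "alpha", "beta", "gamma", "kd", "kd_prime", "koff_prime"),
    tibble(scenario = x$scenario, mode = x$mode, provenance = x$provenance)
  )
}
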
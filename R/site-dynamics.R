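# Time-dependent binding-site availability B_total(tau) under the two
# turnover scenarios, with settling times, anchors and the functional window.

#' Scenario anchor times
#'
#' Dimensionless landmarks of the site-availability curve. Scenario 1
#' (exponential species turnover) peaks at the normalized settling time
#' `xi_bar = 3`. Scenario 2 (logistic state gating) starts at 5% availability,
#' which fixes the buildup midpoint `tau01 = ln(19)`, the peak
#' `xi_bar = 3 + tau01`, and the decay midpoint `tau02 = 3 + xi_bar`.
#'
#' @param scenario 1 or 2.
#' @return One-row tibble with `scenario`, `tau01`, `xi_bar`, `tau02`.
#' @examples
#' scenario_anchors(2)
#' @export
scenario_anchors <- function(scenario) {
  scenario <- check_scenario(scenario)
  if (scenario == 1L) {
    tibble(scenario = 1L, tau01 = NA_real_, xi_bar = 3, tau02 = NA_real_)
  } else {
    tau01 <- log(19)
    xi_bar <- 3 + tau01
    tibble(scenario = 2L, tau01 = tau01, xi_bar = xi_bar, tau02 = 3 + xi_bar)
  }
}

#' Settling time of exponential site buildup
#'
#' Time for `B_total(t) = B_inf * (1 - exp(-ki * t))` to reach 95% of its
#' asymptote (`B_max = 0.95 * B_inf`): `-ln(0.05) / ki`, conventionally
#' quoted as `3 / ki`.
#'
#' @param ki Buildup rate constant (1/s), `> 0`.
#' @return Settling time in seconds.
#' @examples
#' settling_time(1)      # ~2.996 s
#' settling_time(1e-4)   # ~2.996e4 s
#' @export
settling_time <- function(ki) {
  check_positive(ki, "ki")
  -log(0.05) / ki
}

#' Exponential half-life
#'
#' @param k Rate constant (1/s), `> 0`.
#' @return `ln(2) / k`, in seconds.
#' @examples
#' half_life(1e-5) / 3600  # 19.25 hr
#' @export
half_life <- function(k) {
  check_positive(k, "k")
  log(2) / k
}

#' Normalized site availability, scenario 1 (species turnover)
#'
#' Piecewise saw-tooth law in dimensionless time `tau = ki * t`: exponential
#' buildup `(1 - exp(-tau)) / 0.95` up to the normalized settling time
#' `xi_bar = 3`, then exponential decay `exp(-gamma * (tau - 3))` with
#' `gamma = k_minus_i / ki`. Normalized so the maximum (at `tau = 3`) is 1,
#' in units of `B_max = 0.95 * B_inf`. The two branches carry the model's
#' small 0.95 truncation at the switch; `continuous = TRUE` rescales the decay
#' branch to the buildup value at `xi_bar` instead.
#'
#' @param tau Dimensionless time, `>= 0` (vectorized).
#' @param gamma Decay/buildup rate ratio `k_minus_i / ki`, `> 0`.
#' @param continuous Rescale the decay branch to join the buildup branch
#'   exactly at `tau = 3`? Default `FALSE` (the model's own convention).
#' @return Normalized availability values.
#' @examples
#' btotal_scenario1(c(0, 3, 3 + log(2)))
#' @export
btotal_scenario1 <- function(tau, gamma = 1, continuous = FALSE) {
  check_tau(tau)
  check_positive(gamma, "gamma")
  peak <- if (continuous) (1 - exp(-3)) / 0.95 else 1
  ifelse(tau < 3,
         (1 - exp(-tau)) / 0.95,
         peak * exp(-gamma * (tau - 3)))
}

#' Normalized site availability, scenario 2 (conformational gating)
#'
#' Bi-sigmoidal law: logistic rise `1 / (1 + exp(-(tau - tau01)))` up to the
#' peak at `xi_bar = 3 + ln(19)`, then logistic fall. Availability starts at
#' 5% (`tau = 0`) and peaks at ~0.95 at `xi_bar ~ 5.94`. For
#' `gamma = k_minus_i / ki != 1` the decay-branch steepness is scaled by
#' `gamma` about a shifted midpoint `xi_bar + 3 / gamma`, which keeps the
#' curve continuous at the switch and reduces to the canonical midpoint
#' `tau02 = 3 + xi_bar` at `gamma = 1`; such curves are extrapolations beyond
#' the matched-rate derivation.
#'
#' @inheritParams btotal_scenario1
#' @return Availability values in `[0, 1]` (raw logistic units; the maximum is
#'   `1/(1+exp(-3)) ~ 0.9526`, divide by it for a unit-peak curve).
#' @examples
#' btotal_scenario2(c(0, log(19), 3 + log(19)))
#' @export
btotal_scenario2 <- function(tau, gamma = 1) {
  check_tau(tau)
  check_positive(gamma, "gamma")
  a <- scenario_anchors(2)
  tau02g <- a$xi_bar + 3 / gamma
  ifelse(tau < a$xi_bar,
         1 / (1 + exp(-(tau - a$tau01))),
         1 - 1 / (1 + exp(-gamma * (tau - tau02g))))
}

# forcing term of the occupancy ODE, in units of B_inf (scenario 1) or raw
# logistic units (scenario 2); "continuous" joins the scenario-1 decay branch
# at 0.95 (the buildup value at the switch), "paper_literal" restarts it at 1.
btotal_forcing <- function(tau, scenario, gamma, mode = "continuous") {
  if (scenario == 1L) {
    amp <- if (mode == "continuous") 1 - exp(-3) else 1
    ifelse(tau < 3, 1 - exp(-tau), amp * exp(-gamma * (tau - 3)))
  } else {
    btotal_scenario2(tau, gamma)
  }
}

#' Tabulate a site-availability trajectory
#'
#' @param ki,k_minus_i Buildup and decay rate constants (1/s).
#' @param scenario 1 or 2.
#' @param tau_max,n_grid Grid: `n_grid` uniform points on `[0, tau_max]`
#'   (defaults 12 and 1201, one cycle at figure resolution).
#' @param normalize Scale so the grid maximum is 1 (default). Otherwise
#'   scenario-1 values are in `B_max` units and scenario-2 values in raw
#'   logistic units.
#' @return Tibble with `tau`, `time_s` (`tau / ki`) and `b_total`.
#' @examples
#' site_trajectory(1e-4, 1e-4, scenario = 1)
#' @export
site_trajectory <- function(ki, k_minus_i, scenario = 1, tau_max = 12,
                            n_grid = 1201, normalize = TRUE) {
  check_positive(ki, "ki"); check_positive(k_minus_i, "k_minus_i")
  scenario <- check_scenario(scenario)
  gamma <- k_minus_i / ki
  tau <- seq(0, tau_max, length.out = n_grid)
  b <- if (scenario == 1L) btotal_scenario1(tau, gamma) else btotal_scenario2(tau, gamma)
  if (normalize) b <- b / max(b)
  tibble(tau = tau, time_s = tau / ki, b_total = b)
}

#' Functional buildup + decay window
#'
#' Duration for which site availability stays at or above half its maximum --
#' the window over which the site can contribute to cellular function.
#' Scenario 1: `Lambda = (3 - ln 2)/ki + ln 2/k_minus_i`. Scenario 2 is derived
#' for matched rates, `Lambda = 2 ln 2 / ki`; with `ki != k_minus_i` the
#' half-life-based extrapolation `ln 2/ki + ln 2/k_minus_i` is returned and
#' flagged.
#'
#' @inheritParams site_trajectory
#' @return One-row tibble: `scenario`, `ki`, `k_minus_i`, `lambda_s` (seconds),
#'   `lambda_label` (human units), `extrapolated`.
#' @examples
#' functional_window(1e-2, 1e-2, scenario = 1)  # 300 s
#' functional_window(1e-4, 1e-6, scenario = 1)  # ~199 hr
#' @export
functional_window <- function(ki, k_minus_i, scenario = 1) {
  check_positive(ki, "ki"); check_positive(k_minus_i, "k_minus_i")
  scenario <- check_scenario(scenario)
  if (scenario == 1L) {
    lam <- (3 - log(2)) / ki + log(2) / k_minus_i
    extrap <- FALSE
  } else if (isTRUE(all.equal(ki, k_minus_i))) {
    lam <- 2 * log(2) / ki
    extrap <- FALSE
  } else {
    lam <- log(2) / ki + log(2) / k_minus_i
    extrap <- TRUE
  }
  tibble(scenario = scenario, ki = ki, k_minus_i = k_minus_i,
         lambda_s = lam, lambda_label = format_duration(lam),
         extrapolated = extrap)
}

# dimensionless [tau_lo, tau_hi] over which the occupancy profile is judged:
# the half-maximum window of the availability curve. Scenario 1 uses the
# half-B_inf crossings underlying the Lambda formula; scenario 2 uses the
# half-peak crossings of the logistic curve.
window_interval_tau <- function(scenario, gamma) {
  if (scenario == 1L) {
    c(log(2), 3 + log(2) / gamma)
  } else {
    a <- scenario_anchors(2)
    half <- 0.5 / (1 + exp(-3))        # half of the peak value
    lo <- a$tau01 + log(half / (1 - half))
    hi <- (a$xi_bar + 3 / gamma) - log(half / (1 - half)) / gamma
    c(lo, hi)
  }
}
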
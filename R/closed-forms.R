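# Closed-form solutions of the dimensionless occupancy equation
#   dc/dtau = alpha * u(tau) - s * c,   c(0) = 0
# where u(tau) is the site-availability forcing (saw-tooth for scenario 1,
# bi-logistic for scenario 2) and s is the bound-state relaxation rate
# (alpha + beta for matched buildup/decay rates).

.singular_tol <- 1e-8

singular_stop <- function(what) {
  abort(paste0("Closed form is singular (", what,
               " within tolerance); use the numeric solver."),
        class = "occudyn_use_numeric")
}

#' Closed-form occupancy, scenario 1 (saw-tooth site availability)
#'
#' Exact solution of the occupancy equation under exponential site buildup and
#' decay. The buildup branch is the three-eigenvalue form (modes at
#' `lambda1 = -s`, `lambda2 = -1`, `lambda3 = 0`); the decay branch depends on
#' `mode`:
#' \describe{
#'   \item{`"continuous"`}{(default) exact solution with the initial condition
#'     `c(xi_bar-)` carried over from the buildup branch and the forcing
#'     continuous at 95% of plateau -- this matches the numeric integration and
#'     the published trajectory families.}
#'   \item{`"paper_literal"`}{the verbatim decay-branch formula with its
#'     hard-coded `0.95 * c_inf` switch value, kept for reference.}
#' }
#' Near the removable singularities `s = 1` (buildup) and `s = gamma` (decay)
#' the function refuses with a condition of class `occudyn_use_numeric`;
#' callers such as [simulate_occupancy()] fall back to the ODE integrator.
#'
#' @param tau Dimensionless time `ki * t`, `>= 0` (vectorized).
#' @param alpha,beta,gamma Dimensionless groups (see [dimensionless_groups()]).
#' @param mode `"continuous"` or `"paper_literal"`.
#' @return Bound-complex level `c(tau)` in units of `B_max`.
#' @examples
#' c_closed_scenario1(3, alpha = 1.916, beta = 0.197)  # ~0.82
#' @export
c_closed_scenario1 <- function(tau, alpha, beta, gamma = 1,
                               mode = c("continuous", "paper_literal")) {
  check_tau(tau)
  check_positive(alpha, "alpha", allow_zero = TRUE)
  check_positive(beta, "beta", allow_zero = TRUE)
  check_positive(gamma, "gamma")
  mode <- match.arg(mode)
  if (alpha == 0) return(rep(0, length(tau)))
  s <- if (mode == "continuous") alpha + beta * gamma else alpha + beta
  if (abs(s - 1) < .singular_tol) singular_stop("alpha + beta = 1")
  if (abs(s - gamma) < .singular_tol) singular_stop("alpha + beta = gamma")
  if (s == 0) return(rep(0, length(tau)))

  buildup <- function(tt) {
    alpha * ((1 - exp(-s * tt)) / s - (exp(-tt) - exp(-s * tt)) / (s - 1))
  }
  out <- numeric(length(tau))
  up <- tau < 3
  out[up] <- buildup(tau[up])
  if (any(!up)) {
    dt <- tau[!up] - 3
    if (mode == "continuous") {
      c0 <- buildup(3)
      u0 <- 1 - exp(-3)   # forcing continuous at 95% of plateau
      out[!up] <- c0 * exp(-s * dt) +
        alpha * u0 * (exp(-gamma * dt) - exp(-s * dt)) / (s - gamma)
    } else {
      c_inf <- alpha / s
      out[!up] <- 0.95 * c_inf / (s - 1) * exp(-s * dt) *
        (alpha * exp((s - gamma) * dt) + beta - gamma)
    }
  }
  out
}

#' Closed-form occupancy, scenario 2 (bi-logistic site availability)
#'
#' Exact solution of the occupancy equation under logistic site buildup and
#' decay with matched rates (`gamma = 1`), built on the Gauss hypergeometric
#' function [hyp2f1_1b()]. The buildup branch integrates the logistic forcing
#' from `c(0) = 0`; the decay branch either carries the buildup value across
#' the switch (`mode = "continuous"`, default) or restarts from the published
#' `c_inf` switch value (`mode = "paper_literal"`). For `gamma != 1` use the
#' numeric solver ([simulate_occupancy()] does this automatically).
#'
#' @inheritParams c_closed_scenario1
#' @return Bound-complex level `c(tau)` in raw logistic site units (the site
#'   curve peaks at ~0.9526).
#' @examples
#' c_closed_scenario2(c(0, 6, 12), alpha = 2, beta = 2)
#' @export
c_closed_scenario2 <- function(tau, alpha, beta, gamma = 1,
                               mode = c("continuous", "paper_literal")) {
  check_tau(tau)
  check_positive(alpha, "alpha", allow_zero = TRUE)
  check_positive(beta, "beta", allow_zero = TRUE)
  mode <- match.arg(mode)
  if (abs(gamma - 1) > 1e-12) {
    abort("Scenario-2 closed form requires ki = k_minus_i (gamma = 1); use the numeric solver.",
          class = "occudyn_use_numeric")
  }
  s <- alpha + beta
  if (alpha == 0 || s == 0) return(rep(0, length(tau)))
  a <- scenario_anchors(2)

  # buildup: c(tau) = alpha e^{-tau01}/(s+1) [e^tau F1(tau) - e^{-s tau} F1(0)]
  # with F1(t) = 2F1(1, s+1; s+2; -e^{t - tau01})
  F1 <- function(t) hyp2f1_1b(s + 1, exp(t - a$tau01))
  buildup <- function(tt) {
    alpha * exp(-a$tau01) / (s + 1) *
      (exp(tt) * F1(tt) - exp(-s * tt) * F1(0))
  }
  # decay: c(tau) = [c0 - (alpha/s) F2(xi)] e^{-s (tau - xi)} + (alpha/s) F2(tau)
  # with F2(t) = 2F1(1, s; s+1; -e^{t - tau02})
  F2 <- function(t) hyp2f1_1b(s, exp(t - a$tau02))

  out <- numeric(length(tau))
  up <- tau < a$xi_bar
  out[up] <- buildup(tau[up])
  if (any(!up)) {
    c0 <- if (mode == "continuous") buildup(a$xi_bar) else alpha / s
    tt <- tau[!up]
    out[!up] <- (c0 - alpha / s * F2(a$xi_bar)) * exp(-s * (tt - a$xi_bar)) +
      alpha / s * F2(tt)
  }
  out
}
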
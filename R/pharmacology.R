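# Static occupancy algebra and the kinetic-tuning advisor.

#' Hill occupancy
#'
#' Non-competitive, non-cooperative equilibrium fractional occupancy
#' `L / (L + Kd)`. Under a steady-state (SSO) dynamic profile the same form
#' holds at every instant with the hijack-corrected `Kd'`.
#'
#' @param L Free ligand concentration (M), `>= 0`.
#' @param Kd Equilibrium dissociation constant (M), `> 0`.
#' @return Fractional occupancy in `[0, 1)`.
#' @examples
#' hill_occupancy(19e-9, 1e-9)  # 0.95
#' @export
hill_occupancy <- function(L, Kd) {
  check_positive(L, "L", allow_zero = TRUE)
  check_positive(Kd, "Kd")
  L / (L + Kd)
}

#' Occupancy under endogenous ligand competition
#'
#' Competitive Hill form `L / (L + Ki + Ki * Le / Ke)`: the apparent
#' inhibitory constant is inflated by `Ki * Le / Ke` when an endogenous
#' ligand at free concentration `Le` (equilibrium constant `Ke`) competes for
#' the same site. Reduces to [hill_occupancy()] at `Le = 0`.
#'
#' @param L Free drug concentration (M), `>= 0`.
#' @param Ki Inhibitory drug equilibrium constant (M), `> 0`.
#' @param Le Free endogenous ligand concentration (M), `>= 0`.
#' @param Ke Endogenous ligand equilibrium constant (M), `> 0`.
#' @return Fractional drug occupancy.
#' @examples
#' competitive_occupancy(L = 2e-9, Ki = 1e-9, Le = 1e-9, Ke = 1e-9)  # 0.5
#' @export
competitive_occupancy <- function(L, Ki, Le = 0, Ke = 1) {
  check_positive(L, "L", allow_zero = TRUE)
  check_positive(Ki, "Ki")
  check_positive(Le, "Le", allow_zero = TRUE)
  check_positive(Ke, "Ke")
  L / (L + Ki + Ki * Le / Ke)
}

#' Invert the Hill equation for the required ligand concentration
#'
#' Back-calculates the free concentration achieving a given fractional
#' occupancy: `Kd * occ / (1 - occ)`, i.e. the `n` in `L = n * Kd` is
#' `occ / (1 - occ)`.
#'
#' @param occupancy Target fractional occupancy, strictly in `(0, 1)`.
#' @param Kd Equilibrium dissociation constant (M), `> 0`.
#' @return Required concentration (M).
#' @examples
#' invert_hill(0.45, 5e-6)  # 4.1e-6 M
#' invert_hill(0.55, 5e-6)  # 6.1e-6 M
#' @export
invert_hill <- function(occupancy, Kd) {
  if (!is.numeric(occupancy) || anyNA(occupancy) ||
      any(occupancy <= 0 | occupancy >= 1)) {
    abort("`occupancy` must lie strictly in (0, 1).",
          class = "occudyn_domain_error")
  }
  check_positive(Kd, "Kd")
  Kd * occupancy / (1 - occupancy)
}

#' Kinetic-tuning advisor
#'
#' Applies the tuning ladder for optimizing dynamic occupancy: first speed
#' `kon` to at least `konSS = 10 * ki / L0` (below it, slowing `koff` --
#' lengthening residence time -- is futile), then slow `koff` down to the site
#' decay rate `k_minus_i` (beyond it, `koff` is hijacked and further slowing
#' adds nothing). Advisories:
#' \describe{
#'   \item{`speed_kon_first`}{`kon < konSS`; the report carries the ligand
#'     concentration that would compensate instead (`10 * ki / kon`).}
#'   \item{`concentration_compensation_needed`}{`kon < konSS` and `konSS`
#'     exceeds the diffusion limit, so only dose can compensate.}
#'   \item{`slow_koff_within_k_minus_i`}{`kon >= konSS` but `koff > k_minus_i`:
#'     residence-time gains are still available.}
#'   \item{`tuned`}{`kon >= konSS` and `koff <= k_minus_i`: occupancy is
#'     dose-limited; further koff slowing is futile.}
#' }
#'
#' @inheritParams effective_kinetics
#' @inheritParams kon_ss
#' @param k_minus_i Site decay rate constant (1/s).
#' @param target_occupancy Desired fractional occupancy, in `(0, 1)`.
#' @param diffusion_limit Fastest physically plausible `kon` (1/M/s),
#'   default `1e9`.
#' @return One-row tibble: `kon_ss`, `kon_ratio`, `hijacked`, `koff_prime`,
#'   `kd_prime`, `n_required` (`L = n * Kd'` for the target under SSO),
#'   `L_required` (M), `L_compensation` (M; dose giving `alpha = 10` at the
#'   current `kon`, `NA` unless advisory is kon-limited), `advisory`.
#' @examples
#' tuning_report(kon = 5e5, koff = 5e-1, ki = 1e-2, k_minus_i = 1e-2,
#'               L0 = 1e-9, target_occupancy = 0.5)
#' @export
tuning_report <- function(kon, koff, ki, k_minus_i, L0,
                          target_occupancy = 0.5, diffusion_limit = 1e9) {
  if (length(target_occupancy) != 1 || !is.numeric(target_occupancy) ||
      target_occupancy <= 0 || target_occupancy >= 1) {
    abort("`target_occupancy` must lie strictly in (0, 1).",
          class = "occudyn_domain_error")
  }
  eff <- effective_kinetics(kon, koff, k_minus_i)
  kss <- kon_ss(ki, L0)
  kon_ratio <- kon / kss
  n_required <- target_occupancy / (1 - target_occupancy)
  advisory <- if (kon < kss) {
    if (kss > diffusion_limit) "concentration_compensation_needed" else "speed_kon_first"
  } else if (koff > k_minus_i) {
    "slow_koff_within_k_minus_i"
  } else {
    "tuned"
  }
  tibble(
    kon = kon, koff = koff, ki = ki, k_minus_i = k_minus_i, L0 = L0,
    kon_ss = kss, kon_ratio = kon_ratio,
    hijacked = eff$hijacked, koff_prime = eff$koff_prime,
    kd_prime = eff$kd_prime,
    n_required = n_required,
    L_required = n_required * eff$kd_prime,
    L_compensation = if (kon < kss) 10 * ki / kon else NA_real_,
    advisory = advisory
  )
}
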
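# Rate-constant algebra: koff hijacking, the konSS rule, and the
# dimensionless groups that drive the closed-form occupancy solutions.

#' Effective (hijack-corrected) dissociation kinetics
#'
#' Site decay sets a floor under dissociation: a complex cannot outlive its
#' binding site, so when `koff <= k_minus_i` the observable off-rate is
#' "hijacked" by site decay, `koff' = k_minus_i`, and the effective
#' equilibrium constant rises to `Kd' = koff' / kon >= Kd`.
#'
#' @param kon Association rate constant (1/M/s), `> 0`.
#' @param koff Dissociation rate constant (1/s), `>= 0`.
#' @param k_minus_i Binding-site decay rate constant (1/s), `> 0`.
#' @return Tibble (vectorized over inputs) with `kon`, `koff`, `kd`,
#'   `koff_prime`, `kd_prime`, `hijacked`.
#' @examples
#' effective_kinetics(4.57e3, 3.64e-4, 2.3e-3)  # hijacked: koff' = 2.3e-3
#' @export
effective_kinetics <- function(kon, koff, k_minus_i) {
  check_positive(kon, "kon")
  check_positive(koff, "koff", allow_zero = TRUE)
  check_positive(k_minus_i, "k_minus_i")
  n <- max(length(kon), length(koff), length(k_minus_i))
  kon <- rep_len(kon, n); koff <- rep_len(koff, n)
  k_minus_i <- rep_len(k_minus_i, n)
  hijacked <- koff <= k_minus_i
  koff_prime <- ifelse(hijacked, k_minus_i, koff)
  tibble(kon = kon, koff = koff, kd = koff / kon,
         koff_prime = koff_prime, kd_prime = koff_prime / kon,
         hijacked = hijacked)
}

#' Hijack-corrected dissociation rate
#'
#' Scalar shortcut for the `koff'` rule: `max(koff, k_minus_i)`.
#'
#' @inheritParams effective_kinetics
#' @return Numeric vector of `koff'` values (1/s).
#' @examples
#' effective_koff(3.64e-4, 2.3e-3)
#' @export
effective_koff <- function(koff, k_minus_i) {
  check_positive(koff, "koff", allow_zero = TRUE)
  check_positive(k_minus_i, "k_minus_i")
  pmax(koff, k_minus_i)
}

#' Minimum association rate for steady-state occupancy (konSS)
#'
#' For bound-complex buildup to keep pace with binding-site buildup, the
#' dimensionless on-rate `alpha = kon * L0 / ki` must reach about 10,
#' i.e. `konSS = 10 * ki / L0`. Below this threshold the occupancy profile is
#' non-steady-state regardless of how slow `koff` is.
#'
#' @param ki Binding-site buildup rate constant (1/s), `> 0`.
#' @param L0 Free ligand concentration (M), `> 0`.
#' @param prefactor The `alpha >~ 10` threshold; exposed for sensitivity
#'   analyses, default 10.
#' @return Required association rate constant (1/M/s).
#' @examples
#' kon_ss(1e-4, 1e-9)  # 1e6
#' kon_ss(1e-2, 1e-9)  # 1e8
#' @export
kon_ss <- function(ki, L0, prefactor = 10) {
  check_positive(ki, "ki")
  check_positive(L0, "L0")
  check_positive(prefactor, "prefactor")
  prefactor * ki / L0
}

#' Dimensionless groups of the occupancy system
#'
#' Recasts rates and dose into the groups driving the closed-form solutions:
#' `alpha = kon * L0 / ki` (on-flux vs site buildup), `beta = koff' / k_minus_i`
#' (dissociation vs site decay), `gamma = k_minus_i / ki`. The relaxation rate
#' of the bound state in `tau = ki * t` units is `s = alpha + beta * gamma`
#' (`= alpha + beta` for matched rates, the eigenvalue `-lambda1`), and the
#' long-time fractional plateau is
#' `c_inf = alpha / s = kon * L0 / (kon * L0 + koff')`.
#'
#' @inheritParams effective_kinetics
#' @inheritParams kon_ss
#' @return One-row tibble: `alpha`, `beta`, `gamma`, `s`, `lambda1` (`-s`),
#'   `lambda2` (-1), `lambda3` (0), `c_inf`, `koff_prime`, `kd_prime`,
#'   `hijacked`, `n_mult` (`L0 / Kd'`), `kon_ss`, plus the input rates.
#' @param hijack Apply the `koff'` correction (default `TRUE`). Set `FALSE`
#'   when `koff` is already an effective (corrected) rate, as in the packaged
#'   PCSK9 table.
#' @examples
#' dimensionless_groups(kon = 1e5, koff = 1e-4, ki = 1e-4, k_minus_i = 1e-4,
#'                      L0 = 1e-9)  # alpha = beta = 1
#' @export
dimensionless_groups <- function(kon, koff, ki, k_minus_i, L0, hijack = TRUE) {
  check_positive(ki, "ki")
  check_positive(L0, "L0", allow_zero = TRUE)
  eff <- effective_kinetics(kon, koff, k_minus_i)
  if (!hijack) {
    eff$koff_prime <- eff$koff
    eff$kd_prime <- eff$kd
    eff$hijacked <- FALSE
  }
  alpha <- kon * L0 / ki
  beta <- eff$koff_prime / k_minus_i
  gamma <- k_minus_i / ki
  s <- alpha + beta * gamma
  tibble(
    kon = kon, koff = koff, ki = ki, k_minus_i = k_minus_i, L0 = L0,
    alpha = alpha, beta = beta, gamma = gamma, s = s,
    lambda1 = -s, lambda2 = -1, lambda3 = 0,
    c_inf = alpha / s,
    koff_prime = eff$koff_prime, kd = eff$kd, kd_prime = eff$kd_prime,
    hijacked = eff$hijacked,
    n_mult = if (all(eff$kd_prime > 0)) L0 / eff$kd_prime else NA_real_,
    kon_ss = if (L0 > 0) kon_ss(ki, L0) else Inf
  )
}

#' Equilibrium fractional occupancy of the dimensionless system
#'
#' Long-time limit of the bound fraction: `alpha / (alpha + beta)` for
#' matched buildup/decay rates, equivalently `kon L0 / (kon L0 + koff')`.
#'
#' @param alpha,beta Dimensionless on- and off-rate groups, `>= 0`, not both 0.
#' @return Fractional occupancy in `[0, 1]`.
#' @examples
#' c_equilibrium(19, 1)  # 0.95
#' @export
c_equilibrium <- function(alpha, beta) {
  check_positive(alpha, "alpha", allow_zero = TRUE)
  check_positive(beta, "beta", allow_zero = TRUE)
  if (any(alpha + beta == 0)) {
    abort("`alpha + beta` must be > 0.", class = "occudyn_domain_error")
  }
  alpha / (alpha + beta)
}
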
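test_that("free + bound sites reconstruct total availability on every grid point", {
  for (scn in 1:2) {
    sim <- simulate_occupancy(1e5, 1e-4, 1e-3, 1e-3, 1e-9, scenario = scn)
    traj <- sim$trajectory
    expect_equal(traj$b_free + traj$c, traj$b_total, tolerance = 1e-12)
    expect_true(all(traj$c >= 0))
    expect_true(all(traj$c <= traj$b_total + 1e-6))
  }
})

test_that("closed form and ODE integration agree on randomized matched-rate systems", {
  set.seed(99)
  tau <- seq(0, 12, length.out = 301)
  n_ok <- 0
  while (n_ok < 25) {
    alpha <- r_logunif(1, 0.1, 50)
    beta <- r_logunif(1, 0.1, 50)
    if (abs(alpha + beta - 1) < 1e-3) next
    g <- tibble::tibble(alpha = alpha, beta = beta, gamma = 1, s = alpha + beta)
    cc <- c_closed_scenario1(tau, alpha, beta, 1)
    cn <- solve_occupancy_numeric(g, tau, scenario = 1)
    expect_lt(max(abs(cc - cn)), 1e-6)
    n_ok <- n_ok + 1
  }
})

test_that("equilibrium-regime run holds 95% fractional occupancy throughout", {
  # slow turnover, dose at 19 * Kd: the bound fraction is pinned at 0.95
  sim <- simulate_occupancy(kon = 1e5, koff = 1e-4, ki = 1e-8, k_minus_i = 1e-8,
                            L0 = 19e-9)
  f <- sim$trajectory$f_occ
  f <- f[is.finite(f)][-1]   # skip the start-up sliver at tau ~ 0
  expect_true(all(abs(f - 0.95) < 0.01))
  expect_equal(sim$profile$label, "SSO")
})

test_that("peak occupancy is non-decreasing along a kon ladder", {
  kons <- 10^seq(5, 7, length.out = 10)
  peaks <- vapply(kons, function(k) {
    sim <- simulate_occupancy(kon = k, koff = k * 1e-9, ki = 1e-4,
                              k_minus_i = 1e-4, L0 = 1e-9)
    peak_occupancy(sim)$c_peak
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-12))
})

test_that("slowing koff 1e5-fold is futile when kon is far below konSS", {
  # fast turnover (5-min window), kon 1000-fold below konSS = 1e8
  base <- function(koff) {
    simulate_occupancy(kon = 1e5, koff = koff, ki = 1e-2, k_minus_i = 1e-2,
                       L0 = 1e-9)$trajectory$c
  }
  c_fast <- base(5e-1)
  c_slow <- base(5e-6)
  expect_lt(max(abs(c_slow - c_fast)), 0.01)
})

test_that("profile classification reproduces the published regimes", {
  # slow turnover at L0 = Kd: 50% steady-state occupancy regardless of kon
  sso <- simulate_occupancy(1e5, 1e-4, 1e-8, 1e-8, 1e-9)
  expect_equal(sso$profile$label, "SSO")
  expect_equal(sso$profile$c_inf, 0.5)

  # fast turnover with kon 1000-fold below konSS: nearly zero occupancy
  nsso <- simulate_occupancy(1e5, 1e-4, 1e-2, 1e-2, 1e-9)
  expect_equal(nsso$profile$label, "nSSO")
  expect_lt(nsso$profile$c_peak, 0.01)

  # konSS boundary: kon = konSS classifies steady, 10-fold below does not
  at_kss <- simulate_occupancy(1e4, 1e-5, 1e-6, 1e-6, 1e-9)
  expect_equal(at_kss$profile$label, "SSO")
  below <- simulate_occupancy(1e3, 1e-6, 1e-6, 1e-6, 1e-9)
  expect_false(below$profile$label == "SSO")

  # saturating dose rescues a slow kon only into the quasi-steady regime
  qsso <- simulate_occupancy(1e4, 1e-5, 1e-3, 1e-3, 1e-6)
  expect_true(qsso$profile$label %in% c("SSO", "qSSO"))
})

test_that("vanishing turnover recovers the Hill limit", {
  sim <- simulate_occupancy(kon = 1e5, koff = 1e-4, ki = 1e-8, k_minus_i = 1e-8,
                            L0 = 1e-9)
  f <- sim$trajectory$f_occ
  f <- f[is.finite(f)][-1]
  expect_true(all(abs(f - hill_occupancy(1e-9, 1e-9)) < 0.01))
  expect_equal(sim$profile$label, "SSO")
})

test_that("peak extraction and solver input validation behave", {
  mono <- tibble::tibble(tau = 0:10, c = seq(0, 1, length.out = 11))
  pk <- peak_occupancy(mono)
  expect_equal(pk$tau_peak, 10)
  expect_error(peak_occupancy(tibble::tibble()), class = "occudyn_domain_error")

  g <- dimensionless_groups(1e5, 1e-4, 1e-4, 1e-4, 1e-9)
  expect_error(solve_occupancy_numeric(g, c(1, 0.5)),
               class = "occudyn_domain_error")
})

test_that("auto method falls back to the integrator at closed-form singularities", {
  # alpha + beta = 1 exactly: scenario-1 closed form is singular
  sim <- simulate_occupancy(kon = 5e4, koff = 5e-5, ki = 1e-4, k_minus_i = 1e-4,
                            L0 = 1e-9, hijack = FALSE)
  expect_equal(sim$provenance, "numeric")
  expect_error(
    simulate_occupancy(5e4, 5e-5, 1e-4, 1e-4, 1e-9, method = "closed",
                       hijack = FALSE),
    class = "occudyn_use_numeric")
  # gamma != 1 in scenario 2 also runs numeric
  sim2 <- simulate_occupancy(1e5, 0.5, 13, 2.1, 1e-5, scenario = 2)
  expect_equal(sim2$provenance, "numeric")
})
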
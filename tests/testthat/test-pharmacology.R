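test_that("Hill occupancy and its inverse reproduce the worked concentrations", {
  expect_equal(hill_occupancy(1e-9, 1e-9), 0.5)
  expect_equal(hill_occupancy(19e-9, 1e-9), 0.95)
  expect_equal(hill_occupancy(0, 1e-9), 0)
  # back-calculated pro-arrhythmic concentrations at Kd = 5 uM
  expect_equal(signif(invert_hill(0.45, 5e-6), 2), 4.1e-6)
  expect_equal(signif(invert_hill(0.55, 5e-6), 2), 6.1e-6)
  expect_equal(invert_hill(0.5, 5e-6), 5e-6)
  expect_error(hill_occupancy(1e-9, 0), class = "occudyn_domain_error")
  expect_error(invert_hill(1, 1e-9), class = "occudyn_domain_error")
  expect_error(invert_hill(0, 1e-9), class = "occudyn_domain_error")
})

test_that("Hill and inverse Hill are mutual inverses across the occupancy range", {
  occ <- seq(0.01, 0.99, by = 0.01)
  kd <- 3.7e-8
  round_trip <- hill_occupancy(invert_hill(occ, kd), kd)
  expect_equal(round_trip, occ, tolerance = 1e-12)
  L <- 10^seq(-12, -3, length.out = 50)
  expect_equal(invert_hill(hill_occupancy(L, kd), kd), L, tolerance = 1e-12)
})

test_that("competition inflates the apparent Ki and only vanishes with the competitor", {
  expect_equal(competitive_occupancy(3e-9, 1e-9, Le = 0, Ke = 1e-9),
               hill_occupancy(3e-9, 1e-9))
  # Ki = Ke: half-occupancy at L = Ki + Le
  Ki <- 2e-9; Le <- 5e-9
  expect_equal(competitive_occupancy(Ki + Le, Ki, Le, Ki), 0.5)
  # strictly decreasing in Le at fixed L
  Le_grid <- seq(0, 1e-7, length.out = 30)
  occ <- competitive_occupancy(1e-8, 1e-9, Le_grid, 1e-9)
  expect_true(all(diff(occ) < 0))
  # never exceeds the non-competitive value
  set.seed(11)
  L <- r_logunif(100, 1e-12, 1e-5); Ki <- r_logunif(100, 1e-12, 1e-5)
  Le <- r_logunif(100, 1e-12, 1e-5); Ke <- r_logunif(100, 1e-12, 1e-5)
  expect_true(all(competitive_occupancy(L, Ki, Le, Ke) <=
                    hill_occupancy(L, Ki) + 1e-15))
})

test_that("tuning advisor reproduces the kinetic-tuning ladder", {
  # kon far below konSS = 1e8: speed kon first (residence time is futile)
  slow_on <- tuning_report(kon = 5e5, koff = 5e-1, ki = 1e-2, k_minus_i = 1e-2,
                           L0 = 1e-9)
  expect_equal(slow_on$advisory, "speed_kon_first")
  expect_equal(slow_on$kon_ss, 1e8)

  # kon above konSS but koff still faster than site decay: slow koff next
  fast_on <- tuning_report(kon = 5e8, koff = 5e-1, ki = 1e-2, k_minus_i = 1e-2,
                           L0 = 1e-9)
  expect_equal(fast_on$advisory, "slow_koff_within_k_minus_i")

  # both conditions met: tuned, further koff slowing adds nothing
  tuned <- tuning_report(kon = 5e8, koff = 5e-5, ki = 1e-2, k_minus_i = 1e-2,
                         L0 = 1e-9)
  expect_equal(tuned$advisory, "tuned")
  expect_true(tuned$hijacked)

  # konSS beyond the diffusion limit: only dose can compensate
  undiff <- tuning_report(kon = 1e6, koff = 1e0, ki = 1e1, k_minus_i = 1e1,
                          L0 = 1e-9)
  expect_equal(undiff$advisory, "concentration_compensation_needed")

  # required multiple follows the inverse Hill form with Kd'
  expect_equal(tuned$n_required, 1)
  n95 <- tuning_report(5e8, 5e-5, 1e-2, 1e-2, 1e-9, target_occupancy = 0.95)
  expect_equal(n95$n_required, 19)
  expect_equal(n95$L_required, 19 * n95$kd_prime)
})

test_that("tuning advisory is a pure function of kon ratio and koff vs site decay", {
  set.seed(23)
  for (i in 1:100) {
    kon <- r_logunif(1, 1e2, 1e10)
    koff <- r_logunif(1, 1e-7, 1e1)
    ki <- r_logunif(1, 1e-7, 1e1)
    kmi <- r_logunif(1, 1e-7, 1e1)
    L0 <- r_logunif(1, 1e-11, 1e-6)
    rep <- tuning_report(kon, koff, ki, kmi, L0)
    kss <- 10 * ki / L0
    want <- if (kon < kss) {
      if (kss > 1e9) "concentration_compensation_needed" else "speed_kon_first"
    } else if (koff > kmi) "slow_koff_within_k_minus_i" else "tuned"
    expect_equal(rep$advisory, want)
    expect_equal(rep$kon_ratio, kon / kss)
  }
})

test_that("futility of extra residence time shows up in the trajectories once tuned", {
  # kon >= konSS: slowing koff raises occupancy...
  hi <- function(koff) {
    peak_occupancy(simulate_occupancy(5e8, koff, 1e-2, 1e-2, 1e-9))$c_peak
  }
  expect_gt(hi(5e-2), hi(5e-1))
  # ...until koff reaches the site decay rate; beyond that, nothing changes
  expect_equal(hi(5e-5), hi(5e-7), tolerance = 1e-9)
})
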
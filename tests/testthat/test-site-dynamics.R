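test_that("settling time is -ln(0.05)/ki and scales inversely with ki", {
  expect_equal(settling_time(1), 2.9957, tolerance = 1e-4)
  expect_equal(settling_time(1e-4), -log(0.05) / 1e-4)
  expect_equal(settling_time(2 * 0.37), settling_time(0.37) / 2)
  expect_error(settling_time(0), class = "occudyn_domain_error")
  # buildup law reaches exactly 95% of its asymptote at the settling time
  expect_equal(1 - exp(-1e-3 * settling_time(1e-3)), 0.95)
})

test_that("half-life reproduces the printed turnover grid entries", {
  expect_equal(half_life(1e-5) / 3600, 19.25, tolerance = 1e-3)
  expect_equal(half_life(8e-4) / 60, 14.4, tolerance = 1e-2)
  expect_equal(half_life(log(2)), 1)
  expect_error(half_life(-1), class = "occudyn_domain_error")
})

test_that("scenario-1 availability starts at zero, peaks at tau = 3, halves per decay half-life", {
  expect_equal(btotal_scenario1(0), 0)
  tau <- seq(0, 12, length.out = 1201)
  expect_equal(tau[which.max(btotal_scenario1(tau))], 3)
  expect_equal(btotal_scenario1(3 + log(2), gamma = 1), 0.5)
  expect_error(btotal_scenario1(-0.1), class = "occudyn_domain_error")
})

test_that("scenario-2 availability starts at 5%, crosses 50% at tau01, peaks near 6", {
  a <- scenario_anchors(2)
  expect_equal(a$tau01, log(19))
  expect_equal(a$xi_bar, 3 + log(19))
  expect_equal(a$tau02, 6 + log(19))
  expect_equal(btotal_scenario2(0), 0.05)
  expect_equal(btotal_scenario2(a$tau01), 0.5)
  tau <- seq(0, 12, length.out = 1201)
  peak_tau <- tau[which.max(btotal_scenario2(tau))]
  expect_equal(peak_tau, a$xi_bar, tolerance = 0.011)
  expect_equal(peak_tau, 6, tolerance = 0.1)
  expect_error(btotal_scenario2(-1), class = "occudyn_domain_error")
})

test_that("availability curves are nonnegative and unimodal with a single switch", {
  tau <- seq(0, 12, length.out = 2401)
  for (gamma in c(0.1, 1, 5)) {
    for (fn in list(btotal_scenario1, btotal_scenario2)) {
      b <- fn(tau, gamma = gamma)
      expect_true(all(b >= 0))
      i <- which.max(b)
      expect_true(all(diff(b[seq_len(i)]) >= -1e-12))
      expect_true(all(diff(b[i:length(b)]) <= 1e-12))
    }
  }
})

test_that("scenario-2 decay branch stays continuous at the switch for any gamma", {
  a <- scenario_anchors(2)
  for (gamma in c(2.1 / 13, 0.5, 1, 4)) {
    lhs <- btotal_scenario2(a$xi_bar - 1e-9, gamma = gamma)
    rhs <- btotal_scenario2(a$xi_bar, gamma = gamma)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("functional window reproduces printed values and the exact matched-rate identity", {
  expect_equal(functional_window(1e-2, 1e-2, 1)$lambda_s, 300)
  expect_equal(functional_window(1e-4, 1e-6, 1)$lambda_s / 3600, 199,
               tolerance = 0.01)
  expect_equal(functional_window(1e-4, 1e-4, 2)$lambda_s / 3600, 3.85,
               tolerance = 0.01)
  # Lambda * ki = 3 exactly at matched rates (scenario 1)
  for (ki in c(1e-6, 1e-3, 2)) {
    expect_equal(functional_window(ki, ki, 1)$lambda_s * ki, 3)
  }
  expect_true(functional_window(13, 2.1, 2)$extrapolated)
  expect_false(functional_window(1e-4, 1e-6, 1)$extrapolated)
  expect_error(functional_window(0, 1, 1), class = "occudyn_domain_error")
})

test_that("scenario-1 window formula equals the measured half-maximum width", {
  set.seed(421)
  ki <- r_logunif(20, 1e-8, 10)
  kmi <- r_logunif(20, 1e-8, 10)
  for (i in seq_along(ki)) {
    lam <- functional_window(ki[i], kmi[i], 1)$lambda_s
    meas <- measure_window_s1(ki[i], kmi[i])
    expect_equal(lam, meas, tolerance = 0.02,
                 label = sprintf("ki=%g k-i=%g formula", ki[i], kmi[i]))
  }
})

test_that("site_trajectory returns a normalized tibble on the figure grid", {
  st <- site_trajectory(1e-4, 1e-4, scenario = 1)
  expect_s3_class(st, "tbl_df")
  expect_equal(nrow(st), 1201)
  expect_equal(max(st$b_total), 1)
  expect_equal(st$time_s, st$tau / 1e-4)
  st2 <- site_trajectory(1e-3, 1e-3, scenario = 2)
  expect_equal(max(st2$b_total), 1)
})
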
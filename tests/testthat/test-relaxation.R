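test_that("layer 0 relaxes as an exact exponential and output stays bounded", {
  p <- base_fsf()
  tr <- simulate_relaxation(heinrich_model(p), grid = tau_grid(n = 150),
                            full_state = TRUE)
  ref <- steady_state_gains(p)$m_tilde[1] * exp(-p$beta[1] * tr$time)
  expect_lt(max(abs(tr$state[, 1] - ref)), 1e-6)
  expect_true(all(tr$output >= 0))
  expect_true(all(tr$state <= matrix(p$m_tot, nrow(tr$state), 3,
                                     byrow = TRUE) + 1e-9))
  expect_lt(tr$output[length(tr$output)], tr$output0)
  expect_true(all(diff(tr$time) > 0))
})

test_that("halving solver tolerances leaves the trajectory unchanged", {
  p <- cascade_params(c(50, 50, 50), c(2, 0.05, 1))
  m <- heinrich_model(p)
  g <- tau_grid(n = 100)
  a <- simulate_relaxation(m, grid = g, rtol = 1e-8, atol = 1e-12)
  b <- simulate_relaxation(m, grid = g, rtol = 5e-9, atol = 5e-13)
  expect_equal(a$output, b$output, tolerance = 1e-6)
})

test_that("single-stage half-life equals ln(2)/beta in every model", {
  for (b in c(0.5, 3)) {
    p1 <- cascade_params(2, b, 1, 1)
    expect_equal(half_life(heinrich_model(p1)), log(2) / b,
                 tolerance = 1e-7)
    expect_equal(half_life(linearized_model(p1)), log(2) / b,
                 tolerance = 1e-7)
  }
})

test_that("root-refined half-life agrees with a brute-force oracle", {
  for (p in random_params_pool(4)) {
    theta <- half_life(linearized_model(p))
    expect_equal(theta, half_life_bruteforce(p), tolerance = 1e-6)
  }
})

test_that("nonlinear and linearized half-lives follow the slow-mode formula", {
  # slow rate 100x below the others: the approximation is within 5%
  p <- cascade_params(c(100, 100, 100), c(0.01, 1, 10))
  th <- half_life(linearized_model(p))
  expect_equal(duration_approx(linearized_solution(p)), th,
               tolerance = 0.05)
})

test_that("half-life is covariant under time rescaling", {
  p <- base_fsf()
  th <- half_life(heinrich_model(p))
  for (s in c(10, 0.1)) {
    ps <- cascade_params(p$alpha_bar * s, p$beta * s, p$m_tot, p$e0_init)
    expect_equal(half_life(heinrich_model(ps)), th / s, tolerance = 1e-6)
    expect_equal(half_life(linearized_model(ps)),
                 half_life(linearized_model(p)) / s, tolerance = 1e-6)
  }
})

test_that("half-life search extends its horizon for very slow relaxation", {
  # slow mode at 1e-5: theta ~ 7e5, beyond the default search horizon
  p <- cascade_params(c(100, 100, 100), c(1e-5, 1, 10))
  th_non <- half_life(heinrich_model(p))
  th_lin <- half_life(linearized_model(p))
  expect_gt(th_non, 6e4)
  expect_gt(th_lin, 6e4)
  # the linearized value obeys the slow-mode closed form tightly here
  expect_equal(th_lin, duration_approx(linearized_solution(p)),
               tolerance = 1e-4)
  # the nonlinear model shares the slow-mode timescale (prefactor differs
  # through saturation, shifting theta only logarithmically)
  expect_equal(th_non, th_lin, tolerance = 0.15)
})

test_that("Heinrich closed-form steady state matches the relaxation start", {
  p <- base_fsf()
  ss <- pre_stimulus_steady_state(heinrich_model(p))
  expect_s3_class(ss, "steady_state")
  tr <- simulate_relaxation(heinrich_model(p),
                            grid = tau_grid(-4, 0, n = 50))
  # early output is continuous with the pre-stimulus value
  expect_equal(tr$output[1], ss$m_tilde[3], tolerance = 1e-3)
})
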
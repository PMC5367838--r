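test_that("effective kinase activities follow their definition", {
  p <- cascade_params(alpha_bar = c(1, 0.1, 2), beta = c(1, 1, 1),
                      m_tot = c(50, 20, 10), e0_init = 100)
  a <- effective_alphas(p)
  expect_equal(a[1], 100)   # alpha_bar[1] * e0_init
  expect_equal(a[2], 5)     # alpha_bar[2] * m_tot[1]
  expect_equal(a[3], 40)    # alpha_bar[3] * m_tot[2]
  # alpha_0 vanishes with the stimulus
  p2 <- cascade_params(c(1, 0.1, 2), c(1, 1, 1), c(50, 20, 10),
                       e0_init = 1e-12)
  expect_lt(effective_alphas(p2)[1], 1e-11)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(cascade_params(c(1, 1), c(1, 1, 1)), "equal length")
  expect_error(cascade_params(c(1, -1, 1), c(1, 1, 1)), "positive")
  expect_error(steady_state_gains(c(1, 1), c(1, 1, 1)), "equal length")
})

test_that("steady-state gain recursion matches closed forms and the ODE limit", {
  # alpha_i = beta_i gives the harmonic sequence 1/2, 1/3, 1/4
  expect_equal(steady_state_gains(c(2, 3, 4), c(2, 3, 4))$g,
               c(1 / 2, 1 / 3, 1 / 4))
  # no dephosphorylation: full phosphorylation
  expect_equal(steady_state_gains(c(5, 5, 5), c(0, 0, 0))$g, rep(1, 3))
  # fast kinases: g2 near 1 (frozen from the recursion)
  g <- steady_state_gains(c(100, 100, 100), c(1, 1, 1))$g
  expect_equal(g[3], 0.9900, tolerance = 1e-4)
  # long-time limit of the stimulated nonlinear system agrees
  p <- cascade_params(alpha_bar = c(100, 100, 100), beta = c(1, 1, 1))
  expect_equal(stimulated_heinrich_limit(p),
               steady_state_gains(p)$m_tilde, tolerance = 1e-6)
  p2 <- base_fsf()
  expect_equal(stimulated_heinrich_limit(p2),
               steady_state_gains(p2)$m_tilde, tolerance = 1e-6)
})

test_that("gains are monotone in rates and blind to downstream parameters", {
  for (p in random_params_pool(4)) {
    g0 <- steady_state_gains(p)$g
    for (j in 1:3) {
      up_b <- p; up_b$beta[j] <- p$beta[j] * 2
      g_b <- steady_state_gains(cascade_params(up_b$alpha_bar, up_b$beta,
                                               up_b$m_tot, up_b$e0_init))$g
      up_a <- p; up_a$alpha_bar[j] <- p$alpha_bar[j] * 2
      g_a <- steady_state_gains(cascade_params(up_a$alpha_bar, up_a$beta,
                                               up_a$m_tot, up_a$e0_init))$g
      for (i in 1:3) {
        if (i >= j) {
          expect_lt(g_b[i], g0[i])   # more phosphatase: less activation
          expect_gt(g_a[i], g0[i])   # more kinase: more activation
        } else {
          expect_identical(g_b[i], g0[i])  # upstream blind to downstream
          expect_identical(g_a[i], g0[i])
        }
      }
    }
  }
})

test_that("post-stimulus RHS has the right structure", {
  p <- base_fsf()
  expect_equal(heinrich_rhs(c(0, 0, 0), p), c(0, 0, 0))
  # layer 0 decays independently of the other components
  s1 <- c(0.3, 0.1, 0.9); s2 <- c(0.3, 0.8, 0.2)
  expect_equal(heinrich_rhs(s1, p)[1], -p$beta[1] * 0.3)
  expect_equal(heinrich_rhs(s1, p)[1], heinrich_rhs(s2, p)[1])
  expect_error(heinrich_rhs(c(-0.5, 0, 0), p), "outside")
})

test_that("RHS matches finite differences of an integrated trajectory", {
  p <- cascade_params(c(5, 4, 3), c(1, 0.2, 2))
  h <- 1e-5
  for (tt in c(0.1, 1, 5)) {
    rhs_f <- function(t) {
      sol <- deSolve::ode(steady_state_gains(p)$m_tilde, c(0, t),
                          function(t, y, parms) list(heinrich_rhs(y, p)),
                          NULL, method = "bdf", rtol = 1e-11, atol = 1e-13)
      sol[2, -1]
    }
    fd <- (rhs_f(tt + h) - rhs_f(tt - h)) / (2 * h)
    expect_equal(unname(fd), heinrich_rhs(unname(rhs_f(tt)), p),
                 tolerance = 1e-5)
  }
})

test_that("normalized system is the rescaled nonlinear system", {
  p <- cascade_params(c(20, 8, 3), c(2, 0.1, 1), c(2, 0.5, 3), e0_init = 4)
  ss <- steady_state_gains(p)
  alpha <- effective_alphas(p)
  # steady-state initial condition: the driven layers start balanced
  # (layer 0 has no production post-stimulus and decays at -beta_0)
  d0 <- normalized_rhs(rep(1, 3), alpha, p$beta, ss$g)
  expect_equal(d0[1], -p$beta[1])
  expect_equal(d0[2:3], rep(0, 2), tolerance = 1e-12)
  times <- c(0, 10^seq(-2, 2, length.out = 50))
  sol_raw <- deSolve::ode(ss$m_tilde, times,
                          function(t, y, parms) list(heinrich_rhs(y, p)),
                          NULL, method = "bdf", rtol = 1e-10, atol = 1e-13)
  sol_norm <- deSolve::ode(rep(1, 3), times, function(t, y, parms)
    list(normalized_rhs(y, alpha, p$beta, ss$g)),
    NULL, method = "bdf", rtol = 1e-10, atol = 1e-13)
  rescaled <- sweep(sol_raw[, -1], 2, ss$m_tilde, "/")
  expect_equal(unname(sol_norm[, -1]), unname(rescaled), tolerance = 1e-7)
  # first component is a pure exponential
  expect_equal(unname(sol_norm[, 2]), exp(-p$beta[1] * times),
               tolerance = 1e-7)
  expect_error(normalized_rhs(rep(1, 3), alpha, p$beta, c(0, 1, 1)),
               "positive")
})

test_that("linearized closed form matches an ODE oracle", {
  for (p in random_params_pool(6)) {
    ts <- 10^seq(-2, min(4, log10(3 / min(p$beta))), length.out = 30)
    expect_equal(linearized_output(ts, linearized_solution(p)),
                 linearized_ode_oracle(p, ts), tolerance = 1e-8)
  }
})

test_that("linearized coefficients sum to one and degenerate cases work", {
  p <- cascade_params(c(100, 100, 100), c(0.01, 1, 10))
  sol <- linearized_solution(p)
  expect_equal(sum(sol$coefficients), 1, tolerance = 1e-12)
  expect_equal(linearized_output(0, sol), 1, tolerance = 1e-12)
  # the fast-slow-fast base has coincident outer rates: confluent form,
  # normalized initial condition still exact
  expect_equal(linearized_output(0, linearized_solution(base_fsf())), 1,
               tolerance = 1e-12)
  # one-stage cascade: a single pure exponential
  p1 <- cascade_params(3, 0.7, 1, 1)
  ts <- c(0, 0.5, 2, 10)
  expect_equal(linearized_output(ts, linearized_solution(p1)),
               exp(-0.7 * ts), tolerance = 1e-12)
  # exactly coincident rates: confluent branch, still matches the ODE
  pc <- cascade_params(c(10, 10, 10), c(0.5, 0.5, 2))
  solc <- linearized_solution(pc)
  expect_null(solc$coefficients)
  ts <- 10^seq(-2, 1.5, length.out = 25)
  expect_equal(linearized_output(ts, solc), linearized_ode_oracle(pc, ts),
               tolerance = 1e-8)
  expect_equal(linearized_output(0, solc), 1, tolerance = 1e-12)
})
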
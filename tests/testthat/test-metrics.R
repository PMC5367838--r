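test_that("similarity measure: zero, closed form, symmetry, homogeneity", {
  cfg <- similarity_config()
  tau <- tau_grid(n = 400)
  a <- exp(-10^tau / 50)
  expect_equal(consecutive_similarity(a, a, 0.2, cfg, tau = tau), 0)
  # constant offset delta over the full window of length 6 + log10(6)
  b <- a + 0.1
  expect_equal(consecutive_similarity(a, b, 0.2, cfg, tau = tau),
               0.1 * sqrt(6 + log10(6)) / 0.2, tolerance = 1e-10)
  # symmetric in the two profiles
  c2 <- exp(-10^tau / 5)
  expect_equal(consecutive_similarity(a, c2, 0.2, cfg, tau = tau),
               consecutive_similarity(c2, a, 0.2, cfg, tau = tau))
  # homogeneous of degree 1 in the output scale (rooted form)
  expect_equal(consecutive_similarity(3 * a, 3 * c2, 0.2, cfg, tau = tau),
               3 * consecutive_similarity(a, c2, 0.2, cfg, tau = tau),
               tolerance = 1e-10)
  # un-rooted literal form is the squared norm over the step
  cfg2 <- similarity_config(use_sqrt = FALSE)
  expect_equal(consecutive_similarity(a, b, 0.2, cfg2, tau = tau),
               0.1^2 * (6 + log10(6)) / 0.2, tolerance = 1e-10)
  expect_error(consecutive_similarity(a, b, 0, cfg, tau = tau), "nonzero")
  expect_error(consecutive_similarity(a, b[-1], 0.2, cfg, tau = tau),
               "grid")
})

test_that("similarity converges under grid refinement", {
  cfg <- similarity_config()
  val <- function(n) {
    tau <- tau_grid(n = n)
    consecutive_similarity(exp(-10^tau / 50), exp(-10^tau / 5), 0.2, cfg,
                           tau = tau)
  }
  expect_lt(abs(val(600) - val(1200)), 1e-4)
})

test_that("logarithmic gain recovers power laws", {
  expect_equal(log_gain(function(x) 1 / x, 1), -1, tolerance = 1e-12)
  for (k in c(-2, 0.5, 3))
    expect_equal(log_gain(function(x) 4 * x^k, 2), k, tolerance = 1e-10)
  expect_equal(log_gain(function(x) 7, 3), 0)
  expect_error(log_gain(function(x) x - 2, 1), "positive")
})

test_that("activation criterion is a strict threshold", {
  expect_true(is_activated(0.51))
  expect_false(is_activated(0.5))
  expect_false(is_activated(0.25))
  expect_true(is_activated(0.4, threshold = 0.3))
})

test_that("beta_max: closed form, bisection agreement, edge cases", {
  # upstream layers fully active: g2 = 1/(1 + b2/a2) = 0.5 at b2 = a2
  p <- cascade_params(c(10, 10, 10), c(1e-15, 1e-15, 1))
  expect_equal(beta_max(p, 3), effective_alphas(p)[3], tolerance = 1e-9)
  for (pp in random_params_pool(4)) {
    bm <- beta_max(pp, 2)
    if (is.finite(bm))
      expect_equal(bm, beta_max(pp, 2, method = "bisection"),
                   tolerance = 1e-5)
  }
  # never activated: reported absent
  p_off <- cascade_params(c(1, 1, 1), c(100, 100, 100))
  expect_warning(bm <- beta_max(p_off, 1), "not activated")
  expect_true(is.na(bm))
})

test_that("kinase activity moves its own activation bound proportionally", {
  p <- base_fsf()
  for (k in 1:3) {
    p_up <- set_param(p, paste0("alpha.", k - 1), 2000)
    for (i in 1:3) {
      ratio <- beta_max(p_up, i) / beta_max(p, i)
      if (i == k) {
        expect_equal(ratio, 2, tolerance = 1e-2)   # ~proportional
      } else if (i > k) {
        # saturated upstream layers barely move downstream bounds
        expect_lt(abs(ratio - 1), 1e-2)
      } else {
        # a faster downstream kinase never shrinks upstream bounds
        expect_gte(ratio, 1 - 1e-12)
      }
    }
  }
})

test_that("raising an unsaturated downstream kinase expands upstream bounds", {
  # middle layer far from saturation (beta_1/alpha_1 = 0.5): raising
  # alpha_1 substantially expands the beta_0 activation bound
  p <- cascade_params(c(1000, 2, 1000), c(1, 1, 1))
  p_up <- set_param(p, "alpha.1", 20)
  expect_gt(beta_max(p_up, 1) / beta_max(p, 1), 1.3)
  # while the bound of the raised layer itself scales ~proportionally
  expect_equal(beta_max(p_up, 2) / beta_max(p, 2), 10, tolerance = 0.01)
})

test_that("slow-mode duration approximation behaves", {
  # single stage: c = 1, theta = ln 2 / beta
  p1 <- cascade_params(1, 0.01, 1, 1)
  expect_equal(duration_approx(linearized_solution(p1)), log(2) / 0.01,
               tolerance = 1e-12)
  # hand-built solution with c_k = 0.5: approximation degenerates to 0
  lin <- structure(list(rates = c(0.1, 1), coefficients = c(0.5, 0.5),
                        terms = list()), class = "linearized_solution")
  expect_equal(duration_approx(lin), 0)
  lin$coefficients <- c(0.2, 0.8)
  expect_warning(v <- duration_approx(lin), "invalid")
  expect_true(is.na(v))
})

test_that("coefficient route and direct route give the same duration gain", {
  p <- cascade_params(c(100, 100, 100), c(0.01, 1, 10))
  for (stage in 2:3) {
    direct <- log_gain(function(b) {
      pp <- p; pp$beta[stage] <- b
      duration_approx(linearized_solution(
        cascade_params(pp$alpha_bar, pp$beta, pp$m_tot, pp$e0_init)))
    }, p$beta[stage], step_log10 = 1e-3)
    expect_equal(gain_from_coefficients(p, stage, step_log10 = 1e-3),
                 direct, tolerance = 1e-6)
  }
  expect_error(gain_from_coefficients(p, 1), "minimal")
})

test_that("fast downstream kinases shield the duration gain", {
  # as downstream kinases speed up, the activation-driven part of the
  # gain vanishes and only a small dynamical residue remains, far below
  # the 0.3 robustness threshold
  gains <- sapply(c(10, 100, 1000, 10000), function(a) {
    p <- cascade_params(c(10, a, a), c(0.01, 1, 10))
    abs(gain_from_coefficients(p, 2))
  })
  expect_true(all(diff(gains) < 0))
  expect_lt(gains[length(gains)], 0.1)
})

test_that("duration-robustness conditions evaluate with margins", {
  alpha <- c(1000, 1000, 1000)
  beta <- c(1, 0.01, 1)
  r1 <- check_conditions(alpha, beta, stage = 1)
  expect_true(r1$rate_limiting_ok)        # min beta (0.01) < beta_0 (1)
  r2 <- check_conditions(alpha, beta, stage = 2)
  expect_false(r2$rate_limiting_ok)       # beta_1 is the minimum
  # nested activation product ~ 0.001 < 1
  expect_true(r1$initial_condition_ok)
  expect_equal(1 - r1$margins$initial_condition,
               (1 / 1000) * (1 + 0.01 / 1000) * (1 + 1 / 1000),
               tolerance = 1e-12)
  expect_true(r1$fast_downstream_ok)
  expect_true(r1$all_ok)
})

test_that("robustness intervals from synthetic sweeps", {
  lg <- seq(-2, 2, by = 0.2)
  flat <- data.frame(log10_value = lg, theta = rep(5, length(lg)),
                     activated = TRUE)
  ri <- robustness_interval(flat)
  expect_equal(nrow(ri$intervals), 1)
  expect_equal(ri$intervals$log10_lo, -2)
  expect_equal(ri$intervals$log10_hi, 2)
  inv <- data.frame(log10_value = lg, theta = 10 / 10^lg, activated = TRUE)
  expect_equal(nrow(robustness_interval(inv)$intervals), 0)
})
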
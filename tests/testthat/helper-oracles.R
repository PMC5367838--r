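# Shared fixtures and independent oracles for the suite.

# Fast-kinase, fast-slow-fast base set used across tests (same organization
# as heinrich_base() but spelled out so tests do not depend on paramgen).
base_fsf <- function() {
  cascade_params(alpha_bar = c(1000, 1000, 1000), beta = c(1, 0.01, 1),
                 m_tot = c(1, 1, 1), e0_init = 1)
}

# Independent oracle: integrate the *stimulated* Heinrich system (input
# enzyme held at e0_init) from zero phosphorylation to its long-time limit.
stimulated_heinrich_limit <- function(params, t_end = 1000) {
  rhs <- function(t, y, parms) {
    n <- params$n_stages
    drive <- c(params$e0_init, y[-n])
    list(params$alpha_bar * drive * (params$m_tot - y) - params$beta * y)
  }
  sol <- deSolve::ode(rep(0, params$n_stages), c(0, t_end), rhs, NULL,
                      method = "bdf", rtol = 1e-10, atol = 1e-14)
  unname(sol[nrow(sol), -1])
}

# Independent oracle: integrate the linearized chain
#   dm_1/dt = -beta_1 m_1,  dm_i/dt = lambda_i m_{i-1} - beta_i m_i,
# all m_i(0) = 1, and return the output layer at the requested times.
linearized_ode_oracle <- function(params, times) {
  alpha <- effective_alphas(params)
  g <- steady_state_gains(params)$g
  beta <- params$beta
  n <- params$n_stages
  lambda <- c(0, alpha[-1] * g[-n] / g[-1])
  rhs <- function(t, y, parms)
    list(c(-beta[1] * y[1],
           if (n > 1) lambda[-1] * y[-n] - beta[-1] * y[-1]))
  sol <- deSolve::ode(rep(1, n), c(0, times), rhs, NULL, method = "bdf",
                      rtol = 1e-12, atol = 1e-14)
  unname(sol[-1, 1 + n])
}

# Brute-force half-life oracle: first 0.5-crossing of the closed-form
# linearized output on a very fine log-time grid + local bisection.
half_life_bruteforce <- function(params, t_hi = 6e6) {
  sol <- linearized_solution(params)
  f <- function(t) linearized_output(t, sol) - 0.5
  ts <- 10^seq(-8, log10(t_hi), length.out = 200000)
  v <- f(ts)
  i <- which(v[-1] <= 0 & v[-length(v)] > 0)[1]
  lo <- ts[i]; hi <- ts[i + 1]
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small random cascade parameter sets with well-separated rates, for
# property loops (deterministic).
random_params_pool <- function(n = 8, seed = 42) {
  random_ensemble(n, seed = seed,
                  constraints = list(activated = TRUE, distinct_beta = TRUE,
                                     range = c(1e-2, 1e2)))
}
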
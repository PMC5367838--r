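#' Configuration of the profile-similarity measure
#'
#' @param tau_lower,tau_upper integration bounds in `log10(time)`.
#' @param threshold similarity value below which consecutive profiles are
#'   considered dynamics-robust.
#' @param use_sqrt if `TRUE` (default) the conventional L2 norm (square root
#'   of the integrated squared difference) is used; if `FALSE` the un-rooted
#'   integral itself.
#' @param profile_normalized if `TRUE`, profiles are divided by their
#'   pre-stimulus output before comparison (useful across models); default
#'   compares raw outputs.
#' @return object of class `similarity_config`.
#' @export
similarity_config <- function(tau_lower = -2, tau_upper = 4 + log10(6),
                              threshold = 0.3, use_sqrt = TRUE,
                              profile_normalized = FALSE) {
  if (tau_lower >= tau_upper) stop("tau_lower must be below tau_upper")
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(tau_lower = tau_lower, tau_upper = tau_upper,
                 threshold = threshold, use_sqrt = isTRUE(use_sqrt),
                 profile_normalized = isTRUE(profile_normalized)),
            class = "similarity_config")
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Similarity between consecutive relaxation profiles
#'
#' Distance between two output profiles sampled on the same `log10(time)`
#' grid, scaled by the parameter step that separates them:
#' `(1 / |delta_log_beta|) * sqrt( integral |out_a(tau) - out_b(tau)|^2 dtau )`
#' (trapezoid rule). Small values mean the temporal profile barely moved
#' when the parameter was perturbed — dynamics robustness.
#'
#' @param profile_a,profile_b [simulate_relaxation] trajectories (or plain
#'   numeric output vectors, in which case `tau` must be supplied).
#' @param delta_log_beta the `log10` step between the two parameter values.
#' @param config a [similarity_config].
#' @param tau sample grid when profiles are plain vectors.
#' @return nonnegative scalar.
#' @export
consecutive_similarity <- function(profile_a, profile_b, delta_log_beta,
                                   config = similarity_config(),
                                   tau = NULL) {
  if (delta_log_beta == 0) stop("delta_log_beta must be nonzero")
  get_out <- function(p) {
    if (inherits(p, "cascade_trajectory")) {
      out <- p$output
      if (config$profile_normalized) out <- out / p$output0
      list(tau = p$tau, out = out)
    } else {
      if (!is.null(tau) && length(p) != length(tau))
        stop("profile length must match the tau grid")
      list(tau = tau, out = as.numeric(p))
    }
  }
  a <- get_out(profile_a)
  b <- get_out(profile_b)
  if (is.null(a$tau) || is.null(b$tau))
    stop("tau grid required for plain-vector profiles")
  if (length(a$tau) != length(b$tau) ||
      max(abs(a$tau - b$tau)) > 1e-12)
    stop("profiles must share an identical tau grid")
  keep <- a$tau >= config$tau_lower - 1e-12 &
    a$tau <= config$tau_upper + 1e-12
  integral <- .trapz(a$tau[keep], (a$out[keep] - b$out[keep])^2)
  if (config$use_sqrt) sqrt(integral) / abs(delta_log_beta)
  else integral / abs(delta_log_beta)
}

#' Logarithmic gain of a function
#'
#' The slope of `y` against `x` on a log-log plot, `dlog(y)/dlog(x)`,
#' estimated by a central difference with step `step_log10` in `log10(x)`.
#' Inverse proportionality gives -1; a power law `y = c x^k` gives `k`.
#'
#' @param f positive scalar function of one positive argument.
#' @param x0 point of evaluation.
#' @param step_log10 half-width of the central difference in `log10`.
#' @return the logarithmic gain (dimensionless).
#' @examples
#' log_gain(function(x) 1 / x, 1)   # -1
#' @export
log_gain <- function(f, x0, step_log10 = 0.05) {
  y_hi <- f(x0 * 10^step_log10)
  y_lo <- f(x0 * 10^-step_log10)
  if (!is.finite(y_hi) || !is.finite(y_lo) || y_hi <= 0 || y_lo <= 0)
    stop("f must be positive and finite at 10^(+/-step) * x0")
  (log10(y_hi) - log10(y_lo)) / (2 * step_log10)
}

#' Is the cascade activated?
#'
#' A cascade is considered activated when the pre-stimulus phosphorylated
#' fraction of the output layer exceeds the activation threshold (strictly).
#'
#' @param g2 output-layer phosphorylated fraction, in `[0, 1]`.
#' @param threshold activation threshold (default 0.5; the exact value is
#'   not essential to the analysis).
#' @return logical.
#' @export
is_activated <- function(g2, threshold = 0.5) {
  stopifnot(is.numeric(g2), g2 >= 0, g2 <= 1)
  g2 > threshold
}

#' Largest phosphatase activity keeping the cascade activated
#'
#' `beta_max` for layer `stage` is the largest value of that layer's
#' phosphatase activity at which the output fraction `g2` still exceeds the
#' activation threshold; it marks the upper edge of the duration-robustness
#' interval. For the Heinrich cascade `1/g2` is affine in any single
#' `beta_i`, so the bound is solved in closed form (a log-bisection route is
#' kept as a cross-check); for the Huang-Ferrell model the bound on
#' `p_tot[stage]` is found by bisection on the equilibrated steady state.
#'
#' @param x a [cascade_params] or [hf_model] object.
#' @param stage layer index, 1-based.
#' @param threshold activation threshold on `g2`.
#' @param method `"analytic"` (Heinrich closed form) or `"bisection"`.
#' @param lower,upper bisection bracket for the swept value.
#' @param tol relative tolerance of the bisection.
#' @param ... unused.
#' @return the maximal activity (time^-1 for Heinrich; a concentration,
#'   `p_tot`, for HF), or `NA` when the cascade is not activated even at
#'   vanishing phosphatase activity.
#' @export
beta_max <- function(x, stage, ...) UseMethod("beta_max")

#' @rdname beta_max
#' @export
beta_max.cascade_params <- function(x, stage, threshold = 0.5,
                                    method = c("analytic", "bisection"),
                                    lower = 1e-12, upper = 1e12,
                                    tol = 1e-6, ...) {
  method <- match.arg(method)
  stopifnot(stage >= 1, stage <= x$n_stages)
  alpha <- effective_alphas(x)
  inv_g2 <- function(b) {
    beta <- x$beta
    beta[stage] <- b
    1 / steady_state_gains(alpha, beta, x$m_tot)$g[x$n_stages]
  }
  target <- 1 / threshold
  f0 <- inv_g2(0)
  if (f0 >= target) {
    warning("cascade not activated even at vanishing phosphatase activity")
    return(NA_real_)
  }
  if (method == "analytic") {
    slope <- inv_g2(1) - f0       # 1/g2 is affine in beta[stage]
    return((target - f0) / slope)
  }
  g <- function(b) inv_g2(b) - target
  if (g(upper) < 0) stop("bisection bracket does not contain beta_max")
  lo <- log(lower)
  hi <- log(upper)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(exp(mid)) < 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' @rdname beta_max
#' @export
beta_max.hf_model <- function(x, stage, threshold = 0.5,
                              lower = 1e-8, upper = 1e6, tol = 1e-3, ...) {
  stopifnot(stage >= 1, stage <= 3)
  g2_at <- function(ptot) {
    p <- x$params
    p$p_tot[stage] <- ptot
    m <- hf_model(p, stimulus_removal = x$stimulus_removal,
                  output_include_bound = x$output_include_bound)
    pre_stimulus_steady_state(m)$g2
  }
  if (g2_at(lower) <= threshold) {
    warning("cascade not activated at the lower phosphatase bound")
    return(NA_real_)
  }
  if (g2_at(upper) > threshold)
    stop("bisection bracket does not contain beta_max")
  lo <- log(lower)
  hi <- log(upper)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g2_at(exp(mid)) > threshold) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Closed-form approximation of the half-life
#'
#' When the slowest phosphatase rate `beta_k` is well separated from the
#' others, the linearized output is dominated at long times by its slowest
#' exponential and the half-life is approximately
#' `theta ~ (1 / beta_k) * log(2 * c_k)`.
#'
#' @param lin a [linearized_solution] with pairwise distinct rates.
#' @return approximate half-life; `NA` with a warning when `c_k < 0.5`
#'   (the slow mode never carries half the output, so the log is negative
#'   and the approximation does not apply).
#' @export
duration_approx <- function(lin) {
  stopifnot(inherits(lin, "linearized_solution"))
  if (is.null(lin$coefficients))
    stop("duration approximation requires pairwise distinct rates")
  k <- which.min(lin$rates)
  ck <- lin$coefficients[k]
  if (2 * ck < 1) {
    warning("c_k < 0.5: slow-mode half-life approximation invalid")
    return(NA_real_)
  }
  log(2 * ck) / lin$rates[k]
}

#' Duration gain from the slow-mode coefficient
#'
#' Differentiating `theta ~ (log 2 + log c_k) / beta_k` with respect to a
#' non-minimal rate `beta_i` gives the logarithmic gain of the duration as
#' `(1 / (log 2 + log c_k)) * dlog(c_k)/dlog(beta_i)`; the partial is
#' computed by central differences of the slow-mode coefficient. Consistent
#' with [log_gain] applied to [duration_approx] up to discretization error.
#'
#' @param params a [cascade_params] object (linearized cascade).
#' @param stage index (1-based) of the perturbed phosphatase rate; must not
#'   be the minimal-rate layer.
#' @param step_log10 central-difference step.
#' @return the logarithmic gain of the approximate duration.
#' @export
gain_from_coefficients <- function(params, stage, step_log10 = 0.05) {
  stopifnot(inherits(params, "cascade_params"))
  k <- which.min(params$beta)
  if (stage == k)
    stop("stage must not be the minimal-rate layer (slow-mode formula)")
  ck_at <- function(b) {
    p <- params
    p$beta[stage] <- b
    sol <- linearized_solution(p)
    sol$coefficients[which.min(sol$rates)]
  }
  b0 <- params$beta[stage]
  ck <- ck_at(b0)
  if (2 * ck < 1)
    stop("c_k < 0.5: slow-mode formula does not apply")
  dlog_ck <- (log(ck_at(b0 * 10^step_log10)) -
                log(ck_at(b0 * 10^-step_log10))) / (2 * step_log10 * log(10))
  dlog_ck / (log(2) + log(ck))
}

#' Duration-robustness conditions for one layer
#'
#' Checks the three conditions under which the half-life of an N-stage
#' cascade is robust to perturbations of `beta[stage]`:
#'
#' 1. *Rate-limiting constraint*: `min(beta) < beta[stage]` — the perturbed
#'    layer is not the slowest (otherwise it sets the relaxation timescale
#'    and the gain is near -1).
#' 2. *Initial-condition constraint*:
#'    `(beta_N / alpha_N) * (1 + beta_{N-1}/alpha_{N-1}) * ... * (1 + beta_1/alpha_1) < 1`
#'    — the kinases are fast enough that the output layer is activated.
#' 3. *Fast downstream kinase*: some layer `k >= stage` has
#'    `beta_k / alpha_k` below `ll_factor` — a saturated downstream layer
#'    shields the output activation from upstream changes.
#'
#' @param alpha effective kinase activities, or a [cascade_params] object.
#' @param beta phosphatase rates (ignored when `alpha` is a parameter set).
#' @param stage perturbed layer, 1-based.
#' @param ll_factor operational cutoff for "much smaller than" in
#'   condition 3.
#' @return object of class `condition_report`: logical fields
#'   `rate_limiting_ok`, `initial_condition_ok`, `fast_downstream_ok`,
#'   `all_ok`, and a `margins` list (`rate_limiting` = log10 of
#'   `beta[stage] / min(beta)`; `initial_condition` = 1 minus the nested
#'   product; `fast_downstream` = `ll_factor` minus the smallest downstream
#'   `beta/alpha` ratio). Positive margins mean the condition holds.
#' @export
check_conditions <- function(alpha, beta = NULL, stage, ll_factor = 0.1) {
  if (inherits(alpha, "cascade_params")) {
    beta <- alpha$beta
    alpha <- effective_alphas(alpha)
  }
  n <- length(alpha)
  stopifnot(length(beta) == n, stage >= 1, stage <= n)
  ratio <- beta / alpha
  prod_ic <- ratio[n]
  if (n > 1) prod_ic <- prod_ic * prod(1 + ratio[seq_len(n - 1)])
  down <- min(ratio[stage:n])
  rep <- list(
    rate_limiting_ok = min(beta) < beta[stage],
    initial_condition_ok = prod_ic < 1,
    fast_downstream_ok = down < ll_factor,
    margins = list(rate_limiting = log10(beta[stage] / min(beta)),
                   initial_condition = 1 - prod_ic,
                   fast_downstream = ll_factor - down),
    stage = stage, ll_factor = ll_factor)
  rep$all_ok <- rep$rate_limiting_ok && rep$initial_condition_ok &&
    rep$fast_downstream_ok
  structure(rep, class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  ok <- function(b) if (b) "ok " else "FAIL"
  cat(sprintf("Duration-robustness conditions, layer %d\n", x$stage))
  cat(sprintf("  1 rate-limiting     %s (log10 margin %+.3g)\n",
              ok(x$rate_limiting_ok), x$margins$rate_limiting))
  cat(sprintf("  2 initial condition %s (margin %+.3g)\n",
              ok(x$initial_condition_ok), x$margins$initial_condition))
  cat(sprintf("  3 fast downstream   %s (margin %+.3g)\n",
              ok(x$fast_downstream_ok), x$margins$fast_downstream))
  invisible(x)
}

#' Duration-robustness intervals of a sweep
#'
#' Maximal contiguous sub-intervals of a parameter sweep on which the
#' cascade is activated and the magnitude of the logarithmic gain of the
#' half-life stays below the robustness threshold. Also reports the
#' crossover point at which the swept rate becomes the minimum rate of the
#' cascade (left of it the layer is rate-limiting and the gain approaches
#' -1).
#'
#' @param sweep a [run_sweep] result, or a data.frame with columns
#'   `log10_value`, `theta`, `activated` and optionally `gain` (computed by
#'   central differences of `log10(theta)` when absent).
#' @param threshold gain-magnitude threshold.
#' @param use_refined prefer the refined-step gain column when present.
#' @return list with `intervals` (data.frame of `log10_lo`, `log10_hi`,
#'   `n_points`) and `crossover` (the parameter value at which the swept
#'   rate equals the smallest other rate, or `NA` when unknown).
#' @export
robustness_interval <- function(sweep, threshold = 0.3,
                                use_refined = TRUE) {
  if (inherits(sweep, "sweep_result")) {
    df <- sweep$records
    crossover <- sweep$crossover
  } else {
    df <- as.data.frame(sweep)
    crossover <- NA_real_
  }
  stopifnot(all(c("log10_value", "theta", "activated") %in% names(df)))
  ord <- order(df$log10_value)
  df <- df[ord, ]
  gain <- if (use_refined && !is.null(df$gain_refined) &&
                any(is.finite(df$gain_refined))) df$gain_refined
  else df$gain
  if (is.null(gain)) {
    lt <- log10(df$theta)
    lx <- df$log10_value
    n <- nrow(df)
    gain <- rep(NA_real_, n)
    if (n >= 2) {
      gain[1] <- (lt[2] - lt[1]) / (lx[2] - lx[1])
      gain[n] <- (lt[n] - lt[n - 1]) / (lx[n] - lx[n - 1])
      if (n > 2)
        gain[2:(n - 1)] <- (lt[3:n] - lt[1:(n - 2)]) / (lx[3:n] - lx[1:(n - 2)])
    }
  }
  ok <- df$activated & is.finite(gain) & abs(gain) < threshold &
    is.finite(df$theta)
  ok[is.na(ok)] <- FALSE
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  intervals <- data.frame(log10_lo = df$log10_value[starts[keep]],
                          log10_hi = df$log10_value[ends[keep]],
                          n_points = runs$lengths[keep])
  list(intervals = intervals, crossover = crossover)
}
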
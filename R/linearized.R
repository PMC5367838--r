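#' Closed-form relaxation of the linearized cascade
#'
#' Linearizing the normalized cascade about the deactivated state drops the
#' saturation term, leaving the lower-triangular chain
#' `dm_0/dt = -beta_0 m_0`,
#' `dm_i/dt = (alpha_i g_{i-1} / g_i) m_{i-1} - beta_i m_i`,
#' with all `m_i(0) = 1`. When the phosphatase rates are pairwise distinct
#' the output layer relaxes as a linear combination of exponentials,
#' `m_out(t) = sum_i c_i exp(-beta_i t)` with `sum_i c_i = 1` — the classic
#' decay-chain (Bateman-type) form. Coincident rates (relative gap below
#' `tie_tol`) are handled exactly by the confluent form, in which the
#' exponential prefactors become polynomials in `t`.
#'
#' @param params a [cascade_params] object.
#' @param stage which layer's trajectory to express (default: the output
#'   layer, i.e. the last stage).
#' @param tie_tol relative gap below which two phosphatase rates are treated
#'   as equal and the confluent branch is used.
#' @return An object of class `linearized_solution`: list with
#'   * `rates` — the phosphatase rates `beta_i` entering the solution,
#'   * `terms` — list of `(rate, poly)` pairs; each contributes
#'     `polyval(poly, t) * exp(-rate * t)`,
#'   * `coefficients` — the `c_i` aligned with `rates` when all prefactors
#'     are constants, otherwise `NULL` (confluent case).
#' @examples
#' p <- cascade_params(c(100, 100, 100), beta = c(0.01, 1, 10))
#' sol <- linearized_solution(p)
#' sum(sol$coefficients)  # 1: the normalized initial condition
#' linearized_output(0, sol)
#' @export
linearized_solution <- function(params, stage = params$n_stages,
                                tie_tol = 1e-9) {
  stopifnot(inherits(params, "cascade_params"))
  n <- params$n_stages
  if (stage < 1 || stage > n)
    stop("stage out of range")
  alpha <- effective_alphas(params)
  beta <- params$beta
  g <- steady_state_gains(alpha, beta, params$m_tot)$g

  same_rate <- function(a, b) abs(a - b) / max(a, b) < tie_tol

  # terms: list of list(rate, poly); poly[k] multiplies t^(k-1)
  terms <- list(list(rate = beta[1], poly = 1))
  for (i in seq_len(stage)[-1]) {
    lambda <- alpha[i] * g[i - 1] / g[i]
    bi <- beta[i]
    new_terms <- list()
    for (tm in terms) {
      p <- lambda * tm$poly
      if (same_rate(bi, tm$rate)) {
        # confluent: q' = p  =>  integrate the polynomial, same rate
        q <- c(0, p / seq_along(p))
      } else {
        # q' + (bi - r) q = p, solved degree by degree from the top
        delta <- bi - tm$rate
        d <- length(p)
        q <- numeric(d)
        q[d] <- p[d] / delta
        if (d > 1)
          for (k in (d - 1):1) q[k] <- (p[k] - k * q[k + 1]) / delta
      }
      new_terms[[length(new_terms) + 1L]] <- list(rate = tm$rate, poly = q)
    }
    # homogeneous term at rate beta_i fixes m_i(0) = 1
    h <- 1 - sum(vapply(new_terms, function(tm) tm$poly[1], numeric(1)))
    hit <- which(vapply(new_terms, function(tm) same_rate(tm$rate, bi),
                        logical(1)))
    if (length(hit) > 0) {
      j <- hit[1]
      new_terms[[j]]$poly[1] <- new_terms[[j]]$poly[1] + h
    } else {
      new_terms[[length(new_terms) + 1L]] <- list(rate = bi, poly = h)
    }
    terms <- new_terms
  }

  degree0 <- all(vapply(terms, function(tm) length(tm$poly) == 1L,
                        logical(1)))
  structure(list(
    rates = vapply(terms, function(tm) tm$rate, numeric(1)),
    terms = terms,
    coefficients = if (degree0)
      vapply(terms, function(tm) tm$poly[1], numeric(1)) else NULL,
    gains = g, alpha = alpha, beta = beta[seq_len(stage)],
    stage = stage), class = "linearized_solution")
}

#' @export
print.linearized_solution <- function(x, ...) {
  cat(sprintf("Linearized cascade output, stage %d\n", x$stage))
  if (!is.null(x$coefficients)) {
    for (i in seq_along(x$rates))
      cat(sprintf("  %+ .6g * exp(-%g t)\n", x$coefficients[i], x$rates[i]))
  } else {
    cat("  confluent form (polynomial-in-t prefactors)\n")
  }
  invisible(x)
}

#' Evaluate the linearized cascade output
#'
#' @param t time(s) at which to evaluate (vectorized).
#' @param sol a [linearized_solution], or a [cascade_params] from which the
#'   output-layer solution is built.
#' @return normalized output `m_out(t)`; equals 1 at `t = 0`.
#' @export
linearized_output <- function(t, sol) {
  if (inherits(sol, "cascade_params"))
    sol <- linearized_solution(sol)
  stopifnot(inherits(sol, "linearized_solution"))
  out <- numeric(length(t))
  for (tm in sol$terms) {
    pv <- rep(tm$poly[length(tm$poly)], length(t))
    if (length(tm$poly) > 1)
      for (k in (length(tm$poly) - 1):1) pv <- pv * t + tm$poly[k]
    out <- out + pv * exp(-tm$rate * t)
  }
  out
}
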
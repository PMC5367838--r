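#' Cascade model constructors
#'
#' A model object couples a parameter set with the kinetics used to simulate
#' it. Three variants are provided:
#'
#' * `heinrich_model()` — the nonlinear Heinrich cascade: first-order
#'   dephosphorylation, second-order phosphorylation with substrate
#'   conservation `M_i + Mp_i = m_tot[i]` in each layer.
#' * `linearized_model()` — the linearization of the normalized Heinrich
#'   cascade about the deactivated state (the origin), whose relaxation is a
#'   chain of exponentials with closed-form coefficients.
#' * `hf_model()` — the Huang-Ferrell mass-action MAPK cascade with explicit
#'   phosphatases, enzyme-substrate complexes, and double phosphorylation in
#'   the two downstream layers (see [hf_params]).
#'
#' @param params a [cascade_params] (Heinrich/linearized) or [hf_params]
#'   (Huang-Ferrell) object.
#' @param stimulus_removal for `hf_model`, how the stimulus is removed at
#'   `t = 0`: `"hard"` (default) removes free E0 *and* E0-substrate
#'   complexes, returning sequestered substrate to its free unphosphorylated
#'   pool; `"free_only"` zeroes only free E0 and lets existing complexes
#'   turn over.
#' @param output_include_bound for `hf_model`, whether the reported output
#'   (doubly phosphorylated terminal substrate) includes the
#'   phosphatase-bound form. Default `FALSE` (free form only).
#' @return an object of class `c("<variant>_model", "cascade_model")`.
#' @examples
#' m <- heinrich_model(cascade_params(c(1000, 1000, 1000), c(1, 0.01, 1)))
#' half_life(m)
#' @export
heinrich_model <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  structure(list(params = params),
            class = c("heinrich_model", "cascade_model"))
}

#' @rdname heinrich_model
#' @export
linearized_model <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  structure(list(params = params),
            class = c("linearized_model", "cascade_model"))
}

#' @rdname heinrich_model
#' @export
hf_model <- function(params, stimulus_removal = c("hard", "free_only"),
                     output_include_bound = FALSE) {
  stopifnot(inherits(params, "hf_params"))
  structure(list(params = params,
                 stimulus_removal = match.arg(stimulus_removal),
                 output_include_bound = isTRUE(output_include_bound)),
            class = c("hf_model", "cascade_model"))
}

#' Post-stimulus right-hand side of the Heinrich cascade
#'
#' Time derivatives of the phosphorylated concentrations once the stimulus
#' has been removed: layer 0 decays freely,
#' `dMp_0/dt = -beta_0 * Mp_0`, and each downstream layer is phosphorylated
#' by the layer above while being dephosphorylated first-order,
#' `dMp_i/dt = alpha_bar_i * Mp_{i-1} * (m_tot_i - Mp_i) - beta_i * Mp_i`.
#'
#' @param state numeric vector of phosphorylated concentrations `Mp_i`,
#'   each within `[0, m_tot[i]]` (a small tolerance is allowed for solver
#'   overshoot).
#' @param params a [cascade_params] object.
#' @param tol how far outside `[0, m_tot]` a state component may lie before
#'   it is rejected.
#' @return numeric vector of derivatives.
#' @export
heinrich_rhs <- function(state, params, tol = 1e-8) {
  n <- params$n_stages
  if (length(state) != n)
    stop("state length must equal the number of stages")
  if (any(state < -tol) || any(state > params$m_tot + tol))
    stop("state outside [0, m_tot]")
  d <- numeric(n)
  d[1] <- -params$beta[1] * state[1]
  if (n > 1) {
    i <- 2:n
    d[i] <- params$alpha_bar[i] * state[i - 1] *
      (params$m_tot[i] - state[i]) - params$beta[i] * state[i]
  }
  d
}

#' Post-stimulus right-hand side of the normalized Heinrich cascade
#'
#' The normalized variables `m_i = Mp_i / Mtilde_i` start at 1 when the
#' stimulus is removed. Their dynamics are
#' `dm_0/dt = -beta_0 * m_0` and, for downstream layers,
#' `dm_i/dt = alpha_i * g_{i-1} * m_{i-1} * (1/g_i - m_i) - beta_i * m_i`,
#' with `alpha` the effective kinase activities and `g` the pre-stimulus
#' phosphorylated fractions. The normalized trajectory equals the
#' [heinrich_rhs] trajectory divided componentwise by `Mtilde_i`.
#'
#' @param state numeric vector of normalized phosphorylated levels.
#' @param alpha effective kinase activities ([effective_alphas]).
#' @param beta phosphatase rates.
#' @param gains pre-stimulus fractions `g` ([steady_state_gains]).
#' @return numeric vector of derivatives.
#' @export
normalized_rhs <- function(state, alpha, beta, gains) {
  n <- length(alpha)
  if (length(state) != n || length(beta) != n || length(gains) != n)
    stop("state, alpha, beta and gains must have equal length")
  if (any(gains <= 0))
    stop("gains must be strictly positive")
  d <- numeric(n)
  d[1] <- -beta[1] * state[1]
  if (n > 1) {
    i <- 2:n
    d[i] <- alpha[i] * gains[i - 1] * state[i - 1] *
      (1 / gains[i] - state[i]) - beta[i] * state[i]
  }
  d
}
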
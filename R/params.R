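#' Kinetic parameters of an N-stage Heinrich cascade
#'
#' Bundles the rate constants and total concentrations of a linear
#' phosphorylation cascade in which the phosphorylated product of each layer
#' acts as the kinase of the next. Layer 0 is driven by the receptor/stimulus
#' `E0`, present at concentration `e0_init` for `t < 0` and removed at
#' `t = 0`.
#'
#' @param alpha_bar numeric vector of second-order kinase rate constants
#'   (concentration^-1 time^-1), one per layer.
#' @param beta numeric vector of first-order phosphatase rate constants
#'   (time^-1), one per layer.
#' @param m_tot numeric vector of total substrate concentrations per layer.
#' @param e0_init stimulus (receptor) concentration applied for `t < 0`.
#'
#' @details All entries must be strictly positive (use a small positive
#'   number rather than 0 to represent a negligible rate; `steady_state_gains`
#'   additionally accepts exact zeros for `beta`). Units are arbitrary but
#'   must be mutually consistent; all derived quantities are reported in the
#'   same units.
#'
#' @return An object of class `cascade_params` with fields `alpha_bar`,
#'   `beta`, `m_tot`, `e0_init`, `n_stages`.
#' @examples
#' p <- cascade_params(alpha_bar = c(1000, 1000, 1000),
#'                     beta = c(1, 0.01, 1),
#'                     m_tot = c(1, 1, 1), e0_init = 1)
#' effective_alphas(p)
#' @export
cascade_params <- function(alpha_bar, beta, m_tot = rep(1, length(beta)),
                           e0_init = 1) {
  n <- length(alpha_bar)
  if (n < 1L)
    stop("at least one stage is required")
  if (length(beta) != n || length(m_tot) != n)
    stop("alpha_bar, beta and m_tot must have equal length")
  vals <- c(alpha_bar, beta, m_tot, e0_init)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("all parameters must be strictly positive and finite")
  structure(list(alpha_bar = as.numeric(alpha_bar),
                 beta = as.numeric(beta),
                 m_tot = as.numeric(m_tot),
                 e0_init = as.numeric(e0_init),
                 n_stages = n),
            class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat(sprintf("Heinrich cascade parameters (%d stages)\n", x$n_stages))
  cat("  alpha_bar:", format(x$alpha_bar, digits = 4), "\n")
  cat("  beta:     ", format(x$beta, digits = 4), "\n")
  cat("  m_tot:    ", format(x$m_tot, digits = 4), "\n")
  cat("  e0_init:  ", format(x$e0_init, digits = 4), "\n")
  invisible(x)
}

#' Effective kinase activities
#'
#' Converts the second-order kinase rate constants into the effective
#' first-order kinase activities `alpha[1] = alpha_bar[1] * e0_init` and
#' `alpha[i] = alpha_bar[i] * m_tot[i - 1]` for downstream layers (each layer
#' is driven by the phosphorylated substrate of the layer above, whose scale
#' is set by that layer's total substrate).
#'
#' @param params a [cascade_params] object.
#' @return numeric vector of effective kinase activities (time^-1).
#' @export
effective_alphas <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  n <- params$n_stages
  drivers <- c(params$e0_init, params$m_tot[-n])
  params$alpha_bar * drivers
}

#' Pre-stimulus steady-state phosphorylation of a Heinrich cascade
#'
#' Under a sustained stimulus the phosphorylated fraction of each layer,
#' `g_i = Mtilde_i / m_tot[i]`, obeys the downward recursion
#' `g_0 = 1 / (1 + beta_0 / alpha_0)`,
#' `g_i = 1 / (1 + (beta_i / alpha_i) / g_{i-1})`,
#' where `alpha` are the effective kinase activities. The phosphorylated
#' concentrations are `Mtilde_i = g_i * m_tot[i]`.
#'
#' @param alpha effective kinase activities (time^-1), or a
#'   [cascade_params] object from which both `alpha` and `beta` are taken.
#' @param beta phosphatase rates; ignored when `alpha` is a `cascade_params`.
#'   Exact zeros are allowed (no dephosphorylation, `g = 1`).
#' @param m_tot total substrate per layer (default 1 each: normalized units).
#' @return An object of class `steady_state`: list with `g` (fractions in
#'   (0, 1]) and `m_tilde` (concentrations).
#' @examples
#' ss <- steady_state_gains(alpha = c(100, 100, 100), beta = c(1, 1, 1))
#' ss$g
#' @export
steady_state_gains <- function(alpha, beta = NULL,
                               m_tot = rep(1, length(alpha))) {
  if (inherits(alpha, "cascade_params")) {
    params <- alpha
    beta <- params$beta
    m_tot <- params$m_tot
    alpha <- effective_alphas(params)
  }
  n <- length(alpha)
  if (length(beta) != n)
    stop("alpha and beta must have equal length")
  if (any(alpha <= 0))
    stop("effective kinase activities must be strictly positive")
  if (any(beta < 0))
    stop("phosphatase rates must be nonnegative")
  g <- numeric(n)
  g_prev <- 1
  for (i in seq_len(n)) {
    g[i] <- 1 / (1 + (beta[i] / alpha[i]) / g_prev)
    g_prev <- g[i]
  }
  structure(list(g = g, m_tilde = g * m_tot), class = "steady_state")
}
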
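# Synthetic parameter sets. The kinetic organization they encode — fast
# kinase activities, phosphatase rates fast-slow-fast across the three
# layers, strong activation under stimulus — emulates the qualitative
# layout of measured MAPK cascade kinetics; the numeric values are
# emulated defaults, not measurements.

#' Specification for the synthetic parameter generator
#'
#' @param seed integer seed fixing every random choice of the generator
#'   (the organized base sets are fully deterministic; the seed matters for
#'   [random_ensemble]).
#' @param organization `"fast-slow-fast"`: phosphatase rates fast, slow,
#'   fast across the three layers; `"custom"` leaves the rates to the
#'   caller via `beta`.
#' @param kinase_speed_factor ratio of the effective kinase activities to
#'   the slow phosphatase rate. The default `1e5` makes every layer deeply
#'   saturated under stimulus.
#' @param activation_floor required pre-stimulus output fraction `g2` of a
#'   generated base set.
#' @param beta for `organization = "custom"`, the phosphatase rate vector.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           organization = c("fast-slow-fast", "custom"),
                           kinase_speed_factor = 1e5,
                           activation_floor = 0.9, beta = NULL) {
  organization <- match.arg(organization)
  if (kinase_speed_factor <= 0) stop("kinase_speed_factor must be positive")
  if (activation_floor <= 0 || activation_floor >= 1)
    stop("activation_floor must lie in (0, 1)")
  if (organization == "custom" && is.null(beta))
    stop("custom organization requires an explicit beta vector")
  structure(list(seed = as.integer(seed), organization = organization,
                 kinase_speed_factor = kinase_speed_factor,
                 activation_floor = activation_floor, beta = beta),
            class = "generator_spec")
}

#' Organized Heinrich base parameter set
#'
#' Builds a 3-stage Heinrich cascade with the fast-slow-fast phosphatase
#' organization (`beta = (1, 0.01, 1)` in the default time unit of the slow
#' layer's timescale x 100), unit substrate totals, and fast kinases: every
#' effective kinase activity equals `kinase_speed_factor` times the slow
#' phosphatase rate. The stimulus is raised (in decades, up to 1e6) until
#' the output activation `g2` clears `activation_floor`; with the defaults
#' the base stimulus already does.
#'
#' @param spec a [generator_spec].
#' @return a [cascade_params] object (attribute `generator_seed` records
#'   the seed).
#' @examples
#' p <- heinrich_base(generator_spec())
#' steady_state_gains(p)$g
#' @export
heinrich_base <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  beta <- if (spec$organization == "fast-slow-fast") c(1, 0.01, 1)
  else spec$beta
  if (length(beta) != 3L) stop("base set is a 3-stage cascade")
  alpha <- rep(spec$kinase_speed_factor * min(beta), 3L)
  m_tot <- rep(1, 3L)
  for (e0 in 10^(0:6)) {
    # effective alpha held fixed: alpha_bar.0 compensates the stimulus
    params <- cascade_params(alpha_bar = c(alpha[1] / e0, alpha[2:3]),
                             beta = beta, m_tot = m_tot, e0_init = e0)
    g2 <- steady_state_gains(params)$g[3]
    if (g2 > spec$activation_floor) {
      attr(params, "generator_seed") <- spec$seed
      return(params)
    }
  }
  stop("no stimulus up to 1e6 reaches the requested activation floor")
}

#' Organized Huang-Ferrell base parameter set
#'
#' All 10 enzymatic steps share one Michaelis-type scale (`a = 1`,
#' `d = 1`, `k = 1`, so Km = 2 in concentration units), substrate totals
#' are 100 per layer, and the phosphatase totals follow the fast-slow-fast
#' organization `p_tot = (1, 0.01, 1)`. The stimulus `e0_init` is raised
#' in decades (bounded search up to 1e4) until the equilibrated cascade is
#' activated (`g2 > 0.5`).
#'
#' @param spec a [generator_spec].
#' @param ... passed to [pre_stimulus_steady_state] (HF convergence
#'   controls).
#' @return an [hf_params] object.
#' @export
hf_base <- function(spec = generator_spec(), ...) {
  stopifnot(inherits(spec, "generator_spec"))
  p_tot <- if (spec$organization == "fast-slow-fast") c(1, 0.01, 1)
  else spec$beta
  for (e0 in 10^(1:4)) {
    params <- hf_params(a = rep(1, 10), d = rep(1, 10), k = rep(1, 10),
                        m_tot = rep(100, 3), p_tot = p_tot, e0_init = e0)
    g2 <- pre_stimulus_steady_state(hf_model(params), ...)$g2
    if (is_activated(g2)) {
      attr(params, "generator_seed") <- spec$seed
      return(params)
    }
  }
  stop("no stimulus up to 1e4 activates the generated HF cascade")
}

#' Random ensemble of cascade parameter sets
#'
#' Draws `n` 3-stage Heinrich parameter sets with log-uniform effective
#' kinase activities and phosphatase rates, filtered to the requested
#' constraints. Unit substrate totals and unit stimulus, so `alpha_bar`
#' equals the effective activity. Reproducible for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param n number of parameter sets to return.
#' @param seed integer seed.
#' @param constraints list with any of `activated` (logical: require
#'   `g2 > 0.5`), `distinct_beta` (logical: require pairwise relative beta
#'   gaps above 1e-6), `range` (length-2 numeric: log-uniform sampling
#'   range for all rates, default `c(1e-4, 1e4)`).
#' @param max_tries sampling attempts before giving up; if fewer than 1%
#'   of attempts pass the filter the constraint set is reported as too
#'   tight.
#' @return list of [cascade_params] objects, length `n`.
#' @export
random_ensemble <- function(n, seed = 1L,
                            constraints = list(activated = TRUE,
                                               distinct_beta = TRUE),
                            max_tries = max(1000L, 200L * n)) {
  stopifnot(n >= 1)
  range <- constraints$range %||% c(1e-4, 1e4)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draw <- function() 10^stats::runif(3, log10(range[1]), log10(range[2]))
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    params <- cascade_params(alpha_bar = draw(), beta = draw())
    if (isTRUE(constraints$distinct_beta)) {
      b <- sort(params$beta)
      if (any(diff(b) / b[-1] < 1e-6)) next
    }
    if (isTRUE(constraints$activated) &&
        !is_activated(steady_state_gains(params)$g[3])) next
    got <- got + 1L
    out[[got]] <- params
  }
  if (got < n)
    stop(sprintf(paste0("constraint acceptance too low: %d/%d sets after ",
                        "%d attempts"), got, n, tries))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
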
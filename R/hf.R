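# Huang-Ferrell mass-action MAPK cascade: 3 layers, explicit phosphatases
# and enzyme-substrate complexes; single phosphorylation in layer 0, double
# phosphorylation in layers 1 and 2 (10 enzymatic steps in total).
#
# Enzymatic step table (enzyme, substrate, product):
#   1  E0   + M0   -> M0p      2  P0 + M0p  -> M0
#   3  M0p  + M1   -> M1p      4  P1 + M1p  -> M1
#   5  M0p  + M1p  -> M1pp     6  P1 + M1pp -> M1p
#   7  M1pp + M2   -> M2p      8  P2 + M2p  -> M2
#   9  M1pp + M2p  -> M2pp    10  P2 + M2pp -> M2p
# Each step j is E + S <=>(a_j, d_j) C_j ->(k_j) E + P.

.hf_species <- c("M0", "M0p", "M1", "M1p", "M1pp", "M2", "M2p", "M2pp",
                 "E0", "P0", "P1", "P2", paste0("C", 1:10))

.hf_reactions <- data.frame(
  enzyme    = c("E0", "P0", "M0p", "P1", "M0p", "P1", "M1pp", "P2",
                "M1pp", "P2"),
  substrate = c("M0", "M0p", "M1", "M1p", "M1p", "M1pp", "M2", "M2p",
                "M2p", "M2pp"),
  product   = c("M0p", "M0", "M1p", "M1", "M1pp", "M1p", "M2p", "M2",
                "M2pp", "M2p"),
  stringsAsFactors = FALSE)

#' Parameters of the Huang-Ferrell mass-action cascade
#'
#' Each of the 10 enzymatic steps (see the step table in the package source)
#' is a Michaelis scheme `E + S <=> C -> E + P` with association rate `a`
#' (concentration^-1 time^-1), dissociation rate `d` (time^-1) and catalytic
#' rate `k` (time^-1). Phosphatases `P0, P1, P2` are explicit species, so
#' the dephosphorylation activity of a layer is proportional to its total
#' phosphatase concentration `p_tot`.
#'
#' @param a,d,k numeric vectors of length 10: association, dissociation and
#'   catalytic rates of enzymatic steps 1..10.
#' @param m_tot total substrate concentration of each of the 3 layers.
#' @param p_tot total phosphatase concentration of each of the 3 layers.
#' @param e0_init total input enzyme (receptor) present for `t < 0`.
#' @return object of class `hf_params`.
#' @seealso [hf_model], [hf_rhs], [hf_base]
#' @export
hf_params <- function(a, d, k, m_tot, p_tot, e0_init) {
  if (length(a) != 10L || length(d) != 10L || length(k) != 10L)
    stop("a, d and k must each have length 10 (one triplet per step)")
  if (length(m_tot) != 3L || length(p_tot) != 3L)
    stop("m_tot and p_tot must have length 3")
  vals <- c(a, d, k, m_tot, p_tot, e0_init)
  if (any(!is.finite(vals)) || any(c(a, d, k, m_tot, e0_init) <= 0) ||
      any(p_tot < 0))
    stop("rates, totals and e0_init must be positive (p_tot may be 0)")
  structure(list(a = as.numeric(a), d = as.numeric(d), k = as.numeric(k),
                 m_tot = as.numeric(m_tot), p_tot = as.numeric(p_tot),
                 e0_init = as.numeric(e0_init)),
            class = "hf_params")
}

#' Initial (fully dephosphorylated) state of the Huang-Ferrell cascade
#'
#' All substrate unphosphorylated and free, all enzymes free, no complexes;
#' the state from which the stimulated system is equilibrated.
#'
#' @param params an [hf_params] object.
#' @param stimulated if `FALSE`, free `E0` starts at 0 instead of `e0_init`.
#' @return named numeric vector over the 22 species.
#' @export
hf_initial_state <- function(params, stimulated = TRUE) {
  s <- stats::setNames(numeric(length(.hf_species)), .hf_species)
  s[c("M0", "M1", "M2")] <- params$m_tot
  s["E0"] <- if (stimulated) params$e0_init else 0
  s[c("P0", "P1", "P2")] <- params$p_tot
  s
}

#' Mass-action right-hand side of the Huang-Ferrell cascade
#'
#' Every enzymatic step `j` contributes the fluxes of
#' `E + S <=>(a_j, d_j) C_j ->(k_j) E + P` to the derivatives of its enzyme,
#' substrate, product and complex. Conservation of each substrate pool and
#' each enzyme pool holds by construction.
#'
#' @param state named numeric vector over the 22 species (see
#'   [hf_initial_state] for the naming).
#' @param params an [hf_params] object.
#' @param tol negative-concentration tolerance; components below `-tol` are
#'   rejected.
#' @return named numeric vector of derivatives.
#' @export
hf_rhs <- function(state, params, tol = 1e-8) {
  if (is.null(names(state))) names(state) <- .hf_species
  if (any(state < -tol))
    stop("negative concentrations beyond tolerance")
  d <- stats::setNames(numeric(length(state)), names(state))
  for (j in 1:10) {
    enz <- .hf_reactions$enzyme[j]
    sub <- .hf_reactions$substrate[j]
    prd <- .hf_reactions$product[j]
    cpx <- paste0("C", j)
    v_f <- params$a[j] * state[[enz]] * state[[sub]]
    v_b <- params$d[j] * state[[cpx]]
    v_c <- params$k[j] * state[[cpx]]
    d[[cpx]] <- d[[cpx]] + v_f - v_b - v_c
    d[[enz]] <- d[[enz]] - v_f + v_b + v_c
    d[[sub]] <- d[[sub]] - v_f + v_b
    d[[prd]] <- d[[prd]] + v_c
  }
  d
}

#' Conserved totals of a Huang-Ferrell state
#'
#' Sums each substrate pool (free forms plus every complex containing that
#' substrate) and each enzyme pool (free plus its complexes). Constant along
#' any trajectory of [hf_rhs].
#'
#' @param state named numeric state vector.
#' @return named numeric vector of the 7 conserved totals.
#' @export
hf_conserved_totals <- function(state) {
  c(substrate0 = unname(state["M0"] + state["M0p"] + state["C1"] +
                          state["C2"] + state["C3"] + state["C5"]),
    substrate1 = unname(state["M1"] + state["M1p"] + state["M1pp"] +
                          state["C3"] + state["C4"] + state["C5"] +
                          state["C6"] + state["C7"] + state["C9"]),
    substrate2 = unname(state["M2"] + state["M2p"] + state["M2pp"] +
                          state["C7"] + state["C8"] + state["C9"] +
                          state["C10"]),
    E0 = unname(state["E0"] + state["C1"]),
    P0 = unname(state["P0"] + state["C2"]),
    P1 = unname(state["P1"] + state["C4"] + state["C6"]),
    P2 = unname(state["P2"] + state["C8"] + state["C10"]))
}

# Remove the stimulus from an equilibrated HF state.
# hard: free E0 and the E0.M0 complex are deleted; the M0 sequestered in
#   that complex returns to the free unphosphorylated pool, so substrate
#   conservation is preserved while every trace of the input enzyme is gone.
# free_only: only free E0 is zeroed; existing complexes keep turning over.
hf_remove_stimulus <- function(state, mode = c("hard", "free_only")) {
  mode <- match.arg(mode)
  state["E0"] <- 0
  if (mode == "hard") {
    state["M0"] <- state["M0"] + state["C1"]
    state["C1"] <- 0
  }
  state
}

# Output (doubly phosphorylated terminal substrate) of an HF state.
hf_output <- function(state, include_bound = FALSE) {
  out <- state[["M2pp"]]
  if (include_bound) out <- out + state[["C10"]]
  out
}
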
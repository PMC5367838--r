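# Flat-key YAML parameter configs. Layer indices in keys are 0-based
# (beta.0 is the first layer) and reaction indices 1-based (a.1 .. a.10),
# matching the conventional notation for these models; R-level function
# arguments are 1-based as usual.

#' Read and write cascade parameter configs
#'
#' Parameter sets are serialized as flat-key YAML:
#' Heinrich — `alpha_bar.0 ..`, `beta.0 ..`, `m_tot.0 ..`, `e0_init`;
#' Huang-Ferrell — `a.1 .. a.10`, `d.1 ..`, `k.1 ..`, `substrate_tot.0 ..
#' substrate_tot.2`, `p_tot.0 .. p_tot.2`, `e0_init`. The model kind is
#' detected from the keys on read.
#'
#' @param params a [cascade_params] or [hf_params] object.
#' @param path file path.
#' @return `read_params` returns the parameter object; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  flat <- if (inherits(params, "cascade_params")) {
    n <- params$n_stages
    idx <- seq_len(n) - 1L
    c(stats::setNames(as.list(params$alpha_bar), paste0("alpha_bar.", idx)),
      stats::setNames(as.list(params$beta), paste0("beta.", idx)),
      stats::setNames(as.list(params$m_tot), paste0("m_tot.", idx)),
      list(e0_init = params$e0_init))
  } else if (inherits(params, "hf_params")) {
    c(stats::setNames(as.list(params$a), paste0("a.", 1:10)),
      stats::setNames(as.list(params$d), paste0("d.", 1:10)),
      stats::setNames(as.list(params$k), paste0("k.", 1:10)),
      stats::setNames(as.list(params$m_tot), paste0("substrate_tot.", 0:2)),
      stats::setNames(as.list(params$p_tot), paste0("p_tot.", 0:2)),
      list(e0_init = params$e0_init))
  } else stop("unsupported parameter object")
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- yaml::read_yaml(path)
  pick <- function(prefix, idx) {
    keys <- paste0(prefix, ".", idx)
    if (!all(keys %in% names(flat)))
      stop("missing config keys: ",
           paste(setdiff(keys, names(flat)), collapse = ", "))
    vapply(flat[keys], as.numeric, numeric(1), USE.NAMES = FALSE)
  }
  if ("a.1" %in% names(flat)) {
    hf_params(a = pick("a", 1:10), d = pick("d", 1:10), k = pick("k", 1:10),
              m_tot = pick("substrate_tot", 0:2),
              p_tot = pick("p_tot", 0:2),
              e0_init = as.numeric(flat$e0_init))
  } else {
    n <- sum(grepl("^beta\\.[0-9]+$", names(flat)))
    if (n == 0) stop("no beta.<i> keys found: not a cascade config")
    idx <- seq_len(n) - 1L
    cascade_params(alpha_bar = pick("alpha_bar", idx),
                   beta = pick("beta", idx), m_tot = pick("m_tot", idx),
                   e0_init = as.numeric(flat$e0_init))
  }
}

#' Set one parameter by flat key
#'
#' Addresses a single entry of a parameter set by its flat config key
#' (`beta.0`, `alpha_bar.1`, `m_tot.2`, `e0_init`, `p_tot.2`, `a.3`, ...).
#' For Heinrich parameter sets the pseudo-key `alpha.<i>` sets the
#' *effective* kinase activity of layer `i` by rescaling the underlying
#' second-order constant (`alpha.0` via `e0_init`-driven `alpha_bar.0`,
#' `alpha.i` via `m_tot[i-1]`-driven `alpha_bar.i`).
#'
#' @param params a [cascade_params] or [hf_params] object.
#' @param name flat key.
#' @param value new (positive) value.
#' @return the modified parameter object.
#' @export
set_param <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  field <- parts[1]
  idx <- if (length(parts) > 1) as.integer(parts[2]) else NA_integer_
  if (inherits(params, "cascade_params")) {
    i <- idx + 1L   # 0-based key -> 1-based layer
    switch(field,
      e0_init = { params$e0_init <- value },
      alpha_bar = { params$alpha_bar[i] <- value },
      beta = { params$beta[i] <- value },
      m_tot = { params$m_tot[i] <- value },
      alpha = {
        driver <- if (i == 1L) params$e0_init else params$m_tot[i - 1L]
        params$alpha_bar[i] <- value / driver
      },
      stop("unknown Heinrich parameter key: ", name))
    cascade_params(params$alpha_bar, params$beta, params$m_tot,
                   params$e0_init)
  } else if (inherits(params, "hf_params")) {
    switch(field,
      e0_init = { params$e0_init <- value },
      a = { params$a[idx] <- value },
      d = { params$d[idx] <- value },
      k = { params$k[idx] <- value },
      p_tot = { params$p_tot[idx + 1L] <- value },
      substrate_tot = { params$m_tot[idx + 1L] <- value },
      stop("unknown HF parameter key: ", name))
    hf_params(params$a, params$d, params$k, params$m_tot, params$p_tot,
              params$e0_init)
  } else stop("unsupported parameter object")
}
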
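#' Specification of a parameter sweep
#'
#' Describes one robustness sweep: which model, which parameter (by flat
#' key, see [set_param]), and a descending log10 grid of values.
#'
#' @param model `"heinrich"`, `"linearized"` or `"hf"`.
#' @param param flat parameter key, e.g. `"beta.0"`, `"alpha.1"`,
#'   `"p_tot.2"`.
#' @param base base parameter set ([cascade_params] or [hf_params]).
#' @param log_start,log_stop log10 of the first and last grid value.
#' @param log_step grid spacing in log10 (positive; applied in the
#'   `log_start -> log_stop` direction).
#' @return object of class `sweep_spec`.
#' @examples
#' base <- heinrich_base(generator_spec())
#' spec <- sweep_spec("heinrich", "beta.0", base,
#'                    log_start = 2, log_stop = -2)
#' @export
sweep_spec <- function(model = c("heinrich", "linearized", "hf"), param,
                       base, log_start, log_stop, log_step = 0.2) {
  model <- match.arg(model)
  if (log_step <= 0) stop("log_step must be positive")
  if (log_start == log_stop) stop("log_start and log_stop must differ")
  if (model == "hf") stopifnot(inherits(base, "hf_params"))
  else stopifnot(inherits(base, "cascade_params"))
  grid <- seq(log_start, log_stop,
              by = if (log_start > log_stop) -log_step else log_step)
  structure(list(model = model, param = param, base = base,
                 log_start = log_start, log_stop = log_stop,
                 log_step = log_step, grid = grid),
            class = "sweep_spec")
}

.make_model <- function(kind, params, ...) {
  switch(kind,
         heinrich = heinrich_model(params),
         linearized = linearized_model(params),
         hf = hf_model(params, ...))
}

.model_g2 <- function(model) {
  if (inherits(model, "hf_model")) pre_stimulus_steady_state(model)$g2
  else {
    ss <- pre_stimulus_steady_state(model)
    ss$g[length(ss$g)]
  }
}

# Smallest beta (Heinrich/linearized) or p_tot (HF) among the *other*
# layers, used to place the rate-limiting crossover marker; NA when the
# swept key is not a per-layer phosphatase activity.
.crossover_value <- function(spec) {
  parts <- strsplit(spec$param, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NA_real_)
  i <- as.integer(parts[2]) + 1L
  if (spec$model == "hf" && parts[1] == "p_tot")
    return(min(spec$base$p_tot[-i]))
  if (spec$model != "hf" && parts[1] == "beta")
    return(min(spec$base$beta[-i]))
  NA_real_
}

#' Run a robustness sweep
#'
#' For every grid value of the swept parameter: recompute the pre-stimulus
#' steady state, simulate the post-stimulus relaxation, measure the
#' half-life, the similarity of the output profile to the previous grid
#' point's, and the logarithmic gain of the half-life. Per-point failures
#' are recorded in the `status` column and do not abort the sweep; the
#' whole computation is deterministic given the spec.
#'
#' @param spec a [sweep_spec].
#' @param grid the `log10(t)` sampling grid for profiles ([tau_grid]).
#' @param sim_config a [similarity_config].
#' @param refine_gain also compute a locally refined gain at each point
#'   (central difference with `gain_step`, re-measuring the half-life), so
#'   robustness intervals do not depend on the sweep grid coarseness.
#'   Default on except for the (costly) HF model.
#' @param gain_step log10 half-step of the refined gain.
#' @param activation_threshold threshold on `g2` for [is_activated].
#' @param gain_threshold robustness threshold on the gain magnitude.
#' @param verbose print per-point progress.
#' @return Object of class `sweep_result`: list with
#'   * `records` — data.frame (one row per grid point): `log10_value`,
#'     `value`, `g2`, `activated`, `theta`, `similarity`, `gain`
#'     (sweep-grid central difference), `gain_refined`, `status`;
#'   * `profiles` — matrix of output profiles (rows = tau samples);
#'   * `tau` — profile sample grid;
#'   * `intervals`, `crossover` — see [robustness_interval];
#'   * `beta_max` — activation bound of the swept activity (when the swept
#'     key is a phosphatase activity), else `NA`;
#'   * `spec`, `sim_config`.
#' @export
run_sweep <- function(spec, grid = tau_grid(),
                      sim_config = similarity_config(),
                      refine_gain = spec$model != "hf",
                      gain_step = 0.05,
                      activation_threshold = 0.5, gain_threshold = 0.3,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  lg <- spec$grid
  npt <- length(lg)
  records <- data.frame(log10_value = lg, value = 10^lg,
                        g2 = NA_real_, activated = FALSE,
                        theta = NA_real_, similarity = NA_real_,
                        gain = NA_real_, gain_refined = NA_real_,
                        status = "ok", stringsAsFactors = FALSE)
  profiles <- matrix(NA_real_, nrow = length(grid), ncol = npt)
  prev_traj <- NULL

  theta_at <- function(value) {
    params <- set_param(spec$base, spec$param, value)
    half_life(.make_model(spec$model, params))
  }

  for (j in seq_len(npt)) {
    res <- tryCatch({
      params <- set_param(spec$base, spec$param, 10^lg[j])
      model <- .make_model(spec$model, params)
      g2 <- .model_g2(model)
      traj <- simulate_relaxation(model, grid = grid)
      theta <- suppressWarnings(half_life(model))
      list(g2 = g2, traj = traj, theta = theta, err = NULL)
    }, error = function(e) list(err = conditionMessage(e)))
    if (!is.null(res$err)) {
      records$status[j] <- res$err
      prev_traj <- NULL
      next
    }
    records$g2[j] <- res$g2
    records$activated[j] <- is_activated(res$g2, activation_threshold)
    records$theta[j] <- res$theta
    profiles[, j] <- res$traj$output
    if (!is.null(prev_traj))
      records$similarity[j] <- consecutive_similarity(
        prev_traj, res$traj, lg[j] - lg[j - 1], config = sim_config)
    prev_traj <- res$traj
    if (verbose)
      message(sprintf("  %s = 10^%.2f: g2 = %.4f, theta = %.4g",
                      spec$param, lg[j], res$g2, res$theta))
  }

  # central-difference gain of log10(theta) on the sweep grid itself
  lt <- log10(records$theta)
  for (j in seq_len(npt)) {
    lo <- if (j > 1) j - 1 else j
    hi <- if (j < npt) j + 1 else j
    if (hi > lo && is.finite(lt[lo]) && is.finite(lt[hi]))
      records$gain[j] <- (lt[hi] - lt[lo]) / (lg[hi] - lg[lo])
  }
  if (isTRUE(refine_gain)) {
    for (j in seq_len(npt)) {
      if (!is.finite(records$theta[j])) next
      records$gain_refined[j] <- tryCatch(
        log_gain(theta_at, 10^lg[j], step_log10 = gain_step),
        error = function(e) NA_real_)
    }
  }

  result <- structure(list(records = records, profiles = profiles,
                           tau = grid, spec = spec,
                           sim_config = sim_config,
                           crossover = .crossover_value(spec),
                           beta_max = NA_real_),
                      class = "sweep_result")
  ri <- robustness_interval(result, threshold = gain_threshold)
  result$intervals <- ri$intervals
  parts <- strsplit(spec$param, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    stage <- as.integer(parts[2]) + 1L
    if (spec$model != "hf" && parts[1] == "beta")
      result$beta_max <- suppressWarnings(
        beta_max(spec$base, stage, threshold = activation_threshold))
    else if (spec$model == "hf" && parts[1] == "p_tot")
      result$beta_max <- suppressWarnings(tryCatch(
        beta_max(.make_model("hf", spec$base), stage,
                 threshold = activation_threshold),
        error = function(e) NA_real_))
  }
  result
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep of %s (%s model): %d points, 10^%.2f .. 10^%.2f\n",
              x$spec$param, x$spec$model, length(x$spec$grid),
              x$spec$log_start, x$spec$log_stop))
  cat(sprintf("  activated points: %d / %d\n", sum(x$records$activated),
              nrow(x$records)))
  if (nrow(x$intervals) > 0) {
    cat("  robust intervals (log10):\n")
    for (r in seq_len(nrow(x$intervals)))
      cat(sprintf("    [%.2f, %.2f] (%d points)\n",
                  x$intervals$log10_lo[r], x$intervals$log10_hi[r],
                  x$intervals$n_points[r]))
  } else cat("  no robust interval\n")
  if (is.finite(x$beta_max))
    cat(sprintf("  activation bound (beta_max): %.4g\n", x$beta_max))
  if (is.finite(x$crossover))
    cat(sprintf("  rate-limiting crossover at: %.4g\n", x$crossover))
  invisible(x)
}

#' Effect of kinase activity on activation bounds
#'
#' For each requested effective kinase activity value, rebuilds the cascade
#' and recomputes the activation bound `beta_max` of each requested layer.
#' Verifies the upstream-shielding structure: raising `alpha_k` raises
#' `beta_max` proportionally for layers at or above `k` and leaves layers
#' below `k` untouched.
#'
#' @param base a [cascade_params] object.
#' @param alpha_stage which effective kinase activity to vary (1-based).
#' @param alpha_values values to set it to.
#' @param beta_stages layers whose `beta_max` to record (1-based).
#' @param sweep_grid optional `c(log_start, log_stop)`; when given, a
#'   half-life sweep of each layer's `beta` is run at every alpha value and
#'   returned under `curves`.
#' @param ... passed to [run_sweep].
#' @return list with `beta_max` (data.frame: `alpha_value`, `stage`,
#'   `beta_max`) and `curves` (list of [run_sweep] results or `NULL`).
#' @export
kinase_effect_scan <- function(base, alpha_stage, alpha_values,
                               beta_stages = seq_len(base$n_stages),
                               sweep_grid = NULL, ...) {
  stopifnot(inherits(base, "cascade_params"))
  key <- paste0("alpha.", alpha_stage - 1L)
  rows <- expand.grid(alpha_value = alpha_values, stage = beta_stages)
  rows$beta_max <- NA_real_
  curves <- if (is.null(sweep_grid)) NULL else list()
  for (r in seq_len(nrow(rows))) {
    params <- set_param(base, key, rows$alpha_value[r])
    rows$beta_max[r] <- suppressWarnings(
      beta_max(params, rows$stage[r]))
  }
  if (!is.null(sweep_grid)) {
    for (av in alpha_values) {
      params <- set_param(base, key, av)
      for (st in beta_stages) {
        id <- sprintf("alpha%d=%g_beta%d", alpha_stage - 1L, av, st - 1L)
        curves[[id]] <- run_sweep(
          sweep_spec("heinrich", paste0("beta.", st - 1L), params,
                     log_start = sweep_grid[1], log_stop = sweep_grid[2]),
          ...)
      }
    }
  }
  list(beta_max = rows, curves = curves)
}

#' Export and re-import sweep results
#'
#' Writes the per-point record table as CSV and the derived summary
#' (sweep definition, robust intervals, activation bound, crossover) as
#' JSON. `read_sweep_records` reads the CSV back into an identical
#' data.frame.
#'
#' @param result a [run_sweep] result.
#' @param dir output directory (created if needed).
#' @param name file stem; files are `<name>.csv` and `<name>.json`.
#' @return invisibly, the two file paths.
#' @export
export_results <- function(result, dir, name = "sweep") {
  stopifnot(inherits(result, "sweep_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  json <- file.path(dir, paste0(name, ".json"))
  utils::write.csv(result$records, csv, row.names = FALSE)
  report <- list(
    model = result$spec$model,
    param = result$spec$param,
    grid = list(log_start = result$spec$log_start,
                log_stop = result$spec$log_stop,
                log_step = result$spec$log_step,
                n_points = length(result$spec$grid)),
    intervals = result$intervals,
    beta_max = result$beta_max,
    crossover = result$crossover,
    n_activated = sum(result$records$activated))
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = json))
}

#' @rdname export_results
#' @param path CSV path written by `export_results`.
#' @export
read_sweep_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Structural check of an exported sweep report
#'
#' Verifies that a JSON report written by [export_results] has the expected
#' fields and types (the bundled `inst/extdata/sweep-report-schema.json`
#' documents the layout).
#'
#' @param path JSON report path.
#' @return `TRUE` (invisibly) or an error describing the first violation.
#' @export
validate_report <- function(path) {
  rep <- jsonlite::read_json(path)
  need <- c("model", "param", "grid", "intervals", "n_activated")
  miss <- setdiff(need, names(rep))
  if (length(miss) > 0)
    stop("report missing fields: ", paste(miss, collapse = ", "))
  if (!rep$model %in% c("heinrich", "linearized", "hf"))
    stop("unknown model kind in report")
  gneed <- c("log_start", "log_stop", "log_step", "n_points")
  if (!all(gneed %in% names(rep$grid)))
    stop("report grid block incomplete")
  for (iv in rep$intervals)
    if (!all(c("log10_lo", "log10_hi", "n_points") %in% names(iv)))
      stop("malformed interval entry")
  invisible(TRUE)
}

#' Plot a sweep result
#'
#' Four base-graphics panels: half-life vs swept value (log-log, robust
#' intervals shaded), logarithmic gain with the robustness band, profile
#' similarity, and the activation level `g2`.
#'
#' @param x a [run_sweep] result.
#' @param ... unused.
#' @export
plot.sweep_result <- function(x, ...) {
  df <- x$records
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(df$log10_value, log10(df$theta), type = "b", pch = 16,
                 cex = 0.6, xlab = paste0("log10 ", x$spec$param),
                 ylab = "log10 half-life", main = "duration")
  if (nrow(x$intervals) > 0)
    for (r in seq_len(nrow(x$intervals)))
      graphics::abline(v = c(x$intervals$log10_lo[r],
                             x$intervals$log10_hi[r]), lty = 2)
  if (is.finite(x$crossover))
    graphics::points(log10(x$crossover),
                     min(log10(df$theta), na.rm = TRUE), pch = 17,
                     col = "magenta")
  gain <- ifelse(is.finite(df$gain_refined), df$gain_refined, df$gain)
  graphics::plot(df$log10_value, gain, type = "b", pch = 16, cex = 0.6,
                 xlab = paste0("log10 ", x$spec$param),
                 ylab = "log gain of half-life", main = "gain")
  graphics::abline(h = c(-0.3, 0.3), lty = 3)
  graphics::plot(df$log10_value, df$similarity, type = "b", pch = 16,
                 cex = 0.6, xlab = paste0("log10 ", x$spec$param),
                 ylab = "consecutive similarity", main = "similarity")
  graphics::abline(h = x$sim_config$threshold, lty = 3)
  graphics::plot(df$log10_value, df$g2, type = "b", pch = 16, cex = 0.6,
                 ylim = c(0, 1), xlab = paste0("log10 ", x$spec$param),
                 ylab = "g2", main = "activation")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
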
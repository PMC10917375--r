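#' Construct a region time-series container
#'
#' @param values Volumes x nodes matrix of BOLD signal.
#' @param TR Repetition time (s).
#' @param run Integer run label per volume.
#' @param nodes Node labels (column names of `values`).
#' @param units Character description of the signal units.
#' @param meta Optional named list of provenance metadata (seed, parameters
#'   file, simulation settings).
#' @return Object of class `region_ts`.
#' @export
region_ts <- function(values, TR, run, nodes = colnames(values),
                      units = "% signal change", meta = list()) {
  stopifnot(is.matrix(values), !anyNA(values), length(run) == nrow(values))
  colnames(values) <- nodes
  structure(list(values = values, TR = TR, run = as.integer(run),
                 nodes = nodes, units = units, meta = meta),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat("Region time series:", nrow(x$values), "volumes x",
      ncol(x$values), "nodes;", length(unique(x$run)), "run(s); TR =",
      x$TR, "s;", x$units, "\n")
  invisible(x)
}

#' Simulate BOLD time series from a DCM parameter set
#'
#' Integrates the bilinear neural dynamics `dx/dt = J(u) x + C u` and the
#' balloon hemodynamic cascade at microtime resolution and samples the BOLD
#' observation at every TR. Inputs are piecewise constant over microtime
#' bins, so the neural substep uses the exact matrix-exponential propagator
#' of `J(u)` over one bin (propagators are cached per distinct input value);
#' the hemodynamic states are advanced by classical RK4. The noiseless
#' simulation is a deterministic, reproducible function of the parameters
#' and design. With `noise_seed` set, iid Gaussian noise with per-node
#' variance `exp(-noise_log_precision)` is added.
#'
#' @param params A [dcm_params()] object.
#' @param design An [experiment_design()].
#' @param noise_seed Integer seed for observation noise, or `NULL` for a
#'   noiseless simulation.
#' @param TE Echo time (s).
#' @param return_neural If `TRUE`, attach the microtime neural trajectory as
#'   attribute `"neural"`.
#' @param x_bound Instability guard: integration aborts with an error if any
#'   `|x|` exceeds this bound.
#' @return A [region_ts()] of simulated BOLD in % signal change.
#' @export
simulate_bold <- function(params, design, noise_seed = NULL, TE = 0.03,
                          return_neural = FALSE, x_bound = 8) {
  stopifnot(inherits(params, "dcm_params"), inherits(design, "experiment_design"))
  U <- design_inputs(design)
  mod_idx <- match(names(params$B), colnames(U))
  drv_idx <- match(colnames(params$C), colnames(U))
  if (anyNA(mod_idx) || anyNA(drv_idx)) {
    stop("design inputs do not cover the model's modulatory/driving inputs")
  }
  # identical input rows share one cached propagator (grouping precomputed
  # by experiment_design)
  grp <- design$input_group
  Ug <- U[design$group_rows, , drop = FALSE]

  res <- .simulate_dcm_cpp(
    A = params$A,
    B = array(unlist(params$B), dim = c(nrow(params$A), ncol(params$A),
                                        length(params$B))),
    C = params$C,
    Umod = Ug[, mod_idx, drop = FALSE],
    Udrive = Ug[, drv_idx, drop = FALSE],
    grp = as.integer(grp - 1L),
    sample_idx = as.integer(design$sample_idx),
    run_start = as.integer(design$run_start),
    kappa = params$hemo$kappa, gamma_ = params$hemo$gamma,
    tau = params$hemo$tau, alpha = params$hemo$alpha,
    E0 = params$hemo$E0, V0 = params$hemo$V0,
    TE = TE, dt = design$microtime_dt, x_bound = x_bound,
    return_neural = return_neural,
    stride = if (round(design$TR / design$microtime_dt) %% 2 == 0) 2L else 1L
  )
  if (!res$ok) {
    stop(sprintf(paste0(
      "unstable simulation at microtime step %d (max |neural activity| ",
      "%.2f, bound %g): the A/B/C parameter regime either makes J(u) ",
      "non-contracting or drives the hemodynamics out of their admissible ",
      "domain (inflow collapse under sustained negative drive)"),
      res$bad_step, res$max_abs_x, x_bound))
  }
  y <- res$bold
  colnames(y) <- params$nodes
  if (!is.null(noise_seed)) {
    sdn <- exp(-params$noise_log_precision / 2)
    noise <- with_seed(noise_seed, {
      matrix(rnorm(length(y)), nrow(y), ncol(y)) %*% diag(sdn, ncol(y))
    })
    y <- y + noise
  }
  ts <- region_ts(y, TR = design$TR, run = design_run_labels(design),
                  nodes = params$nodes,
                  meta = list(noise_seed = noise_seed, TE = TE,
                              microtime_dt = design$microtime_dt,
                              mean_centered = design$mean_center))
  if (return_neural) {
    neural <- res$neural
    colnames(neural) <- params$nodes
    attr(ts, "neural") <- neural
  }
  ts
}
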
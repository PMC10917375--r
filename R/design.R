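#' Construct an experiment design for forward simulation and inversion
#'
#' Holds the condition input functions at microtime resolution together with
#' the acquisition timing. Condition inputs are boxcars built from block
#' onsets and durations; they are stored in raw 0/1 form and, when
#' `mean_center = TRUE` (the default, matching the convention that all model
#' inputs are mean-centered so that the `A` matrix is mean effective
#' connectivity independent of condition), the temporal mean of each input
#' over the whole session is subtracted before the inputs enter the model.
#'
#' @param blocks Data frame with columns `run`, `condition`, `onset` (s,
#'   relative to run start) and `duration` (s).
#' @param TR Repetition time in seconds.
#' @param n_volumes Number of volumes per run.
#' @param n_runs Number of runs.
#' @param microtime_dt Integration step in seconds; must divide `TR`.
#'   Defaults to `TR / 16`.
#' @param conditions Input names, in order; defaults to the conditions
#'   present in `blocks`.
#' @param modulatory,driving Which conditions enter the `B` and `C`
#'   matrices. Defaults: all conditions enter both.
#' @param mean_center Whether model inputs are mean-centered.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(blocks, TR, n_volumes, n_runs,
                              microtime_dt = TR / 16,
                              conditions = NULL,
                              modulatory = NULL, driving = NULL,
                              mean_center = TRUE) {
  steps_per_tr <- TR / microtime_dt
  if (abs(steps_per_tr - round(steps_per_tr)) > 1e-9) {
    stop("`microtime_dt` must divide `TR`")
  }
  steps_per_tr <- as.integer(round(steps_per_tr))
  if (is.null(conditions)) conditions <- unique(as.character(blocks$condition))
  if (is.null(modulatory)) modulatory <- conditions
  if (is.null(driving)) driving <- conditions

  nmicro_run <- n_volumes * steps_per_tr
  t_run <- (seq_len(nmicro_run) - 1) * microtime_dt
  U <- matrix(0, nmicro_run * n_runs, length(conditions),
              dimnames = list(NULL, conditions))
  for (r in seq_len(n_runs)) {
    off <- (r - 1) * nmicro_run
    br <- blocks[blocks$run == r, , drop = FALSE]
    for (i in seq_len(nrow(br))) {
      on <- t_run >= br$onset[i] & t_run < br$onset[i] + br$duration[i]
      U[off + which(on), as.character(br$condition[i])] <- 1
    }
  }
  run_start <- rep(FALSE, nrow(U))
  run_start[(seq_len(n_runs) - 1) * nmicro_run + 1] <- TRUE
  sample_idx <- rep(-1L, nrow(U))
  vol <- 0L
  for (r in seq_len(n_runs)) {
    idx <- (r - 1) * nmicro_run + (seq_len(n_volumes) - 1) * steps_per_tr + 1
    sample_idx[idx] <- vol + seq_len(n_volumes) - 1L
    vol <- vol + n_volumes
  }
  # cache the grouping of identical input rows (propagators are computed
  # once per distinct input value during simulation)
  key <- do.call(paste, c(lapply(seq_len(ncol(U)), function(j) U[, j]),
                          sep = "\r"))
  structure(
    list(inputs_raw = U, conditions = conditions, modulatory = modulatory,
         driving = driving, TR = TR, n_volumes = n_volumes, n_runs = n_runs,
         microtime_dt = microtime_dt, mean_center = mean_center,
         run_start = run_start, sample_idx = sample_idx, blocks = blocks,
         input_group = match(key, unique(key)),
         group_rows = which(!duplicated(key))),
    class = "experiment_design"
  )
}

#' Model inputs of a design (mean-centered if requested)
#'
#' @param design An [experiment_design()].
#' @return Matrix of input values at microtime resolution; values lie in
#'   `[0, 1]` before centering and in `[-1, 1]` after.
#' @export
design_inputs <- function(design) {
  U <- design$inputs_raw
  if (isTRUE(design$mean_center)) {
    U <- sweep(U, 2, colMeans(U), "-")
  }
  U
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", x$n_runs, "run(s) x", x$n_volumes,
      "volumes, TR =", x$TR, "s, dt =", x$microtime_dt, "s\n")
  cat("Inputs:", paste(x$conditions, collapse = ", "),
      if (isTRUE(x$mean_center)) "(mean-centered)" else "(raw)", "\n")
  invisible(x)
}

#' Volume indices partitioning runs
#' @param design An [experiment_design()].
#' @return Integer vector of run labels, one per volume.
#' @export
design_run_labels <- function(design) {
  rep(seq_len(design$n_runs), each = design$n_volumes)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
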
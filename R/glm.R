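#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak at ~5 s, undershoot at
#' ~15 s, undershoot ratio 1/6), normalized to unit peak.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay,undershoot_delay Gamma shape parameters (rate 1).
#' @param ratio Undershoot ratio.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h / max(h)
}

#' Discrete cosine high-pass basis
#'
#' The standard drift basis: `floor(2 * duration / cutoff) + 1` cosine
#' regressors (including the constant term) spanning fluctuations slower
#' than the cutoff period.
#'
#' @param n Number of samples.
#' @param TR Sampling interval (s).
#' @param cutoff High-pass cutoff period (s), default 128.
#' @return Matrix `n x K`.
#' @export
dct_basis <- function(n, TR, cutoff = 128) {
  K <- floor(2 * n * TR / cutoff) + 1
  k <- seq_len(K) - 1
  outer(seq_len(n) - 0.5, k, function(i, kk) cos(pi * kk * i / n))
}

#' Build an event-related GLM design
#'
#' Condition regressors are built as boxcars at microtime resolution from
#' trial onsets and durations, convolved with the canonical HRF, and sampled
#' at the TR. High-pass filtering is implemented as residualization against
#' a discrete cosine basis (cutoff default 128 s), kept in the design as
#' nuisance columns together with any supplied confounds and run
#' intercepts.
#'
#' @param events Data frame with `onset`, `duration`, `trial_type` and
#'   optionally `run` (onsets relative to run start).
#' @param TR Repetition time (s).
#' @param n_volumes Volumes per run.
#' @param n_runs Number of runs.
#' @param confounds Optional matrix of confound columns (e.g. six motion
#'   parameters), `n_volumes * n_runs` rows.
#' @param hp_cutoff High-pass cutoff in seconds.
#' @param microtime_dt Microtime resolution for convolution (s).
#' @return Object of class `glm_design` with `X` (condition regressors),
#'   `nuisance` (cosine basis per run, run intercepts, confounds) and
#'   metadata.
#' @export
build_design <- function(events, TR, n_volumes, n_runs = 1L,
                         confounds = NULL, hp_cutoff = 128,
                         microtime_dt = TR / 16) {
  if (is.null(events$run)) events$run <- 1L
  conditions <- sort(unique(as.character(events$trial_type)))
  n_total <- n_volumes * n_runs
  steps <- as.integer(round(TR / microtime_dt))
  nm_run <- n_volumes * steps
  t_run <- (seq_len(nm_run) - 1) * microtime_dt
  hrf <- canonical_hrf(seq(0, 32, by = microtime_dt))

  X <- matrix(0, n_total, length(conditions),
              dimnames = list(NULL, conditions))
  for (r in seq_len(n_runs)) {
    er <- events[events$run == r, , drop = FALSE]
    if (max(er$onset + er$duration, 0) > n_volumes * TR) {
      stop("events overrun the scan duration in run ", r)
    }
    for (cond in conditions) {
      ec <- er[er$trial_type == cond, , drop = FALSE]
      u <- numeric(nm_run)
      for (i in seq_len(nrow(ec))) {
        on <- t_run >= ec$onset[i] & t_run < ec$onset[i] + ec$duration[i]
        u[on] <- 1
      }
      conv <- stats::convolve(u, rev(hrf), type = "open")[seq_len(nm_run)] *
        microtime_dt
      rows <- (r - 1) * n_volumes + seq_len(n_volumes)
      X[rows, cond] <- conv[(seq_len(n_volumes) - 1) * steps + 1]
    }
  }
  dct <- dct_basis(n_volumes, TR, hp_cutoff)
  nuis <- matrix(0, n_total, ncol(dct) * n_runs)
  for (r in seq_len(n_runs)) {
    rows <- (r - 1) * n_volumes + seq_len(n_volumes)
    cols <- (r - 1) * ncol(dct) + seq_len(ncol(dct))
    nuis[rows, cols] <- dct
  }
  colnames(nuis) <- paste0("dct", seq_len(ncol(nuis)))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == n_total)
    nuis <- cbind(nuis, confounds)
  }
  qrX <- qr(cbind(X - qr.fitted(qr(nuis), X)))
  if (qrX$rank < ncol(X)) {
    stop("condition regressors are rank deficient after filtering")
  }
  structure(list(X = X, nuisance = nuis, conditions = conditions, TR = TR,
                 n_volumes = n_volumes, n_runs = n_runs,
                 hp_cutoff = hp_cutoff),
            class = "glm_design")
}

#' Fit a contrast by ordinary least squares
#'
#' Residualizes the data and condition regressors against the nuisance
#' space (cosine drift basis, run intercepts, confounds), fits OLS per
#' series and returns the contrast effect, t-statistic
#' `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)` and two-sided p-value, with a
#' peak table sorted by t.
#'
#' @param data Matrix (volumes x series), [region_ts()], or vector.
#' @param design A [build_design()] result.
#' @param contrast Named or positional weights over conditions (e.g.
#'   `c(Go = -1, NoGo = 1)` for NoGo > Go).
#' @return Object of class `contrast_result`: data frame `table` (series,
#'   effect, t, p) and `peaks` (sorted by t, descending).
#' @export
fit_contrast <- function(data, design, contrast) {
  Y <- if (inherits(data, "region_ts")) data$values else as.matrix(data)
  stopifnot(nrow(Y) == nrow(design$X))
  cw <- setNames(rep(0, ncol(design$X)), design$conditions)
  if (!is.null(names(contrast))) cw[names(contrast)] <- contrast
  else cw[] <- contrast
  if (all(cw == 0)) stop("degenerate contrast: all weights zero")

  qn <- qr(design$nuisance)
  Yr <- Y - qr.fitted(qn, Y)
  Xr <- design$X - qr.fitted(qn, design$X)
  XtXi <- solve(crossprod(Xr))
  beta <- XtXi %*% crossprod(Xr, Yr)
  fitted <- Xr %*% beta
  res <- Yr - fitted
  df <- nrow(Y) - qn$rank - qr(Xr)$rank
  sigma2 <- colSums(res^2) / df
  if (any(sigma2 <= .Machine$double.eps * colSums(Yr^2 + 1))) {
    stop("degenerate fit: zero residual variance in at least one series")
  }
  eff <- drop(crossprod(cw, beta))
  se <- sqrt(sigma2 * drop(crossprod(cw, XtXi %*% cw)))
  t <- eff / se
  tab <- data.frame(series = seq_len(ncol(Y)), effect = eff, t = t,
                    p = 2 * pt(-abs(t), df))
  if (!is.null(colnames(Y))) tab$series <- colnames(Y)
  structure(list(table = tab, peaks = tab[order(-tab$t), ], df = df,
                 contrast = cw, beta = beta),
            class = "contrast_result")
}

#' Second-level t-tests over subject contrast values
#'
#' One-sample t-test of the group mean, or a two-sample comparison when a
#' grouping factor (e.g. sex) is given.
#'
#' @param con Numeric vector of per-subject contrast values (or matrix,
#'   subjects x voxels).
#' @param group Optional factor with two levels.
#' @return Data frame with t, df and p per column.
#' @export
group_ttest <- function(con, group = NULL) {
  con <- as.matrix(con)
  out <- lapply(seq_len(ncol(con)), function(j) {
    if (is.null(group)) {
      tt <- stats::t.test(con[, j])
    } else {
      tt <- stats::t.test(con[, j] ~ group, var.equal = TRUE)
    }
    data.frame(column = j, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Define an individual region of interest around a group peak
#'
#' The individual peak is the voxel maximizing the t-map within the
#' intersection of an atlas mask and a sphere around the group peak. Ties
#' are broken deterministically by the lexicographically smallest
#' coordinate; if no voxel survives an optional threshold the group peak is
#' returned, flagged as a fallback.
#'
#' @param tmap Numeric vector of t-values per voxel.
#' @param coords Integer matrix (voxels x 3) of 0-based voxel coordinates.
#' @param mask Logical vector: atlas mask membership per voxel.
#' @param group_peak Length-3 coordinate of the group-level peak.
#' @param radius Inclusion radius in voxels (default 2).
#' @param threshold Optional minimum t.
#' @param label Node label.
#' @return Object of class `roi_definition` with the individual peak, the
#'   member voxel indices (within the radius of the individual peak), and a
#'   `fallback` flag.
#' @export
define_roi <- function(tmap, coords, mask, group_peak, radius = 2,
                       threshold = NULL, label = "ROI") {
  stopifnot(length(tmap) == nrow(coords), length(mask) == nrow(coords))
  if (!any(mask)) stop("empty atlas mask")
  d2 <- rowSums(sweep(coords, 2, group_peak, "-")^2)
  cand <- which(mask & d2 <= radius^2)
  if (!is.null(threshold)) cand <- cand[tmap[cand] > threshold]
  fallback <- length(cand) == 0
  if (fallback) {
    peak <- group_peak
  } else {
    best <- cand[tmap[cand] == max(tmap[cand])]
    if (length(best) > 1) {
      ord <- do.call(order, as.data.frame(coords[best, , drop = FALSE]))
      best <- best[ord[1]]
    }
    peak <- coords[best, ]
  }
  d2i <- rowSums(sweep(coords, 2, peak, "-")^2)
  members <- which(mask & d2i <= radius^2)
  structure(list(label = label, peak = peak, group_peak = group_peak,
                 members = members, radius = radius, fallback = fallback),
            class = "roi_definition")
}

#' Extract a region's summary time series (first eigenvariate)
#'
#' The first principal eigenvariate of the ROI voxel matrix, sign-aligned
#' with the ROI mean signal and rescaled so its standard deviation equals
#' that of the ROI mean. Invariant to voxel ordering.
#'
#' @param Y Matrix (time x voxels) of the full grid, or of the ROI only.
#' @param roi A [define_roi()] result, or voxel indices; omit to use all
#'   columns of `Y`.
#' @return Numeric time series (demeaned).
#' @export
extract_timeseries <- function(Y, roi = NULL) {
  idx <- if (is.null(roi)) seq_len(ncol(Y)) else
    if (inherits(roi, "roi_definition")) roi$members else roi
  stopifnot(length(idx) >= 1)
  Yr <- Y[, idx, drop = FALSE]
  Yr <- sweep(Yr, 2, colMeans(Yr), "-")
  m <- rowMeans(Yr)
  if (sd(m) == 0 && all(apply(Yr, 2, sd) == 0)) {
    stop("constant ROI data: zero-variance signal")
  }
  sv <- svd(Yr, nu = 1, nv = 0)
  ts <- sv$u[, 1] * sv$d[1]
  if (sum(ts * m) < 0) ts <- -ts
  if (sd(ts) > 0 && sd(m) > 0) ts <- ts * sd(m) / sd(ts)
  ts
}
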
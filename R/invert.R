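#' Invert a DCM for one subject's region time series
#'
#' Fits the full bilinear model to observed (or simulated) BOLD by
#' variational Laplace (see [vl_fit()]): Gauss-Newton updates of the
#' posterior mean with Levenberg damping so the accepted free-energy trace
#' is non-decreasing, and safeguarded Newton updates of one iid noise log
#' precision per node. Runs are handled by concatenation with run-wise mean
#' removal of both data and prediction (run-specific baselines) and state
#' resets between runs; there is no dynamic carry-over across runs.
#' Inversion is deterministic given data and priors.
#'
#' @param data A [region_ts()] aligned with `design`.
#' @param design The [experiment_design()] used for the forward model.
#' @param priors A [prior_spec()]; defaults to [default_priors()].
#' @param model Template [dcm_params()] fixing the model structure (nodes,
#'   input names, non-estimated hemodynamic constants).
#' @param control Optimizer control passed to [vl_fit()].
#' @return A `posterior_estimate` with `explained_variance` (%) attached.
#' @export
invert_dcm <- function(data, design, priors = default_priors(model),
                       model = default_truth_template(),
                       control = list()) {
  stopifnot(inherits(data, "region_ts"), inherits(design, "experiment_design"))
  if (nrow(data$values) != design$n_volumes * design$n_runs) {
    stop("data and design are not aligned (volume count mismatch)")
  }
  runs <- data$run
  demean_runs <- function(Y) {
    for (r in unique(runs)) {
      idx <- runs == r
      Y[idx, ] <- sweep(Y[idx, , drop = FALSE], 2,
                        colMeans(Y[idx, , drop = FALSE]), "-")
    }
    Y
  }
  yf <- demean_runs(data$values)
  g <- function(theta) {
    pars <- unpack_params(theta, model)
    demean_runs(simulate_bold(pars, design)$values)
  }
  post <- vl_fit(yf, g, priors, control = control)
  post$explained_variance <- explained_variance(post)
  post$nodes <- model$nodes
  post
}

#' Percent variance explained by the posterior-mean prediction
#'
#' `100 (1 - SS_res / SS_tot)` with sums over all nodes and volumes of the
#' run-demeaned data versus the posterior-mean prediction. Subjects whose
#' model explains less than 10% are conventionally excluded from group
#' analysis (see [apply_inclusion_rule()]).
#'
#' @param post A `posterior_estimate` from [invert_dcm()] (or [vl_fit()]),
#'   which carries the filtered data and prediction.
#' @return Explained variance in percent (at most 100; can be negative if
#'   the model predicts worse than the mean).
#' @export
explained_variance <- function(post) {
  y <- post$observed
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("zero total variance in the observed series")
  100 * (1 - sum((y - post$prediction)^2) / ss_tot)
}

#' Apply the explained-variance inclusion rule to a cohort of fits
#'
#' Partitions subjects into included (explained variance at or above the
#' threshold) and excluded, and -- when a behavioral table is supplied --
#' reports two-sample comparisons of the behavioral summaries between the
#' two groups as a selection-bias check.
#'
#' @param posteriors List of `posterior_estimate`s (or a numeric vector of
#'   explained variances).
#' @param threshold Explained-variance cutoff in percent (default 10).
#' @param behavior Optional [behavior_table()]-style data frame, one row per
#'   subject in the same order.
#' @return List with `included`, `excluded` (integer indices), `ev`, and
#'   `bias_check` (data frame of p-values, or `NULL`).
#' @export
apply_inclusion_rule <- function(posteriors, threshold = 10,
                                 behavior = NULL) {
  stopifnot(threshold > 0, threshold < 100)
  ev <- if (is.numeric(posteriors)) posteriors else
    vapply(posteriors, function(p) p$explained_variance, numeric(1))
  included <- which(ev >= threshold)
  excluded <- which(ev < threshold)
  if (!length(included)) stop("inclusion rule excluded every subject")
  bias <- NULL
  if (!is.null(behavior) && length(excluded) >= 2 && length(included) >= 2) {
    measures <- intersect(c("go_acc", "nogo_acc", "rt_ms"), names(behavior))
    bias <- do.call(rbind, lapply(measures, function(m) {
      tt <- stats::t.test(behavior[[m]][included], behavior[[m]][excluded])
      data.frame(measure = m, t = unname(tt$statistic), p = tt$p.value)
    }))
  }
  list(included = included, excluded = excluded, ev = ev, bias_check = bias,
       threshold = threshold)
}
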
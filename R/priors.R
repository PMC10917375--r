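#' Prior specification for model inversion
#'
#' Diagonal Gaussian priors over the estimable parameter vector (see
#' [param_names()]) plus Gaussian hyperpriors on the per-node log precision
#' of observation noise. Parameters with zero prior variance are switched
#' off: they stay at their prior mean exactly and are excluded from the
#' estimation subspace.
#'
#' @param mean Named prior mean vector.
#' @param var Named prior variance vector (entries >= 0).
#' @param hyper_mean,hyper_var Prior mean and variance of the noise log
#'   precisions (per node). `hyper_var = 0` fixes the noise precision.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(mean, var, hyper_mean, hyper_var) {
  stopifnot(length(mean) == length(var), all(var >= 0), all(hyper_var >= 0),
            !is.null(names(mean)))
  names(var) <- names(mean)
  structure(list(mean = mean, var = var, hyper_mean = hyper_mean,
                 hyper_var = hyper_var), class = "prior_spec")
}

#' Default shrinkage priors for the four-node inhibition DCM
#'
#' Zero-mean Gaussians with variance 1/16 on intrinsic off-diagonal
#' couplings and all modulatory and driving entries, 1/256 on the
#' self-connection log scalings and the hemodynamic decay/transit
#' deviations; noise log-precision hyperprior N(4, 1/2) per node. The
#' coupling priors follow standard shrinkage practice for bilinear fMRI
#' models; the noise hyperprior is kept deliberately weak because the
#' observation scale (% signal change) puts plausible noise precisions
#' several nats below the conventional mean of 4. All values are
#' configurable.
#'
#' @param template A [dcm_params()] giving nodes and input names.
#' @return A [prior_spec()].
#' @export
default_priors <- function(template = default_truth_template()) {
  nm <- param_names(template$nodes, names(template$B), colnames(template$C))
  v <- setNames(rep(1 / 16, length(nm)), nm)
  nodes <- template$nodes
  v[sprintf("A[%s,%s]", nodes, nodes)] <- 1 / 256
  v[param_block(nm, "hemo")] <- 1 / 256
  prior_spec(
    mean = setNames(rep(0, length(nm)), nm), var = v,
    hyper_mean = setNames(rep(4, length(nodes)), nodes),
    hyper_var = setNames(rep(1 / 2, length(nodes)), nodes)
  )
}
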
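# Bayesian model reduction, greedy search over reduced models, Bayesian
# model averaging, Bayesian contrasts and Savage-Dickey null tests at the
# group level. Everything here is closed-form Gaussian algebra: a reduced
# model differs from the full one only in its prior, so its evidence and
# posterior follow from the full-model (prior, posterior) pair without
# refitting.

#' Evidence change and posterior under a reduced prior
#'
#' Given a Gaussian full prior, the corresponding posterior, and a reduced
#' prior that differs only by shrunk or zeroed variances (and possibly
#' shifted means), returns the change in log evidence `dF` and the implied
#' reduced posterior. Zero-variance dimensions of the reduced prior are
#' handled exactly: the parameter is clamped to the reduced prior mean and
#' integrated out as a point mass.
#'
#' @param post List with `mean`, `cov`: the full-model posterior.
#' @param prior List with `mean`, `var` (diagonal) or `cov`: the full prior.
#' @param reduced Like `prior`, the reduced prior; variances may be zero.
#' @return List with `dF`, `mean`, `cov` of the reduced posterior.
#' @export
bmr_evidence <- function(post, prior, reduced) {
  as_cov <- function(x, p) if (!is.null(x$cov)) x$cov else diag(x$var, p)
  p <- length(post$mean)
  S0 <- as_cov(prior, p)
  Sr <- as_cov(reduced, p)
  S <- (post$cov + t(post$cov)) / 2
  P0 <- solve(S0)
  Pp <- solve(S)
  Pd <- Pp - P0
  bd <- drop(Pp %*% post$mean) - drop(P0 %*% prior$mean)

  log_int <- function(Pd, bd, m, V) {
    # integral of the extracted likelihood against N(m, V); V must be PD
    Vinv <- solve(V)
    Pc <- Pd + Vinv
    cc <- chol((Pc + t(Pc)) / 2)
    bc <- bd + drop(Vinv %*% m)
    z <- backsolve(cc, bc, transpose = TRUE)
    ld <- determinant(V, logarithm = TRUE)$modulus
    list(logZ = -0.5 * as.numeric(ld) - sum(log(diag(cc))) + 0.5 * sum(z^2) -
           0.5 * drop(crossprod(m, Vinv %*% m)),
         mean = drop(chol2inv(cc) %*% bc), cov = chol2inv(cc))
  }

  full <- log_int(Pd, bd, prior$mean, S0)
  off <- diag(Sr) <= 0
  mr <- reduced$mean
  if (!any(off)) {
    red <- log_int(Pd, bd, mr, Sr)
    mean_r <- red$mean
    cov_r <- red$cov
    logZr <- red$logZ
  } else if (all(off)) {
    logZr <- -0.5 * drop(crossprod(mr, Pd %*% mr)) + sum(bd * mr)
    mean_r <- mr
    cov_r <- matrix(0, p, p)
  } else {
    on <- !off
    bd_s <- bd[on] - drop(Pd[on, off, drop = FALSE] %*% mr[off])
    const0 <- -0.5 * drop(crossprod(mr[off], Pd[off, off, drop = FALSE] %*%
                                      mr[off])) + sum(bd[off] * mr[off])
    red <- log_int(Pd[on, on, drop = FALSE], bd_s, mr[on],
                   Sr[on, on, drop = FALSE])
    logZr <- const0 + red$logZ
    mean_r <- mr
    mean_r[on] <- red$mean
    cov_r <- matrix(0, p, p)
    cov_r[on, on] <- red$cov
  }
  nms <- names(post$mean)
  names(mean_r) <- nms
  dimnames(cov_r) <- list(nms, nms)
  list(dF = logZr - full$logZ, mean = mean_r, cov = cov_r)
}

#' Greedy search over reduced group-level models with Bayesian model
#' averaging
#'
#' Iteratively prunes group-level effects that do not contribute to the
#' free energy: at each sweep the effects whose individual removal is least
#' costly (up to `final_k` of them) define a family of `2^final_k` reduced
#' models, evaluated in closed form by Bayesian model reduction; effects
#' switched off in the best model are pruned permanently and the sweep
#' repeats until the best model stops improving. The models of the final
#' sweep (256 when `final_k = 8` effects remain in play) are combined by
#' Bayesian model averaging with softmax weights on their free energies.
#'
#' @param peb A [fit_peb()] result.
#' @param candidates Parameter names (or indices) eligible for pruning;
#'   defaults to all group effects.
#' @param final_k Size of the exhaustively searched set per sweep.
#' @return Object of class `bma_result`: model on/off matrix, model free
#'   energies and posterior probabilities, BMA `mean`/`cov`, per-parameter
#'   posterior probability `Pp` of being present, and the prior.
#' @export
greedy_search <- function(peb, candidates = NULL, final_k = 8L) {
  nb <- length(peb$mean)
  nms <- names(peb$mean)
  cand <- if (is.null(candidates)) seq_len(nb) else
    if (is.character(candidates)) match(candidates, nms) else candidates
  stopifnot(!anyNA(cand), length(cand) >= 1)
  reduced_k <- length(cand) < final_k

  # cache the likelihood extracted from the (prior, posterior) pair; every
  # reduced model's evidence and posterior then follows from one Cholesky
  # of its on-subspace (prior means are zero, so switched-off parameters
  # contribute nothing)
  v0 <- peb$prior$var
  Pp_full <- solve((peb$cov + t(peb$cov)) / 2)
  Pd <- Pp_full - diag(1 / v0, nb)
  bd <- drop(Pp_full %*% peb$mean)
  eval_model <- function(on, want_posterior = FALSE) {
    if (!any(on)) {
      return(list(logZ = 0, mean = setNames(rep(0, nb), nms),
                  cov = matrix(0, nb, nb)))
    }
    Pc <- Pd[on, on, drop = FALSE] + diag(1 / v0[on], sum(on))
    cc <- chol((Pc + t(Pc)) / 2)
    z <- backsolve(cc, bd[on], transpose = TRUE)
    logZ <- -0.5 * sum(log(v0[on])) - sum(log(diag(cc))) + 0.5 * sum(z^2)
    out <- list(logZ = logZ)
    if (want_posterior) {
      S <- chol2inv(cc)
      mu <- setNames(rep(0, nb), nms)
      mu[on] <- drop(S %*% bd[on])
      cv <- matrix(0, nb, nb)
      cv[on, on] <- S
      out$mean <- mu
      out$cov <- cv
    }
    out
  }
  F_full <- eval_model(rep(TRUE, nb))$logZ

  state <- rep(TRUE, nb)  # permanently-on/off state
  repeat {
    active <- intersect(which(state), cand)
    if (!length(active)) break
    F_cur <- eval_model(state)$logZ
    dF1 <- vapply(active, function(j) {
      on <- state
      on[j] <- FALSE
      eval_model(on)$logZ - F_cur
    }, numeric(1))
    k <- min(final_k, length(active))
    sweep_set <- active[order(dF1, decreasing = TRUE)][seq_len(k)]
    combos <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
    models <- vector("list", nrow(combos))
    Fm <- numeric(nrow(combos))
    onmat <- matrix(FALSE, nrow(combos), nb)
    for (mi in seq_len(nrow(combos))) {
      on <- state
      on[sweep_set] <- combos[mi, ]
      red <- eval_model(on, want_posterior = TRUE)
      models[[mi]] <- red
      Fm[mi] <- red$logZ
      onmat[mi, ] <- on
    }
    best <- which.max(Fm)
    to_off <- sweep_set[!combos[best, ]]
    if (length(to_off) && Fm[best] > F_cur) {
      state[to_off] <- FALSE
    } else {
      break
    }
  }

  w <- exp(Fm - max(Fm))
  w <- w / sum(w)
  mu <- Reduce(`+`, Map(function(m, wi) wi * m$mean, models, w))
  second <- Reduce(`+`, Map(function(m, wi) {
    wi * (m$cov + tcrossprod(m$mean))
  }, models, w))
  cov <- second - tcrossprod(mu)
  cov <- (cov + t(cov)) / 2
  Pp <- drop(w %*% onmat)
  names(Pp) <- nms
  structure(
    list(mean = setNames(mu, nms), cov = cov, Pp = Pp,
         models = onmat, model_F = Fm - F_full, model_prob = w,
         n_models = length(w), reduced_family = reduced_k,
         prior = peb$prior, param_names = peb$param_names,
         covariates = peb$covariates, threshold = 0.95),
    class = "bma_result"
  )
}

#' @export
print.bma_result <- function(x, ...) {
  cat("Bayesian model average over", x$n_models, "reduced models\n")
  strong <- names(x$Pp)[x$Pp > x$threshold & abs(x$mean) > 0]
  cat(length(strong), "effect(s) with Pp >", x$threshold, "\n")
  invisible(x)
}

#' Posterior probability that a group effect is present
#'
#' The summed posterior probability of the reduced models in which the
#' effect is switched on; `Pp > 0.95` is conventionally read as strong
#' evidence.
#'
#' @param bma A [greedy_search()] result.
#' @param parameter Effect name (`"<covariate>:<parameter>"`) or index.
#' @return Probability in `[0, 1]`.
#' @export
posterior_probability <- function(bma, parameter) {
  j <- if (is.character(parameter)) match(parameter, names(bma$Pp)) else parameter
  if (anyNA(j)) stop("unknown parameter: ", parameter)
  unname(bma$Pp[j])
}

#' Bayesian contrast over averaged group effects
#'
#' Gaussian posterior of `c' theta` under the model average; reports the
#' posterior probabilities that the contrast is positive and negative (used
#' for directional condition comparisons such as NoGo vs Go modulation of a
#' connection).
#'
#' @param bma A [greedy_search()] result (or any object with `mean`/`cov`).
#' @param weights Named (or full-length) contrast weights.
#' @return List with `mean`, `var`, `p_positive`, `p_negative`.
#' @export
bayesian_contrast <- function(bma, weights) {
  cvec <- setNames(rep(0, length(bma$mean)), names(bma$mean))
  if (!is.null(names(weights))) {
    j <- match(names(weights), names(cvec))
    if (anyNA(j)) stop("unknown parameter(s) in contrast weights")
    cvec[j] <- weights
  } else {
    stopifnot(length(weights) == length(cvec))
    cvec[] <- weights
  }
  if (all(cvec == 0)) stop("degenerate contrast: all weights zero")
  mu <- sum(cvec * bma$mean)
  v <- drop(crossprod(cvec, bma$cov %*% cvec))
  if (v <= 0) stop("degenerate contrast: zero posterior variance")
  list(mean = mu, var = v,
       p_positive = pnorm(mu / sqrt(v)),
       p_negative = pnorm(-mu / sqrt(v)))
}

#' NoGo-vs-Go contrast on one connection's modulation
#'
#' Convenience wrapper building the `B_NoGo - B_Go` contrast for a given
#' target/source pair on a chosen covariate (default the group mean).
#'
#' @param bma A [greedy_search()] result from a PEB over the `B` block.
#' @param target,source Node labels.
#' @param covariate Covariate name (default `"Mean"`).
#' @return As [bayesian_contrast()].
#' @export
contrast_nogo_go <- function(bma, target, source, covariate = "Mean") {
  w <- setNames(
    c(1, -1),
    sprintf("%s:B_%s[%s,%s]", covariate, c("NoGo", "Go"), target, source)
  )
  bayesian_contrast(bma, w)
}

#' Savage-Dickey Bayes factor against a point null
#'
#' Evidence against `theta_j = 0`, computed as the ratio of the prior to the
#' posterior density at zero under the Gaussian model average.
#'
#' @param bma A [greedy_search()] result.
#' @param parameter Effect name or index.
#' @return Bayes factor (> 1 favors a nonzero effect).
#' @export
bayes_factor_null <- function(bma, parameter) {
  j <- if (is.character(parameter)) match(parameter, names(bma$Pp)) else parameter
  if (anyNA(j)) stop("unknown parameter: ", parameter)
  v0 <- bma$prior$var[j]
  if (v0 <= 0) stop("parameter has zero prior variance (no prior density)")
  vpost <- bma$cov[j, j]
  if (vpost <= 0) stop("parameter is switched off in every model")
  dnorm(0, 0, sqrt(v0)) / dnorm(0, bma$mean[j], sqrt(vpost))
}
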
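# Parametric empirical Bayes: a linear Gaussian between-subject model over
# first-level posteriors. Each subject's likelihood contribution is
# recovered from its (prior, posterior) pair -- the same Gaussian identity
# used for Bayesian model reduction -- so no first-level refitting is ever
# needed. Given the random-effects precision the model is linear-Gaussian
# and all conditionals are exact; the precision itself is optimized by
# maximizing the second-level free energy.

#' Between-subject design matrix for PEB
#'
#' Column 1 is the constant (commonalities / group mean); optional columns:
#' sex coded +0.5 (female) / -0.5 (male), mean-centered NoGo accuracy, and
#' mean-centered age. The coding keeps the intercept interpretable as the
#' group mean.
#'
#' @param behavior Data frame with one row per subject (needs `sex`,
#'   `nogo_acc`, `age` as requested).
#' @param sex,performance,age Which covariates to include.
#' @return Numeric design matrix with named columns.
#' @export
peb_design <- function(behavior, sex = TRUE, performance = TRUE, age = FALSE) {
  X <- matrix(1, nrow(behavior), 1, dimnames = list(NULL, "Mean"))
  if (sex) {
    X <- cbind(X, Sex = ifelse(behavior$sex == "female", 0.5, -0.5))
  }
  if (performance) {
    X <- cbind(X, NoGoAcc = behavior$nogo_acc - mean(behavior$nogo_acc))
  }
  if (age) {
    X <- cbind(X, Age = behavior$age - mean(behavior$age))
  }
  X
}

# Extract per-subject likelihood information (data precision and
# precision-weighted data) for a block of parameters, from the subject's
# prior and posterior. The data precision is floored at zero eigenvalues:
# marginalization of a nonlinear-model posterior can make it marginally
# indefinite.
subject_information <- function(post, idx) {
  mu <- post$mean[idx]
  S <- post$cov[idx, idx, drop = FALSE]
  m0 <- post$prior$mean[idx]
  v0 <- post$prior$var[idx]
  Pi <- solve((S + t(S)) / 2)
  Pd <- Pi - diag(1 / v0, length(idx))
  es <- eigen((Pd + t(Pd)) / 2, symmetric = TRUE)
  Pd <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
  bd <- drop(Pi %*% mu) - m0 / v0
  list(Pd = Pd, bd = bd, m0 = m0, v0 = v0, F = post$F)
}

# log of integral exp(-0.5 t'Pd t + bd't) N(t; m, V) dt for PD V (given as
# its precision Vinv and log determinant of V)
log_gauss_integral <- function(Pd, bd, m, Vinv, logdetV) {
  Pc <- Pd + Vinv
  cc <- chol((Pc + t(Pc)) / 2)
  bc <- bd + drop(Vinv %*% m)
  z <- backsolve(cc, bc, transpose = TRUE)
  -0.5 * logdetV - sum(log(diag(cc))) + 0.5 * sum(z^2) -
    0.5 * drop(crossprod(m, Vinv %*% m))
}

#' Fit a parametric empirical Bayes model over first-level posteriors
#'
#' Models the selected first-level parameters as `theta_i = (x_i' kron I)
#' beta + epsilon_i` with Gaussian random effects `epsilon_i ~ N(0,
#' exp(-gamma) V)`; `V` defaults to 1/16 of the first-level prior variances.
#' `beta` carries a zero-mean Gaussian prior whose variances default to the
#' first-level prior variances for every covariate. The random-effects log
#' precision `gamma` (hyperprior N(0, 1/16)) is profiled out by maximizing
#' the second-level free energy, which is available in closed form given
#' `gamma`.
#'
#' @param posteriors List of `posterior_estimate`s with identical
#'   parameterization.
#' @param X Between-subject design matrix ([peb_design()]); first column
#'   must be constant.
#' @param block Which first-level block to model: `"A"`, `"B"`, `"C"` or a
#'   vector of parameter names.
#' @param b_prior_var Optional named/numeric prior variances for the group
#'   effects (recycled over covariates).
#' @param re_scale Random-effects variance as a fraction of the first-level
#'   prior variance (default 1/16).
#' @param gamma_prior_var Hyperprior variance of `gamma`.
#' @return Object of class `peb_result` with effect estimates (matrix
#'   parameters x covariates), posterior mean/covariance of `beta`, the
#'   `beta` prior, free energy and `gamma`.
#' @export
fit_peb <- function(posteriors, X, block = "B", b_prior_var = NULL,
                    re_scale = 1 / 16, gamma_prior_var = 1 / 16) {
  m <- length(posteriors)
  stopifnot(m >= 2, nrow(X) == m)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient between-subject design")
  full_names <- names(posteriors[[1]]$mean)
  idx <- if (is.character(block) && length(block) == 1 &&
               block %in% c("A", "B", "C", "hemo")) {
    param_block(full_names, block)
  } else if (is.character(block)) {
    match(block, full_names)
  } else {
    block
  }
  # drop switched-off parameters: they carry no first-level information
  idx <- idx[posteriors[[1]]$prior$var[idx] > 0]
  pnames <- full_names[idx]
  p <- length(idx)
  c_cov <- ncol(X)
  covs <- colnames(X)

  info <- lapply(posteriors, subject_information, idx = idx)
  v0 <- info[[1]]$v0
  vb <- if (is.null(b_prior_var)) rep(v0, c_cov) else rep(b_prior_var,
                                                          length.out = p * c_cov)
  b_names <- as.vector(outer(pnames, covs, function(a, b) paste0(b, ":", a)))

  # subject constants independent of gamma: c_i = F_i - log I_i(first-level prior)
  c_const <- vapply(info, function(s) {
    s$F - log_gauss_integral(s$Pd, s$bd, s$m0, diag(1 / s$v0, p),
                             sum(log(s$v0)))
  }, numeric(1))

  v_re <- v0 * re_scale
  objective <- function(gamma) {
    Vinv <- diag(exp(gamma) / v_re, p)
    logdetV <- sum(log(v_re)) - p * gamma
    Q <- matrix(0, p * c_cov, p * c_cov)
    rhs <- numeric(p * c_cov)
    const <- 0
    for (i in seq_len(m)) {
      Pc <- info[[i]]$Pd + Vinv
      cc <- chol((Pc + t(Pc)) / 2)
      Pci <- chol2inv(cc)
      Wi <- Vinv - Vinv %*% Pci %*% Vinv
      ti <- drop(Vinv %*% (Pci %*% info[[i]]$bd))
      xi <- X[i, ]
      Q <- Q + kronecker(tcrossprod(xi), Wi)
      rhs <- rhs + kronecker(xi, ti)
      z <- backsolve(cc, info[[i]]$bd, transpose = TRUE)
      const <- const - 0.5 * logdetV - sum(log(diag(cc))) + 0.5 * sum(z^2)
    }
    Pb <- Q + diag(1 / vb, p * c_cov)
    cb <- chol((Pb + t(Pb)) / 2)
    mu_b <- drop(chol2inv(cb) %*% rhs)
    logZ <- const - 0.5 * sum(log(vb)) - sum(log(diag(cb))) +
      0.5 * sum(rhs * mu_b)
    list(F = logZ + dnorm(gamma, 0, sqrt(gamma_prior_var), log = TRUE),
         mu_b = mu_b, Pb = Pb)
  }
  opt <- stats::optimize(function(g) objective(g)$F, c(-6, 10), maximum = TRUE)
  gamma_hat <- opt$maximum
  fit <- objective(gamma_hat)
  # Laplace correction for the profiled hyperparameter
  h <- 1e-3
  d2 <- (objective(gamma_hat + h)$F - 2 * fit$F +
           objective(gamma_hat - h)$F) / h^2
  v_gamma <- if (is.finite(d2) && d2 < 0) -1 / d2 else gamma_prior_var
  F2 <- sum(c_const) + fit$F + 0.5 * log(2 * pi * v_gamma)

  Sb <- chol2inv(chol((fit$Pb + t(fit$Pb)) / 2))
  dimnames(Sb) <- list(b_names, b_names)
  mu_b <- setNames(fit$mu_b, b_names)
  effects <- matrix(mu_b, p, c_cov, dimnames = list(pnames, covs))
  effects_sd <- matrix(sqrt(diag(Sb)), p, c_cov, dimnames = list(pnames, covs))
  structure(
    list(mean = mu_b, cov = Sb, effects = effects, effects_sd = effects_sd,
         prior = list(mean = setNames(rep(0, p * c_cov), b_names), var = vb),
         F = F2, gamma = gamma_hat, gamma_var = v_gamma,
         param_names = pnames, covariates = covs, X = X,
         n_subjects = m, block = block),
    class = "peb_result"
  )
}

#' @export
print.peb_result <- function(x, ...) {
  cat("PEB over", length(x$param_names), "parameters x",
      length(x$covariates), "covariates;", x$n_subjects, "subjects; F =",
      formatC(x$F, format = "f", digits = 2),
      "; gamma =", formatC(x$gamma, format = "f", digits = 2), "\n")
  cat("Group-mean effects (posterior mean):\n")
  print(round(x$effects, 3))
  invisible(x)
}

#' Fabricate first-level posteriors around a cohort's true parameters
#'
#' Builds synthetic Gaussian first-level posteriors: the maximum-likelihood
#' estimate is the subject's true parameter vector plus iid Gaussian error
#' of SD `obs_sd`, which is then combined with the first-level prior
#' (posterior precision = data precision + prior precision). This isolates
#' the group-level machinery from the cost of full model inversion and is
#' used for calibration and power studies of the PEB stage; it emulates the
#' location and scale of first-level posteriors but not their correlation
#' structure.
#'
#' @param cohort A `cohort` from [generate_cohort()] (can be generated with
#'   `simulate = FALSE`).
#' @param obs_sd Effective first-level measurement SD per parameter.
#' @param priors First-level [prior_spec()].
#' @param seed RNG seed.
#' @return List of `posterior_estimate`-like objects.
#' @export
simulate_first_level_posteriors <- function(cohort, obs_sd = 0.05,
                                            priors = NULL, seed = 1L) {
  spec <- attr(cohort, "spec")
  template <- if (!is.null(spec)) spec$template else default_truth_template()
  if (is.null(priors)) priors <- default_priors(template)
  lapply(seq_along(cohort), function(i) {
    with_seed((seed + 977L * i) %% .Machine$integer.max, {
      theta <- cohort[[i]]$theta_true
      free <- priors$var > 0
      mle <- theta + rnorm(length(theta), 0, obs_sd)
      post_prec <- ifelse(free, 1 / obs_sd^2 + 1 / priors$var, Inf)
      post_var <- ifelse(free, 1 / post_prec, 0)
      post_mean <- ifelse(
        free,
        post_var * (mle / obs_sd^2 + priors$mean / priors$var),
        priors$mean
      )
      structure(
        list(mean = setNames(post_mean, names(theta)),
             cov = diag(post_var, length(theta)) |>
               `dimnames<-`(list(names(theta), names(theta))),
             free = which(free), F = 0, converged = TRUE, prior = priors),
        class = "posterior_estimate"
      )
    })
  })
}
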
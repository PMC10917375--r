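linear_gaussian_post <- function(X, y, m0, S0diag) {
  P <- crossprod(X) + diag(1 / S0diag)
  S <- solve(P)
  list(mean = drop(S %*% (crossprod(X, y) + m0 / S0diag)), cov = S)
}

test_that("Bayesian model reduction equals explicit refitting", {
  set.seed(12)
  p <- 6
  n <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p) + rnorm(n)
  m0 <- rnorm(p, 0, 0.3)
  S0 <- runif(p, 0.3, 2)
  post <- linear_gaussian_post(X, y, m0, S0)
  prior <- list(mean = m0, var = S0)

  # identity reduction: no change
  same <- bmr_evidence(post, prior, prior)
  expect_equal(same$dF, 0, tolerance = 1e-9)
  expect_equal(same$mean, setNames(post$mean, names(same$mean)),
               tolerance = 1e-9)

  f_full <- refit_log_evidence(X, y, m0, S0)
  # shrunk variances (all positive)
  S_shrunk <- S0 * c(1, 0.1, 1, 0.05, 1, 1)
  red1 <- bmr_evidence(post, prior, list(mean = m0, var = S_shrunk))
  expect_equal(red1$dF, refit_log_evidence(X, y, m0, S_shrunk) - f_full,
               tolerance = 1e-8)

  # switched-off parameters (exact zero variance)
  S_off <- S0
  S_off[c(2, 5)] <- 0
  m_off <- m0
  m_off[c(2, 5)] <- 0
  red2 <- bmr_evidence(post, prior, list(mean = m_off, var = S_off))
  expect_equal(red2$dF, refit_log_evidence(X, y, m_off, S_off) - f_full,
               tolerance = 1e-8)
  # reduced posterior agrees with direct conditional refit
  direct <- linear_gaussian_post(
    X[, -c(2, 5)], y, m_off[-c(2, 5)], S0[-c(2, 5)])
  expect_equal(unname(red2$mean[-c(2, 5)]), direct$mean, tolerance = 1e-8)
  expect_equal(unname(red2$mean[c(2, 5)]), c(0, 0))

  # pruning a decisively nonzero parameter costs evidence
  strong <- which.max(abs(post$mean / sqrt(diag(post$cov))))
  S_bad <- S0
  S_bad[strong] <- 0
  m_bad <- m0
  m_bad[strong] <- 0
  red3 <- bmr_evidence(post, prior, list(mean = m_bad, var = S_bad))
  expect_lt(red3$dF, 0)
})

test_that("PEB with identical precise subjects returns the shared estimate", {
  tpl <- default_truth_template()
  pri <- default_priors(tpl)
  nm <- names(pri$mean)
  theta <- pack_params(tpl)
  free <- pri$var > 0
  posts <- lapply(1:8, function(i) {
    structure(list(
      mean = theta,
      cov = diag(ifelse(free, 1e-6, 0), length(nm)) |>
        `dimnames<-`(list(nm, nm)),
      free = which(free), F = 0, converged = TRUE, prior = pri),
      class = "posterior_estimate")
  })
  X <- matrix(1, 8, 1, dimnames = list(NULL, "Mean"))
  peb <- fit_peb(posts, X, block = "A")
  expect_equal(unname(peb$effects[, "Mean"]),
               unname(theta[param_block(nm, "A")]), tolerance = 1e-3)
  expect_error(fit_peb(posts, cbind(X, X), block = "A"), "rank")
})

test_that("null cohorts give centered effects and few strong detections", {
  spec <- small_paradigm()
  hits <- c()
  sex_z <- c()
  for (seed in 1:4) {
    co <- cohort_spec(n_subjects = 24, subject_sd = 0.05,
                      sex_effects = c("A[GP,Thal]" = 0),
                      performance_slope = c("B_NoGo[IFG,Thal]" = 0),
                      seed = 100 + seed)
    ch <- generate_cohort(co, spec, simulate = FALSE)
    posts <- simulate_first_level_posteriors(ch, obs_sd = 0.1,
                                             seed = 200 + seed)
    X <- peb_design(behavior_table(ch))
    peb <- fit_peb(posts, X, block = "A")
    sex_z <- c(sex_z, peb$effects[, "Sex"] / peb$effects_sd[, "Sex"])
    bma <- greedy_search(peb)
    cov_effects <- grep("^(Sex|NoGoAcc):", names(bma$Pp))
    hits <- c(hits, bma$Pp[cov_effects] > 0.95)
  }
  expect_lt(abs(mean(sex_z)), 0.5)          # centered on zero
  expect_lte(mean(hits), 0.06)              # ~5% strong-evidence rate
})

test_that("configured group effects are recovered with the right sign", {
  spec <- small_paradigm()
  sex_sign <- perf_sign <- logical(0)
  for (seed in 1:6) {
    co <- cohort_spec(n_subjects = 30, seed = 300 + seed)
    ch <- generate_cohort(co, spec, simulate = FALSE)
    posts <- simulate_first_level_posteriors(ch, obs_sd = 0.1,
                                             seed = 400 + seed)
    X <- peb_design(behavior_table(ch))
    pebA <- fit_peb(posts, X, block = "A")
    sex_sign <- c(sex_sign, pebA$effects["A[GP,Thal]", "Sex"] < 0)
    pebB <- fit_peb(posts, X, block = "B")
    perf_sign <- c(perf_sign,
                   pebB$effects["B_NoGo[IFG,Thal]", "NoGoAcc"] > 0)
  }
  expect_gte(mean(sex_sign), 5 / 6)
  expect_gte(mean(perf_sign), 5 / 6)
})

test_that("greedy search: model family size, normalization, convexity", {
  # all 8 group-mean driving inputs strongly nonzero: nothing is pruned and
  # the final sweep enumerates exactly 2^8 = 256 models
  tpl <- default_truth_template()
  tpl$C[] <- pmax(abs(tpl$C), 0.1) * sign(tpl$C + (tpl$C == 0))
  pri <- default_priors(tpl)
  nm <- names(pri$mean)
  theta0 <- pack_params(tpl)
  set.seed(17)
  posts <- lapply(1:25, function(i) {
    free <- pri$var > 0
    mle <- theta0 + rnorm(length(theta0), 0, 0.03)
    prec <- ifelse(free, 1 / 0.03^2 + 1 / pri$var, Inf)
    pv <- ifelse(free, 1 / prec, 0)
    pm <- ifelse(free, pv * (mle / 0.03^2 + pri$mean / pri$var), pri$mean)
    structure(list(mean = setNames(pm, nm),
                   cov = diag(pv, length(nm)) |> `dimnames<-`(list(nm, nm)),
                   free = which(free), F = 0, converged = TRUE, prior = pri),
              class = "posterior_estimate")
  })
  X <- matrix(1, 25, 1, dimnames = list(NULL, "Mean"))
  peb <- fit_peb(posts, X, block = "C")  # 8 strongly supported effects
  bma <- greedy_search(peb)
  expect_equal(bma$n_models, 256)
  expect_equal(sum(bma$model_prob), 1, tolerance = 1e-10)
  expect_true(all(bma$Pp >= 0 & bma$Pp <= 1))
  expect_true(all(bma$Pp > 0.95))
  # nothing pruned: the average stays close to the full posterior
  expect_equal(unname(bma$mean), unname(peb$mean), tolerance = 0.01)
  # BMA mean is a convex combination of the model means
  mu_models <- sapply(seq_len(bma$n_models), function(m) {
    on <- bma$models[m, ]
    vr <- peb$prior$var
    vr[!on] <- 0
    bmr_evidence(list(mean = peb$mean, cov = peb$cov),
                 list(mean = peb$prior$mean, var = peb$prior$var),
                 list(mean = peb$prior$mean, var = vr))$mean
  })
  expect_equal(drop(mu_models %*% bma$model_prob), bma$mean,
               tolerance = 1e-8)
  # fewer than 8 candidates (all strongly supported): family is 2^k, flagged
  small <- greedy_search(peb, candidates = names(peb$mean)[1:3])
  expect_equal(small$n_models, 8)
  expect_true(small$reduced_family)
})

test_that("strongly supported parameters survive pruning; zeros are pruned", {
  # truth: half the group-level C effects are exactly zero
  tpl <- default_truth_template()   # C has 5 nonzero of 8 entries
  pri <- default_priors(tpl)
  nm <- names(pri$mean)
  theta0 <- pack_params(tpl)
  set.seed(19)
  posts <- lapply(1:30, function(i) {
    free <- pri$var > 0
    mle <- theta0 + rnorm(length(theta0), 0, 0.05)
    prec <- ifelse(free, 1 / 0.05^2 + 1 / pri$var, Inf)
    pv <- ifelse(free, 1 / prec, 0)
    pm <- ifelse(free, pv * (mle / 0.05^2 + pri$mean / pri$var), pri$mean)
    structure(list(mean = setNames(pm, nm),
                   cov = diag(pv, length(nm)) |> `dimnames<-`(list(nm, nm)),
                   free = which(free), F = 0, converged = TRUE, prior = pri),
              class = "posterior_estimate")
  })
  X <- matrix(1, 30, 1, dimnames = list(NULL, "Mean"))
  peb <- fit_peb(posts, X, block = "C")
  bma <- greedy_search(peb)
  truth_on <- theta0[param_block(nm, "C")] != 0
  Pp <- bma$Pp
  expect_true(all(Pp[truth_on] > 0.95))          # real inputs survive
  expect_gte(mean(Pp[!truth_on] < 0.5), 0.8)     # true zeros mostly pruned
})

test_that("posterior probabilities and contrasts follow Gaussian algebra", {
  # hand-built two-model average: equal free energies, parameter on in one
  bma <- structure(list(
    mean = c("Mean:x" = 0.1, "Mean:y" = -0.3),
    cov = diag(c(0.02, 0.01)) |>
      `dimnames<-`(list(c("Mean:x", "Mean:y"), c("Mean:x", "Mean:y"))),
    Pp = c("Mean:x" = 0.5, "Mean:y" = 1),
    model_prob = c(0.5, 0.5),
    prior = list(mean = c(0, 0), var = c(1, 1)),
    threshold = 0.95), class = "bma_result")
  expect_equal(posterior_probability(bma, "Mean:x"), 0.5)
  expect_equal(posterior_probability(bma, "Mean:y"), 1)
  expect_error(posterior_probability(bma, "Mean:z"), "unknown")

  # contrast on a parameter with posterior N(-0.3, 0.01): P(<0) = Phi(3)
  ctr <- bayesian_contrast(bma, c("Mean:y" = 1))
  expect_equal(ctr$p_negative, pnorm(3), tolerance = 1e-12)
  expect_error(bayesian_contrast(bma, c("Mean:y" = 0)), "degenerate")

  # Savage-Dickey: posterior equal to prior gives BF 1; the N(1, 0.25)
  # example gives dnorm(0,0,1)/dnorm(0,1,0.5) = 3.694 (computed directly)
  bma2 <- bma
  bma2$mean <- c("Mean:x" = 0, "Mean:y" = 1)
  bma2$cov <- diag(c(1, 0.25)) |>
    `dimnames<-`(list(c("Mean:x", "Mean:y"), c("Mean:x", "Mean:y")))
  expect_equal(bayes_factor_null(bma2, "Mean:x"), 1, tolerance = 1e-12)
  expect_equal(bayes_factor_null(bma2, "Mean:y"),
               dnorm(0, 0, 1) / dnorm(0, 1, 0.5), tolerance = 1e-12)
  expect_equal(bayes_factor_null(bma2, "Mean:y"), 3.6945, tolerance = 1e-4)
  # displacement from zero increases the Bayes factor monotonically
  bma3 <- bma2
  bma3$mean["Mean:y"] <- 2
  expect_gt(bayes_factor_null(bma3, "Mean:y"),
            bayes_factor_null(bma2, "Mean:y"))
})

test_that("the left-hemisphere control model is pure configuration", {
  # the same machinery runs unchanged on a different node set
  nodes <- c("lIFG", "lCau", "lGP", "lThal")
  tpl <- default_truth_template()
  ltpl <- dcm_params(`dimnames<-`(tpl$A, list(nodes, nodes)),
                     lapply(tpl$B, `dimnames<-`, list(nodes, nodes)),
                     `rownames<-`(tpl$C, nodes), nodes = nodes)
  des <- generate_paradigm(small_paradigm())$design
  y <- simulate_bold(ltpl, des)
  expect_equal(colnames(y$values), nodes)
  pri <- default_priors(ltpl)
  expect_true(all(grepl("lIFG|lCau|lGP|lThal",
                        grep("^A\\[", names(pri$mean), value = TRUE))))
})
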
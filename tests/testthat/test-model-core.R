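test_that("Jacobian follows the -0.5 Hz self-connection convention", {
  tpl <- default_truth_template()
  zero <- dcm_params(matrix(0, 4, 4),
                     list(Go = matrix(0, 4, 4), NoGo = matrix(0, 4, 4)),
                     tpl$C * 0)
  J <- jacobian_at(zero, c(Go = 0.3, NoGo = -0.2))
  expect_equal(diag(J), setNames(rep(-0.5, 4), dcm_nodes()))
  expect_true(all(J[row(J) != col(J)] == 0))

  # positive log parameter -> stronger self-inhibition, negative -> weaker
  p <- zero
  diag(p$A) <- c(0.4, -0.4, 0, 0)
  Jp <- jacobian_at(p, c(Go = 0, NoGo = 0))
  expect_equal(Jp[1, 1], -0.5 * exp(0.4))
  expect_gt(abs(Jp[1, 1]), 0.5)
  expect_lt(abs(Jp[2, 2]), 0.5)

  # linear superposition of A and modulation on off-diagonals
  p2 <- zero
  p2$A[2, 1] <- 0.3
  p2$B$NoGo[2, 1] <- -0.4
  J2 <- jacobian_at(p2, c(Go = 0, NoGo = 1))
  expect_equal(J2[2, 1], -0.1)
  expect_error(jacobian_at(p2, c(Go = 0)), "one value per modulatory")
})

test_that("neural derivative: rest fixed point and driving inputs", {
  tpl <- default_truth_template()
  expect_equal(neural_derivative(tpl, c(Go = 0, NoGo = 0), rep(0, 4),
                                 u_driving = c(Go = 0, NoGo = 0)),
               setNames(rep(0, 4), dcm_nodes()))
  p <- tpl
  p$C[] <- 0
  p$C["IFG", "NoGo"] <- 0.1
  d <- neural_derivative(p, c(Go = 0, NoGo = 1), rep(0, 4),
                         u_driving = c(Go = 0, NoGo = 1))
  expect_equal(unname(d), c(0.1, 0, 0, 0))
})

test_that("diagonal-only dynamics decay exponentially (closed form)", {
  # A off-diagonal 0, B = 0, C = 0: x(t) = x0 * exp(-0.5 t)
  p <- dcm_params(matrix(0, 4, 4),
                  list(Go = matrix(0, 4, 4), NoGo = matrix(0, 4, 4)),
                  cbind(Go = rep(0, 4), NoGo = rep(0, 4)))
  J <- jacobian_at(p, c(Go = 0, NoGo = 0))
  x0 <- c(1, -2, 0.5, 3)
  for (t in c(0.5, 2, 5)) {
    xt <- expm_vec(J, t, x0)
    expect_equal(xt, x0 * exp(-0.5 * t), tolerance = 1e-10)
  }
})

test_that("balloon model: rest is a fixed point; response signs", {
  hemo <- default_hemo(1)[1, ]
  expect_equal(unname(hemodynamic_derivative(hemo, 0, c(0, 1, 1, 1))),
               rep(0, 4))
  expect_error(hemodynamic_derivative(hemo, 0, c(0, 1, -1, 1)), "domain")
  # BOLD observation: zero at rest, positive when q drops
  expect_equal(bold_observation(hemo, c(0, 1, 1, 1)), 0)
  expect_gt(bold_observation(hemo, c(0, 1, 1, 0.9)), 0)
})

test_that("balloon dynamics: inflow rises under drive, state returns to rest", {
  skip_if_not_installed("deSolve")
  hemo <- default_hemo(1)[1, ]
  derivs <- function(t, y, parms) {
    list(hemodynamic_derivative(hemo, parms$x, y))
  }
  # constant positive drive: f exceeds 1
  sol <- deSolve::lsoda(c(0, 1, 1, 1), seq(0, 10, 0.1), derivs,
                        parms = list(x = 0.5), rtol = 1e-8, atol = 1e-8)
  expect_gt(max(sol[, 3]), 1)
  # release from the driven state: v and q return to 1 within 1e-3 by 60 s
  driven <- sol[nrow(sol), -1]
  rel <- deSolve::lsoda(driven, c(0, 60), derivs, parms = list(x = 0),
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(rel[2, 4]), 1, tolerance = 1e-3)
  expect_equal(unname(rel[2, 5]), 1, tolerance = 1e-3)
})

test_that("BOLD step response matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- one_node_params(cdrive = 0.3)
  des <- one_node_design()  # fine microtime grid (TR/256)
  ts <- simulate_bold(p, des)
  tvol <- (seq_len(nrow(ts$values)) - 1) * des$TR
  orc <- desolve_oracle(p, des, tvol)
  yref <- oracle_bold(p, orc)
  expect_equal(max(abs(ts$values)), max(abs(yref)), tolerance = 1e-6)
  expect_lt(max(abs(ts$values - yref)), 1e-6)
})

test_that("linear-regime neural trajectory matches adaptive ODE solution", {
  skip_if_not_installed("deSolve")
  tpl <- default_truth_template()
  p <- tpl
  p$B <- lapply(p$B, function(b) b * 0)
  p$C <- p$C * 0.1  # small driving inputs
  spec <- small_paradigm()
  des <- generate_paradigm(spec)$design
  ts <- simulate_bold(p, des, return_neural = TRUE)
  neural <- attr(ts, "neural")
  tmicro <- (seq_len(nrow(neural)) - 1) * des$microtime_dt
  pick <- seq(1, length(tmicro), by = 64)
  orc <- desolve_oracle(p, des, tmicro[pick], rtol = 1e-11)
  xref <- orc$states[, 1:4]
  rel <- max(abs(neural[pick, ] - xref)) / max(abs(xref))
  expect_lt(rel, 1e-4)
})

test_that("simulation: flat at rest, deterministic, seeded noise, convergent", {
  null_p <- dcm_params(matrix(0, 4, 4),
                       list(Go = matrix(0, 4, 4), NoGo = matrix(0, 4, 4)),
                       cbind(Go = rep(0, 4), NoGo = rep(0, 4)))
  spec <- small_paradigm()
  des <- generate_paradigm(spec)$design
  expect_equal(max(abs(simulate_bold(null_p, des)$values)), 0)

  tpl <- default_truth_template()
  y1 <- simulate_bold(tpl, des)$values
  y2 <- simulate_bold(tpl, des)$values
  expect_identical(y1, y2)

  n1 <- simulate_bold(tpl, des, noise_seed = 7)$values
  n2 <- simulate_bold(tpl, des, noise_seed = 7)$values
  n3 <- simulate_bold(tpl, des, noise_seed = 8)$values
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))

  # halving the integration step changes no sampled value by more than 1e-4
  des_half <- experiment_design(des$blocks, TR = des$TR,
                                n_volumes = des$n_volumes, n_runs = des$n_runs,
                                microtime_dt = des$microtime_dt / 2,
                                conditions = des$conditions)
  yh <- simulate_bold(tpl, des_half)$values
  expect_lt(max(abs(y1 - yh)), 1e-4)
})

test_that("unstable parameter regimes fail loudly", {
  tpl <- default_truth_template()
  bad <- tpl
  bad$A[row(bad$A) != col(bad$A)] <- 2
  des <- generate_paradigm(small_paradigm())$design
  expect_error(simulate_bold(bad, des), "unstable")
})

test_that("prior draws: self-connections negative; simulation finite or loud", {
  # Gaussian priors admit draws whose J(u) is non-contracting or whose
  # sustained drive collapses the balloon model, so boundedness cannot hold
  # for every draw; the contract is: effective self-connections are always
  # negative, and a simulation either returns finite values or fails with
  # the explicit instability error -- never a silent non-finite result.
  tpl <- default_truth_template()
  pri <- default_priors(tpl)
  des <- generate_paradigm(small_paradigm())$design
  set.seed(42)
  n_ok_full <- 0
  n_ok_small <- 0
  for (i in 1:12) {
    eps <- rnorm(length(pri$mean), 0, sqrt(pri$var))
    p <- unpack_params(pri$mean + eps, tpl)
    for (u in list(c(Go = 0, NoGo = 0), c(Go = 1, NoGo = 0),
                   c(Go = -1, NoGo = 1))) {
      expect_true(all(diag(jacobian_at(p, u)) < 0))
    }
    y <- tryCatch(simulate_bold(p, des)$values, error = function(e) e)
    if (inherits(y, "error")) {
      expect_match(conditionMessage(y), "unstable")
    } else {
      expect_true(all(is.finite(y)))
      n_ok_full <- n_ok_full + 1
    }
    # draws at quarter scale (the template's own magnitude range) are stable
    ps <- unpack_params(pri$mean + eps / 4, tpl)
    ys <- tryCatch(simulate_bold(ps, des)$values, error = function(e) e)
    if (!inherits(ys, "error") && all(is.finite(ys))) {
      n_ok_small <- n_ok_small + 1
    }
  }
  expect_gte(n_ok_small, 10)
})
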
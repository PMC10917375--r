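# Shared fixtures: scaled-down paradigms for fast unit tests and an
# independent deSolve-based integrator used as oracle for the compiled
# forward model.

small_paradigm <- function(n_runs = 1L, seed = 21L) {
  paradigm_spec(n_runs = n_runs, blocks_per_run = 4L, go_blocks_per_run = 2L,
                nogo_blocks_per_run = 2L, trials_per_go_block = 6L,
                go_trials_per_nogo_block = 4L, nogo_trials_per_nogo_block = 2L,
                lead_in = 8, tail = 14, seed = seed)
}

# piecewise integration of the coupled neural + balloon ODEs with lsoda,
# segment by segment between input discontinuities (independent of the
# package's matrix-exponential/RK4 integrator)
desolve_oracle <- function(params, design, times, rtol = 1e-10) {
  skip_if_not_installed("deSolve")
  U <- design_inputs(design)
  n <- length(params$nodes)
  tgrid <- (seq_len(nrow(U)) - 1) * design$microtime_dt
  derivs <- function(t, state, parms) {
    k <- parms$k
    u <- U[k, ]
    x <- state[1:n]
    J <- jacobian_at(params, u[names(params$B)])
    dx <- J %*% x + params$C %*% u[colnames(params$C)]
    dh <- numeric(4 * n)
    for (i in seq_len(n)) {
      st <- state[n + (i - 1) * 4 + 1:4]
      dh[(i - 1) * 4 + 1:4] <-
        hemodynamic_derivative(params$hemo[i, ], x[i], st)
    }
    list(c(dx, dh))
  }
  # segment boundaries: wherever the input row changes
  chg <- c(1, which(rowSums(abs(diff(U))) > 0) + 1)
  seg_t0 <- tgrid[chg]
  seg_t1 <- c(tgrid[chg[-1]],
              max(max(times), tgrid[length(tgrid)]) + design$microtime_dt)
  state <- c(rep(0, n), rep(c(0, 1, 1, 1), n))
  out <- matrix(NA_real_, length(times), 5 * n)
  for (sidx in seq_along(chg)) {
    t0 <- seg_t0[sidx]
    t1 <- seg_t1[sidx]
    want <- which(times >= t0 & times < t1)  # half-open segment
    seg_times <- sort(unique(c(t0, times[want], t1)))
    sol <- deSolve::lsoda(state, seg_times, derivs,
                          parms = list(k = chg[sidx]),
                          rtol = rtol, atol = rtol)
    for (w in want) {
      out[w, ] <- sol[which.min(abs(sol[, 1] - times[w])), -1]
    }
    state <- sol[nrow(sol), -1]
  }
  list(times = times, states = out, n = n)
}

oracle_bold <- function(params, oracle, TE = 0.03) {
  n <- oracle$n
  sapply(seq_len(n), function(i) {
    st <- oracle$states[, n + (i - 1) * 4 + 1:4, drop = FALSE]
    apply(st, 1, function(s) bold_observation(params$hemo[i, ], s, TE))
  })
}

# linear-Gaussian refit oracle: exact log evidence of y ~ X theta with unit
# noise and Gaussian prior (m0, diag S0diag); zero-variance parameters are
# clamped at their prior mean
refit_log_evidence <- function(X, y, m0, S0diag) {
  on <- S0diag > 0
  n <- nrow(X)
  yv <- y - if (any(!on)) X[, !on, drop = FALSE] %*% m0[!on] else 0
  Xo <- X[, on, drop = FALSE]
  V <- Xo %*% (S0diag[on] * t(Xo)) + diag(n)
  mu0 <- Xo %*% m0[on]
  drop(-0.5 * (as.numeric(determinant(V)$modulus) +
                 crossprod(yv - mu0, solve(V, yv - mu0)) + n * log(2 * pi)))
}

# matrix exponential applied to a vector (via Matrix), independent of the
# package's compiled propagators
expm_vec <- function(J, t, x0) {
  unname(drop(as.matrix(Matrix::expm(J * t)) %*% x0))
}

# single-node model: pure self-decay plus one driving input
one_node_params <- function(cdrive = 0.3, self_log = 0) {
  dcm_params(
    A = matrix(self_log, 1, 1),
    B = list(Go = matrix(0, 1, 1)),
    C = matrix(cdrive, 1, 1, dimnames = list(NULL, "Go")),
    hemo = default_hemo(1), noise_log_precision = 4, nodes = "node"
  )
}

one_node_design <- function(onset = 10, duration = 20, total = 60, TR = 2,
                            dt = TR / 256, mean_center = FALSE) {
  experiment_design(
    blocks = data.frame(run = 1, condition = "Go", onset = onset,
                        duration = duration),
    TR = TR, n_volumes = ceiling(total / TR), n_runs = 1, microtime_dt = dt,
    conditions = "Go", mean_center = mean_center
  )
}
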
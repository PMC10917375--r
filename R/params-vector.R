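#' Names of the estimable parameter vector
#'
#' The inversion and group-level machinery operate on a flat named vector
#' collecting, in a fixed order: intrinsic off-diagonal couplings
#' `A[target,source]` (Hz), self-connection log scalings `A[t,t]`, all
#' modulatory entries `B_<input>[target,source]` (off-diagonals in Hz,
#' diagonals unitless log scalings), driving inputs `C[target,input]` (Hz),
#' and per-node log deviations of the hemodynamic decay rate
#' (`decay[node]`, kappa = 0.64 exp(.)) and transit time (`transit[node]`,
#' tau = 2 exp(.)).
#'
#' @param nodes Node labels.
#' @param mod_inputs Modulatory input names.
#' @param drv_inputs Driving input names.
#' @return Character vector of parameter names.
#' @export
param_names <- function(nodes = dcm_nodes(), mod_inputs = c("Go", "NoGo"),
                        drv_inputs = c("Go", "NoGo")) {
  n <- length(nodes)
  offdiag <- character(0)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t != s) offdiag <- c(offdiag, sprintf("[%s,%s]", nodes[t], nodes[s]))
    }
  }
  a_off <- paste0("A", offdiag)
  a_diag <- sprintf("A[%s,%s]", nodes, nodes)
  b <- unlist(lapply(mod_inputs, function(m) {
    full <- character(0)
    for (s in seq_len(n)) for (t in seq_len(n))
      full <- c(full, sprintf("B_%s[%s,%s]", m, nodes[t], nodes[s]))
    full
  }))
  cc <- unlist(lapply(drv_inputs, function(d) sprintf("C[%s,%s]", nodes, d)))
  hemo <- c(sprintf("decay[%s]", nodes), sprintf("transit[%s]", nodes))
  c(a_off, a_diag, b, cc, hemo)
}

#' Flatten a DCM parameter set to the estimable vector
#'
#' @param params A [dcm_params()] object.
#' @return Named numeric vector in [param_names()] order.
#' @export
pack_params <- function(params) {
  nodes <- params$nodes
  n <- length(nodes)
  nm <- param_names(nodes, names(params$B), colnames(params$C))
  theta <- setNames(numeric(length(nm)), nm)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    theta[sprintf("A[%s,%s]", nodes[t], nodes[s])] <- params$A[t, s]
  }
  for (m in names(params$B)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      theta[sprintf("B_%s[%s,%s]", m, nodes[t], nodes[s])] <- params$B[[m]][t, s]
    }
  }
  for (d in colnames(params$C)) {
    theta[sprintf("C[%s,%s]", nodes, d)] <- params$C[, d]
  }
  theta[sprintf("decay[%s]", nodes)] <- log(params$hemo$kappa / 0.64)
  theta[sprintf("transit[%s]", nodes)] <- log(params$hemo$tau / 2.0)
  theta
}

#' Rebuild a DCM parameter set from the estimable vector
#'
#' @param theta Named vector as produced by [pack_params()].
#' @param template A [dcm_params()] providing node labels, input names and
#'   the non-estimated hemodynamic constants.
#' @return A [dcm_params()] object.
#' @export
unpack_params <- function(theta, template) {
  nodes <- template$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    A[t, s] <- theta[[sprintf("A[%s,%s]", nodes[t], nodes[s])]]
  }
  B <- lapply(setNames(names(template$B), names(template$B)), function(m) {
    b <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (s in seq_len(n)) for (t in seq_len(n)) {
      b[t, s] <- theta[[sprintf("B_%s[%s,%s]", m, nodes[t], nodes[s])]]
    }
    b
  })
  C <- template$C
  for (d in colnames(C)) C[, d] <- theta[sprintf("C[%s,%s]", nodes, d)]
  hemo <- template$hemo
  hemo$kappa <- 0.64 * exp(theta[sprintf("decay[%s]", nodes)])
  hemo$tau <- 2.0 * exp(theta[sprintf("transit[%s]", nodes)])
  dcm_params(A, B, C, hemo, template$noise_log_precision, nodes)
}

#' Indices of a parameter block within the estimable vector
#'
#' @param names Parameter names as from [param_names()].
#' @param block One of `"A"`, `"B"`, `"C"`, `"hemo"`, or a specific
#'   modulatory input block such as `"B_NoGo"`.
#' @return Integer indices.
#' @export
param_block <- function(names, block) {
  pattern <- switch(block,
    A = "^A\\[", B = "^B_", C = "^C\\[",
    hemo = "^(decay|transit)\\[",
    paste0("^", block, "\\[")
  )
  grep(pattern, names)
}
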
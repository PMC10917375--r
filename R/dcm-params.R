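#' @useDynLib inhibcircuit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm dnorm pnorm sd var coef lm pt pf qnorm setNames
#' @importFrom utils read.delim write.table head tail modifyList
NULL

#' Canonical node order of the response-inhibition circuit
#'
#' The four-node right-lateralized circuit is modelled in a single fixed node
#' order -- inferior frontal gyrus (IFG), caudate (Cau), globus pallidus (GP),
#' thalamus (Thal) -- so that every matrix in the package shares the same row
#' and column meaning (rows are targets, columns are sources).
#'
#' @return Character vector of node labels.
#' @export
dcm_nodes <- function() c("IFG", "Cau", "GP", "Thal")

#' Default balloon-model hemodynamic constants
#'
#' Per-node hemodynamic parameters of the balloon model: signal decay rate
#' `kappa` (1/s), autoregulatory feedback rate `gamma` (1/s), mean transit
#' time `tau` (s), vessel stiffness exponent `alpha`, resting oxygen
#' extraction fraction `E0`, and resting venous blood volume fraction `V0`.
#' Defaults are the canonical published values for 3T BOLD.
#'
#' @param n_nodes Number of regions.
#' @return Data frame with one row per node.
#' @export
default_hemo <- function(n_nodes = 4L) {
  data.frame(
    kappa = rep(0.64, n_nodes), gamma = rep(0.32, n_nodes),
    tau = rep(2.0, n_nodes), alpha = rep(0.32, n_nodes),
    E0 = rep(0.4, n_nodes), V0 = rep(0.04, n_nodes)
  )
}

#' Construct a DCM parameter set
#'
#' Bundles the bilinear model parameters of one subject: the intrinsic
#' coupling matrix `A` (off-diagonal entries in Hz; diagonal entries are
#' unitless log-scaling factors of the default -0.5 Hz self-connection), one
#' modulatory matrix `B` per experimental input with the same conventions,
#' the driving-input matrix `C` (Hz per unit input), per-node hemodynamic
#' parameters, and per-node log precisions of the observation noise.
#'
#' Rows index target regions and columns index source regions, so `A["Thal",
#' "IFG"]` is the influence of IFG on Thal.
#'
#' @param A Square intrinsic coupling matrix.
#' @param B Named list of square modulatory matrices (one per modulatory
#'   input, e.g. `Go`, `NoGo`).
#' @param C Matrix of driving inputs, nodes x driving inputs, with column
#'   names naming the inputs.
#' @param hemo Data frame of hemodynamic parameters as in [default_hemo()].
#' @param noise_log_precision Per-node log precision of additive Gaussian
#'   observation noise (noise SD = `exp(-lp/2)` in % signal change).
#' @param nodes Node labels.
#' @return Object of class `dcm_params`.
#' @export
dcm_params <- function(A, B, C, hemo = default_hemo(nrow(A)),
                       noise_log_precision = rep(4, nrow(A)),
                       nodes = dcm_nodes()) {
  n <- length(nodes)
  stopifnot(is.matrix(A), nrow(A) == n, ncol(A) == n)
  stopifnot(is.list(B), !is.null(names(B)))
  for (b in B) stopifnot(is.matrix(b), nrow(b) == n, ncol(b) == n)
  stopifnot(is.matrix(C), nrow(C) == n, !is.null(colnames(C)))
  stopifnot(nrow(hemo) == n, all(hemo$alpha > 0 & hemo$alpha < 1),
            all(hemo$E0 > 0 & hemo$E0 < 1), all(hemo$tau > 0))
  dimnames(A) <- list(nodes, nodes)
  B <- lapply(B, function(b) {
    dimnames(b) <- list(nodes, nodes)
    b
  })
  rownames(C) <- nodes
  structure(
    list(A = A, B = B, C = C, hemo = hemo,
         noise_log_precision = setNames(as.numeric(noise_log_precision), nodes),
         nodes = nodes),
    class = "dcm_params"
  )
}

#' @export
print.dcm_params <- function(x, ...) {
  cat("DCM parameters:", length(x$nodes), "nodes (",
      paste(x$nodes, collapse = ", "), ")\n")
  cat("Modulatory inputs:", paste(names(x$B), collapse = ", "), "\n")
  cat("Driving inputs:", paste(colnames(x$C), collapse = ", "), "\n")
  cat("A (Hz off-diagonal; diagonal = log self-scaling):\n")
  print(round(x$A, 3))
  invisible(x)
}

#' Input-dependent Jacobian of the neural dynamics
#'
#' Evaluates the effective coupling matrix `J(u)` at given modulatory input
#' values. Off-diagonal entries are `A[i,k] + sum_j u_j B_j[i,k]` in Hz.
#' Diagonal entries follow the self-connection convention: the unitless log
#' scaling parameters are exponentiated and multiplied by the default value
#' of -0.5 Hz, i.e. `-0.5 * exp(A[i,i] + sum_j u_j B_j[i,i])`, which keeps
#' every effective self-connection strictly negative. A positive log
#' parameter therefore means increased self-inhibition (reduced sensitivity
#' to inputs from the rest of the network).
#'
#' @param params A [dcm_params()] object.
#' @param u Named numeric vector of modulatory input values, one per
#'   modulatory matrix in `params$B`.
#' @return Square matrix in Hz.
#' @export
jacobian_at <- function(params, u) {
  B <- params$B
  if (length(u) != length(B)) {
    stop("`u` must supply one value per modulatory input (",
         length(B), " expected, ", length(u), " given)")
  }
  if (!is.null(names(u))) u <- u[names(B)]
  J <- params$A
  dlog <- diag(params$A)
  diag(J) <- 0
  for (j in seq_along(B)) {
    bj <- B[[j]]
    bd <- diag(bj)
    diag(bj) <- 0
    J <- J + u[j] * bj
    dlog <- dlog + u[j] * bd
  }
  diag(J) <- -0.5 * exp(dlog)
  J
}

#' Neural rate of change under the bilinear model
#'
#' `dx/dt = J(u) x + C u_driving`, where `J(u)` is [jacobian_at()].
#'
#' @param params A [dcm_params()] object.
#' @param u Named modulatory input values.
#' @param x Neural activity vector.
#' @param u_driving Named driving input values (defaults to `u` entries that
#'   match the columns of `C`).
#' @return Vector of derivatives (1/s).
#' @export
neural_derivative <- function(params, u, x, u_driving = NULL) {
  stopifnot(all(is.finite(x)), length(x) == length(params$nodes))
  if (is.null(u_driving)) {
    u_driving <- setNames(rep(0, ncol(params$C)), colnames(params$C))
    common <- intersect(names(u), colnames(params$C))
    u_driving[common] <- u[common]
  } else {
    u_driving <- u_driving[colnames(params$C)]
  }
  drop(jacobian_at(params, u) %*% x + params$C %*% u_driving)
}

#' Balloon-model state derivative for one region
#'
#' States are the vasodilatory signal `s`, normalized inflow `f`, venous
#' volume `v` and deoxyhemoglobin content `q` (`f`, `v`, `q` equal 1 at
#' rest). The dynamics are `ds/dt = x - kappa s - gamma (f - 1)`,
#' `df/dt = s`, `tau dv/dt = f - v^(1/alpha)`, and
#' `tau dq/dt = f E(f)/E0 - v^(1/alpha) q / v` with
#' `E(f) = 1 - (1 - E0)^(1/f)`.
#'
#' @param hemo One-row data frame (or list) of hemodynamic constants.
#' @param x Neural drive (scalar).
#' @param state Numeric vector `c(s, f, v, q)`.
#' @return Derivative vector `c(ds, df, dv, dq)`.
#' @export
hemodynamic_derivative <- function(hemo, x, state) {
  s <- state[[1]]; f <- state[[2]]; v <- state[[3]]; q <- state[[4]]
  if (!all(is.finite(state)) || v <= 0 || q <= 0 || f <= 0) {
    stop("hemodynamic state left its admissible domain (integration blow-up)")
  }
  fv <- v^(1 / hemo$alpha)
  ef <- 1 - (1 - hemo$E0)^(1 / f)
  c(s = x - hemo$kappa * s - hemo$gamma * (f - 1),
    f = s,
    v = (f - fv) / hemo$tau,
    q = (f * ef / hemo$E0 - fv * q / v) / hemo$tau)
}

#' BOLD observation equation
#'
#' Maps a hemodynamic state to percent BOLD signal change using the revised
#' coefficients `k1 = 4.3 nu0 E0 TE`, `k2 = eps r0 E0 TE`, `k3 = 1 - eps`
#' with `nu0 = 40.3` 1/s, `r0 = 25` 1/s and `eps = 1`:
#' `y = 100 V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`. The resting state
#' maps to exactly 0.
#'
#' @param hemo One-row data frame (or list) with `E0` and `V0`.
#' @param state Numeric vector `c(s, f, v, q)`.
#' @param TE Echo time in seconds.
#' @return Scalar BOLD signal in % signal change.
#' @export
bold_observation <- function(hemo, state, TE = 0.03) {
  v <- state[[3]]; q <- state[[4]]
  eps <- 1
  k1 <- 4.3 * 40.3 * hemo$E0 * TE
  k2 <- eps * 25 * hemo$E0 * TE
  k3 <- 1 - eps
  100 * hemo$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}
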
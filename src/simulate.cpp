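// Forward integration of the bilinear neural model coupled to the balloon
// hemodynamic observation model.
//
// Inputs are piecewise constant over microtime bins, so the neural substep
// uses the exact matrix-exponential propagator of the input-dependent
// Jacobian J(u) over one bin; propagators are cached per distinct input row.
// The hemodynamic states evolve on time constants of seconds and are
// advanced by classical RK4 over one or two microtime bins (`stride`); the
// neural drive at the RK4 start/mid/end nodes is exact in either case
// (half-bin propagator for stride 1, the intermediate bin state for
// stride 2). Volume sampling and run resets are aligned to hemo steps by
// the R wrapper.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

// per-node balloon model in log state space: state (s, log f, log v, log q),
// neural drive x. Log states keep inflow, volume and deoxyhemoglobin
// strictly positive (the natural-space equations are singular at f = 0).
static inline vec::fixed<4> hemo_deriv(const double x, const vec::fixed<4> &y,
                                       const double kappa, const double gamma,
                                       const double tau, const double alpha,
                                       const double log1mE0,
                                       const double E0) {
  vec::fixed<4> d;
  // clamp log states so all rates stay finite while an inadmissible state
  // is being detected (the integrator flags |log state| > 4 as a domain
  // violation; the clamp is never active in the physiological range)
  const double zf = std::clamp(y(1), -4.0, 4.0);
  const double zv = std::clamp(y(2), -4.0, 4.0);
  const double zq = std::clamp(y(3), -4.0, 4.0);
  const double s = y(0);
  const double f = std::exp(zf);
  const double ia = 1.0 / alpha;
  const double fv = std::exp(zv * ia);            // v^(1/alpha)
  const double ef = 1.0 - std::exp(log1mE0 / f);  // 1 - (1-E0)^(1/f)
  d(0) = x - kappa * s - gamma * (f - 1.0);
  d(1) = s / f;
  d(2) = (f - fv) * std::exp(-zv) / tau;
  d(3) = (f * ef / E0 * std::exp(-zq) - std::exp(zv * (ia - 1.0))) / tau;
  return d;
}

// [[Rcpp::export(name = ".simulate_dcm_cpp")]]
List simulate_dcm_cpp(const arma::mat &A, const arma::cube &B,
                      const arma::mat &C, const arma::mat &Umod,
                      const arma::mat &Udrive, const arma::ivec &grp,
                      const arma::ivec &sample_idx,
                      const arma::ivec &run_start, const arma::vec &kappa,
                      const arma::vec &gamma_, const arma::vec &tau,
                      const arma::vec &alpha, const arma::vec &E0,
                      const arma::vec &V0, const double TE, const double dt,
                      const double x_bound, const bool return_neural,
                      const int stride) {
  const uword n = A.n_rows;
  const uword nu = B.n_slices;
  const uword G = Umod.n_rows;
  const uword nmicro = grp.n_elem;
  const bool paired = stride == 2;

  sword nvol = 0;
  for (uword k = 0; k < nmicro; ++k)
    if (sample_idx(k) + 1 > nvol) nvol = sample_idx(k) + 1;

  // cache per distinct input row: full/half-bin propagators and the
  // particular solution of the driven linear system over the bin
  std::vector<mat> Efull(G), Ehalf(G);
  std::vector<vec> dfull(G), dhalf(G);
  const mat I = eye<mat>(n, n);
  for (uword g = 0; g < G; ++g) {
    mat J = A;
    J.diag().zeros();
    vec dlog = A.diag();
    for (uword j = 0; j < nu; ++j) {
      mat Bj = B.slice(j);
      vec bdiag = Bj.diag();
      Bj.diag().zeros();
      J += Umod(g, j) * Bj;
      dlog += Umod(g, j) * bdiag;
    }
    J.diag() = -0.5 * exp(dlog);
    Efull[g] = expmat(J * dt);
    vec cu = C * Udrive.row(g).t();
    dfull[g] = (norm(cu) > 0) ? vec(solve(J, (Efull[g] - I) * cu))
                              : zeros<vec>(n);
    if (!paired) {
      Ehalf[g] = expmat(J * (dt / 2.0));
      dhalf[g] = (norm(cu) > 0) ? vec(solve(J, (Ehalf[g] - I) * cu))
                                : zeros<vec>(n);
    }
  }

  vec x = zeros<vec>(n), xmid(n), xnew(n);
  mat hemo(4, n);  // rows: s, log f, log v, log q (rest state is all zero)
  auto reset_states = [&]() {
    x.zeros();
    hemo.zeros();
  };
  reset_states();

  mat bold(nvol > 0 ? (uword)nvol : 0, n, fill::zeros);
  mat neural;
  if (return_neural) neural.set_size(nmicro, n);

  const double k1c = 4.3 * 40.3, r0 = 25.0, eps = 1.0;
  bool ok = true;
  sword bad_step = -1;
  double max_abs_x = 0.0;
  const double h = paired ? 2.0 * dt : dt;

  for (uword k = 0; k < nmicro; k += (paired ? 2 : 1)) {
    if (run_start(k)) reset_states();
    if (return_neural) neural.row(k) = x.t();

    if (sample_idx(k) >= 0) {
      for (uword i = 0; i < n; ++i) {
        const double v = std::exp(hemo(2, i)), q = std::exp(hemo(3, i));
        const double kk1 = k1c * E0(i) * TE;
        const double kk2 = eps * r0 * E0(i) * TE;
        const double kk3 = 1.0 - eps;
        bold((uword)sample_idx(k), i) =
            100.0 * V0(i) * (kk1 * (1.0 - q) + kk2 * (1.0 - q / v) +
                             kk3 * (1.0 - v));
      }
    }

    if (paired) {
      const uword g1 = (uword)grp(k), g2 = (uword)grp(k + 1);
      xmid = Efull[g1] * x;
      xmid += dfull[g1];
      xnew = Efull[g2] * xmid;
      xnew += dfull[g2];
      if (return_neural) neural.row(k + 1) = xmid.t();
    } else {
      const uword g = (uword)grp(k);
      xmid = Ehalf[g] * x;
      xmid += dhalf[g];
      xnew = Efull[g] * x;
      xnew += dfull[g];
    }

    bool bad = false;
    for (uword i = 0; i < n; ++i) {
      vec::fixed<4> y;
      y(0) = hemo(0, i); y(1) = hemo(1, i); y(2) = hemo(2, i); y(3) = hemo(3, i);
      const double ka = kappa(i), ga = gamma_(i), ta = tau(i), al = alpha(i),
                   e0 = E0(i), lE = std::log(1.0 - e0);
      vec::fixed<4> k1s = hemo_deriv(x(i), y, ka, ga, ta, al, lE, e0);
      vec::fixed<4> k2s =
          hemo_deriv(xmid(i), y + 0.5 * h * k1s, ka, ga, ta, al, lE, e0);
      vec::fixed<4> k3s =
          hemo_deriv(xmid(i), y + 0.5 * h * k2s, ka, ga, ta, al, lE, e0);
      vec::fixed<4> k4s =
          hemo_deriv(xnew(i), y + h * k3s, ka, ga, ta, al, lE, e0);
      y += (h / 6.0) * (k1s + 2.0 * k2s + 2.0 * k3s + k4s);
      hemo(0, i) = y(0); hemo(1, i) = y(1); hemo(2, i) = y(2); hemo(3, i) = y(3);
      const double ax = std::max(std::fabs(xnew(i)), std::fabs(xmid(i)));
      if (ax > max_abs_x) max_abs_x = ax;
      const double zmax = std::max(std::fabs(y(1)),
                                   std::max(std::fabs(y(2)), std::fabs(y(3))));
      if (!std::isfinite(ax) || ax > x_bound || zmax > 4.0 ||
          !std::isfinite(y(0) + y(1) + y(2) + y(3))) {
        bad = true;
      }
    }
    x = xnew;
    if (bad) {
      ok = false;
      bad_step = (sword)k;
      break;
    }
  }

  List out = List::create(Named("bold") = bold, Named("ok") = ok,
                          Named("bad_step") = bad_step + 1,
                          Named("max_abs_x") = max_abs_x);
  if (return_neural) out["neural"] = neural;
  return out;
}
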
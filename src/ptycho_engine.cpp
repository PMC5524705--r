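// Ptychographic phase retrieval engine: difference-map iterations and
// maximum-likelihood (Poisson) conjugate-gradient refinement.
//
// Conventions shared with the R side:
//  * frames I are n1 x n2 x J cubes of measured intensities (photon counts);
//  * win is a J x 2 matrix of 0-based top-left (row, col) indices of each
//    probe window in the object grid;
//  * frac is a J x 2 matrix of sub-pixel (row, col) offsets in [-0.5, 0.5];
//    the probe used at position j is the nominal probe Fourier-shifted by
//    frac(j,) (exact for band-limited fields). All-zero frac enables a fast
//    path without per-position shift transforms;
//  * the DFT is orthonormal: F(x) = fft2(x)/sqrt(n1*n2), so Parseval holds
//    without extra factors.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double TWO_PI = 6.283185307179586476925286766559;

// frequency index in cycles/sample for an n-point DFT, as a column vector
static vec fft_freq(uword n) {
  vec f(n);
  for (uword k = 0; k < n; ++k) {
    double kk = (k <= (n - 1) / 2) ? (double)k : ((double)k - (double)n);
    f(k) = kk / (double)n;
  }
  return f;
}

// phase ramps implementing real-space shift by (dr, dc):  F{x(r-d)} = e^{-2pi i f.d} F{x}
static cx_cube make_ramps(uword n1, uword n2, const mat& frac) {
  uword J = frac.n_rows;
  cx_cube ramps(n1, n2, J);
  vec fr = fft_freq(n1), fc = fft_freq(n2);
  for (uword j = 0; j < J; ++j) {
    vec pr = -TWO_PI * fr * frac(j, 0);
    vec pc = -TWO_PI * fc * frac(j, 1);
    cx_vec er(n1), ec(n2);
    for (uword k = 0; k < n1; ++k) er(k) = std::polar(1.0, pr(k));
    for (uword k = 0; k < n2; ++k) ec(k) = std::polar(1.0, pc(k));
    ramps.slice(j) = er * ec.st();
  }
  return ramps;
}

// [[Rcpp::export]]
arma::cx_cube cpp_fft2_stack(const arma::cx_cube& A, bool inverse, bool orthonormal) {
  cx_cube out(size(A));
  double s = std::sqrt((double)(A.n_rows * A.n_cols));
  for (uword j = 0; j < A.n_slices; ++j) {
    if (inverse) {
      out.slice(j) = ifft2(A.slice(j));
      if (orthonormal) out.slice(j) *= s;
    } else {
      out.slice(j) = fft2(A.slice(j));
      if (orthonormal) out.slice(j) /= s;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_mat cpp_fourier_shift(const arma::cx_mat& x, double dr, double dc) {
  mat fr(1, 2);
  fr(0, 0) = dr; fr(0, 1) = dc;
  cx_cube ramp = make_ramps(x.n_rows, x.n_cols, fr);
  return ifft2(fft2(x) % ramp.slice(0));
}

struct Geometry {
  uword n1, n2, J, H, W;
  double sqrtN;
  umat win;
  bool has_frac;
  cx_cube ramps;   // forward ramps (shift by +frac)
  Geometry(const cube& I, const umat& win_, const mat& frac, uword H_, uword W_)
    : n1(I.n_rows), n2(I.n_cols), J(I.n_slices), H(H_), W(W_), win(win_) {
    sqrtN = std::sqrt((double)(n1 * n2));
    has_frac = (abs(frac).max() > 1e-12);
    if (has_frac) ramps = make_ramps(n1, n2, frac);
  }
  // per-position probes (probe Fourier-shifted by frac)
  void shifted_probes(const cx_mat& P, cx_cube& Pj) const {
    if (!has_frac) {
      for (uword j = 0; j < J; ++j) Pj.slice(j) = P;
    } else {
      cx_mat Ph = fft2(P);
      for (uword j = 0; j < J; ++j) Pj.slice(j) = ifft2(Ph % ramps.slice(j));
    }
  }
  cx_mat owin(const cx_mat& O, uword j) const {
    return O.submat(win(j, 0), win(j, 1), win(j, 0) + n1 - 1, win(j, 1) + n2 - 1);
  }
  // adjoint of the fractional shift (shift back by -frac)
  cx_mat unshift(const cx_mat& x, uword j) const {
    if (!has_frac) return x;
    return ifft2(fft2(x) % conj(ramps.slice(j)));
  }
};

// object update: O = sum_j conj(Pj) psi_j / max(sum_j |Pj|^2, eps)
static void overlap_object(const Geometry& g, const cx_cube& Pj, const cx_cube& psi,
                           cx_mat& O, double eps_rel) {
  cx_mat num(g.H, g.W, fill::zeros);
  mat den(g.H, g.W, fill::zeros);
  for (uword j = 0; j < g.J; ++j) {
    uword r0 = g.win(j, 0), c0 = g.win(j, 1);
    num.submat(r0, c0, r0 + g.n1 - 1, c0 + g.n2 - 1) += conj(Pj.slice(j)) % psi.slice(j);
    den.submat(r0, c0, r0 + g.n1 - 1, c0 + g.n2 - 1) += square(abs(Pj.slice(j)));
  }
  double eps = eps_rel * den.max();
  if (eps <= 0) eps = 1e-300;
  mat denc = clamp(den, eps, datum::inf);
  O = num / conv_to<cx_mat>::from(denc);
  // pixels with negligible illumination are unconstrained by the data;
  // cap them at the passive-sample bound |O| <= 1 so they cannot feed
  // spurious power into the probe update (inactive on covered pixels)
  double low = 1e-3 * den.max();
  for (uword i = 0; i < O.n_elem; ++i) {
    if (den(i) < low) {
      double a = std::abs(O(i));
      if (a > 1.0) O(i) /= a;
    }
  }
}

// probe update: P = sum_j S_j^H(conj(O_wj) psi_j) / max(sum_j |O_wj|^2, eps).
// The numerator uses the exact adjoint of the fractional shift; the
// denominator uses the unshifted object power (positive by construction --
// a band-limited shift of |O|^2 can ring negative, and clamping those
// pixels would amplify them catastrophically; |O|^2 varies slowly so the
// sub-pixel difference is negligible).
static void overlap_probe(const Geometry& g, const cx_mat& O, const cx_cube& psi,
                          cx_mat& P, double eps_rel) {
  cx_mat num(g.n1, g.n2, fill::zeros);
  mat den(g.n1, g.n2, fill::zeros);
  for (uword j = 0; j < g.J; ++j) {
    cx_mat ow = g.owin(O, j);
    num += g.unshift(conj(ow) % psi.slice(j), j);
    den += square(abs(ow));
  }
  double eps = eps_rel * den.max();
  if (eps <= 0) eps = 1e-300;
  den = clamp(den, eps, datum::inf);
  cx_mat Pnew = num / conv_to<cx_mat>::from(den);
  // with sub-pixel positions the diagonal update is only approximate
  // (S^H |O|^2 S does not commute); damping keeps the feedback loop stable
  P = g.has_frac ? cx_mat(0.5 * P + 0.5 * Pnew) : Pnew;
}

// [[Rcpp::export]]
Rcpp::List cpp_dm_engine(const arma::cube& I, const arma::cx_mat& O0,
                         const arma::cx_mat& P0, const arma::umat& win,
                         const arma::mat& frac, int n_iter, int probe_freeze,
                         bool update_probe, double eps_rel) {
  if (!I.is_finite()) Rcpp::stop("diffraction frames contain non-finite values");
  if (I.max() <= 0) Rcpp::stop("all diffraction frames are zero");
  Geometry g(I, win, frac, O0.n_rows, O0.n_cols);
  cube sqrtI = sqrt(I);
  double sumI = accu(I);

  cx_mat O = O0, P = P0;
  cx_cube Pj(g.n1, g.n2, g.J), psi(g.n1, g.n2, g.J);
  g.shifted_probes(P, Pj);
  for (uword j = 0; j < g.J; ++j) psi.slice(j) = Pj.slice(j) % g.owin(O, j);

  vec err(n_iter, fill::zeros);
  for (int it = 0; it < n_iter; ++it) {
    overlap_object(g, Pj, psi, O, eps_rel);
    if (update_probe && it >= probe_freeze) {
      overlap_probe(g, O, psi, P, eps_rel);
      g.shifted_probes(P, Pj);
    }
    double e2 = 0.0;
    for (uword j = 0; j < g.J; ++j) {
      cx_mat po = Pj.slice(j) % g.owin(O, j);
      cx_mat A = fft2(po) / g.sqrtN;
      cx_mat B = fft2(psi.slice(j)) / g.sqrtN;
      cx_mat G = 2.0 * A - B;
      e2 += accu(square(abs(A) - sqrtI.slice(j)));
      mat aG = clamp(abs(G), 1e-30, datum::inf);
      cx_mat Gp = G % conv_to<cx_mat>::from(sqrtI.slice(j) / aG);
      psi.slice(j) += ifft2(Gp) * g.sqrtN - po;
    }
    err(it) = std::sqrt(e2 / sumI);
    if ((it & 15) == 0) Rcpp::checkUserInterrupt();
  }
  // return object/probe consistent with the final exit waves
  overlap_object(g, Pj, psi, O, eps_rel);
  if (update_probe && n_iter > probe_freeze) overlap_probe(g, O, psi, P, eps_rel);

  return Rcpp::List::create(Rcpp::Named("object") = O, Rcpp::Named("probe") = P,
                            Rcpp::Named("error") = err);
}

// Poisson negative log-likelihood and (optionally) its Wirtinger gradients
static double ml_eval(const Geometry& g, const cube& I, const cx_mat& O, const cx_mat& P,
                      double eps, bool want_grad, cx_mat& gO, cx_mat& gP) {
  double L = 0.0;
  if (want_grad) { gO.zeros(g.H, g.W); gP.zeros(g.n1, g.n2); }
  cx_mat Ph;
  if (g.has_frac) Ph = fft2(P);
  for (uword j = 0; j < g.J; ++j) {
    cx_mat Pjs = g.has_frac ? cx_mat(ifft2(Ph % g.ramps.slice(j))) : P;
    cx_mat ow = g.owin(O, j);
    cx_mat po = Pjs % ow;
    cx_mat Psi = fft2(po) / g.sqrtN;
    mat Ij = square(abs(Psi));
    L += accu(Ij) - accu(I.slice(j) % log(Ij + eps));
    if (want_grad) {
      cx_mat chi = Psi % conv_to<cx_mat>::from(1.0 - I.slice(j) / (Ij + eps));
      cx_mat chir = ifft2(chi) * g.sqrtN;
      uword r0 = g.win(j, 0), c0 = g.win(j, 1);
      gO.submat(r0, c0, r0 + g.n1 - 1, c0 + g.n2 - 1) += conj(Pjs) % chir;
      gP += g.unshift(conj(ow) % chir, j);
    }
  }
  return L;
}

// [[Rcpp::export]]
Rcpp::List cpp_ml_engine(const arma::cube& I, const arma::cx_mat& O0,
                         const arma::cx_mat& P0, const arma::umat& win,
                         const arma::mat& frac, int n_iter, bool update_probe,
                         double eps_rel, double grad_tol) {
  if (!I.is_finite()) Rcpp::stop("diffraction frames contain non-finite values");
  Geometry g(I, win, frac, O0.n_rows, O0.n_cols);
  double eps = eps_rel * I.max();
  cx_mat O = O0, P = P0;

  // diagonal preconditioners (illumination / object power), fixed at entry
  cx_cube Pj(g.n1, g.n2, g.J);
  g.shifted_probes(P, Pj);
  mat mO(g.H, g.W, fill::zeros), mP(g.n1, g.n2, fill::zeros);
  for (uword j = 0; j < g.J; ++j) {
    uword r0 = g.win(j, 0), c0 = g.win(j, 1);
    mO.submat(r0, c0, r0 + g.n1 - 1, c0 + g.n2 - 1) += square(abs(Pj.slice(j)));
    mP += square(abs(g.owin(O, j)));
  }
  mO += 1e-6 * mO.max() + 1e-300;
  mP += 1e-6 * mP.max() + 1e-300;

  cx_mat gO, gP, sO, sP, dO, dP, gOp, gPp, sOp, sPp;
  std::vector<double> Lhist;
  int flag = 0, done = 0;
  double t_prev = 0.5, gnorm0 = NA_REAL;

  for (int it = 0; it < n_iter; ++it) {
    double L0 = ml_eval(g, I, O, P, eps, true, gO, gP);
    if (!update_probe) gP.zeros();
    Lhist.push_back(L0);
    double gnorm = std::sqrt(std::pow(norm(gO, "fro"), 2) + std::pow(norm(gP, "fro"), 2));
    if (it == 0) gnorm0 = gnorm;
    if (gnorm < grad_tol * std::max(1.0, std::abs(L0))) { flag = 0; break; }

    sO = gO / conv_to<cx_mat>::from(mO);
    sP = gP / conv_to<cx_mat>::from(mP);
    double beta = 0.0;
    if (it > 0) {
      double num = accu(real(conj(sO) % (gO - gOp))) + accu(real(conj(sP) % (gP - gPp)));
      double den = accu(real(conj(sOp) % gOp)) + accu(real(conj(sPp) % gPp));
      if (den > 0) beta = std::max(0.0, num / den);
    }
    if (it == 0) { dO = -sO; dP = -sP; }
    else { dO = -sO + beta * dO; dP = -sP + beta * dP; }
    double dphi0 = 2.0 * (accu(real(conj(gO) % dO)) + accu(real(conj(gP) % dP)));
    if (dphi0 >= 0) {  // not a descent direction: restart with steepest descent
      dO = -sO; dP = -sP;
      dphi0 = 2.0 * (accu(real(conj(gO) % dO)) + accu(real(conj(gP) % dP)));
    }
    gOp = gO; gPp = gP; sOp = sO; sPp = sP;

    // parabolic line search with bounded backtracking
    double t1 = t_prev > 0 ? t_prev : 0.5;
    double t_best = -1.0, L_best = L0;
    cx_mat dummyO, dummyP;
    for (int tries = 0; tries < 7; ++tries) {
      double L1 = ml_eval(g, I, O + t1 * dO, P + t1 * dP, eps, false, dummyO, dummyP);
      double denom = L1 - L0 - dphi0 * t1;
      double tq = (denom > 0) ? (-dphi0 * t1 * t1 / (2.0 * denom)) : 2.0 * t1;
      tq = std::min(std::max(tq, 0.1 * t1), 10.0 * t1);
      double L2 = ml_eval(g, I, O + tq * dO, P + tq * dP, eps, false, dummyO, dummyP);
      if (L1 < L_best && L1 < L0) { L_best = L1; t_best = t1; }
      if (L2 < L_best && L2 < L0) { L_best = L2; t_best = tq; }
      if (t_best > 0) break;
      t1 *= 0.25;
    }
    if (t_best <= 0) { flag = 1; break; }  // line search failed: stop, keep state
    O += t_best * dO;
    if (update_probe) P += t_best * dP;
    t_prev = t_best;
    done = it + 1;
    Rcpp::checkUserInterrupt();
  }
  cx_mat dummyO, dummyP;
  Lhist.push_back(ml_eval(g, I, O, P, eps, false, dummyO, dummyP));

  return Rcpp::List::create(
      Rcpp::Named("object") = O, Rcpp::Named("probe") = P,
      Rcpp::Named("likelihood") = Lhist, Rcpp::Named("flag") = flag,
      Rcpp::Named("iterations") = done, Rcpp::Named("gnorm0") = gnorm0);
}
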
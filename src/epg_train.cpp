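// Extended-phase-graph (EPG) simulation of a fast-spin-echo refocusing train,
// with optional forward-mode propagation of dS/dalpha through every operator.
//
// State convention (Weigel-style F+/F-/Z configuration states):
//   rows  k = 0..K        dephasing order
//   col 0                 the state itself
//   col j (j = 1..ETL)    d(state)/d(alpha_j), propagated alongside
// All EPG operators (relaxation, gradient shift, RF mixing) are real-linear in
// the state, so derivative columns evolve under the identical maps; the only
// extra term is the injection dT(alpha_i)/dalpha_i * state at pulse i.
// Work is windowed to the populated orders (<= pulse count) and the active
// derivative columns, which keeps the Jacobian at O(ETL^3) element updates.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::complex<double> cplx;

static inline void relax_shift(cx_mat& Fp, cx_mat& Fm, cx_mat& Z,
                               double E1, double E2, double M0,
                               int kmax, int cmax) {
  const int K = Fp.n_rows - 1;
  const int ktop = std::min(kmax + 1, K); // highest order populated after shift
  for (int c = 0; c <= cmax; ++c) {
    cplx* fp = Fp.colptr(c);
    cplx* fm = Fm.colptr(c);
    cplx* z = Z.colptr(c);
    for (int k = 0; k <= kmax; ++k) {
      fp[k] *= E2;
      fm[k] *= E2;
      z[k] *= E1;
    }
    if (c == 0) z[0] += cplx(M0 * (1.0 - E1), 0.0); // regrowth: state only
    // unit gradient dephasing: F+ up one order, F- down one order
    std::memmove(fp + 1, fp, ktop * sizeof(cplx));
    std::memmove(fm, fm + 1, kmax * sizeof(cplx));
    fm[kmax] = cplx(0.0, 0.0);
    fp[0] = std::conj(fm[0]); // lowest F+ state mirrors lowest F-
  }
}

static inline void apply_rf(cx_mat& Fp, cx_mat& Fm, cx_mat& Z,
                            double a, double phi,
                            int dcol, int kmax, int cmax) {
  const cplx i1(0.0, 1.0);
  const cplx e1p = std::exp(i1 * phi), e1m = std::exp(-i1 * phi);
  const cplx e2p = e1p * e1p, e2m = e1m * e1m;
  const double ca2 = std::cos(a / 2.0), sa2 = std::sin(a / 2.0);
  const double ca = std::cos(a), sa = std::sin(a);
  const cplx T11 = ca2 * ca2,         T12 = e2p * (sa2 * sa2), T13 = -i1 * e1p * sa;
  const cplx T21 = e2m * (sa2 * sa2), T22 = ca2 * ca2,         T23 = i1 * e1m * sa;
  const cplx T31 = -0.5 * i1 * e1m * sa, T32 = 0.5 * i1 * e1p * sa, T33 = ca;

  // pre-pulse state (column 0), needed for the derivative injection
  cx_vec fp0, fm0, z0;
  if (dcol >= 0) {
    fp0 = Fp.submat(0, 0, kmax, 0);
    fm0 = Fm.submat(0, 0, kmax, 0);
    z0 = Z.submat(0, 0, kmax, 0);
  }
  for (int c = 0; c <= cmax; ++c) {
    cplx* fp = Fp.colptr(c);
    cplx* fm = Fm.colptr(c);
    cplx* z = Z.colptr(c);
    for (int k = 0; k <= kmax; ++k) {
      const cplx a0 = fp[k], b0 = fm[k], c0 = z[k];
      fp[k] = T11 * a0 + T12 * b0 + T13 * c0;
      fm[k] = T21 * a0 + T22 * b0 + T23 * c0;
      z[k] = T31 * a0 + T32 * b0 + T33 * c0;
    }
  }
  if (dcol >= 0) {
    // d/da of the mixing coefficients, applied to the pre-pulse state
    const cplx d11 = -0.5 * sa,      d12 = e2p * 0.5 * sa, d13 = -i1 * e1p * ca;
    const cplx d21 = e2m * 0.5 * sa, d22 = -0.5 * sa,      d23 = i1 * e1m * ca;
    const cplx d31 = -0.5 * i1 * e1m * ca, d32 = 0.5 * i1 * e1p * ca, d33 = -sa;
    cplx* fp = Fp.colptr(dcol);
    cplx* fm = Fm.colptr(dcol);
    cplx* z = Z.colptr(dcol);
    for (int k = 0; k <= kmax; ++k) {
      fp[k] += d11 * fp0[k] + d12 * fm0[k] + d13 * z0[k];
      fm[k] += d21 * fp0[k] + d22 * fm0[k] + d23 * z0[k];
      z[k] += d31 * fp0[k] + d32 * fm0[k] + d33 * z0[k];
    }
  }
}

// alpha: refocusing flip angles in radians; exc_fa/exc_phase: excitation pulse;
// refoc_phase: common refocusing phase (CPMG: excitation 90 deg out of phase);
// E1h/E2h: relaxation factors over half an echo spacing; inversion: ideal 180
// on Z followed by pure T1 recovery exp(-TI/T1) = E1ti before excitation.
// Returns per-echo magnitudes S (length ETL) and, if jacobian, the matrix
// J[i, j] = dS_i / dalpha_j in 1/radian.
// [[Rcpp::export]]
Rcpp::List epg_fse_train_cpp(const arma::vec& alpha,
                             double exc_fa, double exc_phase, double refoc_phase,
                             double E1h, double E2h, double M0,
                             bool inversion, double E1ti,
                             int K, bool jacobian) {
  const int n = alpha.n_elem;
  const int ncol = jacobian ? n + 1 : 1;
  if (K < 1) Rcpp::stop("truncation order K must be >= 1");

  cx_mat Fp(K + 1, ncol, fill::zeros);
  cx_mat Fm(K + 1, ncol, fill::zeros);
  cx_mat Z(K + 1, ncol, fill::zeros);

  double Mz = M0;
  if (inversion) Mz = M0 * (1.0 - 2.0 * E1ti); // -M0 inverted, then T1 recovery
  Z(0, 0) = cplx(Mz, 0.0);

  // excitation (no dependence on the refocusing train)
  apply_rf(Fp, Fm, Z, exc_fa, exc_phase, -1, 0, 0);

  vec S(n, fill::zeros);
  mat J;
  if (jacobian) J.zeros(n, n);

  int kmax = 0;
  for (int i = 0; i < n; ++i) {
    const int cmax = jacobian ? (i + 1) : 0;
    relax_shift(Fp, Fm, Z, E1h, E2h, M0, kmax, cmax);
    kmax = std::min(kmax + 1, K);
    apply_rf(Fp, Fm, Z, alpha[i], refoc_phase, jacobian ? (i + 1) : -1,
             kmax, cmax);
    relax_shift(Fp, Fm, Z, E1h, E2h, M0, kmax, cmax);
    kmax = std::min(kmax + 1, K);

    const cplx f = Fp(0, 0);
    const double m = std::abs(f);
    S[i] = m;
    if (jacobian && m > 1e-300) {
      for (int j = 0; j <= i; ++j) {
        const cplx df = Fp(0, j + 1);
        J(i, j) = (f.real() * df.real() + f.imag() * df.imag()) / m;
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("S") = S);
  if (jacobian) out["J"] = J;
  return out;
}
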
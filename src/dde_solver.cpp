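#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

// Classical RK4 with the method of steps for the linear delay system
//   dc/dt = A c(t) + theta(t - tau) B c(t - tau),  c(0) = c0,
// on a uniform grid of step h that divides tau exactly (tau = L h, L >= 1),
// so the derivative discontinuities propagated from t = tau land on grid
// nodes. Delayed values at stage midpoints come from cubic Hermite
// interpolation of the stored past (values + one-sided derivatives). At the
// node t = tau the derivative is two-sided: the left limit (no delayed term)
// is used when interpolating the history interval ending there, the right
// limit otherwise, which preserves the integrator's order across the kink.
// tau == 0 must be folded into A by the caller (B all zero, L = 0).
// [[Rcpp::export]]
ComplexMatrix cpp_solve_linear_dde(ComplexMatrix A_, ComplexMatrix B_,
                                   double tau, double h, int n_steps,
                                   ComplexVector c0_) {
  const int d = A_.nrow();
  const int n = n_steps;
  const int L = tau > 0.0 ? (int)std::lround(tau / h) : 0;

  std::vector<cplx> A((size_t)d * d), B((size_t)d * d);
  for (int i = 0; i < d * d; ++i) {
    A[i] = cplx(A_[i].r, A_[i].i);
    B[i] = cplx(B_[i].r, B_[i].i);
  }

  // c: node values; dR: right-sided derivative per node (equals the left
  // derivative everywhere except node L, stored separately).
  std::vector<cplx> c((size_t)(n + 1) * d), dR((size_t)(n + 1) * d);
  std::vector<cplx> dL_at_L(d);
  for (int i = 0; i < d; ++i) c[i] = cplx(c0_[i].r, c0_[i].i);

  std::vector<cplx> u0(d), um(d), u1(d), k1(d), k2(d), k3(d), k4(d), tmp(d);

  auto matvec = [&](const std::vector<cplx>& M, const cplx* v, cplx* out) {
    for (int i = 0; i < d; ++i) {
      cplx s(0.0, 0.0);
      for (int j = 0; j < d; ++j) s += M[(size_t)i + (size_t)d * j] * v[j];
      out[i] = s;
    }
  };

  for (int k = 0; k < n; ++k) {
    const bool active = (L > 0 && k >= L);
    cplx* ck = &c[(size_t)k * d];
    cplx* dk = &dR[(size_t)k * d];

    // node derivative (right-sided)
    matvec(A, ck, dk);
    if (active) {
      matvec(B, &c[(size_t)(k - L) * d], tmp.data());
      for (int i = 0; i < d; ++i) dk[i] += tmp[i];
    }
    if (k == L && L > 0) {
      // left-sided derivative at the activation node (no delayed term)
      matvec(A, ck, dL_at_L.data());
    }

    if (active) {
      const int j = k - L;  // history interval [j, j+1] holds t - tau + h/2
      const cplx* cj = &c[(size_t)j * d];
      const cplx* cj1 = &c[(size_t)(j + 1) * d];
      const cplx* dj = &dR[(size_t)j * d];
      const cplx* dj1 = (j + 1 == L) ? dL_at_L.data() : &dR[(size_t)(j + 1) * d];
      for (int i = 0; i < d; ++i) {
        u0[i] = cj[i];
        um[i] = 0.5 * (cj[i] + cj1[i]) + (h / 8.0) * (dj[i] - dj1[i]);
        u1[i] = cj1[i];
      }
    }

    // RK4 stages; delayed input is stage-time specific but state independent
    for (int i = 0; i < d; ++i) k1[i] = dk[i];

    for (int i = 0; i < d; ++i) tmp[i] = ck[i] + 0.5 * h * k1[i];
    matvec(A, tmp.data(), k2.data());
    if (active) {
      matvec(B, um.data(), tmp.data());
      for (int i = 0; i < d; ++i) k2[i] += tmp[i];
    }

    for (int i = 0; i < d; ++i) tmp[i] = ck[i] + 0.5 * h * k2[i];
    matvec(A, tmp.data(), k3.data());
    if (active) {
      matvec(B, um.data(), tmp.data());
      for (int i = 0; i < d; ++i) k3[i] += tmp[i];
    }

    for (int i = 0; i < d; ++i) tmp[i] = ck[i] + h * k3[i];
    matvec(A, tmp.data(), k4.data());
    if (active) {
      matvec(B, u1.data(), tmp.data());
      for (int i = 0; i < d; ++i) k4[i] += tmp[i];
    }

    cplx* cn = &c[(size_t)(k + 1) * d];
    for (int i = 0; i < d; ++i) {
      cn[i] = ck[i] + (h / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
  }

  ComplexMatrix out(n + 1, d);
  for (int k = 0; k <= n; ++k) {
    for (int i = 0; i < d; ++i) {
      const cplx v = c[(size_t)k * d + i];
      out(k, i) = Rcomplex{v.real(), v.imag()};
    }
  }
  return out;
}
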
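#include <Rcpp.h>
using namespace Rcpp;

// Exact one-step Gaussian propagation of the 3-coordinate linear trap
// network, segment-wise over a Markov state trajectory, with block-averaged
// decimation to the output rate.
//
// Per state s the caller supplies Phi = expm(A dt), the lower Cholesky factor
// of the one-step noise covariance, the affine fixed point xc, and the
// complex amplitude (Xr, Xi) of the sinusoidal particular solution so that
// x_p(t) = Xr sin(w t) + Xi cos(w t).  The update
//   x(t+dt) = xc + x_p(t+dt) + Phi (x(t) - xc - x_p(t)) + cholQ z
// is exact for the linear SDE; accuracy is limited only by the piecewise
// rounding of state-transition times to internal steps.
//
// seg_state: 0-based state index per segment; seg_len: internal steps per
// segment (sum = n_out * navg).  Output: n_out x 2 block means of (x1, x2).

// [[Rcpp::export]]
NumericMatrix ou_propagate_cpp(IntegerVector seg_state, NumericVector seg_len,
                               List Phi, List cholQ, List xc,
                               List Xr, List Xi,
                               double dt, double omega, int navg, int n_out,
                               NumericVector x0) {
  const int n_state = Phi.size();
  std::vector<double> phi(9 * n_state), cq(9 * n_state), xcv(3 * n_state),
      xr(3 * n_state), xi(3 * n_state);
  for (int s = 0; s < n_state; ++s) {
    NumericMatrix P = Phi[s], C = cholQ[s];
    NumericVector c0 = xc[s], r = Xr[s], im = Xi[s];
    for (int a = 0; a < 3; ++a) {
      for (int b = 0; b < 3; ++b) {
        phi[9 * s + 3 * a + b] = P(a, b);
        cq[9 * s + 3 * a + b] = C(a, b);
      }
      xcv[3 * s + a] = c0[a];
      xr[3 * s + a] = r[a];
      xi[3 * s + a] = im[a];
    }
  }

  NumericMatrix out(n_out, 2);
  double x[3] = {x0[0], x0[1], x0[2]};
  double acc1 = 0.0, acc2 = 0.0;
  long step = 0;
  int jout = 0, in_block = 0;
  double sp_cur = 0.0, cp_cur = 1.0;  // sin/cos at t = 0

  RNGScope scope;
  const int n_seg = seg_state.size();
  for (int seg = 0; seg < n_seg; ++seg) {
    const int s = seg_state[seg];
    const double *P = &phi[9 * s], *C = &cq[9 * s];
    const double *c0 = &xcv[3 * s], *r = &xr[3 * s], *im = &xi[3 * s];
    const long len = (long)seg_len[seg];
    for (long k = 0; k < len; ++k) {
      const double t1 = (step + 1) * dt;
      double sp = 0.0, cp = 1.0;
      if (omega > 0.0) { sp = ::sin(omega * t1); cp = ::cos(omega * t1); }
      double v[3], y[3];
      for (int a = 0; a < 3; ++a)
        v[a] = x[a] - c0[a] - (r[a] * sp_cur + im[a] * cp_cur);
      const double z0 = norm_rand(), z1 = norm_rand(), z2 = norm_rand();
      y[0] = P[0] * v[0] + P[1] * v[1] + P[2] * v[2] + C[0] * z0;
      y[1] = P[3] * v[0] + P[4] * v[1] + P[5] * v[2] + C[3] * z0 + C[4] * z1;
      y[2] = P[6] * v[0] + P[7] * v[1] + P[8] * v[2] +
             C[6] * z0 + C[7] * z1 + C[8] * z2;
      for (int a = 0; a < 3; ++a)
        x[a] = c0[a] + r[a] * sp + im[a] * cp + y[a];
      sp_cur = sp; cp_cur = cp;
      ++step;
      acc1 += x[0]; acc2 += x[1];
      if (++in_block == navg) {
        if (jout < n_out) {
          out(jout, 0) = acc1 / navg;
          out(jout, 1) = acc2 / navg;
        }
        ++jout; in_block = 0; acc1 = 0.0; acc2 = 0.0;
      }
    }
  }
  return out;
}
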
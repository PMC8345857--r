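#include <Rcpp.h>
using namespace Rcpp;

// Finite-volume right-hand side on the masked mesh, interleaved state
// y = (n_1, m_1, n_2, m_2, ...). Mirrors rhs_r() in R/dynamics.R exactly;
// the interleaving keeps the Jacobian banded (half-bandwidth 3) for the
// stiff integrator.
//
// dx:      node spacings (N-1)
// w:       cell widths (N)
// Dface:   effective diffusivity at interior faces (N-1), um^2/s
// tmask:   active-transport mask at interior faces (N-1)
// imask:   interconversion mask per node (N)
// pars:    f, v_a, v_r, delta, epsilon, beta, gamma
// [[Rcpp::export]]
NumericVector rhs_interleaved(NumericVector y,
                              NumericVector dx, NumericVector w,
                              NumericVector Dface, NumericVector tmask,
                              NumericVector imask,
                              double f, double va, double vr,
                              double delta, double eps,
                              double beta, double gamma) {
  const int N = w.size();
  NumericVector dy(2 * N);
  double flux_left = 0.0;  // zero-flux Neumann at x = 0
  for (int i = 0; i < N; ++i) {
    const double n_i = y[2 * i], m_i = y[2 * i + 1];
    double flux_right = 0.0;
    if (i < N - 1) {
      const double n_r = y[2 * (i + 1)], m_r = y[2 * (i + 1) + 1];
      flux_right = -Dface[i] * (n_r - n_i) / dx[i];
      if (tmask[i] > 0.0) {
        const double nbar = 0.5 * (n_i + n_r), mbar = 0.5 * (m_i + m_r);
        const double v = va * (1.0 + delta * nbar) * (1.0 - eps * mbar) - vr;
        flux_right += (1.0 - f) * v * (v > 0.0 ? n_i : n_r);
      }
    }
    const double G = imask[i] * (beta * m_i - gamma * n_i * (n_i + m_i));
    dy[2 * i] = -(flux_right - flux_left) / w[i] + G;
    dy[2 * i + 1] = -G;
    flux_left = flux_right;
  }
  return dy;
}
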
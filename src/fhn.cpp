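#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the networked FitzHugh-Nagumo model:
//   tau_x dx_i = gamma x_i - x_i^3/3 - y_i + (k/<d>) sum_j A_ij (x_j - x_i),
//   tau_y dy_i = x_i - beta y_i + a,
// with additive Gaussian noise on x only (the y equation is noise-free).
// `noise_step` is the pre-computed per-Euler-step noise amplitude; the R
// wrapper owns the choice of discretization. The inner loop runs over an
// edge list for speed; x is sampled every `sample_every` steps.
//
// k_norm is the pre-normalized coupling k/<d>.

// [[Rcpp::export]]
List fhn_integrate_cpp(IntegerMatrix A, NumericVector x0, NumericVector y0,
                       double gamma, double beta, double a,
                       double tau_x, double tau_y,
                       double k_norm, double noise_step, double dt,
                       int n_steps, int sample_every) {
  const int n = A.nrow();
  if (x0.size() != n || y0.size() != n)
    stop("initial conditions do not match graph size");
  // adjacency -> flat neighbour lists
  std::vector<int> nb_start(n + 1, 0);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0) nb.push_back(j);
    nb_start[i + 1] = (int)nb.size();
  }
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> xn(n), deg(n);
  const int n_samples = n_steps / sample_every + 1;
  NumericMatrix xs(n, n_samples), ys(n, n_samples);
  for (int i = 0; i < n; ++i) { xs(i, 0) = x[i]; ys(i, 0) = y[i]; }
  const double cx = dt / tau_x, cy = dt / tau_y;
  int col = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double coup = 0.0;
      for (int e = nb_start[i]; e < nb_start[i + 1]; ++e)
        coup += x[nb[e]] - x[i];
      double dx = gamma * x[i] - x[i] * x[i] * x[i] / 3.0 - y[i] + k_norm * coup;
      xn[i] = x[i] + cx * dx;
      if (noise_step > 0) xn[i] += noise_step * norm_rand();
      y[i] += cy * (x[i] - beta * y[i] + a);
    }
    for (int i = 0; i < n; ++i) {
      if (!R_finite(xn[i]) || std::fabs(xn[i]) > 1e6)
        stop("FitzHugh-Nagumo integration blew up at step %d (node %d)",
             step, i + 1);
      x[i] = xn[i];
    }
    if (step % sample_every == 0) {
      for (int i = 0; i < n; ++i) { xs(i, col) = x[i]; ys(i, col) = y[i]; }
      ++col;
    }
  }
  return List::create(_["x"] = xs, _["y"] = ys);
}
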
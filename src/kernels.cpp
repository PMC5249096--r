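#include <Rcpp.h>
using namespace Rcpp;

// Empirical MSD and fourth displacement moment for one 2-D trajectory.
// Column 1: <r^2(n)>, column 2: <r^4(n)>, column 3: number of averaged pairs.
// [[Rcpp::export]]
NumericMatrix msd_moments_cpp(NumericVector x, NumericVector y, int max_lag) {
  int N = x.size();
  if (max_lag < 1 || max_lag > N - 1)
    stop("max_lag must lie in [1, N - 1]");
  NumericMatrix out(max_lag, 3);
  for (int n = 1; n <= max_lag; ++n) {
    double s2 = 0.0, s4 = 0.0;
    int m = N - n;
    for (int i = 0; i < m; ++i) {
      double dx = x[i + n] - x[i];
      double dy = y[i + n] - y[i];
      double r2 = dx * dx + dy * dy;
      s2 += r2;
      s4 += r2 * r2;
    }
    out(n - 1, 0) = s2 / m;
    out(n - 1, 1) = s4 / m;
    out(n - 1, 2) = m;
  }
  return out;
}

// Confined random walk inside a circular boundary centred at the origin.
// Each recorded step is composed of n_sub sub-steps; a proposed sub-step is
// kept only when the new position stays strictly inside the radius, otherwise
// the position is left unchanged (rejection at the boundary). four_D_dtsub is
// 4*D*dt_sub, the squared Rayleigh scale of one sub-step.
// [[Rcpp::export]]
NumericMatrix cd_walk_cpp(int n_steps, int n_sub, double four_D_dtsub,
                          double radius) {
  NumericMatrix pos(n_steps + 1, 2);
  double cx = 0.0, cy = 0.0;
  double r2max = radius * radius;
  for (int s = 1; s <= n_steps; ++s) {
    for (int k = 0; k < n_sub; ++k) {
      double u = std::sqrt(-four_D_dtsub * std::log(R::runif(0.0, 1.0)));
      double th = R::runif(0.0, 2.0 * M_PI);
      double nx = cx + u * std::cos(th);
      double ny = cy + u * std::sin(th);
      if (nx * nx + ny * ny < r2max) {
        cx = nx;
        cy = ny;
      }
    }
    pos(s, 0) = cx;
    pos(s, 1) = cy;
  }
  return pos;
}
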
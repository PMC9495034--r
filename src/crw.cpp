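#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time correlated random walk with state-dependent speed and turning
// concentration, optional heading bias toward a water point, and reflection
// at a rectangular fence. Uses R's RNG so results are reproducible under
// set.seed(). Positions are recorded at every step; row 1 is the start.
//
// state:    n_steps x n_animals, 1 = resting, 2 = grazing, 3 = walking
// attract:  per-step mixing weight in [0,1] toward the water bearing
// cohesion: per-state mixing weight toward the herd centroid (cattle keep
//           closer together while resting than while grazing)
// [[Rcpp::export]]
List crw_paths(IntegerMatrix state, NumericVector speed, NumericVector turn_sd,
               double speed_sdlog, NumericVector attract,
               NumericVector cohesion,
               double water_x, double water_y,
               double width, double height,
               NumericVector x0, NumericVector y0, double step_min) {
  int n_steps = state.nrow(), n_a = state.ncol();
  NumericMatrix x(n_steps, n_a), y(n_steps, n_a);
  std::vector<double> heading(n_a);
  for (int a = 0; a < n_a; ++a) {
    x(0, a) = x0[a];
    y(0, a) = y0[a];
    heading[a] = R::runif(0, 2 * M_PI);
  }
  for (int t = 1; t < n_steps; ++t) {
    double w = attract[t];
    double cx = 0, cy = 0;
    for (int a = 0; a < n_a; ++a) { cx += x(t - 1, a); cy += y(t - 1, a); }
    cx /= n_a; cy /= n_a;
    for (int a = 0; a < n_a; ++a) {
      int s = state(t, a) - 1;
      double h = heading[a] + R::rnorm(0, turn_sd[s]);
      if (w > 0) {
        double b = atan2(water_y - y(t - 1, a), water_x - x(t - 1, a));
        h = atan2((1 - w) * sin(h) + w * sin(b),
                  (1 - w) * cos(h) + w * cos(b));
      }
      double ch = cohesion[s];
      if (ch > 0 && n_a > 1) {
        double b = atan2(cy - y(t - 1, a), cx - x(t - 1, a));
        h = atan2((1 - ch) * sin(h) + ch * sin(b),
                  (1 - ch) * cos(h) + ch * cos(b));
      }
      double len = speed[s] * step_min;
      if (len > 0 && speed_sdlog > 0) len *= exp(R::rnorm(0, speed_sdlog));
      double nx = x(t - 1, a) + len * cos(h);
      double ny = y(t - 1, a) + len * sin(h);
      for (int k = 0; k < 8 && (nx < 0 || nx > width); ++k)
        nx = nx < 0 ? -nx : 2 * width - nx;
      for (int k = 0; k < 8 && (ny < 0 || ny > height); ++k)
        ny = ny < 0 ? -ny : 2 * height - ny;
      x(t, a) = nx;
      y(t, a) = ny;
      heading[a] = h;
    }
  }
  return List::create(_["x"] = x, _["y"] = y);
}
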
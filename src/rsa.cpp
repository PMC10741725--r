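#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Random sequential adsorption of unit-diameter hard disks on an L x L
// periodic square. Placement attempts are uniform on the torus; an attempt
// is accepted iff the candidate center is at least one diameter (minimum
// image) from every accepted center. Draws come from R's RNG stream so a
// prior set.seed() makes the run fully reproducible.
//
// use_grid selects the cell-list acceleration (cell edge = L / floor(L)
// >= 1 diameter, so a 3x3 neighborhood bounds all possible overlaps); the
// brute-force path checks every accepted disk. Both consume the RNG stream
// identically, so they must produce bit-identical configurations.
// [[Rcpp::export(name = ".rsa_fill_cpp")]]
List rsa_fill_cpp(double box_length, double tau_max, bool use_grid,
                  int checkpoints_per_decade) {
  const double L = box_length;
  const double half = L / 2.0;
  long long max_attempts = (long long)std::llround(tau_max * L * L);
  if (max_attempts < 1) stop("attempt budget is empty");

  // log-spaced attempt checkpoints for the coverage history
  std::vector<long long> checks;
  {
    double decades = std::log10((double)max_attempts);
    int ncheck = std::max(2, (int)std::ceil(checkpoints_per_decade *
                                            std::max(1.0, decades)));
    long long prev = 0;
    for (int i = 1; i <= ncheck; ++i) {
      long long a =
          (long long)std::llround(std::pow(10.0, decades * i / ncheck));
      if (a > prev && a <= max_attempts) {
        checks.push_back(a);
        prev = a;
      }
    }
    if (checks.empty() || checks.back() != max_attempts)
      checks.push_back(max_attempts);
  }

  int nc = (int)std::floor(L);
  bool grid_ok = use_grid && nc >= 3;
  double cell = grid_ok ? L / nc : L;
  std::vector<std::vector<int> > grid;
  if (grid_ok) grid.resize((size_t)nc * (size_t)nc);

  std::vector<double> xs, ys;
  std::vector<double> hist_tau, hist_theta;
  hist_tau.reserve(checks.size());
  hist_theta.reserve(checks.size());
  size_t ci = 0;

  for (long long att = 1; att <= max_attempts; ++att) {
    double x = unif_rand() * L;
    double y = unif_rand() * L;
    bool ok = true;
    if (grid_ok) {
      int gx = (int)(x / cell);
      if (gx >= nc) gx = nc - 1;
      int gy = (int)(y / cell);
      if (gy >= nc) gy = nc - 1;
      for (int dx = -1; dx <= 1 && ok; ++dx) {
        int ix = (gx + dx + nc) % nc;
        for (int dy = -1; dy <= 1 && ok; ++dy) {
          int iy = (gy + dy + nc) % nc;
          const std::vector<int>& cl = grid[(size_t)ix * nc + iy];
          for (size_t k = 0; k < cl.size(); ++k) {
            double ddx = std::fabs(x - xs[cl[k]]);
            if (ddx > half) ddx = L - ddx;
            double ddy = std::fabs(y - ys[cl[k]]);
            if (ddy > half) ddy = L - ddy;
            if (ddx * ddx + ddy * ddy < 1.0) {
              ok = false;
              break;
            }
          }
        }
      }
    } else {
      for (size_t k = 0; k < xs.size(); ++k) {
        double ddx = std::fabs(x - xs[k]);
        if (ddx > half) ddx = L - ddx;
        double ddy = std::fabs(y - ys[k]);
        if (ddy > half) ddy = L - ddy;
        if (ddx * ddx + ddy * ddy < 1.0) {
          ok = false;
          break;
        }
      }
    }
    if (ok) {
      xs.push_back(x);
      ys.push_back(y);
      if (grid_ok) {
        int gx = (int)(x / cell);
        if (gx >= nc) gx = nc - 1;
        int gy = (int)(y / cell);
        if (gy >= nc) gy = nc - 1;
        grid[(size_t)gx * nc + gy].push_back((int)xs.size() - 1);
      }
    }
    while (ci < checks.size() && att == checks[ci]) {
      hist_tau.push_back((double)att / (L * L));
      hist_theta.push_back((double)xs.size() * M_PI / (4.0 * L * L));
      ++ci;
    }
    if ((att & 0x3FFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["x"] = NumericVector(xs.begin(), xs.end()),
      _["y"] = NumericVector(ys.begin(), ys.end()),
      _["tau"] = NumericVector(hist_tau.begin(), hist_tau.end()),
      _["theta"] = NumericVector(hist_theta.begin(), hist_theta.end()),
      _["attempts"] = (double)max_attempts);
}
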
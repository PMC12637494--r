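#include <Rcpp.h>
using namespace Rcpp;

// squared-penalty loss of a beads-on-string configuration:
//   chain:      (d - (ri+rj))^2 over consecutive beads of a chromosome
//   constraint: max(0, d - (ra+rb))^2 (attraction toward touching)
//   overlap:    max(0, (ri+rj) - d)^2 over non-adjacent pairs
//   nucleus:    max(0, |c| + r - R)^2
static inline double pair_dist(const NumericMatrix& x, int i, int j) {
  double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1),
         dz = x(i, 2) - x(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static double bead_energy(const NumericMatrix& x, const NumericVector& r,
                          const IntegerVector& chain, const IntegerMatrix& con,
                          double R, int b) {
  const int n = x.nrow();
  double e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == b) continue;
    double d = pair_dist(x, b, j);
    double touch = r[b] + r[j];
    bool adjacent = (chain[b] == chain[j]) && (std::abs(j - b) == 1);
    if (adjacent) {
      double v = d - touch;
      e += v * v;
    } else {
      double v = touch - d;
      if (v > 0) e += v * v;
    }
  }
  for (int k = 0; k < con.nrow(); ++k) {
    int a = con(k, 0), c = con(k, 1);
    if (a != b && c != b) continue;
    double d = pair_dist(x, a, c);
    double v = d - (r[a] + r[c]);
    if (v > 0) e += v * v;
  }
  double norm = std::sqrt(x(b, 0) * x(b, 0) + x(b, 1) * x(b, 1) +
                          x(b, 2) * x(b, 2));
  double v = norm + r[b] - R;
  if (v > 0) e += v * v;
  return e;
}

// [[Rcpp::export]]
double total_loss_cpp(NumericMatrix x, NumericVector r, IntegerVector chain,
                      IntegerMatrix con, double R) {
  const int n = x.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = pair_dist(x, i, j);
      double touch = r[i] + r[j];
      bool adjacent = (chain[i] == chain[j]) && (j - i == 1);
      if (adjacent) {
        double v = d - touch;
        e += v * v;
      } else {
        double v = touch - d;
        if (v > 0) e += v * v;
      }
    }
    double norm = std::sqrt(x(i, 0) * x(i, 0) + x(i, 1) * x(i, 1) +
                            x(i, 2) * x(i, 2));
    double v = norm + r[i] - R;
    if (v > 0) e += v * v;
  }
  for (int k = 0; k < con.nrow(); ++k) {
    int a = con(k, 0), c = con(k, 1);
    double d = pair_dist(x, a, c);
    double v = d - (r[a] + r[c]);
    if (v > 0) e += v * v;
  }
  return e;
}

// Metropolis optimization with single-bead Gaussian displacement proposals
// and geometric cooling; returns the best-so-far configuration and a
// non-increasing best-loss trace sampled every `trace_every` steps.
// [[Rcpp::export]]
List mc_optimize_cpp(NumericMatrix coords, NumericVector r,
                     IntegerVector chain, IntegerMatrix con, double R,
                     int steps, double t0, double cooling, double sigma,
                     int trace_every) {
  RNGScope scope;
  NumericMatrix x = clone(coords);
  const int n = x.nrow();
  double loss = total_loss_cpp(x, r, chain, con, R);
  NumericMatrix best = clone(x);
  double best_loss = loss;
  std::vector<double> trace;
  trace.push_back(best_loss);
  double temp = t0;
  int accepted = 0;

  for (int s = 0; s < steps; ++s) {
    int b = (int)std::floor(unif_rand() * n);
    if (b >= n) b = n - 1;
    double e_old = bead_energy(x, r, chain, con, R, b);
    double ox = x(b, 0), oy = x(b, 1), oz = x(b, 2);
    x(b, 0) = ox + norm_rand() * sigma;
    x(b, 1) = oy + norm_rand() * sigma;
    x(b, 2) = oz + norm_rand() * sigma;
    // hard nuclear envelope: moves leaving the sphere are rejected outright,
    // so containment of the initial configuration is invariant
    double prop_norm = std::sqrt(x(b, 0) * x(b, 0) + x(b, 1) * x(b, 1) +
                                 x(b, 2) * x(b, 2));
    if (prop_norm + r[b] > R) {
      x(b, 0) = ox; x(b, 1) = oy; x(b, 2) = oz;
      temp *= cooling;
      if ((s + 1) % trace_every == 0) trace.push_back(best_loss);
      continue;
    }
    double e_new = bead_energy(x, r, chain, con, R, b);
    double delta = e_new - e_old;
    bool accept = delta <= 0 ||
      (temp > 0 && unif_rand() < std::exp(-delta / temp));
    if (accept) {
      loss += delta;
      ++accepted;
      if (loss < best_loss) {
        best_loss = loss;
        best = clone(x);
      }
    } else {
      x(b, 0) = ox; x(b, 1) = oy; x(b, 2) = oz;
    }
    temp *= cooling;
    if ((s + 1) % trace_every == 0) trace.push_back(best_loss);
  }
  // guard against drift in the incrementally updated loss
  best_loss = total_loss_cpp(best, r, chain, con, R);
  return List::create(_["coords"] = best, _["loss"] = best_loss,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["acceptance"] = (double)accepted / steps);
}
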
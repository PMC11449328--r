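#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EARTH_R = 6371000.0;

// great-circle distance in meters between two WGS84 points (degrees)
static inline double hav(double lat1, double lon1, double lat2, double lon2) {
  const double d2r = M_PI / 180.0;
  double dlat = (lat2 - lat1) * d2r / 2.0;
  double dlon = (lon2 - lon1) * d2r / 2.0;
  double a = std::sin(dlat) * std::sin(dlat) +
    std::cos(lat1 * d2r) * std::cos(lat2 * d2r) * std::sin(dlon) * std::sin(dlon);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R * std::asin(std::sqrt(a));
}

// DTW with the symmetric step pattern (diagonal weight 2, horizontal/vertical
// weight 1, origin cell counted once), no window. a, b: n x 2 / m x 2
// matrices of (lat, lon) in degrees.
// Returns the total weighted path cost; divide by (n + m) for the normalized
// cost. Only two DP rows are kept so memory stays O(min side).
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  if (n < 1 || m < 1) stop("empty sequence");
  std::vector<double> prev(m), cur(m);
  const double INF = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double alat = a(i, 0), alon = a(i, 1);
    for (int j = 0; j < m; ++j) {
      double d = hav(alat, alon, b(j, 0), b(j, 1));
      double best;
      if (i == 0 && j == 0) {
        best = d;
      } else {
        double diag = (i > 0 && j > 0) ? prev[j - 1] + 2.0 * d : INF;
        double up   = (i > 0) ? prev[j] + d : INF;
        double left = (j > 0) ? cur[j - 1] + d : INF;
        best = std::min(diag, std::min(up, left));
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Same DP for scalar series under the absolute-difference local metric;
// used for small worked examples and oracle tests.
// [[Rcpp::export(name = ".dtw_cost_abs_cpp")]]
double dtw_cost_abs_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  if (n < 1 || m < 1) stop("empty sequence");
  std::vector<double> prev(m), cur(m);
  const double INF = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = std::fabs(a[i] - b[j]);
      double best;
      if (i == 0 && j == 0) {
        best = d;
      } else {
        double diag = (i > 0 && j > 0) ? prev[j - 1] + 2.0 * d : INF;
        double up   = (i > 0) ? prev[j] + d : INF;
        double left = (j > 0) ? cur[j - 1] + d : INF;
        best = std::min(diag, std::min(up, left));
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
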
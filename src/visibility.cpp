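#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Natural visibility graph edges by a running-maximum-slope sweep.
//
// Edge (i, j), i < j, exists iff every intermediate sample lies strictly
// below the chord from (i, x_i) to (j, x_j), i.e. iff the chord slope
// (x_j - x_i) / (j - i) strictly exceeds the slope from i to every k with
// i < k < j.  Scanning j upward from each i while tracking the maximum
// slope seen so far decides each pair in O(1), so the whole sweep is O(T^2)
// and agrees exactly with the literal criterion (equality blocks).
//
// Time is the 0-based frame index.  Weights, when requested, are the
// reciprocal Euclidean distance 1 / sqrt((j - i)^2 + (x_j - x_i)^2).
// [[Rcpp::export]]
List vg_edges_cpp(NumericVector x, bool weighted) {
  int n = x.size();
  std::vector<int> ei, ej;
  std::vector<double> w;
  ei.reserve(4 * n);
  ej.reserve(4 * n);
  if (weighted) w.reserve(4 * n);
  for (int i = 0; i < n - 1; ++i) {
    double maxslope = R_NegInf;
    for (int j = i + 1; j < n; ++j) {
      double s = (x[j] - x[i]) / static_cast<double>(j - i);
      if (s > maxslope) {
        ei.push_back(i);
        ej.push_back(j);
        if (weighted) {
          double dt = static_cast<double>(j - i);
          double dx = x[j] - x[i];
          w.push_back(1.0 / std::sqrt(dt * dt + dx * dx));
        }
        maxslope = s;
      }
    }
  }
  List out = List::create(_["i"] = wrap(ei), _["j"] = wrap(ej));
  if (weighted) out["w"] = wrap(w);
  return out;
}

// Binary visibility degree sequence without materialising the edge list;
// used when only degree fluctuations are needed (degree synchrony).
// [[Rcpp::export]]
IntegerVector vg_degree_cpp(NumericVector x) {
  int n = x.size();
  IntegerVector deg(n);
  for (int i = 0; i < n - 1; ++i) {
    double maxslope = R_NegInf;
    for (int j = i + 1; j < n; ++j) {
      double s = (x[j] - x[i]) / static_cast<double>(j - i);
      if (s > maxslope) {
        deg[i] += 1;
        deg[j] += 1;
        maxslope = s;
      }
    }
  }
  return deg;
}
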
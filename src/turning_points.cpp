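#include <Rcpp.h>
using namespace Rcpp;

// Alternating turning points (zigzag) of a sampled signal with a reversal
// threshold. A maximum is reported at the *last* sample attaining the local
// top (the departure point of a plateau) and a minimum at the *first* sample
// attaining the local bottom (the arrival point), so that the time between a
// maximum and the following minimum measures the full duration of a fall.
// Reversals smaller than `prominence` are ignored.
//
// Returns a list with 1-based sample indices and types (+1 max, -1 min).
// [[Rcpp::export(name = ".turning_points_cpp")]]
List turning_points_cpp(NumericVector x, double prominence) {
  int n = x.size();
  std::vector<int> idx;
  std::vector<int> typ;
  if (n < 2) return List::create(_["idx"] = idx, _["type"] = typ);

  int dir = 0;
  double maxv = x[0], minv = x[0];
  int maxi = 0, mini = 0;

  for (int i = 1; i < n; ++i) {
    double v = x[i];
    if (dir == 0) {
      if (v >= maxv) { maxv = v; maxi = i; }
      if (v < minv)  { minv = v; mini = i; }
      if (maxv - minv >= prominence) {
        if (mini > maxi) {            // fell first: leading extremum is a max
          idx.push_back(maxi + 1); typ.push_back(1);
          dir = -1;
        } else {                      // rose first: leading extremum is a min
          idx.push_back(mini + 1); typ.push_back(-1);
          dir = 1;
        }
      }
    } else if (dir == 1) {            // rising: track the running maximum
      if (v >= maxv) { maxv = v; maxi = i; }
      else if (maxv - v >= prominence) {
        idx.push_back(maxi + 1); typ.push_back(1);
        dir = -1; minv = v; mini = i;
      }
    } else {                          // falling: track the running minimum
      if (v < minv) { minv = v; mini = i; }
      else if (v - minv >= prominence) {
        idx.push_back(mini + 1); typ.push_back(-1);
        dir = 1; maxv = v; maxi = i;
      }
    }
  }
  if (dir == 1)  { idx.push_back(maxi + 1); typ.push_back(1); }
  if (dir == -1) { idx.push_back(mini + 1); typ.push_back(-1); }

  return List::create(_["idx"] = idx, _["type"] = typ);
}
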
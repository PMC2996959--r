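#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// Pair energy under the simplified per-pair model; positive return value
// means "not pairable".
static inline double pair_energy(char a, char b,
                                 double egc, double eau, double egu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return egc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return eau;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return egu;
  return 1.0;
}

// Minimum-energy nested secondary structure under a per-pair energy model
// (Nussinov-style dynamic program). min_loop is the minimum number of
// unpaired nucleotides in a hairpin loop. Traceback is deterministic:
// at each subproblem, pairing position i with the smallest admissible k
// is preferred over leaving i unpaired.
// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, double egc, double eau, double egu,
                       int min_loop) {
  const int n = (int) seq.size();
  const double TOL = 1e-9;
  std::vector<double> M((size_t) n * (n > 0 ? n : 1), 0.0);
  auto idx = [n](int i, int j) { return (size_t) i * n + j; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      double best = M[idx(i + 1, j)];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        const double e = pair_energy(seq[i], seq[k], egc, eau, egu);
        if (e < 0.0) {
          const double inner = (k - 1 >= i + 1) ? M[idx(i + 1, k - 1)] : 0.0;
          const double right = (k + 1 <= j) ? M[idx(k + 1, j)] : 0.0;
          const double v = e + inner + right;
          if (v < best) best = v;
        }
      }
      M[idx(i, j)] = best;
    }
  }

  std::string db(n, '.');
  std::vector<std::pair<int, int> > todo;
  if (n > 1) todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first;
    int j = todo.back().second;
    todo.pop_back();
    while (i < j) {
      const double m = M[idx(i, j)];
      if (std::fabs(m) < TOL) break;  // nothing pairs in this region
      bool paired = false;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        const double e = pair_energy(seq[i], seq[k], egc, eau, egu);
        if (e < 0.0) {
          const double inner = (k - 1 >= i + 1) ? M[idx(i + 1, k - 1)] : 0.0;
          const double right = (k + 1 <= j) ? M[idx(k + 1, j)] : 0.0;
          if (std::fabs(e + inner + right - m) < TOL) {
            db[i] = '(';
            db[k] = ')';
            if (k + 1 <= j) todo.push_back(std::make_pair(k + 1, j));
            j = k - 1;
            i = i + 1;
            paired = true;
            break;
          }
        }
      }
      if (!paired) i = i + 1;  // m == M[i+1][j]
    }
  }

  const double energy = (n > 1) ? M[idx(0, n - 1)] : 0.0;
  return List::create(_["dotbracket"] = db, _["energy"] = energy);
}
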
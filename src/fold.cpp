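// Single-hairpin minimum-free-energy folding.
//
// The model is deliberately restricted to structures with exactly one
// terminal loop (a stem-loop with interior loops and bulges, no multiloop),
// which is the only structure class a miRNA precursor is validated
// against.  Energies are nearest-neighbor stacking terms for Watson-Crick
// and GU wobble pairs with loop penalties linear in loop size; absolute
// values are approximate but ordering and thresholded behaviour at the
// -18 kcal/mol hairpin criterion are what downstream code relies on.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// pair codes: 0 AU, 1 UA, 2 GC, 3 CG, 4 GU, 5 UG, -1 unpairable
int pair_code(char a, char b) {
  if (a == 'A' && b == 'T') return 0;
  if (a == 'T' && b == 'A') return 1;
  if (a == 'G' && b == 'C') return 2;
  if (a == 'C' && b == 'G') return 3;
  if (a == 'G' && b == 'T') return 4;
  if (a == 'T' && b == 'G') return 5;
  return -1;
}

// Stacking free energies (kcal/mol), outer pair x inner pair, Turner-like.
// Rows/cols ordered AU, UA, GC, CG, GU, UG.
const double STACK[6][6] = {
  // inner:  AU     UA     GC     CG     GU     UG
  /*AU*/ { -0.9,  -1.1,  -2.1,  -2.2,  -0.6,  -1.4 },
  /*UA*/ { -1.3,  -0.9,  -2.4,  -2.1,  -1.0,  -1.3 },
  /*GC*/ { -2.4,  -2.1,  -3.3,  -2.4,  -1.5,  -2.5 },
  /*CG*/ { -2.1,  -2.2,  -3.4,  -3.3,  -1.4,  -2.1 },
  /*GU*/ { -1.3,  -1.4,  -2.5,  -2.1,  -0.5,  -1.3 },
  /*UG*/ { -1.0,  -0.6,  -1.5,  -1.4,  -0.3,  -0.5 }
};

double hairpin_penalty(int L) {          // terminal loop of L unpaired bases
  return 5.0 + 0.3 * (L - 3);
}

double interior_penalty(int l1, int l2) { // interior loop / bulge
  return 2.0 + 0.5 * (l1 + l2);
}

const int MAX_BULGE = 15;   // per-side interior loop size cap
const int MIN_LOOP  = 3;    // steric minimum terminal loop

} // namespace

// [[Rcpp::export(name = ".fold_hairpin_cpp")]]
List fold_hairpin_cpp(std::string seq) {
  const int n = (int) seq.size();
  // V[i][j]: best energy of a stem-loop closed by pair (i, j); INF if none.
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  // traceback: inner pair (k, l) or (-1, -1) for a terminal hairpin loop
  std::vector<std::vector<int> > TK(n, std::vector<int>(n, -2));
  std::vector<std::vector<int> > TL(n, std::vector<int>(n, -2));

  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pc = pair_code(seq[i], seq[j]);
      if (pc < 0) continue;
      double best = hairpin_penalty(j - i - 1);
      int bk = -1, bl = -1;
      int kmax = std::min(j - 1, i + 1 + MAX_BULGE);
      for (int k = i + 1; k <= kmax; ++k) {
        int lmin = std::max(k + 1, j - 1 - MAX_BULGE);
        for (int l = j - 1; l >= lmin; --l) {
          if (V[k][l] == INF) continue;
          int qc = pair_code(seq[k], seq[l]);
          double e;
          if (k == i + 1 && l == j - 1) e = STACK[pc][qc];
          else e = interior_penalty(k - i - 1, j - l - 1);
          if (V[k][l] + e < best) { best = V[k][l] + e; bk = k; bl = l; }
        }
      }
      V[i][j] = best; TK[i][j] = bk; TL[i][j] = bl;
    }
  }

  double mfe = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (V[i][j] < mfe) { mfe = V[i][j]; bi = i; bj = j; }

  std::string db(n, '.');
  int stem_pairs = 0, loop_len = n;
  if (bi >= 0) {
    int i = bi, j = bj;
    while (true) {
      db[i] = '('; db[j] = ')'; ++stem_pairs;
      int k = TK[i][j], l = TL[i][j];
      if (k < 0) { loop_len = j - i - 1; break; }
      i = k; j = l;
    }
  }
  if (bi < 0) { mfe = 0.0; loop_len = NA_INTEGER; }

  return List::create(
    _["structure"]  = db,
    _["mfe"]        = mfe,
    _["stem_pairs"] = stem_pairs,
    _["loop_length"] = (bi < 0) ? IntegerVector::create(NA_INTEGER)[0] : loop_len
  );
}
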
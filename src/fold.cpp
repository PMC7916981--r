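#include <Rcpp.h>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under a pure
// nearest-neighbor stacking model: the energy of a structure is the sum of
// stacking terms over directly adjacent nested pairs (i,j),(i+1,j-1); lone
// pairs and loops contribute nothing. Nested structures only (no
// pseudoknots), minimum hairpin loop of 3 unpaired nucleotides.
//
// Recurrences (energies; INF where undefined):
//   V(i,j)  : best energy on [i,j] given i pairs j
//           = min( 0,                                  // hairpin
//                  stack(i,j) + V(i+1,j-1),            // stacked pair
//                  Wx(i+1,j-1) )                       // any inner structure
//                                                      // not pairing i+1:j-1
//   W(i,j)  : best energy on [i,j]
//           = min( W(i+1,j), min_k V(i,k) + W(k+1,j) )
//   Wx(i,j) : as W but position i may not pair with j
// Ties are broken toward fewer pairs (unpaired branch first), then the
// smallest pairing partner, so the traceback is deterministic.

static const double INF = 1e9;
static const double EPS = 1e-9;

// base codes: 0=A 1=C 2=G 3=U; pair order CG GC GU UG AU UA
static inline int pairIdx(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

struct FoldDP {
  int n;
  const std::vector<int>& s;
  const NumericMatrix& stk;
  std::vector<double> W, Wx, V;

  FoldDP(const std::vector<int>& seq, const NumericMatrix& stack)
    : n((int)seq.size()), s(seq), stk(stack),
      W(n * n, 0.0), Wx(n * n, 0.0), V(n * n, INF) {}

  inline int id(int i, int j) const { return i * n + j; }
  inline bool pairable(int i, int j) const {
    return j - i >= 4 && pairIdx(s[i], s[j]) >= 0;
  }
  inline double stackE(int i, int j) const {
    // stack of pair (i,j) over inner pair (i+1,j-1)
    int p1 = pairIdx(s[i], s[j]);
    int p2 = pairIdx(s[j - 1], s[i + 1]);
    return stk(p1, p2);
  }

  void run() {
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        if (pairable(i, j)) {
          double best = 0.0;  // hairpin closure
          if (pairable(i + 1, j - 1)) {
            double cand = stackE(i, j) + V[id(i + 1, j - 1)];
            if (cand < best) best = cand;
          }
          if (j - 1 > i + 1) {
            double cand = Wx[id(i + 1, j - 1)];
            if (cand < best) best = cand;
          }
          V[id(i, j)] = best;
        }
        // W and Wx
        double w = W[id(i + 1, j)];
        double wx = w;
        for (int k = i + 4; k <= j; ++k) {
          if (!pairable(i, k)) continue;
          double tail = (k + 1 <= j) ? W[id(k + 1, j)] : 0.0;
          double cand = V[id(i, k)] + tail;
          if (cand < w) w = cand;
          if (k < j && cand < wx) wx = cand;
        }
        W[id(i, j)] = w;
        Wx[id(i, j)] = wx;
      }
    }
  }

  void tbV(int i, int j, std::vector<int>& pt) {
    pt[i] = j; pt[j] = i;
    double v = V[id(i, j)];
    if (v >= -EPS) return;  // hairpin preferred on ties
    if (pairable(i + 1, j - 1)) {
      double cand = stackE(i, j) + V[id(i + 1, j - 1)];
      if (std::abs(cand - v) < EPS) { tbV(i + 1, j - 1, pt); return; }
    }
    tbWgen(i + 1, j - 1, pt, true);
  }

  // traceback for W (excl=false) or Wx (excl=true) on [i,j]
  void tbWgen(int i, int j, std::vector<int>& pt, bool excl) {
    while (i < j) {
      double target = excl ? Wx[id(i, j)] : W[id(i, j)];
      if (target >= -EPS) return;  // nothing stabilizing: leave unpaired
      if (std::abs(W[id(i + 1, j)] - target) < EPS) { ++i; excl = false; continue; }
      int kmax = excl ? j - 1 : j;
      bool found = false;
      for (int k = i + 4; k <= kmax; ++k) {
        if (!pairable(i, k)) continue;
        double tail = (k + 1 <= j) ? W[id(k + 1, j)] : 0.0;
        if (std::abs(V[id(i, k)] + tail - target) < EPS) {
          tbV(i, k, pt);
          i = k + 1; excl = false; found = true; break;
        }
      }
      if (!found) return;  // defensive; should not happen
    }
  }
};

// [[Rcpp::export(name = ".foldStackDP")]]
List foldStackDP(IntegerVector seqCode, NumericMatrix stack) {
  int n = seqCode.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = seqCode[i];
  std::vector<int> pt(n, -1);
  double energy = 0.0;
  if (n >= 5) {
    FoldDP dp(s, stack);
    dp.run();
    energy = dp.W[dp.id(0, n - 1)];
    if (energy < -EPS) dp.tbWgen(0, n - 1, pt, false);
    else energy = 0.0;
  }
  IntegerVector partner(n);
  for (int i = 0; i < n; ++i) partner[i] = pt[i];  // 0-based, -1 unpaired
  return List::create(_["energy"] = energy, _["partner"] = partner);
}
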
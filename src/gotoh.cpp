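// Global nucleotide alignment with affine gaps (Gotoh three-state DP).
// A gap of length k costs gap_open + k * gap_extend. N scores as a
// mismatch against everything, including N. Tie-breaking is deterministic:
// at equal score the diagonal (match/mismatch) state is preferred over
// gap states, and a-gaining gaps over b-gaining ones.
//
// An optional band limits |i - j - (na - nb)/2|-style deviation from the
// main diagonal; band < 0 computes the full matrix.

#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 int match, int mismatch, int gap_open, int gap_extend,
                 int band = -1) {
  const int n = a.size(), m = b.size();
  const long long W = (long long)(m + 1);
  auto idx = [&](int i, int j) { return (long long)i * W + j; };

  std::vector<int> M((long long)(n + 1) * W, NEG),
                   X((long long)(n + 1) * W, NEG),
                   Y((long long)(n + 1) * W, NEG);
  // traceback: 2 bits per state, packed into one byte per cell
  // for M: 0=diag-from-M,1=diag-from-X,2=diag-from-Y
  // for X: 0=open-from-M,1=extend-from-X,2=open-from-Y
  // for Y: 0=open-from-M,1=open-from-X,2=extend-from-Y
  std::vector<unsigned char> TM((long long)(n + 1) * W),
                             TX((long long)(n + 1) * W),
                             TY((long long)(n + 1) * W);

  const int diag_off = n - m;  // keep the band around the global diagonal
  auto in_band = [&](int i, int j) {
    if (band < 0) return true;
    int d = i - j;  // deviation from square diagonal
    int lo = std::min(0, diag_off) - band, hi = std::max(0, diag_off) + band;
    return d >= lo && d <= hi;
  };

  M[idx(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    if (!in_band(i, 0)) continue;
    X[idx(i, 0)] = gap_open + i * gap_extend;
    TX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    if (!in_band(0, j)) continue;
    Y[idx(0, j)] = gap_open + j * gap_extend;
    TY[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (!in_band(i, j)) continue;
      long long c = idx(i, j), cd = idx(i - 1, j - 1),
                cu = idx(i - 1, j), cl = idx(i, j - 1);
      char ca = a[i - 1], cb = b[j - 1];
      int s = (ca == cb && ca != 'N') ? match : mismatch;
      // M: prefer M > X > Y on ties
      int bm = M[cd], st = 0;
      if (X[cd] > bm) { bm = X[cd]; st = 1; }
      if (Y[cd] > bm) { bm = Y[cd]; st = 2; }
      if (bm > NEG) { M[c] = bm + s; TM[c] = st; }
      // X: gap in b (consumes a)
      int xo = (M[cu] > NEG) ? M[cu] + gap_open + gap_extend : NEG;
      int xx = (X[cu] > NEG) ? X[cu] + gap_extend : NEG;
      int xy = (Y[cu] > NEG) ? Y[cu] + gap_open + gap_extend : NEG;
      int bx = xo; int sx = 0;
      if (xx > bx) { bx = xx; sx = 1; }
      if (xy > bx) { bx = xy; sx = 2; }
      if (bx > NEG) { X[c] = bx; TX[c] = sx; }
      // Y: gap in a (consumes b)
      int yo = (M[cl] > NEG) ? M[cl] + gap_open + gap_extend : NEG;
      int yx = (X[cl] > NEG) ? X[cl] + gap_open + gap_extend : NEG;
      int yy = (Y[cl] > NEG) ? Y[cl] + gap_extend : NEG;
      int by = yo; int sy = 0;
      if (yx > by) { by = yx; sy = 1; }
      if (yy > by) { by = yy; sy = 2; }
      if (by > NEG) { Y[c] = by; TY[c] = sy; }
    }
  }

  long long e = idx(n, m);
  int best = M[e]; int state = 0;
  if (X[e] > best) { best = X[e]; state = 1; }
  if (Y[e] > best) { best = Y[e]; state = 2; }
  if (best <= NEG)
    stop("banded alignment infeasible; widen the band");

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    long long c = idx(i, j);
    if (state == 0) {
      int prev = TM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = TX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = (prev == 1) ? 1 : (prev == 0 ? 0 : 2);
    } else {
      int prev = TY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = (prev == 2) ? 2 : (prev == 0 ? 0 : 1);
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = best);
}
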
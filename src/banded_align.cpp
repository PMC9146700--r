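#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <limits>

using namespace Rcpp;

// Banded global alignment with affine gaps (Gotoh, three states).
// A gap of length L scores gap_open + L * gap_ext (both negative).
// The band keeps j - i within [dlo - w, dhi + w] where dlo = min(0, m - n),
// dhi = max(0, m - n), so the (n, m) corner is always reachable.
//
// Scores are kept in two rolling rows; the traceback is stored densely over
// the band as one byte per cell (2 bits per state).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// traceback codes per state
// M:  0 = diag from M, 1 = diag from Ix, 2 = diag from Iy
// Ix (gap in b, consumes a/i): 0 = open from M, 1 = extend
// Iy (gap in a, consumes b/j): 0 = open from M, 1 = extend
// packed: M bits 0-1, Ix bit 2, Iy bit 3, plus "state of best" resolved at end

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_ext,
                      int band) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  const int dlo = std::min(0, m - n);
  const int dhi = std::max(0, m - n);
  const int lo_off = dlo - band;        // minimal j - i
  const int hi_off = dhi + band;        // maximal j - i
  const int W = hi_off - lo_off + 1;    // band width in cells

  // rolling rows, indexed by k = (j - i) - lo_off in [0, W)
  std::vector<double> Mprev(W, NEG_INF), Xprev(W, NEG_INF), Yprev(W, NEG_INF);
  std::vector<double> Mcur(W, NEG_INF), Xcur(W, NEG_INF), Ycur(W, NEG_INF);
  // dense traceback over the band
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);

  // row i = 0
  {
    int jmin = std::max(0, lo_off), jmax = std::min(m, hi_off);
    for (int j = jmin; j <= jmax; ++j) {
      int k = j - lo_off;
      if (j == 0) {
        Mprev[k] = 0.0;
      } else {
        Yprev[k] = gap_open + gap_ext * j;
        tb[(size_t)0 * W + k] |= (1u << 3); // Iy extend (chain back along row)
        if (j == jmin && j - 1 >= 0 && (j - 1) < lo_off) {
          // cannot happen: j == 0 handled above; guard kept for clarity
        }
      }
    }
    // mark the first Iy cell in row 0 as "open"
    if (lo_off <= 1 && 1 <= hi_off && m >= 1) {
      tb[(size_t)0 * W + (1 - lo_off)] &= ~(1u << 3); // open from M at j=1
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    int jmin = std::max(0, i + lo_off), jmax = std::min(m, i + hi_off);
    char ai = a[i - 1];
    unsigned char *tbrow = &tb[(size_t)i * W];
    for (int j = jmin; j <= jmax; ++j) {
      int k = j - lo_off - i; // local band index
      unsigned char code = 0;
      if (j == 0) {
        // leading gap in b
        double open_sc = (i == 1) ? (gap_open + gap_ext)
                                  : NEG_INF;
        double ext_sc = Xprev[k + 1] + gap_ext; // k+1: same j, previous i
        // note Xprev index: offset for row i-1 with same j is j - lo_off - (i-1) = k+1
        double xv;
        if (i == 1) { xv = gap_open + gap_ext; code |= 0u << 2; }
        else {
          xv = ext_sc; code |= 1u << 2;
          (void)open_sc;
        }
        Xcur[k] = xv;
        tbrow[k] = code;
        continue;
      }
      // M: diagonal from row i-1, col j-1 -> same band offset k
      double sub = (ai == b[j - 1]) ? match : mismatch;
      double dM = Mprev[k], dX = Xprev[k], dY = Yprev[k];
      double best = dM; unsigned char mcode = 0;
      if (dX > best) { best = dX; mcode = 1; }
      if (dY > best) { best = dY; mcode = 2; }
      if (best > NEG_INF) Mcur[k] = best + sub;
      code |= mcode;
      // Ix: from row i-1, col j -> band offset k+1
      if (k + 1 < W) {
        double mo = Mprev[k + 1] + gap_open + gap_ext;
        double xe = Xprev[k + 1] + gap_ext;
        if (xe > mo) { Xcur[k] = xe; code |= 1u << 2; }
        else { Xcur[k] = mo; }
      }
      // Iy: from row i, col j-1 -> band offset k-1
      if (k - 1 >= 0) {
        double mo = Mcur[k - 1] + gap_open + gap_ext;
        double ye = Ycur[k - 1] + gap_ext;
        if (ye > mo) { Ycur[k] = ye; code |= 1u << 3; }
        else { Ycur[k] = mo; }
      }
      tbrow[k] = code;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // final cell (n, m): band offset
  int kfin = m - lo_off - n;
  double sM = Mprev[kfin], sX = Xprev[kfin], sY = Yprev[kfin];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (score == NEG_INF)
    stop("banded alignment infeasible: band narrower than length difference");

  // traceback
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  bool edge_hit = false;
  while (i > 0 || j > 0) {
    int k = j - lo_off - i;
    if ((k == 0 || k == W - 1) && i > 0 && j > 0 && i < n)
      edge_hit = true;
    unsigned char code = tb[(size_t)i * W + k];
    if (state == 0) { // M
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      state = code & 3u;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (i == 0 && j > 0) state = 2;
      if (j == 0 && i > 0) state = 1;
    } else if (state == 1) { // Ix: gap in b
      ga.push_back(a[i - 1]); gb.push_back('-');
      bool ext = (code >> 2) & 1u;
      --i;
      state = ext ? 1 : 0;
      if (i == 0 && j > 0) state = 2;
    } else { // Iy: gap in a
      ga.push_back('-'); gb.push_back(b[j - 1]);
      bool ext = (code >> 3) & 1u;
      --j;
      state = ext ? 2 : 0;
      if (j == 0 && i > 0) state = 1;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["score"] = score,
                      _["aln1"] = ga,
                      _["aln2"] = gb,
                      _["edge_hit"] = edge_hit);
}
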
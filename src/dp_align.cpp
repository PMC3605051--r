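#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global dynamic programming over a residue-residue similarity
// matrix S (rows: structure A, cols: structure B). gap_open is charged once
// per gap run, gap_extend per additional gapped position (TM-align uses
// open -0.6, extend 0). Returns the aligned index pairs (1-based, strictly
// increasing in both coordinates). Ties prefer the diagonal (match) state,
// then a gap in B, then a gap in A, which makes the traceback deterministic.

// [[Rcpp::export]]
IntegerMatrix dp_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // state matrices: 0 = M (i aligned to j), 1 = Ix (gap in B, consuming A),
  // 2 = Iy (gap in A, consuming B)
  std::vector<double> M((n + 1) * (m + 1), NEG), Ix((n + 1) * (m + 1), NEG),
      Iy((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0), tbIx((n + 1) * (m + 1), 0),
      tbIy((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    tbIx[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[at(0, j)] = gap_open + (j - 1) * gap_extend;
    tbIy[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: come from any state at (i-1, j-1)
      double mm = M[at(i - 1, j - 1)], ix = Ix[at(i - 1, j - 1)],
             iy = Iy[at(i - 1, j - 1)];
      double best = mm;
      unsigned char tb = 0;
      if (ix > best) { best = ix; tb = 1; }
      if (iy > best) { best = iy; tb = 2; }
      M[at(i, j)] = best + S(i - 1, j - 1);
      tbM[at(i, j)] = tb;
      // Ix: gap in B (move down); allow transition from Iy as well
      double open_ = M[at(i - 1, j)] + gap_open;
      double ext_ = Ix[at(i - 1, j)] + gap_extend;
      double crossx = Iy[at(i - 1, j)] + gap_open;
      Ix[at(i, j)] = open_; tbIx[at(i, j)] = 0;
      if (ext_ > Ix[at(i, j)]) { Ix[at(i, j)] = ext_; tbIx[at(i, j)] = 1; }
      if (crossx > Ix[at(i, j)]) { Ix[at(i, j)] = crossx; tbIx[at(i, j)] = 2; }
      // Iy: gap in A (move right); allow transition from Ix as well
      double openy = M[at(i, j - 1)] + gap_open;
      double exty = Iy[at(i, j - 1)] + gap_extend;
      double crossy = Ix[at(i, j - 1)] + gap_open;
      Iy[at(i, j)] = openy; tbIy[at(i, j)] = 0;
      if (crossy > Iy[at(i, j)]) { Iy[at(i, j)] = crossy; tbIy[at(i, j)] = 1; }
      if (exty > Iy[at(i, j)]) { Iy[at(i, j)] = exty; tbIy[at(i, j)] = 2; }
    }
  }

  // traceback from the best terminal state
  int state = 0;
  double best = M[at(n, m)];
  if (Ix[at(n, m)] > best) { best = Ix[at(n, m)]; state = 1; }
  if (Iy[at(n, m)] > best) { best = Iy[at(n, m)]; state = 2; }

  std::vector<int> ia, ib;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tbM[at(i, j)];
      ia.push_back(i);
      ib.push_back(j);
      --i; --j;
      state = tb;
    } else if (state == 1) {
      unsigned char tb = tbIx[at(i, j)];
      --i;
      state = tb;
    } else {
      unsigned char tb = tbIy[at(i, j)];
      --j;
      state = tb;
    }
  }
  const int k = (int)ia.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = ia[k - 1 - r];
    out(r, 1) = ib[k - 1 - r];
  }
  return out;
}
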
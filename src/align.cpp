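#include "seq_util.h"
using namespace Rcpp;

// Banded global alignment with affine gaps (Gotoh), band of half-width
// `band` around the main diagonal (a[i] vs b[i]). Intended for co-linear
// genome-scale sequences already rotated/offset into a shared frame; the
// caller guarantees |len(a) - len(b)| < band. Returns the two gapped rows
// and the score. Scores: match/mismatch/gap_open/gap_ext, gap penalties
// positive (subtracted); opening a gap of length 1 costs gap_open + gap_ext.
// [[Rcpp::export(rng = false)]]
List cpp_banded_global(std::string a, std::string b, int band,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) >= band)
    stop("band too narrow for length difference (%d vs %d, band %d)", n, m, band);
  const double NEG = -1e18;
  const int W = 2 * band + 1;
  auto col = [&](int i, int j) { return j - i + band; };  // band column index
  std::vector<double> M(W), X(W), Y(W), Mp(W), Xp(W), Yp(W);
  // traceback: 2 bits per matrix per cell
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  // row 0
  for (int w = 0; w < W; ++w) { Mp[w] = Xp[w] = Yp[w] = NEG; }
  Mp[col(0, 0)] = 0;
  for (int j = 1; j <= std::min(m, band); ++j) {
    int w = col(0, j);
    Yp[w] = -gap_open - gap_ext * j;
    if (j > 1) tb[w] |= 0x20;  // Y extends Y; first step opens from M
  }
  for (int i = 1; i <= n; ++i) {
    for (int w = 0; w < W; ++w) { M[w] = X[w] = Y[w] = NEG; }
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int w = col(i, j);
      // X: gap in b (consume a[i])
      {
        double fromM = (w + 1 < W) ? Mp[w + 1] : NEG;  // (i-1, j) is band col w+1
        double fromX = (w + 1 < W) ? Xp[w + 1] : NEG;
        double o = fromM - gap_open - gap_ext, e = fromX - gap_ext;
        if (o >= e) { X[w] = o; } else { X[w] = e; tb[(size_t)i * W + w] |= 0x04; }
      }
      // Y: gap in a (consume b[j])
      if (j > jlo) {
        double fromM = M[w - 1], fromY = Y[w - 1];
        double o = fromM - gap_open - gap_ext, e = fromY - gap_ext;
        if (o >= e) { Y[w] = o; } else { Y[w] = e; tb[(size_t)i * W + w] |= 0x20; }
      }
      // M: align a[i] with b[j]
      if (j > 0) {
        double diagM = Mp[w], diagX = Xp[w], diagY = Yp[w];
        double best = diagM; uint8_t code = 0;
        if (diagX > best) { best = diagX; code = 1; }
        if (diagY > best) { best = diagY; code = 2; }
        if (best > NEG / 2) {
          char ca = a[i - 1], cb = b[j - 1];
          bool isn = (ca == 'N' || ca == 'n' || cb == 'N' || cb == 'n');
          double s = isn ? 0.0 : (ca == cb ? match : mismatch);
          M[w] = best + s;
          tb[(size_t)i * W + w] |= code;
        }
      }
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  int wend = col(n, m);
  double sM = Mp[wend], sX = Xp[wend], sY = Yp[wend];
  int state = 0; double sc = sM;
  if (sX > sc) { sc = sX; state = 1; }
  if (sY > sc) { sc = sY; state = 2; }
  // traceback
  std::string ra, rb;
  ra.reserve(n + band); rb.reserve(m + band);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int w = col(i, j);
    uint8_t t = tb[(size_t)i * W + w];
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = t & 0x03;
      --i; --j;
    } else if (state == 1) {  // X: a aligned to gap
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = (t & 0x04) ? 1 : 0;
      --i;
    } else {  // Y: gap in a
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = (t & 0x20) ? 2 : 0;
      --j;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = sc);
}
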
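#include <Rcpp.h>
using namespace Rcpp;

// Texture-matrix construction for 2-D labeled ROIs.
// Convention throughout: `labels` is an integer matrix with 0 outside the
// mask and gray levels 1..nlevels inside. Directions follow the usual
// 2-D set {0, 45, 90, 135} degrees at distance 1; co-occurrence and
// run-length matrices are summed ("merged") over directions.

static const int DR[4] = {0, -1, -1, -1};
static const int DC[4] = {1,  1,  0, -1};

// [[Rcpp::export(name = ".glcm_counts_cpp")]]
NumericMatrix glcm_counts_cpp(IntegerMatrix labels, int nlevels) {
  int nr = labels.nrow(), nc = labels.ncol();
  NumericMatrix out(nlevels, nlevels);
  for (int d = 0; d < 4; ++d) {
    int dr = DR[d], dc = DC[d];
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        int a = labels(r, c);
        if (a == 0) continue;
        int r2 = r + dr, c2 = c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int b = labels(r2, c2);
        if (b == 0) continue;
        out(a - 1, b - 1) += 1.0;  // symmetrized pair
        out(b - 1, a - 1) += 1.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
NumericMatrix glrlm_counts_cpp(IntegerMatrix labels, int nlevels) {
  int nr = labels.nrow(), nc = labels.ncol();
  int maxlen = nr > nc ? nr : nc;
  NumericMatrix out(nlevels, maxlen);
  for (int d = 0; d < 4; ++d) {
    int dr = DR[d], dc = DC[d];
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        int a = labels(r, c);
        if (a == 0) continue;
        // start of a maximal run: predecessor out of bounds, out of mask,
        // or a different level
        int rp = r - dr, cp = c - dc;
        bool start = (rp < 0 || rp >= nr || cp < 0 || cp >= nc);
        if (!start) start = (labels(rp, cp) != a);
        if (!start) continue;
        int len = 1, r2 = r + dr, c2 = c + dc;
        while (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && labels(r2, c2) == a) {
          ++len; r2 += dr; c2 += dc;
        }
        out(a - 1, len - 1) += 1.0;
      }
    }
  }
  // trim trailing all-zero run-length columns
  int last = 0;
  for (int j = 0; j < maxlen; ++j)
    for (int i = 0; i < nlevels; ++i)
      if (out(i, j) > 0 && j + 1 > last) last = j + 1;
  if (last == 0) last = 1;
  return out(Range(0, nlevels - 1), Range(0, last - 1));
}

// [[Rcpp::export(name = ".glszm_counts_cpp")]]
NumericMatrix glszm_counts_cpp(IntegerMatrix labels, int nlevels) {
  int nr = labels.nrow(), nc = labels.ncol();
  int n = nr * nc;
  std::vector<int> stack;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones;  // (level, size)
  int maxsize = 0;
  for (int idx = 0; idx < n; ++idx) {
    int r0 = idx % nr, c0 = idx / nr;
    int lev = labels(r0, c0);
    if (lev == 0 || seen[idx]) continue;
    // 8-connected flood fill over equal-label in-mask pixels
    int size = 0;
    stack.clear();
    stack.push_back(idx);
    seen[idx] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int r = cur % nr, c = cur / nr;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int idx2 = r2 + nr * c2;
          if (seen[idx2] || labels(r2, c2) != lev) continue;
          seen[idx2] = 1;
          stack.push_back(idx2);
        }
      }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > maxsize) maxsize = size;
  }
  if (maxsize == 0) maxsize = 1;
  NumericMatrix out(nlevels, maxsize);
  for (size_t k = 0; k < zones.size(); ++k)
    out(zones[k].first - 1, zones[k].second - 1) += 1.0;
  return out;
}
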
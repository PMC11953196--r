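#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass-free BFS connected-component labeling of a binary raster.
// mask: logical matrix (TRUE = foreground). connectivity: 4 or 8.
// Returns integer matrix of labels (0 = background), labels 1..k ordered
// by first-encountered pixel in column-major order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qr, qc;
  qr.reserve(nr * nc);
  qc.reserve(nr * nc);
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qr.clear(); qc.clear();
      qr.push_back(i); qc.push_back(j);
      size_t head = 0;
      while (head < qr.size()) {
        int r = qr[head], c = qc[head];
        ++head;
        for (int d = 0; d < ndir; ++d) {
          int rr = r + dr8[d], cc = c + dc8[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            qr.push_back(rr); qc.push_back(cc);
          }
        }
      }
    }
  }
  return lab;
}

// Fill holes: any background region not connected (4-connectivity) to the
// raster border becomes foreground.
// [[Rcpp::export(name = ".cc_fill_holes")]]
LogicalMatrix cc_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> qr, qc;
  qr.reserve(nr * nc); qc.reserve(nr * nc);
  // seed the border background
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if ((i == 0 || i == nr - 1 || j == 0 || j == nc - 1) && !mask(i, j) &&
          !outside[(size_t)j * nr + i]) {
        outside[(size_t)j * nr + i] = 1;
        qr.push_back(i); qc.push_back(j);
      }
    }
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  size_t head = 0;
  while (head < qr.size()) {
    int r = qr[head], c = qc[head];
    ++head;
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      size_t k = (size_t)cc * nr + rr;
      if (!mask(rr, cc) && !outside[k]) {
        outside[k] = 1;
        qr.push_back(rr); qc.push_back(cc);
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !outside[(size_t)j * nr + i];
  return out;
}
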
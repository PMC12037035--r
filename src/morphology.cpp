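#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Pixel neighbourhood offsets. conn is 4 or 8.
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {-1, 1, -1, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dr = connectivity == 8 ? DR8 : DR4;
  const int *dc = connectivity == 8 ? DC8 : DC4;
  int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct WsItem {
  double prio;   // intensity; flood descends from bright seeds
  long order;    // FIFO tie-break for determinism
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsItem &a, const WsItem &b) const {
    if (a.prio != b.prio) return a.prio < b.prio; // max-heap on intensity
    return a.order > b.order;                     // earlier pushes first
  }
};

// Seeded watershed (Meyer flooding, descending from seeds) with one-pixel
// watershed lines (label 0) where two basins meet. Pixels outside `mask`
// stay 0 and act as barriers.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix img, IntegerMatrix seeds,
                            LogicalMatrix mask, int connectivity = 8) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);      // 0 = unassigned/background/line
  LogicalMatrix done(nr, nc);     // finalized pixels (incl. lines)
  const int *dr = connectivity == 8 ? DR8 : DR4;
  const int *dc = connectivity == 8 ? DC8 : DC4;
  int nn = connectivity == 8 ? 8 : 4;
  std::priority_queue<WsItem, std::vector<WsItem>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        done(r, c) = true;
        pq.push({img(r, c), order++, r + c * nr, seeds(r, c)});
      }
  while (!pq.empty()) {
    WsItem it = pq.top(); pq.pop();
    int pr = it.idx % nr, pc = it.idx / nr;
    for (int k = 0; k < nn; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (!mask(qr, qc) || done(qr, qc)) continue;
      // does q touch more than one basin?
      int seen = 0; bool conflict = false;
      for (int m = 0; m < nn; ++m) {
        int sr = qr + dr[m], sc = qc + dc[m];
        if (sr < 0 || sr >= nr || sc < 0 || sc >= nc) continue;
        int l = lab(sr, sc);
        if (l > 0) {
          if (seen == 0) seen = l;
          else if (seen != l) { conflict = true; break; }
        }
      }
      done(qr, qc) = true;
      if (conflict) {
        lab(qr, qc) = 0; // watershed line
      } else {
        lab(qr, qc) = seen > 0 ? seen : it.label;
        pq.push({img(qr, qc), order++, qr + qc * nr, lab(qr, qc)});
      }
    }
  }
  return lab;
}

// Fill holes: background connected (8-conn) to the image border is kept;
// every other non-mask pixel is a hole and becomes foreground. 8-connected
// background flooding deliberately leaves one-pixel watershed lines that
// reach the object boundary unfilled.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix outside(nr, nc);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c : {0, nc - 1})
      if (!mask(r, c) && !outside(r, c)) { outside(r, c) = true; stack.push_back(r + c * nr); }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r : {0, nr - 1})
      if (!mask(r, c) && !outside(r, c)) { outside(r, c) = true; stack.push_back(r + c * nr); }
  }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int pr = p % nr, pc = p / nr;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (!mask(qr, qc) && !outside(qr, qc)) {
        outside(qr, qc) = true;
        stack.push_back(qr + qc * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !outside(r, c);
  return out;
}

// Binary dilation by a disc of given radius (Euclidean, centre-to-centre).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disc(LogicalMatrix mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  int ri = (int)std::floor(radius);
  double r2 = radius * radius;
  std::vector<std::pair<int,int> > offs;
  for (int a = -ri; a <= ri; ++a)
    for (int b = -ri; b <= ri; ++b)
      if ((double)(a * a + b * b) <= r2) offs.push_back(std::make_pair(a, b));
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t k = 0; k < offs.size(); ++k) {
        int qr = r + offs[k].first, qc = c + offs[k].second;
        if (qr >= 0 && qr < nr && qc >= 0 && qc < nc) out(qr, qc) = true;
      }
    }
  return out;
}

// Local maxima with a minimum centre-to-centre distance, enforced greedily
// in decreasing intensity order (ties broken by linear index, deterministic).
// Returns 1-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericMatrix img, double min_distance,
                               double threshold) {
  int nr = img.nrow(), nc = img.ncol();
  int ri = std::max(1, (int)std::ceil(min_distance));
  std::vector<std::pair<double,int> > cand;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      if (!(v > threshold)) continue;
      bool is_max = true;
      for (int a = -1; a <= 1 && is_max; ++a)
        for (int b = -1; b <= 1; ++b) {
          if (a == 0 && b == 0) continue;
          int qr = r + a, qc = c + b;
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          double w = img(qr, qc);
          // strict on earlier pixels, non-strict after: one max per plateau
          if (w > v || (w == v && (qc * nr + qr) < (c * nr + r))) { is_max = false; break; }
        }
      if (is_max) cand.push_back(std::make_pair(v, r + c * nr));
    }
  std::sort(cand.begin(), cand.end(),
            [](const std::pair<double,int> &a, const std::pair<double,int> &b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  double d2 = min_distance * min_distance;
  std::vector<int> keep;
  for (size_t i = 0; i < cand.size(); ++i) {
    int pr = cand[i].second % nr, pc = cand[i].second / nr;
    bool ok = true;
    for (size_t j = 0; j < keep.size(); ++j) {
      int qr = keep[j] % nr, qc = keep[j] / nr;
      double dd = (double)(pr - qr) * (pr - qr) + (double)(pc - qc) * (pc - qc);
      if (dd < d2) { ok = false; break; }
    }
    if (ok) keep.push_back(cand[i].second);
  }
  (void)ri;
  IntegerMatrix out(keep.size(), 2);
  for (size_t i = 0; i < keep.size(); ++i) {
    out(i, 0) = keep[i] % nr + 1;
    out(i, 1) = keep[i] / nr + 1;
  }
  return out;
}
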
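#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input: 0/1 integer matrix; returns the
// 1-pixel-wide skeleton. Out-of-image neighbours are treated as background.

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// [[Rcpp::export(name = ".thin_zs")]]
IntegerMatrix thin_zs(IntegerMatrix mask) {
  IntegerMatrix img = clone(mask);
  int nr = img.nrow(), nc = img.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = px(img, r - 1, c),     p3 = px(img, r - 1, c + 1);
          int p4 = px(img, r, c + 1),     p5 = px(img, r + 1, c + 1);
          int p6 = px(img, r + 1, c),     p7 = px(img, r + 1, c - 1);
          int p8 = px(img, r, c - 1),     p9 = px(img, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = 0;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k)
          img(kill[k].first, kill[k].second) = 0;
      }
    }
  }
  // Zhang-Suen leaves 4-connected staircases; sequentially delete 8-simple
  // non-endpoint pixels (Yokoi connectivity number == 1) to reach a minimal
  // 8-connected 1-px skeleton without changing topology.
  bool removed = true;
  while (removed) {
    removed = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!img(r, c)) continue;
        // neighbours in cyclic order N, NE, E, SE, S, SW, W, NW
        int nb[8] = {px(img, r - 1, c),     px(img, r - 1, c + 1),
                     px(img, r, c + 1),     px(img, r + 1, c + 1),
                     px(img, r + 1, c),     px(img, r + 1, c - 1),
                     px(img, r, c - 1),     px(img, r - 1, c - 1)};
        int n = 0;
        for (int k = 0; k < 8; ++k) n += nb[k];
        if (n < 2) continue; // endpoint or isolated: keep
        int C = 0;
        for (int k = 0; k < 8; k += 2) {
          int b0 = 1 - nb[k], b1 = 1 - nb[(k + 1) % 8],
              b2 = 1 - nb[(k + 2) % 8];
          C += b0 - b0 * b1 * b2;
        }
        if (C == 1) {
          img(r, c) = 0;
          removed = true;
        }
      }
    }
  }
  return img;
}
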
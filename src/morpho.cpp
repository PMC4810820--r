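#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <map>
using namespace Rcpp;

// 8-connected component labelling of a logical mask (flood fill with an
// explicit stack; label order follows column-major first encounter).
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore boundary tracing (Jacob's stopping criterion) of the outer contour
// of a single 8-connected foreground component. Returns an ordered, closed
// (first point not repeated) k x 2 matrix of 1-based (row, col) coordinates,
// traced clockwise in matrix convention starting from the topmost-leftmost
// foreground pixel.
// [[Rcpp::export(name = ".trace_boundary_cpp")]]
IntegerMatrix trace_boundary_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // Moore neighbourhood in clockwise order starting from "west".
  const int dr[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
  const int dc[8] = {-1, -1,  0,  1,  1,  1, 0, -1 };
  int sr = -1, sc = -1;
  for (int i = 0; i < nr && sr < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (mask(i, j)) { sr = i; sc = j; break; }
  if (sr < 0) stop("empty mask");
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  // dir holds the backtrack direction (the neighbour we came from); the
  // scan for the next boundary pixel starts just past it, clockwise. The
  // start pixel is topmost-leftmost, so "west" is a valid backtrack.
  int cr = sr, cc = sc, dir = 0;
  int first_move = -1;
  const size_t maxlen = (size_t)nr * nc * 4 + 16; // each pixel enters a Moore trace at most 4 times
  while (rows.size() < maxlen) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (dir + k) % 8;
      int rr = cr + dr[d], ccol = cc + dc[d];
      if (rr >= 0 && rr < nr && ccol >= 0 && ccol < nc && mask(rr, ccol)) {
        found = d;
        break;
      }
    }
    if (found < 0) break; // isolated pixel
    if (cr == sr && cc == sc) {
      if (first_move < 0) first_move = found;
      else if (found == first_move) break; // closed the loop
    }
    cr += dr[found]; cc += dc[found];
    dir = (found + 4) % 8;
    if (!(cr == sr && cc == sc)) { rows.push_back(cr); cols.push_back(cc); }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}

static double interp_quartile_sorted(const std::vector<double>& x, double p) {
  // R type-7: linear interpolation between order statistics.
  const size_t m = x.size();
  if (m == 1) return x[0];
  double h = (double)(m - 1) * p;
  size_t lo = (size_t)std::floor(h);
  double g = h - (double)lo;
  if (lo + 1 >= m) return x[m - 1];
  return x[lo] + g * (x[lo + 1] - x[lo]);
}

// Quartile from level counts (levels sorted ascending), type-7.
static double interp_quartile_counts(const std::vector<double>& levels,
                                     const std::vector<int>& cnt,
                                     int total, double p) {
  if (total == 1) {
    for (size_t l = 0; l < cnt.size(); ++l) if (cnt[l]) return levels[l];
  }
  double h = (double)(total - 1) * p;
  int lo = (int)std::floor(h);
  double g = h - (double)lo;
  // order statistics x[lo], x[lo+1] (0-based)
  double xlo = 0, xhi = 0;
  int acc = 0;
  bool got_lo = false;
  for (size_t l = 0; l < cnt.size(); ++l) {
    if (!cnt[l]) continue;
    int upto = acc + cnt[l]; // values acc .. upto-1 are levels[l]
    if (!got_lo && lo < upto) { xlo = levels[l]; got_lo = true; }
    if (lo + 1 < upto) { xhi = levels[l]; break; }
    acc = upto;
  }
  if (lo + 1 >= total) xhi = xlo;
  return xlo + g * (xhi - xlo);
}

// Sliding-neighbourhood quartile outlier filter: one pass over a frozen
// copy. For each valid pixel, Q1/Q3 (type-7) of the valid values in the
// n x n window (truncated at borders, invalid pixels excluded); values
// strictly outside [Q1, Q3] are replaced by the window mean of valid
// pixels. Invalid pixels are returned as NA.
//
// A counting fast path is used when the grid holds few distinct values
// (heights quantized to z-levels); otherwise values are gathered and
// partially sorted per window.
// [[Rcpp::export(name = ".quartile_filter_cpp")]]
NumericMatrix quartile_filter_cpp(NumericMatrix h, LogicalMatrix valid, int n) {
  const int nr = h.nrow(), nc = h.ncol(), half = n / 2;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);

  // distinct levels
  std::map<double, int> lev;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (valid(i, j)) lev[h(i, j)] = 0;
  const bool counting = lev.size() > 0 && lev.size() <= 4096;

  if (counting) {
    std::vector<double> levels;
    levels.reserve(lev.size());
    for (std::map<double, int>::iterator it = lev.begin(); it != lev.end(); ++it) {
      it->second = (int)levels.size();
      levels.push_back(it->first);
    }
    const int L = (int)levels.size();
    IntegerMatrix idx(nr, nc);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        idx(i, j) = valid(i, j) ? lev.find(h(i, j))->second : -1;

    std::vector<int> cnt(L);
    for (int i = 0; i < nr; ++i) {
      const int r0 = std::max(0, i - half), r1 = std::min(nr - 1, i + half);
      std::fill(cnt.begin(), cnt.end(), 0);
      int total = 0;
      double sum = 0.0;
      const int c1_init = std::min(nc - 1, half);
      for (int c = 0; c <= c1_init; ++c)
        for (int r = r0; r <= r1; ++r)
          if (idx(r, c) >= 0) { ++cnt[idx(r, c)]; ++total; sum += h(r, c); }
      for (int j = 0; j < nc; ++j) {
        if (j > 0) {
          const int cadd = j + half, cdel = j - half - 1;
          if (cadd < nc)
            for (int r = r0; r <= r1; ++r)
              if (idx(r, cadd) >= 0) { ++cnt[idx(r, cadd)]; ++total; sum += h(r, cadd); }
          if (cdel >= 0)
            for (int r = r0; r <= r1; ++r)
              if (idx(r, cdel) >= 0) { --cnt[idx(r, cdel)]; --total; sum -= h(r, cdel); }
        }
        if (!valid(i, j)) continue;
        const double q1 = interp_quartile_counts(levels, cnt, total, 0.25);
        const double q3 = interp_quartile_counts(levels, cnt, total, 0.75);
        const double v = h(i, j);
        out(i, j) = (v < q1 || v > q3) ? sum / (double)total : v;
      }
    }
  } else {
    std::vector<double> buf;
    buf.reserve((size_t)n * n);
    for (int j = 0; j < nc; ++j) {
      const int c0 = std::max(0, j - half), c1 = std::min(nc - 1, j + half);
      for (int i = 0; i < nr; ++i) {
        if (!valid(i, j)) continue;
        const int r0 = std::max(0, i - half), r1 = std::min(nr - 1, i + half);
        buf.clear();
        double sum = 0.0;
        for (int c = c0; c <= c1; ++c)
          for (int r = r0; r <= r1; ++r)
            if (valid(r, c)) { buf.push_back(h(r, c)); sum += h(r, c); }
        std::sort(buf.begin(), buf.end());
        const double q1 = interp_quartile_sorted(buf, 0.25);
        const double q3 = interp_quartile_sorted(buf, 0.75);
        const double v = h(i, j);
        out(i, j) = (v < q1 || v > q3) ? sum / (double)buf.size() : v;
      }
    }
  }
  return out;
}
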
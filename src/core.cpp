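#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Connected-component labelling of a binary mask with 4- or 8-connectivity.
// Labels are assigned in order of first encounter during a row-major scan,
// so label 1 always owns the lexicographically smallest (row, col) pixel
// among unlabelled foreground.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix mask, const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity == 4 ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i * nc + j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p / nc, pj = p % nc;
        for (int k = 0; k < nn; ++k) {
          const int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi * nc + qj);
          }
        }
      }
    }
  }
  return lab;
}

// Binary erosion with an n x n box structuring element, separable
// implementation. Pixels outside the image count as background. For even n
// the extra row/column of the window lies toward the bottom-right: offsets
// run from -floor((n-1)/2) to +floor(n/2).
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix mask, const int n) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int lo = -((n - 1) / 2), hi = n / 2;
  LogicalMatrix tmp(nr, nc), out(nr, nc);
  // horizontal pass
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      bool all = true;
      for (int d = lo; d <= hi && all; ++d) {
        const int q = j + d;
        if (q < 0 || q >= nc || !mask(i, q)) all = false;
      }
      tmp(i, j) = all;
    }
  }
  // vertical pass
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      bool all = true;
      for (int d = lo; d <= hi && all; ++d) {
        const int q = i + d;
        if (q < 0 || q >= nr || !tmp(q, j)) all = false;
      }
      out(i, j) = all;
    }
  }
  return out;
}

// Seeded region growing. `img255` holds intensities on the 0-255 scale,
// `seeds` are 1-based (row, col) pairs already ordered row-major. FIFO
// frontier; neighbours visited in the fixed order N, NE, E, SE, S, SW, W,
// NW. Every pixel is evaluated at most once (visit marks at evaluation
// time). A pixel is accepted iff it is not black, its absolute intensity
// difference from the originating seed of the current chain lies strictly
// between `lower` and `upper`, and its Euclidean distance from that seed is
// at most `maxDepth`. Seeds themselves are accepted iff not black.
// Returns the grown mask, the number of pixels evaluated, and the
// originating-seed index (1-based into `seeds`, 0 = not grown) per pixel.
// [[Rcpp::export]]
List cpp_grow(const NumericMatrix img255, const IntegerMatrix seeds,
              const double upper, const double lower, const double maxDepth) {
  const int nr = img255.nrow(), nc = img255.ncol();
  const int ns = seeds.nrow();
  LogicalMatrix mask(nr, nc);
  IntegerMatrix visited(nr, nc), origin(nr, nc);
  // neighbour order N, NE, E, SE, S, SW, W, NW in (row, col) image coords
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::queue<int> q; // encoded pixel index; origin read from `origin`
  long evaluated = 0;
  for (int s = 0; s < ns; ++s) {
    const int i = seeds(s, 0) - 1, j = seeds(s, 1) - 1;
    if (i < 0 || i >= nr || j < 0 || j >= nc)
      stop("seed outside image bounds");
    if (visited(i, j)) continue;
    visited(i, j) = 1;
    ++evaluated;
    if (img255(i, j) > 0) {
      mask(i, j) = true;
      origin(i, j) = s + 1;
      q.push(i * nc + j);
    }
  }
  const double depth2 = maxDepth * maxDepth;
  while (!q.empty()) {
    const int p = q.front();
    q.pop();
    const int pi = p / nc, pj = p % nc;
    const int org = origin(pi, pj);
    const int oi = seeds(org - 1, 0) - 1, oj = seeds(org - 1, 1) - 1;
    const double oval = img255(oi, oj);
    for (int k = 0; k < 8; ++k) {
      const int qi = pi + dr[k], qj = pj + dc[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (visited(qi, qj)) continue;
      visited(qi, qj) = 1;
      ++evaluated;
      const double v = img255(qi, qj);
      if (v <= 0) continue;                       // must not be black
      const double diff = std::fabs(v - oval);
      // strict thresholds; lower == 0 disables the lower bound entirely
      if (!((lower <= 0.0 || diff > lower) && diff < upper)) continue;
      const double di = qi - oi, dj = qj - oj;
      if (di * di + dj * dj > depth2) continue;   // depth from origin seed
      mask(qi, qj) = true;
      origin(qi, qj) = org;
      q.push(qi * nc + qj);
    }
  }
  return List::create(_["mask"] = mask, _["evaluated"] = (double)evaluated,
                      _["origin"] = origin);
}

// Directed sums of nearest-point distances between two surface point sets
// ((row, col) coordinates, any units). Brute force all-pairs minimum.
// [[Rcpp::export]]
NumericVector cpp_surface_sums(const NumericMatrix P1, const NumericMatrix P2) {
  const int n1 = P1.nrow(), n2 = P2.nrow();
  double s12 = 0.0, s21 = 0.0;
  std::vector<double> min2(n2, R_PosInf);
  for (int i = 0; i < n1; ++i) {
    double best = R_PosInf;
    const double r = P1(i, 0), c = P1(i, 1);
    for (int j = 0; j < n2; ++j) {
      const double dr = r - P2(j, 0), dc = c - P2(j, 1);
      const double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
      if (d2 < min2[j]) min2[j] = d2;
    }
    s12 += std::sqrt(best);
  }
  for (int j = 0; j < n2; ++j) s21 += std::sqrt(min2[j]);
  return NumericVector::create(s12, s21);
}

// Cumulative DTW cost under the right/diagonal/down move set.
// [[Rcpp::export]]
NumericMatrix cpp_dtw_cumulative(const NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  NumericMatrix cum(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = R_PosInf;
        if (i > 0 && j > 0 && cum(i - 1, j - 1) < best) best = cum(i - 1, j - 1);
        if (i > 0 && cum(i - 1, j) < best) best = cum(i - 1, j);
        if (j > 0 && cum(i, j - 1) < best) best = cum(i, j - 1);
      }
      cum(i, j) = cost(i, j) + best;
    }
  }
  return cum;
}
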
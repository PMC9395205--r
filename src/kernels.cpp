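#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Symmetric boundary reflection: -1 -> 0, -2 -> 1, n -> n-1 (scipy mode "reflect").
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Grayscale erosion/dilation by an arbitrary structuring element given as
// offset lists (dy, dx) with per-offset heights h (all zero for a flat SE).
// border: 0 = reflect, 1 = constant pad with border_value.
// dilate: out(p) = max_k img(p + o_k) + h_k ; erode: min_k img(p + o_k) - h_k.
// [[Rcpp::export]]
NumericMatrix morph_cpp(NumericMatrix img, IntegerVector dy, IntegerVector dx,
                        NumericVector h, bool dilate, int border,
                        double border_value) {
  int nr = img.nrow(), nc = img.ncol(), K = dy.size();
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      double best = dilate ? R_NegInf : R_PosInf;
      for (int k = 0; k < K; ++k) {
        int yy = y + dy[k], xx = x + dx[k];
        double v;
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) {
          if (border == 0) {
            v = img(reflect_idx(yy, nr), reflect_idx(xx, nc));
          } else {
            v = border_value;
          }
        } else {
          v = img(yy, xx);
        }
        double cand = dilate ? v + h[k] : v - h[k];
        if (dilate ? (cand > best) : (cand < best)) best = cand;
      }
      out(y, x) = best;
    }
  }
  return out;
}

// Non-local means, Buades-style: for each pixel i, a weighted average of the
// pixels j in a search window, weight exp(-||patch_i - patch_j||^2 / h^2)
// (plain squared Euclidean patch distance, reflect padding), normalized so
// the weights at each pixel sum to one.
// [[Rcpp::export]]
NumericMatrix nlm_cpp(NumericMatrix img, double h, int patch, int window) {
  int nr = img.nrow(), nc = img.ncol();
  int pr = patch / 2, wr = window / 2;
  double h2 = h * h;
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      double wsum = 0.0, vsum = 0.0;
      for (int jx = x - wr; jx <= x + wr; ++jx) {
        for (int jy = y - wr; jy <= y + wr; ++jy) {
          double d2 = 0.0;
          for (int px = -pr; px <= pr; ++px) {
            for (int py = -pr; py <= pr; ++py) {
              double a = img(reflect_idx(y + py, nr), reflect_idx(x + px, nc));
              double b = img(reflect_idx(jy + py, nr), reflect_idx(jx + px, nc));
              double d = a - b;
              d2 += d * d;
            }
          }
          double w = std::exp(-d2 / h2);
          wsum += w;
          vsum += w * img(reflect_idx(jy, nr), reflect_idx(jx, nc));
        }
      }
      out(y, x) = vsum / wsum;
    }
  }
  return out;
}

// Iterated neighbor-averaging diffusion inpainting of one channel.
// Masked pixels start invalid; each Jacobi sweep replaces every masked pixel
// that has at least one valid 8-neighbor by the mean of its valid neighbors
// (zero center weight, kernel renormalized over available neighbors), then
// marks it valid. Stops after max_iter sweeps or when every masked pixel is
// valid and the largest per-pixel change drops below tol.
// [[Rcpp::export]]
NumericMatrix inpaint_cpp(NumericMatrix img, LogicalMatrix mask, int max_iter,
                          double tol) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix cur = clone(img);
  LogicalMatrix valid(nr, nc);
  std::vector<int> my, mx;
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      valid(y, x) = !mask(y, x);
      if (mask(y, x)) { my.push_back(y); mx.push_back(x); cur(y, x) = 0.0; }
    }
  int n_masked = (int)my.size();
  if (n_masked == 0) return cur;

  for (int iter = 0; iter < max_iter; ++iter) {
    NumericMatrix nxt = clone(cur);
    LogicalMatrix nvalid = clone(valid);
    double max_change = 0.0;
    bool all_valid = true;
    for (int k = 0; k < n_masked; ++k) {
      int y = my[k], x = mx[k];
      double s = 0.0; int n = 0;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dyy = -1; dyy <= 1; ++dyy) {
          if (dx == 0 && dyy == 0) continue;
          int yy = y + dyy, xx = x + dx;
          if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
          if (valid(yy, xx)) { s += cur(yy, xx); ++n; }
        }
      }
      if (n > 0) {
        double v = s / n;
        double ch = valid(y, x) ? std::fabs(v - cur(y, x)) : R_PosInf;
        if (ch > max_change) max_change = ch;
        nxt(y, x) = v;
        nvalid(y, x) = true;
      } else {
        all_valid = false;
      }
      if (!valid(y, x)) all_valid = false;
    }
    cur = nxt;
    valid = nvalid;
    if (all_valid && max_change < tol) break;
  }
  return cur;
}

// Sliding-window median with reflect padding.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  int nr = img.nrow(), nc = img.ncol(), r = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k * k);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      int n = 0;
      for (int dx = -r; dx <= r; ++dx)
        for (int dyy = -r; dyy <= r; ++dyy)
          buf[n++] = img(reflect_idx(y + dyy, nr), reflect_idx(x + dx, nc));
      std::sort(buf.begin(), buf.end());
      out(y, x) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return out;
}

// Conservative smoothing: clamp each pixel to the [min, max] range of its
// k x k neighborhood excluding the center (reflect padding).
// [[Rcpp::export]]
NumericMatrix conservative_cpp(NumericMatrix img, int k) {
  int nr = img.nrow(), nc = img.ncol(), r = k / 2;
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int dx = -r; dx <= r; ++dx) {
        for (int dyy = -r; dyy <= r; ++dyy) {
          if (dx == 0 && dyy == 0) continue;
          double v = img(reflect_idx(y + dyy, nr), reflect_idx(x + dx, nc));
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
      }
      double c = img(y, x);
      out(y, x) = c > hi ? hi : (c < lo ? lo : c);
    }
  }
  return out;
}

// 8-connected component labelling (BFS); labels 1..n in discovery order,
// 0 = background.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      lab(y, x) = ++next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dyy = -1; dyy <= 1; ++dyy) {
            int yy = p.first + dyy, xx = p.second + dx;
            if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
            if (mask(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              q.push(std::make_pair(yy, xx));
            }
          }
        }
      }
    }
  }
  return lab;
}
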
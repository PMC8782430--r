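// Sliding-window texture feature maps.
//
// Per-window semantics must stay identical to the single-patch R functions
// in R/texture.R: window-local quantization maxima, clamp to [1, n_levels],
// degenerate max -> level 1, Sobel with replicate padding of the window
// itself, maximal-run (Galloway) run-length counting.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// quantize m values by their max into [1, nl]; max <= 0 -> all level 1
static void quantize_local(const std::vector<double>& v, int nl,
                           std::vector<int>& q) {
  double mx = 0.0;
  for (double x : v) if (x > mx) mx = x;
  if (mx <= 0.0) {
    std::fill(q.begin(), q.end(), 1);
    return;
  }
  for (size_t t = 0; t < v.size(); ++t) {
    int lev = (int) std::floor(v[t] * nl / mx) + 1;
    q[t] = clampi(lev, 1, nl);
  }
}

// extract win x win window centred at (r, c), replicate padding at image
// borders; column-major within the window
static void extract_window(const NumericMatrix& img, int r, int c, int h,
                           int win, std::vector<double>& patch) {
  int n = img.nrow(), m = img.ncol();
  for (int dc = -h; dc <= h; ++dc) {
    int cc = clampi(c + dc, 0, m - 1);
    for (int dr = -h; dr <= h; ++dr) {
      int rr = clampi(r + dr, 0, n - 1);
      patch[(dc + h) * win + (dr + h)] = img(rr, cc);
    }
  }
}

// Sobel magnitude of a patch/image with replicate padding of its border
static void sobel_patch(const std::vector<double>& v, int nr, int nc,
                        std::vector<double>& g) {
  auto at = [&](int a, int b) {
    return v[clampi(b, 0, nc - 1) * nr + clampi(a, 0, nr - 1)];
  };
  for (int pc = 0; pc < nc; ++pc) {
    for (int pr = 0; pr < nr; ++pr) {
      double gx = (at(pr + 1, pc - 1) + 2.0 * at(pr + 1, pc) +
                   at(pr + 1, pc + 1)) -
                  (at(pr - 1, pc - 1) + 2.0 * at(pr - 1, pc) +
                   at(pr - 1, pc + 1));
      double gy = (at(pr - 1, pc + 1) + 2.0 * at(pr, pc + 1) +
                   at(pr + 1, pc + 1)) -
                  (at(pr - 1, pc - 1) + 2.0 * at(pr, pc - 1) +
                   at(pr + 1, pc - 1));
      g[pc * nr + pr] = std::sqrt(gx * gx + gy * gy);
    }
  }
}

// integer window extraction with replicate padding
static void extract_window_int(const std::vector<int>& q, int n, int m,
                               int r, int c, int h, int win,
                               std::vector<int>& patch) {
  for (int dc = -h; dc <= h; ++dc) {
    int cc = clampi(c + dc, 0, m - 1);
    for (int dr = -h; dr <= h; ++dr) {
      int rr = clampi(r + dr, 0, n - 1);
      patch[(dc + h) * win + (dr + h)] = q[cc * n + rr];
    }
  }
}

// quantize the whole image and its Sobel magnitude once (image-global
// maxima, the default), producing level images used by all windows
static void quantize_global(const NumericMatrix& img, int n_gray,
                            int n_gradient, std::vector<int>& F,
                            std::vector<int>& G) {
  int n = img.nrow(), m = img.ncol();
  std::vector<double> v(img.begin(), img.end()), g(n * m);
  sobel_patch(v, n, m, g);
  quantize_local(v, n_gray, F);
  quantize_local(g, n_gradient, G);
}

// [[Rcpp::export]]
NumericMatrix idm_map_cpp(NumericMatrix img, int win, int n_gray,
                          int n_gradient, bool global_norm) {
  int n = img.nrow(), m = img.ncol(), h = win / 2, np = win * win;
  NumericMatrix out(n, m);
  std::vector<double> patch(np), grad(np);
  std::vector<int> F(np), G(np), Fg, Gg;
  std::vector<int> H(n_gray * n_gradient);
  if (global_norm) {
    Fg.resize(n * m); Gg.resize(n * m);
    quantize_global(img, n_gray, n_gradient, Fg, Gg);
  }

  for (int c = 0; c < m; ++c) {
    for (int r = 0; r < n; ++r) {
      if (global_norm) {
        extract_window_int(Fg, n, m, r, c, h, win, F);
        extract_window_int(Gg, n, m, r, c, h, win, G);
      } else {
        extract_window(img, r, c, h, win, patch);
        sobel_patch(patch, win, win, grad);
        quantize_local(patch, n_gray, F);
        quantize_local(grad, n_gradient, G);
      }
      std::fill(H.begin(), H.end(), 0);
      for (int t = 0; t < np; ++t) H[(G[t] - 1) * n_gray + (F[t] - 1)]++;
      double s = 0.0;
      for (int j = 1; j <= n_gradient; ++j) {
        for (int i = 1; i <= n_gray; ++i) {
          int cnt = H[(j - 1) * n_gray + (i - 1)];
          if (cnt) s += (double) cnt / (1.0 + (double)(i - j) * (i - j));
        }
      }
      out(r, c) = s / np;
    }
  }
  return out;
}

// accumulate LRLGE terms for runs along direction (dr, dc) of a quantized
// win x win patch; returns sum of j^2/i^2 per run and the run count
static void runs_direction(const std::vector<int>& q, int win, int dr, int dc,
                           double& S, int& n_r) {
  for (int c0 = 0; c0 < win; ++c0) {
    for (int r0 = 0; r0 < win; ++r0) {
      // start only where the line enters the patch
      int rp = r0 - dr, cp = c0 - dc;
      if (rp >= 0 && rp < win && cp >= 0 && cp < win) continue;
      int r = r0, c = c0;
      int cur = q[c * win + r], len = 0;
      while (r >= 0 && r < win && c >= 0 && c < win) {
        int v = q[c * win + r];
        if (v == cur) {
          ++len;
        } else {
          S += (double) len * len / ((double) cur * cur);
          ++n_r;
          cur = v;
          len = 1;
        }
        r += dr;
        c += dc;
      }
      S += (double) len * len / ((double) cur * cur);
      ++n_r;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix lrlge_map_cpp(NumericMatrix img, int win, int n_gray,
                            bool global_norm) {
  int n = img.nrow(), m = img.ncol(), h = win / 2, np = win * win;
  NumericMatrix out(n, m);
  std::vector<double> patch(np);
  std::vector<int> q(np), Fg;
  const int drs[4] = {0, -1, -1, -1};  // 0, 45, 90, 135 degrees
  const int dcs[4] = {1, 1, 0, -1};
  if (global_norm) {
    Fg.resize(n * m);
    std::vector<double> v(img.begin(), img.end());
    quantize_local(v, n_gray, Fg);
  }

  for (int c = 0; c < m; ++c) {
    for (int r = 0; r < n; ++r) {
      if (global_norm) {
        extract_window_int(Fg, n, m, r, c, h, win, q);
      } else {
        extract_window(img, r, c, h, win, patch);
        quantize_local(patch, n_gray, q);
      }
      double acc = 0.0;
      for (int d = 0; d < 4; ++d) {
        double S = 0.0;
        int n_r = 0;
        runs_direction(q, win, drs[d], dcs[d], S, n_r);
        acc += S / n_r;
      }
      out(r, c) = acc / 4.0;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix glcm_corr_map_cpp(NumericMatrix img, int win, int n_gray,
                                bool global_norm) {
  int n = img.nrow(), m = img.ncol(), h = win / 2, np = win * win;
  NumericMatrix out(n, m);
  std::vector<double> patch(np);
  std::vector<int> q(np), Fg;
  std::vector<double> C(n_gray * n_gray);
  const int drs[4] = {0, -1, -1, -1};
  const int dcs[4] = {1, 1, 0, -1};
  if (global_norm) {
    Fg.resize(n * m);
    std::vector<double> v(img.begin(), img.end());
    quantize_local(v, n_gray, Fg);
  }

  for (int c = 0; c < m; ++c) {
    for (int r = 0; r < n; ++r) {
      if (global_norm) {
        extract_window_int(Fg, n, m, r, c, h, win, q);
      } else {
        extract_window(img, r, c, h, win, patch);
        quantize_local(patch, n_gray, q);
      }
      double acc = 0.0;
      for (int d = 0; d < 4; ++d) {
        std::fill(C.begin(), C.end(), 0.0);
        double tot = 0.0;
        for (int pc = 0; pc < win; ++pc) {
          for (int pr = 0; pr < win; ++pr) {
            int r2 = pr + drs[d], c2 = pc + dcs[d];
            if (r2 < 0 || r2 >= win || c2 < 0 || c2 >= win) continue;
            int a = q[pc * win + pr] - 1, b = q[c2 * win + r2] - 1;
            C[b * n_gray + a] += 1.0;
            C[a * n_gray + b] += 1.0;
            tot += 2.0;
          }
        }
        if (tot == 0.0) continue;  // correlation defined as 0
        double mu_i = 0.0, mu_j = 0.0;
        for (int j = 1; j <= n_gray; ++j) {
          for (int i = 1; i <= n_gray; ++i) {
            double p = C[(j - 1) * n_gray + (i - 1)] / tot;
            mu_i += i * p;
            mu_j += j * p;
          }
        }
        double v_i = 0.0, v_j = 0.0, cov = 0.0;
        for (int j = 1; j <= n_gray; ++j) {
          for (int i = 1; i <= n_gray; ++i) {
            double p = C[(j - 1) * n_gray + (i - 1)] / tot;
            v_i += (i - mu_i) * (i - mu_i) * p;
            v_j += (j - mu_j) * (j - mu_j) * p;
            cov += (i - mu_i) * (j - mu_j) * p;
          }
        }
        double s = std::sqrt(v_i) * std::sqrt(v_j);
        if (s >= 1e-12) acc += cov / s;
      }
      out(r, c) = acc / 4.0;
    }
  }
  return out;
}
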
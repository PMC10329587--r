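// Low-level numerical kernels for the slice-segmentation network and the
// 3D evaluation metrics. All image batches use the R array layout
// (H, W, C, N), column-major, so H varies fastest.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4D array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col for one sample: M is (Ho*Wo) x (kh*kw*Cin); column index k runs over
// (dh, dw, cin) with dh fastest, matching the (kh, kw, Cin, Cout) weight
// layout flattened column-major.
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* Mbase, size_t ld,
                   size_t row_off) {
  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = x + (size_t)cin * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int k = dh + kh * (dw + kw * cin);
        double* Mcol = Mbase + (size_t)k * ld + row_off;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dw;
          double* Mp = Mcol + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(Mp, Mp + Ho, 0.0);
            continue;
          }
          const double* xcw = xc + (size_t)wi * H;
          if (stride == 1) {
            // contiguous run: ho -> hi = ho - pad + dh
            int off = dh - pad;
            int h0 = std::max(0, -off);           // first valid ho
            int h1 = std::min(Ho, H - off);       // one past last valid
            if (h0 > 0) std::fill(Mp, Mp + h0, 0.0);
            if (h1 > h0)
              std::memcpy(Mp + h0, xcw + h0 + off,
                          (size_t)(h1 - h0) * sizeof(double));
            if (h1 < Ho) std::fill(Mp + std::max(h1, 0), Mp + Ho, 0.0);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + dh;
              Mp[ho] = (hi < 0 || hi >= H) ? 0.0 : xcw[hi];
            }
          }
        }
      }
    }
  }
}

static void col2im_acc(const double* Gbase, size_t ld, size_t row_off,
                       int H, int W, int Cin,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* gx) {
  for (int cin = 0; cin < Cin; ++cin) {
    double* gc = gx + (size_t)cin * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int k = dh + kh * (dw + kw * cin);
        const double* Gcol = Gbase + (size_t)k * ld + row_off;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dw;
          if (wi < 0 || wi >= W) continue;
          const double* Gp = Gcol + (size_t)wo * Ho;
          double* gcw = gc + (size_t)wi * H;
          if (stride == 1) {
            int off = dh - pad;
            int h0 = std::max(0, -off);
            int h1 = std::min(Ho, H - off);
            double* dst = gcw + off;
            for (int ho = h0; ho < h1; ++ho) dst[ho] += Gp[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + dh;
              if (hi >= 0 && hi < H) gcw[hi] += Gp[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
SEXP cpp_conv2d_fwd(NumericVector x, NumericVector w,
                    NumericVector b, int stride, int pad,
                    bool keep_col = false) {
  int dx[4], dw[4];
  get_dim4(x, dx); get_dim4(w, dw);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("channel mismatch between input and weights");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * Cin;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y(no_init(Ho * (size_t)Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  size_t rows = (size_t)N * Ho * Wo;
  size_t hw = (size_t)Ho * Wo;
  // unrolled patches for the whole batch; optionally returned so the
  // backward pass can reuse them
  NumericVector colbuf;
  arma::mat Mown;
  double* mbase;
  if (keep_col) {
    colbuf = NumericVector(no_init(rows * K));
    colbuf.attr("dim") = IntegerVector::create(rows, K);
    mbase = colbuf.begin();
  } else {
    Mown.set_size(rows, K);
    mbase = Mown.memptr();
  }
  for (int n = 0; n < N; ++n)
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, stride, pad, Ho, Wo, mbase, rows, (size_t)n * hw);
  arma::mat Mall(mbase, rows, K, false, true);
  arma::mat Yall = Mall * Wm;             // one gemm for the batch
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      const double* src = Yall.colptr(c) + (size_t)n * hw;
      double* dst = y.begin() + ((size_t)n * Cout + c) * hw;
      double bc = b[c];
      for (size_t i = 0; i < hw; ++i) dst[i] = src[i] + bc;
    }
  if (keep_col) return List::create(_["y"] = y, _["col"] = colbuf);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad,
                    Nullable<NumericVector> col = R_NilValue) {
  int dx[4], dw[4], dg[4];
  get_dim4(x, dx); get_dim4(w, dw); get_dim4(gy, dg);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  int Ho = dg[0], Wo = dg[1];
  int K = kh * kw * Cin;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  arma::mat GW(gw.begin(), K, Cout, false, true);

  NumericVector colbuf;
  bool cached = col.isNotNull();
  if (cached) colbuf = col.get();

  size_t rows = (size_t)N * Ho * Wo;
  size_t hw = (size_t)Ho * Wo;
  arma::mat Mown;
  double* mbase;
  if (cached) {
    mbase = colbuf.begin();
  } else {
    Mown.set_size(rows, K);
    mbase = Mown.memptr();
    for (int n = 0; n < N; ++n)
      im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
             kh, kw, stride, pad, Ho, Wo, mbase, rows, (size_t)n * hw);
  }
  arma::mat Mall(mbase, rows, K, false, true);

  // gather gy (Ho, Wo, Cout, N) into a (N*HoWo) x Cout matrix
  arma::mat GYall(rows, Cout);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      std::memcpy(GYall.colptr(c) + (size_t)n * hw,
                  gy.begin() + ((size_t)n * Cout + c) * hw,
                  hw * sizeof(double));
  GW = Mall.t() * GYall;
  for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(GYall.col(c));
  arma::mat Gcol = GYall * Wm.t();
  for (int n = 0; n < N; ++n)
    col2im_acc(Gcol.memptr(), rows, (size_t)n * hw, H, W, Cin,
               kh, kw, stride, pad, Ho, Wo,
               gx.begin() + (size_t)n * H * W * Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Elementwise ReLU and its backward.
// [[Rcpp::export(name = ".cpp_relu")]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector gy) {
  NumericVector g(no_init(gy.size()));
  g.attr("dim") = gy.attr("dim");
  const double* py = y.begin();
  const double* pg = gy.begin();
  double* q = g.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) q[i] = py[i] > 0 ? pg[i] : 0;
  return g;
}

// Fused per-channel affine: y[h,w,c,n] = x[h,w,c,n] * a[c] + b[c].
// [[Rcpp::export(name = ".cpp_chan_affine")]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector a,
                              NumericVector b) {
  int d[4]; get_dim4(x, d);
  size_t hw = (size_t)d[0] * d[1];
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      double ac = a[c], bc = b[c];
      const double* ps = p + hw * (c + (size_t)d[2] * n);
      double* qs = q + hw * (c + (size_t)d[2] * n);
      for (size_t i = 0; i < hw; ++i) qs[i] = ps[i] * ac + bc;
    }
  return y;
}

// One-pass per-channel sums of x and x*y over (H, W, N).
// [[Rcpp::export(name = ".cpp_chan_sums2")]]
List cpp_chan_sums2(NumericVector x, NumericVector y) {
  int d[4]; get_dim4(x, d);
  size_t hw = (size_t)d[0] * d[1];
  NumericVector s1(d[2]), s2(d[2]);
  const double* px = x.begin();
  const double* py = y.begin();
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      const double* xs = px + hw * (c + (size_t)d[2] * n);
      const double* ys = py + hw * (c + (size_t)d[2] * n);
      double a = 0.0, b = 0.0;
      for (size_t i = 0; i < hw; ++i) { a += xs[i]; b += xs[i] * ys[i]; }
      s1[c] += a; s2[c] += b;
    }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// Bilinear resize, half-pixel centers (align_corners = FALSE), edge clamp.
static inline void lin_coef(int o, int In, double scale, int& i0, int& i1,
                            double& w0, double& w1) {
  double s = (o + 0.5) * scale - 0.5;
  if (s < 0) s = 0;
  if (s > In - 1) s = In - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < In ? i0 + 1 : In - 1;
  w1 = s - i0;
  w0 = 1.0 - w1;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_fwd")]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;

  std::vector<int> h0(Ho), h1(Ho), w0i(Wo), w1i(Wo);
  std::vector<double> ha(Ho), hb(Ho), wa(Wo), wb(Wo);
  for (int ho = 0; ho < Ho; ++ho) lin_coef(ho, H, sh, h0[ho], h1[ho], ha[ho], hb[ho]);
  for (int wo = 0; wo < Wo; ++wo) lin_coef(wo, W, sw, w0i[wo], w1i[wo], wa[wo], wb[wo]);

  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * H * W;
    double* yp = y.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* xa = xp + (size_t)w0i[wo] * H;
      const double* xb = xp + (size_t)w1i[wo] * H;
      double* yc = yp + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        yc[ho] = wa[wo] * (ha[ho] * xa[h0[ho]] + hb[ho] * xa[h1[ho]])
               + wb[wo] * (ha[ho] * xb[h0[ho]] + hb[ho] * xb[h1[ho]]);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_bwd")]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gy, int H, int W) {
  int d[4]; get_dim4(gy, d);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;

  std::vector<int> h0(Ho), h1(Ho), w0i(Wo), w1i(Wo);
  std::vector<double> ha(Ho), hb(Ho), wa(Wo), wb(Wo);
  for (int ho = 0; ho < Ho; ++ho) lin_coef(ho, H, sh, h0[ho], h1[ho], ha[ho], hb[ho]);
  for (int wo = 0; wo < Wo; ++wo) lin_coef(wo, W, sw, w0i[wo], w1i[wo], wa[wo], wb[wo]);

  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gp = gy.begin() + cn * Ho * Wo;
    double* xp = gx.begin() + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      double* xa = xp + (size_t)w0i[wo] * H;
      double* xb = xp + (size_t)w1i[wo] * H;
      const double* gc = gp + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        double g = gc[ho];
        xa[h0[ho]] += wa[wo] * ha[ho] * g;
        xa[h1[ho]] += wa[wo] * hb[ho] * g;
        xb[h0[ho]] += wb[wo] * ha[ho] * g;
        xb[h1[ho]] += wb[wo] * hb[ho] * g;
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".cpp_resize_nearest")]]
NumericVector cpp_resize_nearest(NumericVector x, int Ho, int Wo) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> hi(Ho), wi(Wo);
  for (int ho = 0; ho < Ho; ++ho)
    hi[ho] = std::min((int)std::floor((ho + 0.5) * H / Ho), H - 1);
  for (int wo = 0; wo < Wo; ++wo)
    wi[wo] = std::min((int)std::floor((wo + 0.5) * W / Wo), W - 1);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * H * W;
    double* yp = y.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yp[ho + (size_t)wo * Ho] = xp[hi[ho] + (size_t)wi[wo] * H];
  }
  return y;
}

// Softmax over the channel dimension of an (H, W, C, N) array.
// [[Rcpp::export(name = ".cpp_softmax_ch")]]
NumericVector cpp_softmax_ch(NumericVector x) {
  int d[4]; get_dim4(x, d);
  size_t hw = (size_t)d[0] * d[1];
  int C = d[2];
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (int n = 0; n < d[3]; ++n) {
    const double* pn = p + hw * C * (size_t)n;
    double* qn = q + hw * C * (size_t)n;
    for (size_t i = 0; i < hw; ++i) {
      double mx = pn[i];
      for (int c = 1; c < C; ++c) {
        double v = pn[i + hw * c];
        if (v > mx) mx = v;
      }
      double tot = 0.0;
      for (int c = 0; c < C; ++c) {
        double e = std::exp(pn[i + hw * c] - mx);
        qn[i + hw * c] = e;
        tot += e;
      }
      for (int c = 0; c < C; ++c) qn[i + hw * c] /= tot;
    }
  }
  return y;
}

// Surface voxels of a 3D binary mask (z, y, x layout): foreground voxels
// with at least one background 6-neighbour; outside the array counts as
// background. Returns an n x 3 matrix of 1-based (z, y, x) indices.
// [[Rcpp::export(name = ".cpp_surface_voxels")]]
IntegerMatrix cpp_surface_voxels(IntegerVector mask) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("expected a 3D array");
  int Z = dm[0], Y = dm[1], X = dm[2];
  const int* m = mask.begin();
  auto at = [&](int z, int y, int x) -> int {
    if (z < 0 || z >= Z || y < 0 || y >= Y || x < 0 || x >= X) return 0;
    return m[z + (size_t)Z * (y + (size_t)Y * x)];
  };
  std::vector<int> out;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        if (!at(z, y, x)) continue;
        if (!at(z - 1, y, x) || !at(z + 1, y, x) ||
            !at(z, y - 1, x) || !at(z, y + 1, x) ||
            !at(z, y, x - 1) || !at(z, y, x + 1)) {
          out.push_back(z + 1); out.push_back(y + 1); out.push_back(x + 1);
        }
      }
  int n = out.size() / 3;
  IntegerMatrix res(n, 3);
  for (int i = 0; i < n; ++i) {
    res(i, 0) = out[3 * i]; res(i, 1) = out[3 * i + 1]; res(i, 2) = out[3 * i + 2];
  }
  return res;
}

// For each point in P (n1 x 3, physical mm), the distance to the nearest
// point in Q (n2 x 3). Brute force; surfaces at desk scale are small.
// [[Rcpp::export(name = ".cpp_min_dists")]]
NumericVector cpp_min_dists(NumericMatrix P, NumericMatrix Q) {
  int n1 = P.nrow(), n2 = Q.nrow();
  NumericVector out(n1);
  for (int i = 0; i < n1; ++i) {
    double best = R_PosInf;
    double p0 = P(i, 0), p1 = P(i, 1), p2 = P(i, 2);
    for (int j = 0; j < n2; ++j) {
      double d0 = p0 - Q(j, 0), d1 = p1 - Q(j, 1), d2 = p2 - Q(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Connected-component labelling of a 3D binary mask under 26-connectivity.
// [[Rcpp::export(name = ".cpp_label26")]]
IntegerVector cpp_label26(IntegerVector mask) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("expected a 3D array");
  int Z = dm[0], Y = dm[1], X = dm[2];
  size_t V = (size_t)Z * Y * X;
  IntegerVector lab(V);
  lab.attr("dim") = dm;
  const int* m = mask.begin();
  int* l = lab.begin();
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < V; ++s) {
    if (!m[s] || l[s]) continue;
    ++cur;
    stack.push_back(s);
    l[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int z = v % Z, y = (v / Z) % Y, x = v / ((size_t)Z * Y);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X)
              continue;
            size_t u = zz + (size_t)Z * (yy + (size_t)Y * xx);
            if (m[u] && !l[u]) { l[u] = cur; stack.push_back(u); }
          }
    }
  }
  return lab;
}
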
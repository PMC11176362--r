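// Gated dilated convolutional network engine.
//
// The network maps a 4 x L real plane (a packed complex FID) to a plane of
// the same shape. It is a stack of residual units; each unit applies a
// dilated convolution with kernel 8 (time) x 4 (rows), splits the filters
// into a sigmoid half and a tanh half whose elementwise product forms the
// gated activation, applies a second 8 x 4 convolution, and adds its output
// both to a skip aggregate (which, after a 1x1 projection, forms the network
// output) and to the unit input (feeding the next unit). Training minimises
// the mean squared error between the real parts of the discrete Fourier
// transforms of the predicted and target planes, with RMSprop.
//
// Feature maps are stored as (channels x positions) matrices with position
// index p = r + 4*(t + L*b) over rows r, time t and batch member b.
// Convolution is implemented as im2col + GEMM; "same" padding follows the
// usual even-kernel convention (left pad 1/3d, right pad 2/4d).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int RR = 4;   // plane rows
static const int KR = 4;   // kernel extent along rows
static const int KT = 8;   // kernel extent along time

struct NetShape {
  int L;            // plane columns
  int F;            // filters per convolutional layer (even)
  int half;         // F / 2
  std::vector<int> dil;
};

struct Params {
  mat Win;  vec bin;
  std::vector<mat> Wa, Wb;
  std::vector<vec> ba, bb;
  mat Wout; vec bout;
};

static mat get_mat(Rcpp::List& lst, int i) {
  Rcpp::NumericMatrix m = lst[i];
  return mat(m.begin(), m.nrow(), m.ncol());  // owning copy
}
static vec get_vec(Rcpp::List& lst, int i) {
  Rcpp::NumericVector v = lst[i];
  return vec(v.begin(), v.size());
}
static void put_mat(Rcpp::List& lst, int i, const mat& x) {
  Rcpp::NumericMatrix m = lst[i];
  std::copy(x.begin(), x.end(), m.begin());
}
static void put_vec(Rcpp::List& lst, int i, const vec& x) {
  Rcpp::NumericVector v = lst[i];
  std::copy(x.begin(), x.end(), v.begin());
}

// params list layout: Win, bin, {Wa, ba, Wb, bb} per unit, Wout, bout
static Params read_params(Rcpp::List& lst, int n_units) {
  Params p;
  p.Win = get_mat(lst, 0); p.bin = get_vec(lst, 1);
  for (int u = 0; u < n_units; ++u) {
    p.Wa.push_back(get_mat(lst, 2 + 4 * u));
    p.ba.push_back(get_vec(lst, 3 + 4 * u));
    p.Wb.push_back(get_mat(lst, 4 + 4 * u));
    p.bb.push_back(get_vec(lst, 5 + 4 * u));
  }
  p.Wout = get_mat(lst, 2 + 4 * n_units);
  p.bout = get_vec(lst, 3 + 4 * n_units);
  return p;
}

static void write_params(Rcpp::List& lst, const Params& p, int n_units) {
  put_mat(lst, 0, p.Win); put_vec(lst, 1, p.bin);
  for (int u = 0; u < n_units; ++u) {
    put_mat(lst, 2 + 4 * u, p.Wa[u]);
    put_vec(lst, 3 + 4 * u, p.ba[u]);
    put_mat(lst, 4 + 4 * u, p.Wb[u]);
    put_vec(lst, 5 + 4 * u, p.bb[u]);
  }
  put_mat(lst, 2 + 4 * n_units, p.Wout);
  put_vec(lst, 3 + 4 * n_units, p.bout);
}

// The 8 x 4 kernel is split into its row extent (handled by a row-patch
// matrix built once per convolution input) and its dilated time extent
// (handled by shifted-column subview GEMMs, one per time tap). This keeps
// the materialised patch matrix KT-fold smaller than a full im2col.

// row patches: X (C x P) -> Xr (C*KR x P); column p = r + 4*(t + L*b), so
// the row tap kr reads the column p + (kr - 1) when the row stays in range.
static void im2row(const mat& X, mat& Xr, int C) {
  const int P = (int)X.n_cols;
  const size_t bytes = C * sizeof(double);
  for (int p = 0; p < P; ++p) {
    const int r = p & 3;
    double* dst = Xr.colptr(p);
    for (int kr = 0; kr < KR; ++kr) {
      const int rr = r + kr - 1;
      if (rr >= 0 && rr < RR) {
        std::memcpy(dst + C * kr, X.colptr(p + kr - 1), bytes);
      } else {
        std::memset(dst + C * kr, 0, bytes);
      }
    }
  }
}

// transpose scatter-add of im2row: dXr (C*KR x P) into dX (C x P)
static void row2im_add(const mat& dXr, mat& dX, int C) {
  const int P = (int)dX.n_cols;
  dX.zeros();
  for (int p = 0; p < P; ++p) {
    const int r = p & 3;
    const double* src = dXr.colptr(p);
    for (int kr = 0; kr < KR; ++kr) {
      const int rr = r + kr - 1;
      if (rr >= 0 && rr < RR) {
        double* dst = dX.colptr(p + kr - 1);
        for (int c = 0; c < C; ++c) dst[c] += src[C * kr + c];
      }
    }
  }
}

// dilated time-axis convolution via shifted subview GEMMs:
//   A(:, dest) += W_kt * Xr(:, src) for every time tap and batch member.
// W has KT column blocks of width C*KR (tap-major layout).
static void conv_time(const mat& W, const mat& Xr, mat& A, int L, int B,
                      int d) {
  const int ckr = (int)W.n_cols / KT;
  for (int b = 0; b < B; ++b) {
    const int base = RR * L * b;
    for (int kt = 0; kt < KT; ++kt) {
      const int ot = (kt - 3) * d;
      const int t0 = std::max(0, -ot), t1 = std::min(L, L - ot);
      if (t1 <= t0) continue;
      A.cols(base + RR * t0, base + RR * t1 - 1) +=
        W.cols(kt * ckr, (kt + 1) * ckr - 1) *
        Xr.cols(base + RR * (t0 + ot), base + RR * (t1 + ot) - 1);
    }
  }
}

// gradient of conv_time with respect to the weights
static void conv_time_dW(mat& dW, const mat& dA, const mat& Xr, int L, int B,
                         int d) {
  const int ckr = (int)dW.n_cols / KT;
  for (int b = 0; b < B; ++b) {
    const int base = RR * L * b;
    for (int kt = 0; kt < KT; ++kt) {
      const int ot = (kt - 3) * d;
      const int t0 = std::max(0, -ot), t1 = std::min(L, L - ot);
      if (t1 <= t0) continue;
      dW.cols(kt * ckr, (kt + 1) * ckr - 1) +=
        dA.cols(base + RR * t0, base + RR * t1 - 1) *
        Xr.cols(base + RR * (t0 + ot), base + RR * (t1 + ot) - 1).t();
    }
  }
}

// gradient of conv_time with respect to the row-patch input
static void conv_time_dX(const mat& W, const mat& dA, mat& dXr, int L, int B,
                         int d) {
  const int ckr = (int)W.n_cols / KT;
  dXr.zeros();
  for (int b = 0; b < B; ++b) {
    const int base = RR * L * b;
    for (int kt = 0; kt < KT; ++kt) {
      const int ot = (kt - 3) * d;
      const int t0 = std::max(0, -ot), t1 = std::min(L, L - ot);
      if (t1 <= t0) continue;
      dXr.cols(base + RR * (t0 + ot), base + RR * (t1 + ot) - 1) +=
        W.cols(kt * ckr, (kt + 1) * ckr - 1).t() *
        dA.cols(base + RR * t0, base + RR * t1 - 1);
    }
  }
}

struct Cache {
  std::vector<mat> Hr;   // row patches of unit inputs
  std::vector<mat> A;    // pre-activations
  std::vector<mat> Gr;   // row patches of gated products
  mat skip;
  mat Y;                 // 1 x P output
  // persistent scratch reused across batches
  mat H, A1, G, U, dU, dG, dGr, dH, dHr, sig, th, dA, dskip, g;
  mat HrScratch, GrScratch;  // inference-only row patches (not kept per unit)
};

static void forward(const Params& prm, const NetShape& ns, const mat& X0,
                    int B, Cache& cc, bool keep) {
  const int P = RR * ns.L * B;
  cc.H = prm.Win * X0;
  cc.H.each_col() += prm.bin;
  cc.skip.zeros(ns.F, P);
  const int n_units = (int)ns.dil.size();
  if (keep) {
    cc.Hr.resize(n_units);
    cc.Gr.resize(n_units);
    cc.A.resize(n_units);
  }
  for (int u = 0; u < n_units; ++u) {
    mat& Hr = keep ? cc.Hr[u] : cc.HrScratch;
    Hr.set_size(ns.F * KR, P);
    im2row(cc.H, Hr, ns.F);
    cc.A1.set_size(ns.F, P);
    cc.A1.each_col() = prm.ba[u];
    conv_time(prm.Wa[u], Hr, cc.A1, ns.L, B, ns.dil[u]);
    cc.G = (1.0 / (1.0 + exp(-cc.A1.rows(0, ns.half - 1)))) %
           tanh(cc.A1.rows(ns.half, ns.F - 1));
    if (keep) cc.A[u] = cc.A1;
    mat& Gr = keep ? cc.Gr[u] : cc.GrScratch;
    Gr.set_size(ns.half * KR, P);
    im2row(cc.G, Gr, ns.half);
    cc.U.set_size(ns.F, P);
    cc.U.each_col() = prm.bb[u];
    conv_time(prm.Wb[u], Gr, cc.U, ns.L, B, ns.dil[u]);
    cc.skip += cc.U;
    cc.H += cc.U;
  }
  cc.Y = prm.Wout * cc.skip;
  cc.Y.each_col() += prm.bout;
}

// loss (mean over batch of mean-over-bins squared error of Re(FFT)) and its
// gradient with respect to the output planes
static double loss_and_grad(const mat& Y, const mat& T, int L, int B,
                            mat* dY) {
  double total = 0.0;
  if (dY) dY->zeros();
  for (int b = 0; b < B; ++b) {
    cx_vec zp(L), zt(L);
    const int base = RR * L * b;
    for (int t = 0; t < L; ++t) {
      zp(t) = cx_double(Y(0, base + RR * t), Y(0, base + 1 + RR * t));
      zt(t) = cx_double(T(0, base + RR * t), T(0, base + 1 + RR * t));
    }
    vec e = real(fft(zp)) - real(fft(zt));
    total += mean(square(e));
    if (dY) {
      cx_vec fe = fft(conv_to<cx_vec>::from(e));
      const double s = 2.0 / (double)(L * B);
      for (int t = 0; t < L; ++t) {
        (*dY)(0, base + RR * t) = s * fe(t).real();
        (*dY)(0, base + 1 + RR * t) = -s * fe(t).imag();
      }
    }
  }
  return total / B;
}

struct Grads {
  Params g;
  static Grads like(const Params& p) {
    Grads gr;
    gr.g.Win = zeros(size(p.Win)); gr.g.bin = zeros(size(p.bin));
    for (size_t u = 0; u < p.Wa.size(); ++u) {
      gr.g.Wa.push_back(zeros(size(p.Wa[u])));
      gr.g.ba.push_back(zeros(size(p.ba[u])));
      gr.g.Wb.push_back(zeros(size(p.Wb[u])));
      gr.g.bb.push_back(zeros(size(p.bb[u])));
    }
    gr.g.Wout = zeros(size(p.Wout)); gr.g.bout = zeros(size(p.bout));
    return gr;
  }
  void zero() {
    g.Win.zeros(); g.bin.zeros();
    for (size_t u = 0; u < g.Wa.size(); ++u) {
      g.Wa[u].zeros(); g.ba[u].zeros(); g.Wb[u].zeros(); g.bb[u].zeros();
    }
    g.Wout.zeros(); g.bout.zeros();
  }
};

static void backward(const Params& prm, const NetShape& ns, const mat& X0,
                     int B, Cache& cc, const mat& dY, Grads& gr) {
  const int P = RR * ns.L * B;
  const int n_units = (int)ns.dil.size();
  gr.g.Wout += dY * cc.skip.t();
  gr.g.bout += sum(dY, 1);
  cc.dskip = prm.Wout.t() * dY;
  cc.g.zeros(ns.F, P);
  cc.dG.set_size(ns.half, P);
  cc.dGr.set_size(ns.half * KR, P);
  cc.dH.set_size(ns.F, P);
  cc.dHr.set_size(ns.F * KR, P);
  for (int u = n_units - 1; u >= 0; --u) {
    const int d = ns.dil[u];
    cc.dU = cc.g + cc.dskip;
    // second convolution
    conv_time_dW(gr.g.Wb[u], cc.dU, cc.Gr[u], ns.L, B, d);
    gr.g.bb[u] += sum(cc.dU, 1);
    conv_time_dX(prm.Wb[u], cc.dU, cc.dGr, ns.L, B, d);
    row2im_add(cc.dGr, cc.dG, ns.half);
    // gated activation
    cc.sig = 1.0 / (1.0 + exp(-cc.A[u].rows(0, ns.half - 1)));
    cc.th = tanh(cc.A[u].rows(ns.half, ns.F - 1));
    cc.dA = join_cols(cc.dG % cc.th % cc.sig % (1.0 - cc.sig),
                      cc.dG % cc.sig % (1.0 - cc.th % cc.th));
    // first convolution
    conv_time_dW(gr.g.Wa[u], cc.dA, cc.Hr[u], ns.L, B, d);
    gr.g.ba[u] += sum(cc.dA, 1);
    conv_time_dX(prm.Wa[u], cc.dA, cc.dHr, ns.L, B, d);
    row2im_add(cc.dHr, cc.dH, ns.F);
    cc.g += cc.dH;
  }
  gr.g.Win += cc.g * X0.t();
  gr.g.bin += sum(cc.g, 1);
}

static void rms_update(mat& w, mat& v, const mat& g, double lr) {
  const double rho = 0.9, eps = 1e-7;
  v = rho * v + (1.0 - rho) * square(g);
  w -= lr * g / (sqrt(v) + eps);
}
static void rms_update(vec& w, vec& v, const vec& g, double lr) {
  const double rho = 0.9, eps = 1e-7;
  v = rho * v + (1.0 - rho) * square(g);
  w -= lr * g / (sqrt(v) + eps);
}

// copy selected samples (1-based ids) of a (4, L, n) array into a batch mat
static mat gather_batch(const double* src, int L, const std::vector<int>& ids) {
  const int per = RR * L;
  mat X(1, per * (int)ids.size());
  for (size_t k = 0; k < ids.size(); ++k) {
    std::memcpy(X.colptr(0) + per * k, src + (size_t)per * (ids[k] - 1),
                per * sizeof(double));
  }
  return X;
}

static NetShape make_shape(Rcpp::IntegerVector dilations, int filters, int L) {
  NetShape ns;
  ns.L = L; ns.F = filters; ns.half = filters / 2;
  if (filters % 2 != 0) Rcpp::stop("filters must be even (gating splits them in half)");
  ns.dil = std::vector<int>(dilations.begin(), dilations.end());
  return ns;
}

// One pass over the data in the given order. With update = true performs
// mini-batch RMSprop updates (modifying params and vcache in place) and
// returns the mean training loss; with update = false only evaluates the
// mean loss.
// [[Rcpp::export]]
double fidnet_epoch_cpp(Rcpp::List params, Rcpp::List vcache,
                        Rcpp::NumericVector input, Rcpp::NumericVector target,
                        Rcpp::IntegerVector dims, Rcpp::IntegerVector order,
                        Rcpp::IntegerVector dilations, int filters,
                        double lr, int batch_size, bool update) {
  const int L = dims[1];
  const int n_units = dilations.size();
  NetShape ns = make_shape(dilations, filters, L);
  Params prm = read_params(params, n_units);
  Params vc;
  if (update) vc = read_params(vcache, n_units);

  double loss_sum = 0.0;
  int n_batches = 0;
  std::vector<int> ids;
  Cache cc;
  Grads gr = Grads::like(prm);
  mat dY;
  for (int start = 0; start < order.size(); start += batch_size) {
    ids.clear();
    for (int i = start; i < std::min((int)order.size(), start + batch_size); ++i) {
      ids.push_back(order[i]);
    }
    const int B = (int)ids.size();
    mat X0 = gather_batch(input.begin(), L, ids);
    mat T0 = gather_batch(target.begin(), L, ids);
    forward(prm, ns, X0, B, cc, update);
    if (update) dY.set_size(1, RR * L * B);
    double l = loss_and_grad(cc.Y, T0, L, B, update ? &dY : nullptr);
    if (!std::isfinite(l)) {
      Rcpp::stop("non-finite loss encountered (training diverged)");
    }
    loss_sum += l;
    ++n_batches;
    if (update) {
      gr.zero();
      backward(prm, ns, X0, B, cc, dY, gr);
      rms_update(prm.Win, vc.Win, gr.g.Win, lr);
      rms_update(prm.bin, vc.bin, gr.g.bin, lr);
      for (int u = 0; u < n_units; ++u) {
        rms_update(prm.Wa[u], vc.Wa[u], gr.g.Wa[u], lr);
        rms_update(prm.ba[u], vc.ba[u], gr.g.ba[u], lr);
        rms_update(prm.Wb[u], vc.Wb[u], gr.g.Wb[u], lr);
        rms_update(prm.bb[u], vc.bb[u], gr.g.bb[u], lr);
      }
      rms_update(prm.Wout, vc.Wout, gr.g.Wout, lr);
      rms_update(prm.bout, vc.bout, gr.g.bout, lr);
    }
    Rcpp::checkUserInterrupt();
  }
  if (update) {
    write_params(params, prm, n_units);
    write_params(vcache, vc, n_units);
  }
  return loss_sum / n_batches;
}

// Analytic gradient of the mean loss over the batch with respect to every
// parameter, in the same list layout as params. Used to validate the
// backward pass against finite differences.
// [[Rcpp::export]]
Rcpp::List fidnet_grad_cpp(Rcpp::List params, Rcpp::NumericVector input,
                           Rcpp::NumericVector target,
                           Rcpp::IntegerVector dims,
                           Rcpp::IntegerVector dilations, int filters) {
  const int L = dims[1];
  const int n = dims[2];
  const int n_units = dilations.size();
  NetShape ns = make_shape(dilations, filters, L);
  Params prm = read_params(params, n_units);
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) ids[i] = i + 1;
  mat X0 = gather_batch(input.begin(), L, ids);
  mat T0 = gather_batch(target.begin(), L, ids);
  Cache cc;
  forward(prm, ns, X0, n, cc, true);
  mat dY(1, RR * L * n);
  loss_and_grad(cc.Y, T0, L, n, &dY);
  Grads gr = Grads::like(prm);
  backward(prm, ns, X0, n, cc, dY, gr);
  Rcpp::List out(params.size());
  Rcpp::List tmp = Rcpp::clone(params);
  write_params(tmp, gr.g, n_units);
  return tmp;
}

// Deterministic batched inference: input array (4, L, n) -> same shape.
// [[Rcpp::export]]
Rcpp::NumericVector fidnet_predict_cpp(Rcpp::List params,
                                       Rcpp::NumericVector input,
                                       Rcpp::IntegerVector dims,
                                       Rcpp::IntegerVector dilations,
                                       int filters, int batch_size) {
  const int L = dims[1];
  const int n = dims[2];
  const int n_units = dilations.size();
  NetShape ns = make_shape(dilations, filters, L);
  Params prm = read_params(params, n_units);
  Rcpp::NumericVector out(input.size());
  out.attr("dim") = dims;
  const int per = RR * L;
  std::vector<int> ids;
  for (int start = 0; start < n; start += batch_size) {
    ids.clear();
    for (int i = start; i < std::min(n, start + batch_size); ++i) ids.push_back(i + 1);
    const int B = (int)ids.size();
    mat X0 = gather_batch(input.begin(), L, ids);
    Cache cc;
    forward(prm, ns, X0, B, cc, false);
    for (int k = 0; k < B; ++k) {
      std::memcpy(out.begin() + (size_t)per * (ids[k] - 1),
                  cc.Y.colptr(0) + per * k, per * sizeof(double));
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
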
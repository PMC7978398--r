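#include <Rcpp.h>
using namespace Rcpp;

// 1D "same" convolution (cross-correlation) for multichannel signals.
// x: n x Cin signal, W: k x Cin x Cout kernel (dim attribute), b: length Cout.
// Output t indexes the window x[t - pad .. t - pad + k - 1]; samples outside
// [0, n) are treated as zero.

static void get_dims(const NumericVector& W, int& k, int& cin, int& cout) {
  IntegerVector d = W.attr("dim");
  if (d.size() != 3) stop("kernel must be a k x Cin x Cout array");
  k = d[0]; cin = d[1]; cout = d[2];
}

// [[Rcpp::export]]
NumericMatrix conv1d_fwd(const NumericMatrix& x, const NumericVector& W,
                         const NumericVector& b, const int pad) {
  int n = x.nrow(), cin_x = x.ncol();
  int k, cin, cout;
  get_dims(W, k, cin, cout);
  if (cin != cin_x) stop("channel mismatch between signal and kernel");
  NumericMatrix y(n, cout);
  for (int co = 0; co < cout; ++co) {
    double bco = b[co];
    for (int t = 0; t < n; ++t) y(t, co) = bco;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = &x(0, ci);
      double* yc = &y(0, co);
      for (int i = 0; i < k; ++i) {
        double w = W[i + k * (ci + cin * co)];
        if (w == 0.0) continue;
        int off = i - pad;  // y[t] += w * x[t + off]
        int t0 = std::max(0, -off), t1 = std::min(n, n - off);
        for (int t = t0; t < t1; ++t) yc[t] += w * xc[t + off];
      }
    }
  }
  return y;
}

// Gradient of the loss w.r.t. the input signal: dx[s] = sum_i W[i] * dy[s - i + pad].
// [[Rcpp::export]]
NumericMatrix conv1d_bwd_input(const NumericMatrix& dy, const NumericVector& W,
                               const int n, const int pad) {
  int k, cin, cout;
  get_dims(W, k, cin, cout);
  if (dy.ncol() != cout) stop("channel mismatch between grad and kernel");
  if (dy.nrow() != n) stop("length mismatch between grad and signal");
  NumericMatrix dx(n, cin);
  for (int ci = 0; ci < cin; ++ci) {
    double* dxc = &dx(0, ci);
    for (int co = 0; co < cout; ++co) {
      const double* dyc = &dy(0, co);
      for (int i = 0; i < k; ++i) {
        double w = W[i + k * (ci + cin * co)];
        if (w == 0.0) continue;
        int off = pad - i;  // dx[s] += w * dy[s + off]
        int s0 = std::max(0, -off), s1 = std::min(n, n - off);
        for (int s = s0; s < s1; ++s) dxc[s] += w * dyc[s + off];
      }
    }
  }
  return dx;
}

// Gradient w.r.t. the kernel: dW[i,ci,co] = sum_t dy[t,co] * x[t + i - pad, ci].
// [[Rcpp::export]]
NumericVector conv1d_bwd_kernel(const NumericMatrix& x, const NumericMatrix& dy,
                                const int k, const int pad) {
  int n = x.nrow(), cin = x.ncol(), cout = dy.ncol();
  if (dy.nrow() != n) stop("length mismatch between signal and grad");
  NumericVector dW(k * cin * cout);
  for (int co = 0; co < cout; ++co) {
    const double* dyc = &dy(0, co);
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = &x(0, ci);
      for (int i = 0; i < k; ++i) {
        int off = i - pad;
        int t0 = std::max(0, -off), t1 = std::min(n, n - off);
        double acc = 0.0;
        for (int t = t0; t < t1; ++t) acc += dyc[t] * xc[t + off];
        dW[i + k * (ci + cin * co)] = acc;
      }
    }
  }
  dW.attr("dim") = IntegerVector::create(k, cin, cout);
  return dW;
}
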
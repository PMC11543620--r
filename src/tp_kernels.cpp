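#include <Rcpp.h>
using namespace Rcpp;

// Clebsch-Gordan tensor-product kernels on the flat channel-stacked layout
// (rows = edge x channel, columns = m). The nonzero coupling entries arrive
// as a (k x 3) 1-based index matrix plus their coefficients; doing the
// contraction here avoids one large temporary per nonzero entry. Raw column
// pointers keep the inner loops vectorizable.

// [[Rcpp::export(name = ".tp_forward_cpp")]]
NumericMatrix tp_forward_cpp(const NumericMatrix& x, const NumericMatrix& sh,
                             const NumericVector& w, const IntegerMatrix& nz,
                             const NumericVector& coef, int d3) {
  const size_t n = x.nrow();
  NumericMatrix out(n, d3);
  const double* xp = x.begin();
  const double* sp = sh.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int r = 0; r < nz.nrow(); ++r) {
    const size_t m1 = nz(r, 0) - 1, m2 = nz(r, 1) - 1, m3 = nz(r, 2) - 1;
    const double c = coef[r];
    const double* xc = xp + m1 * n;
    const double* sc = sp + m2 * n;
    double* oc = op + m3 * n;
    for (size_t k = 0; k < n; ++k) oc[k] += c * xc[k] * sc[k] * wp[k];
  }
  return out;
}

// scatter-add rows of x into nout groups (1-based idx)
// [[Rcpp::export(name = ".scatter_add_cpp")]]
NumericMatrix scatter_add_cpp(const NumericMatrix& x, const IntegerVector& idx,
                              int nout) {
  const size_t n = x.nrow(), d = x.ncol();
  NumericMatrix out(nout, d);
  const double* xp = x.begin();
  double* op = out.begin();
  const int* ip = idx.begin();
  for (size_t c = 0; c < d; ++c) {
    const double* xc = xp + c * n;
    double* oc = op + c * (size_t)nout;
    for (size_t k = 0; k < n; ++k) oc[ip[k] - 1] += xc[k];
  }
  return out;
}

// column-wise softmax within row segments (1-based idx, any order)
// [[Rcpp::export(name = ".seg_softmax_cpp")]]
NumericMatrix seg_softmax_cpp(const NumericMatrix& x, const IntegerVector& idx,
                              int nseg) {
  const size_t n = x.nrow(), d = x.ncol();
  NumericMatrix out(n, d);
  std::vector<double> mx(nseg), sm(nseg);
  const int* ip = idx.begin();
  for (size_t c = 0; c < d; ++c) {
    const double* xc = x.begin() + c * n;
    double* oc = out.begin() + c * n;
    std::fill(mx.begin(), mx.end(), -1e300);
    std::fill(sm.begin(), sm.end(), 0.0);
    for (size_t k = 0; k < n; ++k) {
      const int s = ip[k] - 1;
      if (xc[k] > mx[s]) mx[s] = xc[k];
    }
    for (size_t k = 0; k < n; ++k) {
      oc[k] = std::exp(xc[k] - mx[ip[k] - 1]);
      sm[ip[k] - 1] += oc[k];
    }
    for (size_t k = 0; k < n; ++k) oc[k] /= sm[ip[k] - 1];
  }
  return out;
}

// backward of segment softmax: s * (g - seg_dot(g, s))
// [[Rcpp::export(name = ".seg_softmax_bwd_cpp")]]
NumericMatrix seg_softmax_bwd_cpp(const NumericMatrix& g,
                                  const NumericMatrix& s,
                                  const IntegerVector& idx, int nseg) {
  const size_t n = g.nrow(), d = g.ncol();
  NumericMatrix out(n, d);
  std::vector<double> dot(nseg);
  const int* ip = idx.begin();
  for (size_t c = 0; c < d; ++c) {
    const double* gc = g.begin() + c * n;
    const double* sc = s.begin() + c * n;
    double* oc = out.begin() + c * n;
    std::fill(dot.begin(), dot.end(), 0.0);
    for (size_t k = 0; k < n; ++k) dot[ip[k] - 1] += gc[k] * sc[k];
    for (size_t k = 0; k < n; ++k) oc[k] = sc[k] * (gc[k] - dot[ip[k] - 1]);
  }
  return out;
}

// [[Rcpp::export(name = ".tp_backward_cpp")]]
List tp_backward_cpp(const NumericMatrix& g, const NumericMatrix& x,
                     const NumericMatrix& sh, const NumericVector& w,
                     const IntegerMatrix& nz, const NumericVector& coef,
                     int d1) {
  const size_t n = x.nrow();
  NumericMatrix gx(n, d1);
  NumericVector gw(n);
  const double* gp = g.begin();
  const double* xp = x.begin();
  const double* sp = sh.begin();
  const double* wp = w.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int r = 0; r < nz.nrow(); ++r) {
    const size_t m1 = nz(r, 0) - 1, m2 = nz(r, 1) - 1, m3 = nz(r, 2) - 1;
    const double c = coef[r];
    const double* gc = gp + m3 * n;
    const double* xc = xp + m1 * n;
    const double* sc = sp + m2 * n;
    double* gxc = gxp + m1 * n;
    for (size_t k = 0; k < n; ++k) {
      const double gm = c * gc[k] * sc[k];
      gxc[k] += gm * wp[k];
      gwp[k] += gm * xc[k];
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw);
}
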
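// Fused E(n)-equivariant graph layer: forward pass and exact reverse-mode
// backward in one compiled unit. The R-level autodiff tape treats the
// whole layer as a single operation; intermediates needed by the
// backward pass are returned in a cache list.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) {
  return 1.0 / (1.0 + exp(-x));
}

// silu'(x) from the cached sigmoid: s * (1 + x * (1 - s))
static inline mat silu_grad_c(const mat& x, const mat& s) {
  return s % (1.0 + x % (1.0 - s));
}


// Column-wise scatter keeps memory access contiguous in the (large)
// edge matrix; the target has few rows, so its columns stay in cache.
static inline void scatter_add(mat& out, const mat& m, const uvec& idx) {
  const uword E = idx.n_elem, d = m.n_cols;
  for (uword j = 0; j < d; ++j) {
    double* oj = out.colptr(j);
    const double* mj = m.colptr(j);
    for (uword e = 0; e < E; ++e) oj[idx[e]] += mj[e];
  }
}

static inline void scatter_sub(mat& out, const mat& m, const uvec& idx) {
  const uword E = idx.n_elem, d = m.n_cols;
  for (uword j = 0; j < d; ++j) {
    double* oj = out.colptr(j);
    const double* mj = m.colptr(j);
    for (uword e = 0; e < E; ++e) oj[idx[e]] -= mj[e];
  }
}


// [[Rcpp::export(name = ".egnn_forward_cpp")]]
Rcpp::List egnn_forward_cpp(const arma::mat& h, const arma::mat& x,
                            const arma::uvec& src, const arma::uvec& dst,
                            const Rcpp::List& par, bool update_coords,
                            double clamp, double dist_scale) {
  const mat e_src = par["e_src"], e_dst = par["e_dst"];
  const rowvec e_dist = par["e_dist"], e_b = par["e_b"];
  const mat e2W = par["e2W"];  const rowvec e2b = par["e2b"];
  const mat x1W = par["x1W"];  const rowvec x1b = par["x1b"];
  const mat x2W = par["x2W"];  const rowvec x2b = par["x2b"];
  const mat h1W = par["h1W"];  const rowvec h1b = par["h1b"];
  const mat h2W = par["h2W"];  const rowvec h2b = par["h2b"];

  const uword n = h.n_rows, E = src.n_elem;

  mat A = h * e_src;
  mat B = h * e_dst;

  const double inv_ds = 1.0 / (dist_scale * dist_scale);
  mat diff = x.rows(src) - x.rows(dst);
  vec dist2 = sum(square(diff), 1) * inv_ds;  // normalized squared distance

  mat P = A.rows(src) + B.rows(dst) + dist2 * e_dist;
  P.each_row() += e_b;
  mat sP = sigmoid(P);
  mat S1 = P % sP;
  mat M0 = S1 * e2W;
  M0.each_row() += e2b;
  mat sM0 = sigmoid(M0);
  mat M = M0 % sM0;

  vec deg(n, fill::zeros);
  for (uword e = 0; e < E; ++e) deg(src(e)) += 1.0;

  mat x_out = x;
  mat T0, sT0, w, dx_raw;
  vec scale;
  if (update_coords) {
    T0 = M * x1W;
    T0.each_row() += x1b;
    sT0 = sigmoid(T0);
    mat T1 = T0 % sT0;
    w = T1 * x2W;
    w.each_row() += x2b;
    mat dxs = diff.each_col() % w.col(0);
    dx_raw.zeros(n, 3);
    scatter_add(dx_raw, dxs, src);
    for (uword i = 0; i < n; ++i)
      if (deg(i) > 0) dx_raw.row(i) /= deg(i);
    scale.ones(n);
    for (uword i = 0; i < n; ++i) {
      double nr = norm(dx_raw.row(i), 2);
      if (nr > clamp) scale(i) = clamp / nr;
    }
    x_out = x + (dx_raw.each_col() % scale);
  }

  mat agg(n, M.n_cols, fill::zeros);
  scatter_add(agg, M, src);

  mat C = join_rows(h, agg);
  mat U0 = C * h1W;
  U0.each_row() += h1b;
  mat sU0 = sigmoid(U0);
  mat U1 = U0 % sU0;
  mat U = U1 * h2W;
  U.each_row() += h2b;
  mat h_out = h + U;

  return Rcpp::List::create(
    Rcpp::Named("h_out") = h_out, Rcpp::Named("x_out") = x_out,
    Rcpp::Named("cache") = Rcpp::List::create(
      Rcpp::Named("diff") = diff, Rcpp::Named("dist2") = dist2,
      Rcpp::Named("P") = P, Rcpp::Named("sP") = sP,
      Rcpp::Named("M0") = M0, Rcpp::Named("sM0") = sM0,
      Rcpp::Named("M") = M, Rcpp::Named("T0") = T0,
      Rcpp::Named("sT0") = sT0,
      Rcpp::Named("w") = w, Rcpp::Named("dx_raw") = dx_raw,
      Rcpp::Named("scale") = scale, Rcpp::Named("deg") = deg,
      Rcpp::Named("U0") = U0, Rcpp::Named("sU0") = sU0,
      Rcpp::Named("C") = C));
}

// [[Rcpp::export(name = ".egnn_backward_cpp")]]
Rcpp::List egnn_backward_cpp(const arma::mat& h, const arma::mat& x,
                             const arma::uvec& src, const arma::uvec& dst,
                             const Rcpp::List& par, const Rcpp::List& cache,
                             const arma::mat& gh_out, const arma::mat& gx_out,
                             bool update_coords, double clamp,
                             double dist_scale) {
  const mat e_src = par["e_src"], e_dst = par["e_dst"];
  const rowvec e_dist = par["e_dist"];
  const mat e2W = par["e2W"], x1W = par["x1W"], x2W = par["x2W"];
  const mat h1W = par["h1W"], h2W = par["h2W"];

  // zero-copy views into the cached forward intermediates
  #define CACHE_VIEW(NAME) \
    Rcpp::NumericMatrix NAME##_rm = cache[#NAME]; \
    const mat NAME(NAME##_rm.begin(), NAME##_rm.nrow(), NAME##_rm.ncol(), \
                   false)
  CACHE_VIEW(diff); CACHE_VIEW(P); CACHE_VIEW(sP); CACHE_VIEW(M0);
  CACHE_VIEW(sM0); CACHE_VIEW(M); CACHE_VIEW(U0); CACHE_VIEW(sU0);
  CACHE_VIEW(C);
  #undef CACHE_VIEW
  const vec dist2 = cache["dist2"];
  const vec deg = cache["deg"];

  const uword n = h.n_rows, d = h.n_cols, E = src.n_elem;
  const uword dm = M.n_cols;  // message width (may differ from d)

  mat g_h(n, d, fill::zeros);
  mat g_x(n, 3, fill::zeros);
  mat g_M(E, dm, fill::zeros);
  mat g_diff(E, 3, fill::zeros);

  // ---- h residual path -------------------------------------------------
  // h_out = h + U(U1(U0(C)))
  g_h += gh_out;
  mat U1 = U0 % sU0;
  mat g_U1 = gh_out * h2W.t();
  mat g_h2W = U1.t() * gh_out;
  rowvec g_h2b = sum(gh_out, 0);
  mat g_U0 = g_U1 % silu_grad_c(U0, sU0);
  mat g_h1W = C.t() * g_U0;
  rowvec g_h1b = sum(g_U0, 0);
  mat g_C = g_U0 * h1W.t();
  g_h += g_C.cols(0, d - 1);
  mat g_agg = g_C.cols(d, d + dm - 1);
  g_M += g_agg.rows(src);

  // ---- coordinate path -------------------------------------------------
  mat g_x1W(x1W.n_rows, x1W.n_cols, fill::zeros);
  rowvec g_x1b(dm, fill::zeros);
  mat g_x2W(dm, 1, fill::zeros);
  rowvec g_x2b(1, fill::zeros);
  if (update_coords) {
    const mat T0 = cache["T0"];
    const mat sT0 = cache["sT0"];
    const mat w = cache["w"];
    const mat dx_raw = cache["dx_raw"];
    const vec scale = cache["scale"];
    g_x += gx_out;  // identity part of x_out = x + clamp(dx_raw)
    mat g_dx(n, 3);
    for (uword i = 0; i < n; ++i) {
      rowvec g = gx_out.row(i);
      if (scale(i) < 1.0) {
        double nr = norm(dx_raw.row(i), 2);
        double dot = as_scalar(g * dx_raw.row(i).t());
        g_dx.row(i) = scale(i) * g -
          (clamp * dot / (nr * nr * nr)) * dx_raw.row(i);
      } else {
        g_dx.row(i) = g;
      }
    }
    for (uword i = 0; i < n; ++i)
      if (deg(i) > 0) g_dx.row(i) /= deg(i);
    mat g_dxs = g_dx.rows(src);             // E x 3
    vec g_w = sum(g_dxs % diff, 1);         // E x 1
    g_diff += g_dxs.each_col() % w.col(0);
    mat T1 = T0 % sT0;
    mat g_T1 = g_w * x2W.t();
    g_x2W = T1.t() * g_w;
    g_x2b(0) = accu(g_w);
    mat g_T0 = g_T1 % silu_grad_c(T0, sT0);
    g_x1W = M.t() * g_T0;
    g_x1b = sum(g_T0, 0);
    g_M += g_T0 * x1W.t();
  }

  // ---- message path ----------------------------------------------------
  mat g_M0 = g_M % silu_grad_c(M0, sM0);
  mat S1 = P % sP;
  mat g_e2W = S1.t() * g_M0;
  rowvec g_e2b = sum(g_M0, 0);
  mat g_S1 = g_M0 * e2W.t();
  mat g_P = g_S1 % silu_grad_c(P, sP);

  mat g_A(n, dm, fill::zeros), g_B(n, dm, fill::zeros);
  scatter_add(g_A, g_P, src);
  scatter_add(g_B, g_P, dst);
  mat g_e_src = h.t() * g_A;
  mat g_e_dst = h.t() * g_B;
  g_h += g_A * e_src.t() + g_B * e_dst.t();

  vec g_dist2 = g_P * e_dist.t();
  rowvec g_e_dist = dist2.t() * g_P;
  rowvec g_e_b = sum(g_P, 0);
  const double inv_ds = 1.0 / (dist_scale * dist_scale);
  g_diff += 2.0 * inv_ds * (diff.each_col() % g_dist2);

  scatter_add(g_x, g_diff, src);
  scatter_sub(g_x, g_diff, dst);

  return Rcpp::List::create(
    Rcpp::Named("g_h") = g_h, Rcpp::Named("g_x") = g_x,
    Rcpp::Named("g_par") = Rcpp::List::create(
      Rcpp::Named("e_src") = g_e_src, Rcpp::Named("e_dst") = g_e_dst,
      Rcpp::Named("e_dist") = g_e_dist, Rcpp::Named("e_b") = g_e_b,
      Rcpp::Named("e2W") = g_e2W, Rcpp::Named("e2b") = g_e2b,
      Rcpp::Named("x1W") = g_x1W, Rcpp::Named("x1b") = g_x1b,
      Rcpp::Named("x2W") = g_x2W, Rcpp::Named("x2b") = g_x2b,
      Rcpp::Named("h1W") = g_h1W, Rcpp::Named("h1b") = g_h1b,
      Rcpp::Named("h2W") = g_h2W, Rcpp::Named("h2b") = g_h2b));
}
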
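// Geometry kernel: bounding-volume trees for closest-point queries,
// deterministic area-stratified surface sampling, point-to-point ICP with
// PCA initialisation, and paired surface-distance evaluation.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <cstring>
#include <string>
#include <functional>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG (splitmix64): independent of R's RNG so that surface
// sampling is reproducible from a content-derived seed regardless of call
// order or session state.
// ---------------------------------------------------------------------------
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

static uint64_t fnv1a(const unsigned char* data, size_t n,
                      uint64_t h = 1469598103934665603ULL) {
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)data[i];
    h *= 1099511628211ULL;
  }
  return h;
}

// ---------------------------------------------------------------------------
// closest point on a triangle (Ericson, Real-Time Collision Detection).
// Degenerate triangles (a == b == c) fall through to the first vertex, so the
// same routine serves point primitives.
// ---------------------------------------------------------------------------
static inline void closest_pt_triangle(const double* p, const double* a,
                                       const double* b, const double* c,
                                       double* out) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    out[0]=a[0]+v*ab[0]; out[1]=a[1]+v*ab[1]; out[2]=a[2]+v*ab[2]; return;
  }
  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    out[0]=a[0]+w*ac[0]; out[1]=a[1]+w*ac[1]; out[2]=a[2]+w*ac[2]; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    out[0]=b[0]+w*(c[0]-b[0]); out[1]=b[1]+w*(c[1]-b[1]); out[2]=b[2]+w*(c[2]-b[2]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  out[0]=a[0]+ab[0]*v+ac[0]*w;
  out[1]=a[1]+ab[1]*v+ac[1]*w;
  out[2]=a[2]+ab[2]*v+ac[2]*w;
}

static inline double dist2(const double* p, const double* q) {
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// ---------------------------------------------------------------------------
// bounding-volume tree over triangle (or degenerate point) primitives
// ---------------------------------------------------------------------------
struct PrimTree {
  std::vector<double> tri;                 // 9 doubles per primitive, reordered
  std::vector<double> bmin, bmax;          // 3 per node
  std::vector<int> left_, right_, start_, count_;
  static const int LEAF_SIZE = 8;

  size_t n_prim() const { return tri.size() / 9; }

  void build(const std::vector<double>& prims) {
    size_t n = prims.size() / 9;
    std::vector<int> idx(n);
    for (size_t i = 0; i < n; ++i) idx[i] = (int)i;
    std::vector<double> cent(3 * n);
    for (size_t i = 0; i < n; ++i) {
      const double* t = &prims[9*i];
      for (int k = 0; k < 3; ++k)
        cent[3*i+k] = (t[k] + t[3+k] + t[6+k]) / 3.0;
    }
    tri.clear(); bmin.clear(); bmax.clear();
    left_.clear(); right_.clear(); start_.clear(); count_.clear();
    if (n == 0) return;
    tri.reserve(prims.size());
    build_node(idx, 0, (int)n, prims, cent);
  }

  int build_node(std::vector<int>& idx, int lo, int hi,
                 const std::vector<double>& prims,
                 const std::vector<double>& cent) {
    int node = (int)left_.size();
    left_.push_back(-1); right_.push_back(-1);
    start_.push_back(-1); count_.push_back(0);
    double mn[3] = {HUGE_VAL, HUGE_VAL, HUGE_VAL};
    double mx[3] = {-HUGE_VAL, -HUGE_VAL, -HUGE_VAL};
    double cmn[3] = {HUGE_VAL, HUGE_VAL, HUGE_VAL};
    double cmx[3] = {-HUGE_VAL, -HUGE_VAL, -HUGE_VAL};
    for (int i = lo; i < hi; ++i) {
      const double* t = &prims[9*idx[i]];
      const double* c = &cent[3*idx[i]];
      for (int v = 0; v < 3; ++v)
        for (int k = 0; k < 3; ++k) {
          mn[k] = std::min(mn[k], t[3*v+k]);
          mx[k] = std::max(mx[k], t[3*v+k]);
        }
      for (int k = 0; k < 3; ++k) {
        cmn[k] = std::min(cmn[k], c[k]);
        cmx[k] = std::max(cmx[k], c[k]);
      }
    }
    for (int k = 0; k < 3; ++k) { bmin.push_back(mn[k]); bmax.push_back(mx[k]); }
    int n = hi - lo;
    if (n <= LEAF_SIZE) {
      start_[node] = (int)(tri.size() / 9);
      count_[node] = n;
      for (int i = lo; i < hi; ++i)
        tri.insert(tri.end(), &prims[9*idx[i]], &prims[9*idx[i]] + 9);
      return node;
    }
    int ax = 0;
    double span = cmx[0] - cmn[0];
    for (int k = 1; k < 3; ++k)
      if (cmx[k] - cmn[k] > span) { span = cmx[k] - cmn[k]; ax = k; }
    int mid = lo + n / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return cent[3*a+ax] < cent[3*b+ax]; });
    int l = build_node(idx, lo, mid, prims, cent);
    int r = build_node(idx, mid, hi, prims, cent);
    left_[node] = l; right_[node] = r;
    return node;
  }

  double box_dist2(int node, const double* p) const {
    double d = 0.0;
    for (int k = 0; k < 3; ++k) {
      double lo = bmin[3*node+k], hi = bmax[3*node+k];
      double e = (p[k] < lo) ? lo - p[k] : (p[k] > hi ? p[k] - hi : 0.0);
      d += e * e;
    }
    return d;
  }

  void query_node(int node, const double* p, double& best2, double* bestpt) const {
    if (count_[node] > 0) {
      const double* t = &tri[9 * (size_t)start_[node]];
      for (int i = 0; i < count_[node]; ++i, t += 9) {
        double cp[3];
        closest_pt_triangle(p, t, t + 3, t + 6, cp);
        double d2 = dist2(p, cp);
        if (d2 < best2) {
          best2 = d2;
          bestpt[0] = cp[0]; bestpt[1] = cp[1]; bestpt[2] = cp[2];
        }
      }
      return;
    }
    int l = left_[node], r = right_[node];
    double dl = box_dist2(l, p), dr = box_dist2(r, p);
    if (dl <= dr) {
      if (dl < best2) query_node(l, p, best2, bestpt);
      if (dr < best2) query_node(r, p, best2, bestpt);
    } else {
      if (dr < best2) query_node(r, p, best2, bestpt);
      if (dl < best2) query_node(l, p, best2, bestpt);
    }
  }

  // returns squared distance; writes the closest surface point into bestpt.
  // init_best2 may carry a proven upper bound on the squared distance (from
  // the triangle inequality against an earlier query); it only prunes, the
  // returned point is still the exact closest point.
  double query(const double* p, double* bestpt,
               double init_best2 = HUGE_VAL) const {
    double best2 = init_best2 * (1.0 + 1e-12) + 1e-300;
    bestpt[0] = NAN;
    if (!left_.empty()) query_node(0, p, best2, bestpt);
    if (std::isnan(bestpt[0])) {   // bound was too tight for numerics: redo
      best2 = HUGE_VAL;
      if (!left_.empty()) query_node(0, p, best2, bestpt);
    }
    return best2;
  }
};

// ---------------------------------------------------------------------------
// area-stratified deterministic surface sampling
// ---------------------------------------------------------------------------
static void sample_faces(const arma::mat& V, const arma::imat& F, double density,
                         uint64_t seed, std::vector<double>& out) {
  size_t nf = F.n_rows;
  for (size_t f = 0; f < nf; ++f) {
    arma::rowvec3 A = V.row(F(f, 0));
    arma::rowvec3 B = V.row(F(f, 1));
    arma::rowvec3 C = V.row(F(f, 2));
    arma::rowvec3 ab = B - A, ac = C - A;
    double area = 0.5 * std::sqrt(
      std::pow(ab[1]*ac[2] - ab[2]*ac[1], 2) +
      std::pow(ab[2]*ac[0] - ab[0]*ac[2], 2) +
      std::pow(ab[0]*ac[1] - ab[1]*ac[0], 2));
    double lambda = density * area;
    SplitMix rng(seed + 0x9E3779B97F4A7C15ULL * (uint64_t)(f + 1));
    rng.next();
    int n = (int)std::floor(lambda);
    if (rng.unif() < lambda - std::floor(lambda)) n += 1;
    for (int i = 0; i < n; ++i) {
      double r1 = rng.unif(), r2 = rng.unif();
      double s = std::sqrt(r1);
      arma::rowvec3 P = (1.0 - s) * A + s * (1.0 - r2) * B + s * r2 * C;
      out.push_back(P[0]); out.push_back(P[1]); out.push_back(P[2]);
    }
  }
}

static std::vector<double> mesh_prims(const arma::mat& V, const arma::imat& F) {
  std::vector<double> prims;
  prims.reserve(9 * F.n_rows);
  for (size_t f = 0; f < F.n_rows; ++f)
    for (int v = 0; v < 3; ++v)
      for (int k = 0; k < 3; ++k)
        prims.push_back(V(F(f, v), k));
  return prims;
}

static std::vector<double> point_prims(const arma::mat& S) {
  std::vector<double> prims;
  prims.reserve(9 * S.n_cols);
  for (size_t i = 0; i < S.n_cols; ++i)
    for (int v = 0; v < 3; ++v)
      for (int k = 0; k < 3; ++k)
        prims.push_back(S(k, i));
  return prims;
}

// ---------------------------------------------------------------------------
// mesh handle: everything reusable across pairwise comparisons
// ---------------------------------------------------------------------------
struct MeshHandle {
  PrimTree surf;   // triangles
  PrimTree pts;    // sampled points (for ICP correspondences)
  arma::mat S;     // 3 x n sampled points
  arma::mat Sicp;  // 3 x m subsample driving ICP
};

// [[Rcpp::export]]
SEXP cpp_build_handle(const arma::mat& V, const arma::imat& F, double density,
                      double seed, int icp_max_points, int min_points) {
  MeshHandle* h = new MeshHandle();
  std::vector<double> prims = mesh_prims(V, F);
  h->surf.build(prims);
  std::vector<double> samp;
  sample_faces(V, F, density, (uint64_t)seed, samp);
  if ((int)(samp.size() / 3) < min_points) {
    // tiny meshes: raise density so registration has enough support
    double total_area = 0.0;
    for (size_t f = 0; f < F.n_rows; ++f) {
      arma::rowvec3 ab = V.row(F(f,1)) - V.row(F(f,0));
      arma::rowvec3 ac = V.row(F(f,2)) - V.row(F(f,0));
      total_area += 0.5 * arma::norm(arma::cross(ab.t(), ac.t()), 2);
    }
    double d2 = (total_area > 0) ? (double)min_points / total_area * 1.2 : density;
    samp.clear();
    sample_faces(V, F, std::max(density, d2), (uint64_t)seed, samp);
  }
  size_t n = samp.size() / 3;
  h->S.set_size(3, n);
  for (size_t i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) h->S(k, i) = samp[3*i+k];
  h->pts.build(point_prims(h->S));
  int stride = std::max((size_t)1, (n + icp_max_points - 1) / (size_t)icp_max_points);
  size_t m = (n + stride - 1) / stride;
  h->Sicp.set_size(3, m);
  for (size_t i = 0, j = 0; i < n; i += stride, ++j) h->Sicp.col(j) = h->S.col(i);
  return Rcpp::XPtr<MeshHandle>(h, true);
}

// [[Rcpp::export]]
arma::mat cpp_handle_samples(SEXP xp) {
  Rcpp::XPtr<MeshHandle> h(xp);
  return h->S.t();
}

// [[Rcpp::export]]
arma::mat cpp_sample_points(const arma::mat& V, const arma::imat& F,
                            double density, double seed) {
  std::vector<double> samp;
  sample_faces(V, F, density, (uint64_t)seed, samp);
  size_t n = samp.size() / 3;
  arma::mat out(n, 3);
  for (size_t i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = samp[3*i+k];
  return out;
}

// ---------------------------------------------------------------------------
// rigid alignment
// ---------------------------------------------------------------------------
static void kabsch(const arma::mat& P, const arma::mat& Q,
                   arma::mat33& R, arma::vec3& t) {
  arma::vec3 cp = arma::mean(P, 1), cq = arma::mean(Q, 1);
  arma::mat H = (P.each_col() - cp) * (Q.each_col() - cq).t();
  arma::mat U, W;
  arma::vec s;
  arma::svd(U, s, W, H);
  arma::mat33 Rr = W * U.t();
  if (arma::det(Rr) < 0) {
    W.col(2) *= -1.0;
    Rr = W * U.t();
  }
  R = Rr;
  t = cq - R * cp;
}

static arma::mat33 pca_axes(const arma::mat& S) {
  arma::mat C = arma::cov(S.t());
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, C);       // ascending
  arma::mat33 A;
  A.col(0) = evec.col(2);
  A.col(1) = evec.col(1);
  A.col(2) = evec.col(0);
  if (arma::det(A) < 0) A.col(2) *= -1.0;
  return A;
}

static double rms_to_points(const arma::mat& P, const PrimTree& tgt,
                            const arma::mat33& R, const arma::vec3& t) {
  double acc = 0.0;
  double cp[3];
  double prev_d = HUGE_VAL, prev_p[3] = {0, 0, 0};
  for (size_t i = 0; i < P.n_cols; ++i) {
    arma::vec3 q = R * P.col(i) + t;
    double p[3] = {q[0], q[1], q[2]};
    double ub2 = HUGE_VAL;
    if (std::isfinite(prev_d)) {
      double step = std::sqrt(dist2(p, prev_p));
      double ub = prev_d + step;
      ub2 = ub * ub;
    }
    double d2 = tgt.query(p, cp, ub2);
    prev_d = std::sqrt(d2);
    prev_p[0] = p[0]; prev_p[1] = p[1]; prev_p[2] = p[2];
    acc += d2;
  }
  return std::sqrt(acc / (double)P.n_cols);
}

struct ICPOut {
  arma::mat33 R;
  arma::vec3 t;
  double rms;
  int iters;
  bool converged;
};

static ICPOut icp_run(const MeshHandle& src, const MeshHandle& tgt,
                      int max_iter, double tol) {
  const arma::mat& P = src.Sicp;
  arma::vec3 cs = arma::mean(src.S, 1), ct = arma::mean(tgt.S, 1);
  arma::mat33 Es = pca_axes(src.S), Et = pca_axes(tgt.S);
  // 4 proper sign combinations of the principal axes
  const int signs[4][3] = {{1,1,1}, {1,-1,-1}, {-1,1,-1}, {-1,-1,1}};
  arma::mat33 Rbest;
  arma::vec3 tbest;
  double best = HUGE_VAL;
  for (int c = 0; c < 4; ++c) {
    arma::mat33 D(arma::fill::zeros);
    D(0,0) = signs[c][0]; D(1,1) = signs[c][1]; D(2,2) = signs[c][2];
    arma::mat33 R0 = Et * D * Es.t();
    arma::vec3 t0 = ct - R0 * cs;
    double r = rms_to_points(P, tgt.surf, R0, t0);
    if (r < best) { best = r; Rbest = R0; tbest = t0; }
  }
  arma::mat33 R = Rbest;
  arma::vec3 t = tbest;
  double prev = best;
  double rms = best;
  int it = 0;
  bool converged = false;
  arma::mat Q(3, P.n_cols);
  double cp[3];
  // warm-start bounds: the closest distance of a point can change by at most
  // its own displacement between iterations (triangle inequality)
  arma::mat Ppos(3, P.n_cols);
  std::vector<double> dprev(P.n_cols, HUGE_VAL);
  bool have_prev = false;
  for (it = 1; it <= max_iter; ++it) {
    for (size_t i = 0; i < P.n_cols; ++i) {
      arma::vec3 q = R * P.col(i) + t;
      double p[3] = {q[0], q[1], q[2]};
      double ub2 = HUGE_VAL;
      if (have_prev) {
        double step = std::sqrt(dist2(p, Ppos.colptr(i)));
        double ub = dprev[i] + step;
        ub2 = ub * ub;
      }
      double d2 = tgt.surf.query(p, cp, ub2);
      dprev[i] = std::sqrt(d2);
      Ppos(0, i) = p[0]; Ppos(1, i) = p[1]; Ppos(2, i) = p[2];
      Q(0, i) = cp[0]; Q(1, i) = cp[1]; Q(2, i) = cp[2];
    }
    have_prev = true;
    kabsch(P, Q, R, t);
    arma::mat res = (R * P);
    res.each_col() += t;
    res -= Q;
    rms = std::sqrt(arma::accu(arma::square(res)) / (double)P.n_cols);
    if (std::fabs(prev - rms) < tol) { converged = true; break; }
    prev = rms;
  }
  ICPOut out;
  out.R = R; out.t = t; out.rms = rms;
  out.iters = std::min(it, max_iter);
  out.converged = converged;
  return out;
}

// [[Rcpp::export]]
List cpp_icp(SEXP xp_src, SEXP xp_tgt, int max_iter, double tol) {
  Rcpp::XPtr<MeshHandle> src(xp_src), tgt(xp_tgt);
  ICPOut o = icp_run(*src, *tgt, max_iter, tol);
  return List::create(
    _["rotation"] = o.R, _["translation"] = o.t, _["rms"] = o.rms,
    _["iterations"] = o.iters, _["converged"] = o.converged);
}

// directed point-to-surface distances of transformed samples
static void directed_stats(const arma::mat& S, const PrimTree& surf,
                           const arma::mat33& R, const arma::vec3& t,
                           double& mean_d, double& max_d) {
  double acc = 0.0, mx = 0.0, cp[3];
  double prev_d = HUGE_VAL, prev_p[3] = {0, 0, 0};
  for (size_t i = 0; i < S.n_cols; ++i) {
    arma::vec3 q = R * S.col(i) + t;
    double p[3] = {q[0], q[1], q[2]};
    double ub2 = HUGE_VAL;
    if (std::isfinite(prev_d)) {
      // consecutive samples are spatially coherent (face-ordered), so the
      // previous distance plus the step bounds the current one
      double step = std::sqrt(dist2(p, prev_p));
      double ub = prev_d + step;
      ub2 = ub * ub;
    }
    double d = std::sqrt(surf.query(p, cp, ub2));
    prev_d = d;
    prev_p[0] = p[0]; prev_p[1] = p[1]; prev_p[2] = p[2];
    acc += d;
    if (d > mx) mx = d;
  }
  mean_d = acc / (double)S.n_cols;
  max_d = mx;
}

// [[Rcpp::export]]
List cpp_pair_distance(SEXP xp_a, SEXP xp_b, bool do_icp, int max_iter,
                       double tol) {
  Rcpp::XPtr<MeshHandle> a(xp_a), b(xp_b);
  arma::mat33 R(arma::fill::eye);
  arma::vec3 t(arma::fill::zeros);
  double rms = NA_REAL;
  int iters = 0;
  bool converged = true;
  if (do_icp) {
    ICPOut o = icp_run(*a, *b, max_iter, tol);
    R = o.R; t = o.t; rms = o.rms; iters = o.iters; converged = o.converged;
  }
  double mean_ab, max_ab, mean_ba, max_ba;
  directed_stats(a->S, b->surf, R, t, mean_ab, max_ab);
  // map b's samples into a's frame with the inverse transform
  arma::mat33 Ri = R.t();
  arma::vec3 ti = -Ri * t;
  directed_stats(b->S, a->surf, Ri, ti, mean_ba, max_ba);
  double mesd = std::max(mean_ab, mean_ba);
  double masd = std::max(max_ab, max_ba);
  return List::create(
    _["mesd"] = mesd, _["masd"] = masd,
    _["mean_ab"] = mean_ab, _["mean_ba"] = mean_ba,
    _["max_ab"] = max_ab, _["max_ba"] = max_ba,
    _["rotation"] = R, _["translation"] = t,
    _["icp_rms"] = rms, _["icp_iterations"] = iters,
    _["converged"] = converged);
}

// [[Rcpp::export]]
NumericVector cpp_point_surface_distance(const arma::mat& P, const arma::mat& V,
                                         const arma::imat& F) {
  PrimTree tree;
  tree.build(mesh_prims(V, F));
  NumericVector out(P.n_rows);
  double cp[3];
  for (size_t i = 0; i < P.n_rows; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    out[i] = std::sqrt(tree.query(p, cp));
  }
  return out;
}

// [[Rcpp::export]]
int cpp_n_components(const arma::imat& F, int n_vertices) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (size_t f = 0; f < F.n_rows; ++f) {
    int a = find(F(f, 0)), b = find(F(f, 1)), c = find(F(f, 2));
    parent[a] = b = find(b);
    parent[find(c)] = find(b);
  }
  int n = 0;
  for (int i = 0; i < n_vertices; ++i)
    if (find(i) == i) ++n;
  return n;
}

// [[Rcpp::export]]
NumericVector cpp_area_volume(const arma::mat& V, const arma::imat& F) {
  double area = 0.0, vol = 0.0;
  for (size_t f = 0; f < F.n_rows; ++f) {
    arma::vec3 A = V.row(F(f, 0)).t();
    arma::vec3 B = V.row(F(f, 1)).t();
    arma::vec3 C = V.row(F(f, 2)).t();
    arma::vec3 cr = arma::cross(B - A, C - A);
    area += 0.5 * arma::norm(cr, 2);
    vol += arma::dot(A, arma::cross(B, C)) / 6.0;
  }
  return NumericVector::create(area, vol);
}

// [[Rcpp::export]]
NumericVector cpp_tri_areas(const arma::mat& V, const arma::imat& F) {
  NumericVector out(F.n_rows);
  for (size_t f = 0; f < F.n_rows; ++f) {
    arma::vec3 A = V.row(F(f, 0)).t();
    arma::vec3 B = V.row(F(f, 1)).t();
    arma::vec3 C = V.row(F(f, 2)).t();
    out[f] = 0.5 * arma::norm(arma::cross(B - A, C - A), 2);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_hash_string(const std::string& s) {
  uint64_t h = fnv1a((const unsigned char*)s.data(), s.size());
  return (double)(h & ((1ULL << 53) - 1));
}

// [[Rcpp::export]]
double cpp_hash_mesh(const arma::mat& V, const std::string& id) {
  uint64_t h = fnv1a((const unsigned char*)id.data(), id.size());
  // hash coordinates rounded to 1e-9 mm so I/O float round-trips keep keys
  std::vector<int64_t> q(V.n_elem);
  for (size_t i = 0; i < V.n_elem; ++i)
    q[i] = (int64_t)llround(V(i) * 1e6);
  h = fnv1a((const unsigned char*)q.data(), q.size() * sizeof(int64_t), h);
  // fold to 53 bits so the value survives as a double
  return (double)(h & ((1ULL << 53) - 1));
}
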
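// N-dimensional simplex subdivision kernel and master-equation inner loop.
//
// A simplex is stored as an (N+1) x N matrix of vertex coordinates (rows are
// vertices). Cells of the regular grid are half-open boxes
// [base_d + i*cw_d, base_d + (i+1)*cw_d); flat indices are row-major with the
// LAST dimension varying fastest. All indices here are 0-based.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef std::vector<double> Vec;

// Simplex as flat vector: (N+1) rows of N coords, row-major.
struct Simp {
  int n;            // dimension N
  Vec v;            // (n+1)*n coordinates
  double at(int i, int d) const { return v[(size_t)i * n + d]; }
  double &at(int i, int d) { return v[(size_t)i * n + d]; }
};

// |det| of the edge matrix divided by N! (Gaussian elimination, partial pivot)
static double simp_volume(const Simp &s) {
  int n = s.n;
  std::vector<double> m((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < n; ++d)
      m[(size_t)i * n + d] = s.at(i + 1, d) - s.at(0, d);
  double det = 1.0;
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::fabs(m[(size_t)c * n + c]);
    for (int r = c + 1; r < n; ++r) {
      double a = std::fabs(m[(size_t)r * n + c]);
      if (a > best) { best = a; piv = r; }
    }
    if (best == 0.0) return 0.0;
    if (piv != c) {
      for (int d = 0; d < n; ++d)
        std::swap(m[(size_t)piv * n + d], m[(size_t)c * n + d]);
      det = -det;
    }
    double p = m[(size_t)c * n + c];
    det *= p;
    for (int r = c + 1; r < n; ++r) {
      double f = m[(size_t)r * n + c] / p;
      if (f != 0.0)
        for (int d = c; d < n; ++d)
          m[(size_t)r * n + d] -= f * m[(size_t)c * n + d];
    }
  }
  double fact = 1.0;
  for (int k = 2; k <= n; ++k) fact *= k;
  return std::fabs(det) / fact;
}

// Recursive edge-splitting bisection of a simplex by the hyperplane
// x[axis] == offset. Vertices within tol of the plane count as "on".
// Pieces with all vertices above-or-on go to `above`, below-or-on to `below`;
// fully on-plane (zero volume) pieces are dropped.
static void bisect_rec(const Simp &s, int axis, double offset, double tol,
                       std::vector<Simp> &above, std::vector<Simp> &below,
                       int depth) {
  int n = s.n, nv = n + 1;
  int iup = -1, idn = -1;
  bool anyUp = false, anyDn = false;
  std::vector<int> side(nv);
  for (int i = 0; i < nv; ++i) {
    double c = s.at(i, axis);
    if (c > offset + tol) { side[i] = 1; anyUp = true; }
    else if (c < offset - tol) { side[i] = -1; anyDn = true; }
    else side[i] = 0;
  }
  if (!(anyUp && anyDn) || depth > 4 * nv * nv) {
    if (anyUp) above.push_back(s);
    else if (anyDn) below.push_back(s);
    // all on-plane: degenerate, volume 0, drop
    return;
  }
  // first crossing edge (iup above, idn below)
  for (int i = 0; i < nv && iup < 0; ++i) {
    if (side[i] != 1) continue;
    for (int j = 0; j < nv; ++j)
      if (side[j] == -1) { iup = i; idn = j; break; }
  }
  double cu = s.at(iup, axis), cd = s.at(idn, axis);
  double t = (offset - cu) / (cd - cu);
  Vec p(n);
  for (int d = 0; d < n; ++d)
    p[d] = s.at(iup, d) + t * (s.at(idn, d) - s.at(iup, d));
  p[axis] = offset; // exact
  Simp s1 = s, s2 = s;
  for (int d = 0; d < n; ++d) { s1.at(iup, d) = p[d]; s2.at(idn, d) = p[d]; }
  // s1 lost the above-vertex iup, s2 lost the below-vertex idn
  bisect_rec(s1, axis, offset, tol, above, below, depth + 1);
  bisect_rec(s2, axis, offset, tol, above, below, depth + 1);
}

static Simp mat_to_simp(const NumericMatrix &m) {
  Simp s;
  s.n = m.ncol();
  s.v.resize((size_t)m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int d = 0; d < m.ncol(); ++d)
      s.at(i, d) = m(i, d);
  return s;
}

static NumericMatrix simp_to_mat(const Simp &s) {
  NumericMatrix m(s.n + 1, s.n);
  for (int i = 0; i <= s.n; ++i)
    for (int d = 0; d < s.n; ++d)
      m(i, d) = s.at(i, d);
  return m;
}

// [[Rcpp::export]]
double cpp_simplex_volume(NumericMatrix verts) {
  if (verts.nrow() != verts.ncol() + 1)
    stop("a simplex in %d dimensions needs %d vertices, got %d",
         verts.ncol(), verts.ncol() + 1, verts.nrow());
  return simp_volume(mat_to_simp(verts));
}

// [[Rcpp::export]]
List cpp_bisect_simplex(NumericMatrix verts, int axis, double offset,
                        double tol) {
  Simp s = mat_to_simp(verts);
  if (simp_volume(s) <= 0.0)
    stop("degenerate (zero-volume) input simplex");
  std::vector<Simp> ab, bl;
  bisect_rec(s, axis, offset, tol, ab, bl, 0);
  List above(ab.size()), below(bl.size());
  for (size_t k = 0; k < ab.size(); ++k) above[k] = simp_to_mat(ab[k]);
  for (size_t k = 0; k < bl.size(); ++k) below[k] = simp_to_mat(bl[k]);
  return List::create(_["above"] = above, _["below"] = below);
}

// Recursively cut a simplex along every interior grid hyperplane it straddles
// and accumulate terminal volumes per (clamped) cell flat index.
// `budget` bounds the number of terminal pieces per source cell: grossly
// stretched transformed cells (which occur in unreachable corners of the
// state space where the model flow is extreme) would otherwise overlap a
// volume-proportional number of cells and make generation intractable.
// When the budget is exhausted remaining simplices are assigned whole to
// their centroid cell, which still conserves mass exactly.
static void scatter_rec(const Simp &s, const double *base, const double *cw,
                        const int *res, int n,
                        std::map<int64_t, double> &acc, int depth,
                        long *budget) {
  // bounding range per dim
  for (int d = 0; d < n && depth < 10000 && *budget > 0; ++d) {
    double lo = s.at(0, d), hi = lo;
    for (int i = 1; i <= n; ++i) {
      double c = s.at(i, d);
      if (c < lo) lo = c;
      if (c > hi) hi = c;
    }
    double tol = 1e-9 * cw[d];
    // interior planes k = 1..res-1 strictly inside (lo, hi)
    double a = (lo - base[d]) / cw[d];
    int klo = (int)std::floor(a) + 1;
    if (klo < 1) klo = 1;
    for (int k = klo; k <= res[d] - 1; ++k) {
      double plane = base[d] + k * cw[d];
      if (plane >= hi - tol) break;
      if (plane > lo + tol) {
        std::vector<Simp> ab, bl;
        bisect_rec(s, d, plane, tol, ab, bl, 0);
        for (size_t q = 0; q < ab.size(); ++q)
          scatter_rec(ab[q], base, cw, res, n, acc, depth + 1, budget);
        for (size_t q = 0; q < bl.size(); ++q)
          scatter_rec(bl[q], base, cw, res, n, acc, depth + 1, budget);
        return;
      }
    }
  }
  // terminal: assign to the cell containing the centroid, clamped to grid
  double vol = simp_volume(s);
  if (vol <= 0.0) return;
  int64_t flat = 0;
  for (int d = 0; d < n; ++d) {
    double c = 0.0;
    for (int i = 0; i <= n; ++i) c += s.at(i, d);
    c /= (n + 1);
    int idx = (int)std::floor((c - base[d]) / cw[d]);
    if (idx < 0) idx = 0;
    if (idx >= res[d]) idx = res[d] - 1;
    flat = flat * res[d] + idx;
  }
  acc[flat] += vol;
  --(*budget);
}

// [[Rcpp::export]]
List cpp_scatter_simplex(NumericMatrix verts, NumericVector base,
                         NumericVector cw, IntegerVector res) {
  Simp s = mat_to_simp(verts);
  std::map<int64_t, double> acc;
  long budget = 1000000L;
  scatter_rec(s, base.begin(), cw.begin(), res.begin(), s.n, acc, 0,
              &budget);
  IntegerVector idx(acc.size());
  NumericVector vol(acc.size());
  int k = 0;
  for (std::map<int64_t, double>::iterator it = acc.begin(); it != acc.end();
       ++it, ++k) {
    idx[k] = (int)it->first;
    vol[k] = it->second;
  }
  return List::create(_["flat"] = idx, _["volume"] = vol);
}

// Build the full deterministic transition matrix in triplet form.
// tverts: (prod(res_d+1)) x N matrix of TRANSFORMED grid corner coordinates,
//   corner lattice flat-indexed row-major with last dimension fastest.
// simplex_corners: n_simp x (N+1) matrix of corner codes (0..2^N-1), where
//   bit (N-1-d) of a code selects the upper corner along dimension d.
// Returns 0-based (source, target, proportion) triplets plus the count of
// cells whose transformed volume deviates >20% from the cell volume.
// [[Rcpp::export]]
List cpp_generate_transitions(NumericMatrix tverts, IntegerVector res,
                              NumericVector base, NumericVector cw,
                              IntegerMatrix simplex_corners, double drop_tol,
                              int max_pieces) {
  int n = res.size();
  int nsimp = simplex_corners.nrow();
  int64_t ncells = 1;
  for (int d = 0; d < n; ++d) ncells *= res[d];
  // corner lattice strides (last dim fastest), lattice dims res_d + 1
  std::vector<int64_t> vstride(n);
  {
    int64_t st = 1;
    for (int d = n - 1; d >= 0; --d) {
      vstride[d] = st;
      st *= (int64_t)(res[d] + 1);
    }
  }
  std::vector<int> src, tgt;
  std::vector<double> prop;
  src.reserve((size_t)ncells * 4);
  tgt.reserve((size_t)ncells * 4);
  prop.reserve((size_t)ncells * 4);
  int n_warn = 0;

  std::vector<int> midx(n, 0);
  Simp s;
  s.n = n;
  s.v.resize((size_t)(n + 1) * n);

  for (int64_t cell = 0; cell < ncells; ++cell) {
    // corner lattice base index for this cell
    int64_t vbase = 0;
    for (int d = 0; d < n; ++d) vbase += (int64_t)midx[d] * vstride[d];
    std::map<int64_t, double> acc;
    double total = 0.0;
    long budget = max_pieces;
    for (int q = 0; q < nsimp; ++q) {
      for (int i = 0; i <= n; ++i) {
        int code = simplex_corners(q, i);
        int64_t vi = vbase;
        for (int d = 0; d < n; ++d)
          if ((code >> (n - 1 - d)) & 1) vi += vstride[d];
        for (int d = 0; d < n; ++d) s.at(i, d) = tverts(vi, d);
      }
      double vol = simp_volume(s);
      if (vol <= 0.0) continue;
      total += vol;
      scatter_rec(s, base.begin(), cw.begin(), res.begin(), n, acc, 0,
                  &budget);
    }
    if (total <= 0.0) {
      // fully degenerate transformed cell: all mass to the centroid's cell
      int64_t flat = 0;
      for (int d = 0; d < n; ++d) {
        double c = 0.0;
        int cnt = 0;
        for (int code = 0; code < (1 << n); ++code) {
          int64_t vi = vbase;
          for (int dd = 0; dd < n; ++dd)
            if ((code >> (n - 1 - dd)) & 1) vi += vstride[dd];
          c += tverts(vi, d);
          ++cnt;
        }
        c /= cnt;
        int idx = (int)std::floor((c - base[d]) / cw[d]);
        if (idx < 0) idx = 0;
        if (idx >= res[d]) idx = res[d] - 1;
        flat = flat * res[d] + idx;
      }
      src.push_back((int)cell);
      tgt.push_back((int)flat);
      prop.push_back(1.0);
    } else {
      // convexity check: the summed simplex volume should agree with the
      // first-order affine image volume |det(edge matrix)| of the cell;
      // honest contraction/expansion of the flow changes both equally,
      // so a deviation signals a non-convex transformed cell
      Simp aff;
      aff.n = n;
      aff.v.resize((size_t)(n + 1) * n);
      for (int d = 0; d < n; ++d) aff.at(0, d) = tverts(vbase, d);
      for (int e = 0; e < n; ++e) {
        int64_t vi = vbase + vstride[e];
        for (int d = 0; d < n; ++d) aff.at(e + 1, d) = tverts(vi, d);
      }
      double fact = 1.0;
      for (int k = 2; k <= n; ++k) fact *= k;
      double affvol = simp_volume(aff) * fact; // parallelepiped volume
      if (affvol > 0 && std::fabs(total - affvol) > 0.2 * affvol) ++n_warn;
      // normalize, drop tiny entries, renormalize
      double kept = 0.0;
      for (std::map<int64_t, double>::iterator it = acc.begin();
           it != acc.end(); ++it) {
        double f = it->second / total;
        if (f >= drop_tol) kept += f; else it->second = -1.0;
      }
      for (std::map<int64_t, double>::iterator it = acc.begin();
           it != acc.end(); ++it) {
        if (it->second < 0.0) continue;
        src.push_back((int)cell);
        tgt.push_back((int)it->first);
        prop.push_back((it->second / total) / kept);
      }
    }
    // increment multi-index, last dim fastest
    for (int d = n - 1; d >= 0; --d) {
      if (++midx[d] < res[d]) break;
      midx[d] = 0;
    }
  }
  return List::create(_["source"] = IntegerVector(src.begin(), src.end()),
                      _["target"] = IntegerVector(tgt.begin(), tgt.end()),
                      _["proportion"] = NumericVector(prop.begin(), prop.end()),
                      _["n_nonconvex"] = n_warn);
}

// Explicit-Euler solution of dp/dt = sum_k R_k (M_k p - p) over n_substeps
// steps of size h. Each M_k is a dgCMatrix (targets x sources) passed as its
// i/p/x slots. Mass is conserved because each M_k is column-stochastic.
// [[Rcpp::export]]
NumericVector cpp_master_equation(NumericVector p0, List Mi, List Mp, List Mx,
                                  NumericVector rates, double h,
                                  int n_substeps) {
  int n = p0.size();
  int K = rates.size();
  std::vector<double> p(p0.begin(), p0.end()), q(n, 0.0);
  double S = 0.0;
  for (int k = 0; k < K; ++k) S += rates[k];
  if (S <= 0.0 || n_substeps < 1) return p0;
  std::vector<const int *> ii(K);
  std::vector<const int *> pp(K);
  std::vector<const double *> xx(K);
  std::vector<IntegerVector> iv(K), pv(K);
  std::vector<NumericVector> xv(K);
  for (int k = 0; k < K; ++k) {
    iv[k] = as<IntegerVector>(Mi[k]);
    pv[k] = as<IntegerVector>(Mp[k]);
    xv[k] = as<NumericVector>(Mx[k]);
    ii[k] = iv[k].begin();
    pp[k] = pv[k].begin();
    xx[k] = xv[k].begin();
  }
  for (int step = 0; step < n_substeps; ++step) {
    std::fill(q.begin(), q.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      double R = rates[k];
      if (R <= 0.0) continue;
      for (int j = 0; j < n; ++j) {
        double v = R * p[j];
        if (v == 0.0) continue;
        for (int idx = pp[k][j]; idx < pp[k][j + 1]; ++idx)
          q[ii[k][idx]] += xx[k][idx] * v;
      }
    }
    double f = 1.0 - h * S;
    for (int j = 0; j < n; ++j) p[j] = f * p[j] + h * q[j];
  }
  return NumericVector(p.begin(), p.end());
}
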
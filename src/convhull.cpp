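// d-dimensional convex hull volume via incremental (beneath-beyond)
// construction with simplicial facets. Written for moderate problem sizes
// (assemblages of up to a few thousand species in a 5-D trait space);
// visibility scans are linear in the number of live facets.
#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Facet {
  std::vector<int> verts;      // d vertex indices
  std::vector<int> neighbors;  // neighbors[i] shares the ridge verts \ verts[i]
  arma::vec normal;            // outward unit normal
  double offset;               // normal . x = offset on the facet plane
  bool alive;
};

// Solve for the outward normal of the facet spanned by verts, oriented away
// from the interior point c. Rows: (v_i - v_0) must be orthogonal to n,
// and n . (c - v_0) is forced negative.
bool facet_plane(const arma::mat& X, const std::vector<int>& verts,
                 const arma::vec& c, arma::vec& normal, double& offset) {
  const int d = X.n_cols;
  arma::mat A(d, d);
  arma::vec b(d, arma::fill::zeros);
  arma::rowvec v0 = X.row(verts[0]);
  for (int i = 1; i < d; ++i) A.row(i - 1) = X.row(verts[i]) - v0;
  A.row(d - 1) = c.t() - v0;
  b(d - 1) = -1.0;
  arma::vec n;
  if (!arma::solve(n, A, b, arma::solve_opts::no_approx)) return false;
  double nn = arma::norm(n);
  if (!(nn > 0) || !n.is_finite()) return false;
  normal = n / nn;
  offset = arma::dot(normal, v0.t());
  return true;
}

// Greedy initial simplex: repeatedly add the point farthest from the current
// affine hull (Gram-Schmidt residual). Returns false when the cloud has
// affine dimension < d.
bool initial_simplex(const arma::mat& X, double tol, std::vector<int>& simplex) {
  const int n = X.n_rows, d = X.n_cols;
  if (n < d + 1) return false;
  simplex.clear();
  simplex.push_back(0);
  arma::mat basis(d, 0);  // orthonormal directions spanning the affine hull
  arma::rowvec origin = X.row(0);
  for (int step = 0; step < d; ++step) {
    double best = -1.0;
    int best_i = -1;
    arma::vec best_res;
    for (int i = 0; i < n; ++i) {
      arma::vec v = (X.row(i) - origin).t();
      if (basis.n_cols > 0) v -= basis * (basis.t() * v);
      double r = arma::norm(v);
      if (r > best) { best = r; best_i = i; best_res = v; }
    }
    if (best < tol || best_i < 0) return false;
    simplex.push_back(best_i);
    basis.insert_cols(basis.n_cols, best_res / best);
  }
  return true;
}

}  // namespace

//' @keywords internal
// [[Rcpp::export(name = ".convhull_volume_cpp")]]
double convhull_volume_cpp(const arma::mat& pts) {
  const int d = pts.n_cols;
  const int n = pts.n_rows;
  if (d < 1) stop("points must have at least one column");
  if (n < d + 1) return NA_REAL;  // degenerate: too few points

  // Condition the coordinates: center and scale each column to unit range.
  arma::mat X = pts;
  double vol_factor = 1.0;
  for (int j = 0; j < d; ++j) {
    double lo = X.col(j).min(), hi = X.col(j).max();
    double rng = hi - lo;
    if (!(rng > 0)) return NA_REAL;  // flat in one dimension
    X.col(j) = (X.col(j) - (lo + hi) / 2.0) / rng;
    vol_factor *= rng;
  }
  const double eps = 1e-10;

  std::vector<int> simplex;
  if (!initial_simplex(X, 1e-9, simplex)) return NA_REAL;

  arma::vec c(d, arma::fill::zeros);
  for (int i = 0; i <= d; ++i) c += X.row(simplex[i]).t();
  c /= (d + 1.0);

  std::vector<Facet> facets;
  // d+1 facets of the simplex, facet k omits simplex[k]
  for (int k = 0; k <= d; ++k) {
    Facet f;
    for (int i = 0; i <= d; ++i)
      if (i != k) f.verts.push_back(simplex[i]);
    f.neighbors.assign(d, -1);
    if (!facet_plane(X, f.verts, c, f.normal, f.offset))
      stop("degenerate initial simplex facet");
    f.alive = true;
    facets.push_back(f);
  }
  // simplex facet adjacency: facets k and l share all vertices but two
  for (int k = 0; k <= d; ++k) {
    for (int l = 0; l <= d; ++l) {
      if (k == l) continue;
      // facet k omits simplex[l] at some position; neighbor across that ridge
      // is the facet omitting both -> facet l. Find position of simplex[l]
      // in facet k's vertex list.
      for (int i = 0; i < d; ++i) {
        if (facets[k].verts[i] == simplex[l]) { facets[k].neighbors[i] = l; break; }
      }
    }
  }

  std::vector<bool> used(n, false);
  for (int i = 0; i <= d; ++i) used[simplex[i]] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    arma::vec x = X.row(p).t();
    std::vector<int> visible;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      if (arma::dot(facets[f].normal, x) - facets[f].offset > eps)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;  // inside (or on) the current hull

    std::vector<bool> is_vis(facets.size(), false);
    for (int f : visible) is_vis[f] = true;

    // Horizon ridges: (visible facet, slot) whose neighbor is not visible.
    std::map<std::vector<int>, std::pair<int, int> > open_ridge;  // ridge\{v} -> (facet,slot)
    std::vector<int> fresh;
    for (int f : visible) {
      for (int i = 0; i < d; ++i) {
        int g = facets[f].neighbors[i];
        if (g >= 0 && is_vis[g]) continue;
        // ridge = facets[f].verts minus position i; new facet = ridge + p
        Facet nf;
        for (int j = 0; j < d; ++j)
          if (j != i) nf.verts.push_back(facets[f].verts[j]);
        nf.verts.push_back(p);
        nf.neighbors.assign(d, -1);
        if (!facet_plane(X, nf.verts, c, nf.normal, nf.offset))
          continue;  // sliver ridge; skip (volume effect below tolerance)
        nf.alive = true;
        int nf_id = (int)facets.size();
        // neighbor opposite p (slot d-1) is the old non-visible facet g
        nf.neighbors[d - 1] = g;
        facets.push_back(nf);
        fresh.push_back(nf_id);
        // rewire g: the slot in g that pointed at f now points at nf
        if (g >= 0) {
          for (int j = 0; j < d; ++j)
            if (facets[g].neighbors[j] == f) { facets[g].neighbors[j] = nf_id; break; }
        }
        // register the d-1 sub-ridges (each omits one ridge vertex, keeps p)
        for (int j = 0; j < d - 1; ++j) {
          std::vector<int> key;
          for (int k2 = 0; k2 < d; ++k2)
            if (k2 != j) key.push_back(facets[nf_id].verts[k2]);
          std::sort(key.begin(), key.end());
          std::map<std::vector<int>, std::pair<int, int> >::iterator it =
              open_ridge.find(key);
          if (it == open_ridge.end()) {
            open_ridge[key] = std::make_pair(nf_id, j);
          } else {
            facets[nf_id].neighbors[j] = it->second.first;
            facets[it->second.first].neighbors[it->second.second] = nf_id;
            open_ridge.erase(it);
          }
        }
      }
    }
    for (int f : visible) facets[f].alive = false;
    if (!fresh.empty()) used[p] = true;
  }

  // Volume: fan of simplices from the interior point to each facet.
  double dfact = 1.0;
  for (int i = 2; i <= d; ++i) dfact *= i;
  double vol = 0.0;
  arma::mat M(d, d);
  for (size_t f = 0; f < facets.size(); ++f) {
    if (!facets[f].alive) continue;
    for (int i = 0; i < d; ++i)
      M.row(i) = X.row(facets[f].verts[i]) - c.t();
    vol += std::abs(arma::det(M)) / dfact;
  }
  return vol * vol_factor;
}

//' @keywords internal
// [[Rcpp::export(name = ".convhull_vertices_cpp")]]
IntegerVector convhull_vertices_cpp(const arma::mat& pts) {
  // Re-runs the construction and reports the 1-based indices of hull vertices;
  // used for diagnostics and tests.
  const int d = pts.n_cols, n = pts.n_rows;
  if (n < d + 1) return IntegerVector(0);
  double vol = convhull_volume_cpp(pts);
  if (!arma::is_finite(vol)) return IntegerVector(0);
  // Cheap but robust: a point is a hull vertex iff removing it changes volume.
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) {
    arma::mat sub(n - 1, d);
    int r = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) sub.row(r++) = pts.row(j);
    double v2 = convhull_volume_cpp(sub);
    if (!arma::is_finite(v2) || v2 < vol * (1 - 1e-9)) keep.push_back(i + 1);
  }
  return wrap(keep);
}
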
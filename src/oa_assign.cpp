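#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Dense linear sum assignment by shortest augmenting paths with potentials
// (Hungarian method, O(n^2 m)).  Minimizes; callers negate for maximization.
// a is row-major n x m with n <= m; returns the 0-based column of each row.
// ---------------------------------------------------------------------------
static std::vector<int> lsap_min_core(const std::vector<double>& a, int n, int m) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = a[(i0 - 1) * m + (j - 1)] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> ans(n, -1);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j - 1;
  return ans;
}

// Maximize over a (possibly rectangular) similarity matrix.  The smaller side
// is fully matched.  Returns the mapping for the *rows of S* when nrow <= ncol,
// otherwise the mapping for the columns (callers inspect dimensions).
static double lsap_max_score(const NumericMatrix& S, std::vector<int>* map_out) {
  int nr = S.nrow(), nc = S.ncol();
  bool flip = nr > nc;
  int n = flip ? nc : nr;
  int m = flip ? nr : nc;
  std::vector<double> a(static_cast<size_t>(n) * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      a[static_cast<size_t>(i) * m + j] = flip ? -S(j, i) : -S(i, j);
  std::vector<int> as = lsap_min_core(a, n, m);
  double score = 0.0;
  for (int i = 0; i < n; ++i)
    score += flip ? S(as[i], i) : S(i, as[i]);
  if (map_out) *map_out = as;
  return score;
}

//' @noRd
// [[Rcpp::export(name = "cpp_lsap_max")]]
List cpp_lsap_max(NumericMatrix S) {
  std::vector<int> mp;
  double sc = lsap_max_score(S, &mp);
  IntegerVector mapping(mp.size());
  for (size_t i = 0; i < mp.size(); ++i) mapping[i] = mp[i] + 1;  // 1-based
  return List::create(_["score"] = sc, _["mapping"] = mapping,
                      _["rows_are_smaller"] = S.nrow() <= S.ncol());
}

// ---------------------------------------------------------------------------
// Recursive atom-environment similarity.
//
// Per-depth scheme: the center term is an RBF over standardized atom
// descriptors; the environment term matches the neighbor sets (atom descriptors
// concatenated with the incident-bond descriptors) by a small optimal
// assignment of their pairwise similarities, each level damped by the decay of
// its topological distance from the original center.  Combination is a
// decay-weighted mean so that identical environments score exactly 1.
// ---------------------------------------------------------------------------

// combine center and environment terms; lambda = mixing weight of the
// environment, decay = decay at the neighbors' distance from the center.
static inline double combine_terms(double c, double nb, bool both_leaf,
                                   double decay, double lambda) {
  if (both_leaf) return c;
  double num = (1.0 - lambda) * c + lambda * decay * nb;
  double den = (1.0 - lambda) + lambda * decay;
  double v = num / den;
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}

// One refinement level: given previous-level similarities Sprev, compute
// S[i][j] = combine(center RBF, OA over neighbor pairs, decay).
// nbr*: per-atom neighbor index vectors (0-based); bd*: per-atom matrices of
// incident-bond descriptors (row r describes the bond to the r-th neighbor).
static void refine_level(const NumericMatrix& C,
                         const NumericMatrix& Sprev,
                         const std::vector<std::vector<int> >& nbrA,
                         const std::vector<std::vector<int> >& nbrB,
                         const std::vector<NumericMatrix>& bdA,
                         const std::vector<NumericMatrix>& bdB,
                         const NumericMatrix& atomsA,
                         const NumericMatrix& atomsB,
                         double gamma_ab, double decay, double lambda,
                         NumericMatrix& Sout) {
  int nA = C.nrow(), nB = C.ncol();
  int ka = atomsA.ncol();
  for (int i = 0; i < nA; ++i) {
    int nu = static_cast<int>(nbrA[i].size());
    int kb = nu > 0 ? bdA[i].ncol() : 0;
    for (int j = 0; j < nB; ++j) {
      int nv = static_cast<int>(nbrB[j].size());
      if (nu == 0 && nv == 0) { Sout(i, j) = C(i, j); continue; }
      double nbterm = 0.0;
      if (nu > 0 && nv > 0) {
        NumericMatrix M(nu, nv);
        for (int u = 0; u < nu; ++u) {
          int au = nbrA[i][u];
          for (int v = 0; v < nv; ++v) {
            int bv = nbrB[j][v];
            double d2 = 0.0;
            for (int t = 0; t < ka; ++t) {
              double d = atomsA(au, t) - atomsB(bv, t);
              d2 += d * d;
            }
            for (int t = 0; t < kb; ++t) {
              double d = bdA[i](u, t) - bdB[j](v, t);
              d2 += d * d;
            }
            M(u, v) = std::exp(-gamma_ab * d2) * Sprev(au, bv);
          }
        }
        double sc = lsap_max_score(M, 0);
        nbterm = sc / std::max(nu, nv);
      }
      Sout(i, j) = combine_terms(C(i, j), nbterm, false, decay, lambda);
    }
  }
}

//' @noRd
// [[Rcpp::export(name = "cpp_sim_matrix")]]
NumericMatrix cpp_sim_matrix(NumericMatrix atomsA, NumericMatrix atomsB,
                             List nbrA_, List nbrB_, List bdA_, List bdB_,
                             double gamma_a, double gamma_ab,
                             double lambda, NumericVector decays) {
  int nA = atomsA.nrow(), nB = atomsB.nrow();
  int ka = atomsA.ncol();
  if (atomsB.ncol() != ka) stop("descriptor length mismatch between molecules");
  std::vector<std::vector<int> > nbrA(nA), nbrB(nB);
  std::vector<NumericMatrix> bdA(nA), bdB(nB);
  for (int i = 0; i < nA; ++i) {
    IntegerVector v = nbrA_[i];
    for (int t = 0; t < v.size(); ++t) nbrA[i].push_back(v[t] - 1);
    bdA[i] = as<NumericMatrix>(bdA_[i]);
  }
  for (int j = 0; j < nB; ++j) {
    IntegerVector v = nbrB_[j];
    for (int t = 0; t < v.size(); ++t) nbrB[j].push_back(v[t] - 1);
    bdB[j] = as<NumericMatrix>(bdB_[j]);
  }
  // center RBF, shared by all levels
  NumericMatrix C(nA, nB);
  for (int i = 0; i < nA; ++i) {
    std::vector<double> xi(ka);
    for (int t = 0; t < ka; ++t) xi[t] = atomsA(i, t);
    for (int j = 0; j < nB; ++j) {
      double d2 = 0.0;
      for (int t = 0; t < ka; ++t) { double d = xi[t] - atomsB(j, t); d2 += d * d; }
      C(i, j) = std::exp(-gamma_a * d2);
    }
  }
  int depth = decays.size();  // number of refinement levels (default 2)
  NumericMatrix Sprev = clone(C);
  for (int lev = depth - 1; lev >= 0; --lev) {
    NumericMatrix Snext(nA, nB);
    refine_level(C, Sprev, nbrA, nbrB, bdA, bdB, atomsA, atomsB,
                 gamma_ab, decays[lev], lambda, Snext);
    Sprev = Snext;
  }
  return Sprev;
}

// ---------------------------------------------------------------------------
// Batch weighted screening: for each precomputed query-vs-library similarity
// matrix S (m x n_B), scale rows by the weight vector, solve the assignment,
// and normalize by sqrt(m * n_B) (identity self-assignment raw scores).
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export(name = "cpp_screen_scores")]]
NumericVector cpp_screen_scores(List Smats, NumericVector w) {
  int nmol = Smats.size();
  int m = w.size();
  NumericVector out(nmol);
  for (int k = 0; k < nmol; ++k) {
    NumericMatrix S = as<NumericMatrix>(Smats[k]);
    if (S.nrow() != m) stop("weight/atom count mismatch");
    int nB = S.ncol();
    NumericMatrix WS(m, nB);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < nB; ++j)
        WS(i, j) = w[i] * S(i, j);
    double sc = lsap_max_score(WS, 0);
    out[k] = sc / std::sqrt(static_cast<double>(m) * nB);
  }
  return out;
}
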
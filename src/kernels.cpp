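#include <Rcpp.h>
using namespace Rcpp;

// Evaluate an empirical copula at a set of points.
// U: G x p matrix of evaluation points in [0,1]^p.
// V: n x p matrix of rescaled ranks R/n in (0,1]^p (midranks allowed).
// Returns the fraction of rows of V componentwise <= each row of U.
// Comparisons are plain <=: rescaled ranks and grid coordinates built from
// the same j/n arithmetic compare bit-exactly, and Monte Carlo points are
// irrational with probability one.
static void row_major_copy(const NumericMatrix &M, std::vector<double> &out) {
  const int nr = M.nrow(), nc = M.ncol();
  out.resize(static_cast<size_t>(nr) * nc);
  for (int c = 0; c < nc; ++c) {
    const double *col = &M(0, c);
    for (int r = 0; r < nr; ++r) out[static_cast<size_t>(r) * nc + c] = col[r];
  }
}

static void ecop_eval_raw(const std::vector<double> &U, int G,
                          const std::vector<double> &V, int n, int p,
                          double *out) {
  for (int g = 0; g < G; ++g) {
    const double *u = &U[static_cast<size_t>(g) * p];
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      const double *v = &V[static_cast<size_t>(j) * p];
      bool ok = true;
      for (int l = 0; l < p; ++l) {
        if (v[l] > u[l]) { ok = false; break; }
      }
      if (ok) ++cnt;
    }
    out[g] = static_cast<double>(cnt) / n;
  }
}

// [[Rcpp::export]]
NumericVector ecop_eval_cpp(NumericMatrix U, NumericMatrix V) {
  const int G = U.nrow(), n = V.nrow(), p = U.ncol();
  if (V.ncol() != p) stop("dimension mismatch between points and ranks");
  std::vector<double> Ur, Vr;
  row_major_copy(U, Ur);
  row_major_copy(V, Vr);
  NumericVector out(G);
  ecop_eval_raw(Ur, G, Vr, n, p, REAL(out));
  return out;
}

// Cramer-von Mises homogeneity statistic.
// Vlist: list of m matrices of rescaled ranks (one per group).
// sizes: group sizes n_i; U: G x p integration points.
// T = (1/m) sum_i mean_u { C_i(u) - C_{-i}(u) }^2 where C_{-i} is the
// leave-one-out mixture with weights n_j / (N - n_i).
// [[Rcpp::export]]
double cvm_stat_cpp(List Vlist, NumericVector sizes, NumericMatrix U) {
  const int m = Vlist.size();
  const int G = U.nrow();
  const int p = U.ncol();
  std::vector<double> Ur;
  row_major_copy(U, Ur);
  std::vector<double> E(static_cast<size_t>(G) * m);
  std::vector<double> Vr;
  for (int i = 0; i < m; ++i) {
    NumericMatrix Vi = Vlist[i];
    if (Vi.ncol() != p) stop("dimension mismatch between points and ranks");
    row_major_copy(Vi, Vr);
    ecop_eval_raw(Ur, G, Vr, Vi.nrow(), p, &E[static_cast<size_t>(i) * G]);
  }
  double N = 0.0;
  for (int i = 0; i < m; ++i) N += sizes[i];
  double acc = 0.0;
  for (int i = 0; i < m; ++i) {
    double denom = N - sizes[i];
    double s = 0.0;
    for (int g = 0; g < G; ++g) {
      double mix = 0.0;
      for (int j = 0; j < m; ++j)
        if (j != i) mix += sizes[j] / denom * E[static_cast<size_t>(j) * G + g];
      double d = E[static_cast<size_t>(i) * G + g] - mix;
      s += d * d;
    }
    acc += s / G;
  }
  return acc / m;
}

// Cross-group Kendall sums for tau-tilde.
// Ri, Rj: n_i x 2 and n_j x 2 rank matrices (possibly midranks).
// Rescaled ranks are compared through the cross-multiplied difference
// R_is * n_j - R_jt * n_i, exact for (half-)integer ranks.
// Returns c(sum of sign products, N_ij).
// [[Rcpp::export]]
NumericVector kendall_cross_cpp(NumericMatrix Ri, NumericMatrix Rj) {
  const int ni = Ri.nrow(), nj = Rj.nrow();
  double ssum = 0.0, nij = 0.0;
  const double tol = 1e-9;
  for (int s = 0; s < ni; ++s) {
    for (int t = 0; t < nj; ++t) {
      double d1 = Ri(s, 0) * nj - Rj(t, 0) * ni;
      double d2 = Ri(s, 1) * nj - Rj(t, 1) * ni;
      bool tie1 = std::abs(d1) < tol, tie2 = std::abs(d2) < tol;
      if (tie1 || tie2) continue;
      nij += 1.0;
      ssum += ((d1 > 0) ? 1.0 : -1.0) * ((d2 > 0) ? 1.0 : -1.0);
    }
  }
  return NumericVector::create(ssum, nij);
}
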
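#include <Rcpp.h>
using namespace Rcpp;

// Kendall's tau-a between two equal-length vectors: (C - D) / (n(n-1)/2),
// tied pairs counting in neither C nor D.
static double tau_a_core(const double* x, const double* y, int n) {
  double s = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double sx = (dx > 0) - (dx < 0), sy = (dy > 0) - (dy < 0);
      s += sx * sy;
    }
  }
  return s / (0.5 * n * (n - 1));
}

// [[Rcpp::export(name = ".tau_a_cpp")]]
double tau_a_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (n < 2) stop("need length >= 2");
  return tau_a_core(REAL(x), REAL(y), n);
}

// Exhaustive EDI permutation count. EDI under a row permutation pi of the
// split-data RDM depends only on the permuted diagonal sum
// S(pi) = sum_i M[pi(i), i]; EDI is strictly decreasing in S. The null
// count #{pi : EDI(pi) >= EDI(identity)} therefore equals
// #{pi : S(pi) <= S(identity)} (ties included; identity included).
// Recursion over columns with a used-row mask visits every permutation
// once with incremental partial sums.
struct EdiCtx {
  const double* M;
  int n;
  double thresh;
  double count;
  std::vector<char> used;
};

static void edi_rec(EdiCtx& ctx, int col, double partial) {
  if (col == ctx.n) {
    if (partial <= ctx.thresh) ctx.count += 1.0;
    return;
  }
  for (int r = 0; r < ctx.n; ++r) {
    if (!ctx.used[r]) {
      ctx.used[r] = 1;
      edi_rec(ctx, col + 1, partial + ctx.M[r + col * ctx.n]);
      ctx.used[r] = 0;
    }
  }
}

// [[Rcpp::export(name = ".edi_exhaustive_count_cpp")]]
List edi_exhaustive_count_cpp(NumericMatrix M) {
  int n = M.nrow();
  if (M.ncol() != n) stop("matrix must be square");
  if (n > 10) stop("exhaustive enumeration limited to n <= 10");
  double s_id = 0.0;
  for (int i = 0; i < n; ++i) s_id += M(i, i);
  EdiCtx ctx;
  ctx.M = REAL(M);
  ctx.n = n;
  ctx.thresh = s_id + 1e-12;
  ctx.count = 0.0;
  ctx.used.assign(n, 0);
  edi_rec(ctx, 0, 0.0);
  double total = 1.0;
  for (int i = 2; i <= n; ++i) total *= i;
  return List::create(_["count"] = ctx.count, _["total"] = total);
}

// Null distribution of tau-a between the upper triangles of a
// row+column-permuted copy of A and the fixed U, over n_perm random
// condition permutations. Uses R's RNG so set.seed() governs the draws.
// [[Rcpp::export(name = ".tau_a_perm_null_cpp")]]
NumericVector tau_a_perm_null_cpp(NumericMatrix A, NumericMatrix U, int n_perm) {
  int n = A.nrow();
  if (A.ncol() != n || U.nrow() != n || U.ncol() != n)
    stop("A and U must be square with matching size");
  int k = n * (n - 1) / 2;
  std::vector<double> u(k), a(k);
  {
    int idx = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j)
        u[idx++] = U(i, j);
  }
  std::vector<int> perm(n);
  NumericVector out(n_perm);
  RNGScope scope;
  for (int t = 0; t < n_perm; ++t) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    // Fisher-Yates using R's RNG (matches sample.int's unif_rand source)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int idx = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j)
        a[idx++] = A(perm[i], perm[j]);
    out[t] = tau_a_core(a.data(), u.data(), k);
  }
  return out;
}
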
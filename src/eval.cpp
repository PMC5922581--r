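#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Program trees are prefix-encoded integer vectors: a positive entry is a
// 1-based terminal (a feature), a negative entry is a binary operator:
// -1 add, -2 sub, -3 mul, -4 protected div.
//
// Closure conventions (see the methods vignette):
//   a / b  ->  1            when |b| < 1e-9
//   every node output is clamped to [-1e150, 1e150] so no chain of
//   multiplications or divisions can overflow to Inf/NaN.

static const double DIV_EPS = 1e-9;
static const double CLAMP = 1e150;

static inline double clampv(double v) {
  if (v > CLAMP) return CLAMP;
  if (v < -CLAMP) return -CLAMP;
  return v;
}

// Core stack machine over a sample-major matrix Xt (n samples x k features,
// so each feature is a contiguous column).  Scanning the prefix code
// backwards turns it into postfix; the first operand popped at an operator
// is its left child.  The stack is one flat buffer of n-wide slots.
static NumericVector eval_transposed(const IntegerVector& code,
                                     const NumericMatrix& Xt) {
  const int n = Xt.nrow(), k = Xt.ncol(), len = code.size();
  const double* xp = REAL(Xt);
  const int max_slots = len / 2 + 2;
  std::vector<double> stk((size_t) max_slots * n);
  int top = 0;  // slots in use
  for (int p = len - 1; p >= 0; --p) {
    const int c = code[p];
    if (c > 0) {
      if (c > k) stop("terminal index %d out of range for %d features", c, k);
      if (top >= max_slots) stop("malformed program code");
      std::memcpy(&stk[(size_t) top * n], xp + (size_t)(c - 1) * n,
                  n * sizeof(double));
      ++top;
    } else {
      if (c < -4 || c == 0 || top < 2) stop("malformed program code");
      double* a = &stk[(size_t)(top - 1) * n];   // left operand
      double* b = &stk[(size_t)(top - 2) * n];   // right operand, result slot
      switch (c) {
      case -1: for (int j = 0; j < n; ++j) b[j] = clampv(a[j] + b[j]); break;
      case -2: for (int j = 0; j < n; ++j) b[j] = clampv(a[j] - b[j]); break;
      case -3: for (int j = 0; j < n; ++j) b[j] = clampv(a[j] * b[j]); break;
      case -4:
        for (int j = 0; j < n; ++j)
          b[j] = (std::abs(b[j]) < DIV_EPS) ? 1.0 : clampv(a[j] / b[j]);
        break;
      }
      --top;
    }
  }
  if (top != 1) stop("malformed program code");
  return NumericVector(stk.begin(), stk.begin() + n);
}

// Evaluate one program on every column (sample) of X (features x samples).
// [[Rcpp::export]]
NumericVector eval_prefix_cpp(IntegerVector code, NumericMatrix X) {
  NumericMatrix Xt(X.ncol(), X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    for (int j = 0; j < X.ncol(); ++j) Xt(j, i) = X(i, j);
  return eval_transposed(code, Xt);
}

// Same, but the caller already supplies the sample-major transpose
// (n samples x k features): the hot path inside evolve().
// [[Rcpp::export]]
NumericVector eval_prefix_t_cpp(IntegerVector code, NumericMatrix Xt) {
  return eval_transposed(code, Xt);
}

// Depth of every node (root = 0) in a prefix-encoded tree.
// [[Rcpp::export]]
IntegerVector node_depths_cpp(IntegerVector code) {
  const int len = code.size();
  IntegerVector out(len);
  // pending[d] = number of children still expected at depth d
  std::vector<int> pending;
  int depth = 0;
  for (int i = 0; i < len; ++i) {
    out[i] = depth;
    if (code[i] < 0) {            // operator: descend, expect 2 children
      pending.push_back(2);
      ++depth;
    } else {                      // terminal: close finished subtrees
      while (!pending.empty() && --pending.back() == 0) {
        pending.pop_back();
        --depth;
      }
    }
  }
  return out;
}

// Index (1-based, inclusive) of the last node of the subtree rooted at
// 1-based position i of a prefix-encoded tree.
// [[Rcpp::export]]
int subtree_end_cpp(IntegerVector code, int i) {
  const int len = code.size();
  if (i < 1 || i > len) stop("node index out of range");
  int need = 1, p = i - 1;
  while (p < len) {
    need += (code[p] < 0) ? 1 : -1;
    ++p;
    if (need == 0) return p;
  }
  stop("malformed program code");
}
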
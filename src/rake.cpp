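// Two-stage IPF raking kernel. Operates in place on a strata-by-draws
// matrix of expected death counts; margins are defined by integer group
// codes (0-based after the R-side -1L): stage A = (unit, ageBand, year)
// cells, stage B = benchmark (race, ageBand, year) margins. Draws are
// independent, so each column is iterated to joint convergence on its own.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".rakeCounts")]]
List rakeCounts(NumericMatrix C, IntegerVector iA, IntegerVector iB,
                NumericMatrix A, NumericMatrix B,
                double tol, int maxit) {
  const int n = C.nrow(), nd = C.ncol();
  const int nA = A.nrow(), nB = B.nrow();
  std::vector<double> curA(nA), curB(nB);
  NumericVector perA(nA), perB(nB);
  int itersMax = 0;

  for (int j = 0; j < nd; ++j) {
    double *col = &C(0, j);
    int it = 0;
    while (true) {
      ++it;
      // stage A: scale race-specific counts to the all-race cell totals
      std::fill(curA.begin(), curA.end(), 0.0);
      for (int s = 0; s < n; ++s) curA[iA[s]] += col[s];
      for (int a = 0; a < nA; ++a) {
        const double t = A(a, j);
        if (curA[a] == 0.0) {
          if (t > 0.0)
            stop("structurally infeasible stage-A (unit cell) margin %d, draw %d",
                 a + 1, j + 1);
          curA[a] = 1.0;
        } else {
          curA[a] = t / curA[a];
        }
      }
      for (int s = 0; s < n; ++s) col[s] *= curA[iA[s]];
      // stage B: scale to the benchmark margins
      std::fill(curB.begin(), curB.end(), 0.0);
      for (int s = 0; s < n; ++s) curB[iB[s]] += col[s];
      for (int b = 0; b < nB; ++b) {
        const double t = B(b, j);
        if (curB[b] == 0.0) {
          if (t > 0.0)
            stop("structurally infeasible stage-B (benchmark) margin %d, draw %d",
                 b + 1, j + 1);
          curB[b] = 1.0;
        } else {
          curB[b] = t / curB[b];
        }
      }
      for (int s = 0; s < n; ++s) col[s] *= curB[iB[s]];
      // convergence: stage-A relative discrepancy after the B pass
      std::fill(curA.begin(), curA.end(), 0.0);
      for (int s = 0; s < n; ++s) curA[iA[s]] += col[s];
      double d = 0.0;
      for (int a = 0; a < nA; ++a) {
        const double t = A(a, j);
        if (t > 0.0 || curA[a] > 0.0) {
          const double e = std::fabs(curA[a] - t) / std::max(t, 1e-300);
          if (e > d) d = e;
        }
      }
      if (d <= tol) break;
      if (it >= maxit)
        stop("raking did not converge in %d iterations (discrepancy %g, draw %d)",
             maxit, d, j + 1);
    }
    // final stage-A pass: county totals hold to rounding error
    for (int a = 0; a < nA; ++a) {
      if (curA[a] == 0.0) curA[a] = 1.0;
      else curA[a] = A(a, j) / curA[a];
    }
    for (int s = 0; s < n; ++s) col[s] *= curA[iA[s]];
    // achieved discrepancies (maximum over draws per margin row)
    std::fill(curA.begin(), curA.end(), 0.0);
    std::fill(curB.begin(), curB.end(), 0.0);
    for (int s = 0; s < n; ++s) {
      curA[iA[s]] += col[s];
      curB[iB[s]] += col[s];
    }
    for (int a = 0; a < nA; ++a) {
      const double e = std::fabs(curA[a] - A(a, j)) / std::max(A(a, j), 1e-300);
      if (e > perA[a]) perA[a] = e;
    }
    for (int b = 0; b < nB; ++b) {
      const double e = std::fabs(curB[b] - B(b, j)) / std::max(B(b, j), 1e-300);
      if (e > perB[b]) perB[b] = e;
    }
    if (it > itersMax) itersMax = it;
  }
  return List::create(_["iterations"] = itersMax,
                      _["perA"] = perA, _["perB"] = perB);
}
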
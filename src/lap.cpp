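#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Jonker-Volgenant style shortest-augmenting-path solver for the square
// linear assignment problem (minimisation). Dual potentials u, v are
// maintained so each augmentation is a Dijkstra search over columns.
// Deterministic: column scan order is fixed, ties prefer unassigned columns.

static int augmenting_path(int n, const std::vector<double>& cost,
                           std::vector<double>& u, std::vector<double>& v,
                           std::vector<int>& path, std::vector<int>& row4col,
                           std::vector<double>& shortest, int i,
                           std::vector<char>& SR, std::vector<char>& SC,
                           std::vector<int>& remaining, double* p_minVal) {
  double minVal = 0;
  int num_remaining = n;
  for (int it = 0; it < n; it++) remaining[it] = n - it - 1;
  std::fill(SR.begin(), SR.end(), 0);
  std::fill(SC.begin(), SC.end(), 0);
  std::fill(shortest.begin(), shortest.end(), R_PosInf);

  int sink = -1;
  while (sink == -1) {
    int index = -1;
    double lowest = R_PosInf;
    SR[i] = 1;
    for (int it = 0; it < num_remaining; it++) {
      int j = remaining[it];
      double r = minVal + cost[(size_t)i * n + j] - u[i] - v[j];
      if (r < shortest[j]) {
        path[j] = i;
        shortest[j] = r;
      }
      if (shortest[j] < lowest ||
          (shortest[j] == lowest && row4col[j] == -1)) {
        lowest = shortest[j];
        index = it;
      }
    }
    minVal = lowest;
    if (!R_finite(minVal)) return -1;  // infeasible
    int j = remaining[index];
    if (row4col[j] == -1) sink = j; else i = row4col[j];
    SC[j] = 1;
    remaining[index] = remaining[--num_remaining];
  }
  *p_minVal = minVal;
  return sink;
}

// [[Rcpp::export]]
IntegerVector lap_jv_cpp(NumericMatrix costm) {
  int n = costm.nrow();
  if (costm.ncol() != n) stop("lap_jv_cpp requires a square matrix");
  if (n == 0) return IntegerVector(0);
  std::vector<double> cost((size_t)n * n);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < n; j++) {
      double c = costm(i, j);
      if (!R_finite(c)) stop("lap_jv_cpp requires finite costs");
      cost[(size_t)i * n + j] = c;
    }
  std::vector<double> u(n, 0.0), v(n, 0.0), shortest(n);
  std::vector<int> path(n, -1), col4row(n, -1), row4col(n, -1), remaining(n);
  std::vector<char> SR(n), SC(n);

  for (int curRow = 0; curRow < n; curRow++) {
    double minVal = 0;
    int sink = augmenting_path(n, cost, u, v, path, row4col, shortest,
                               curRow, SR, SC, remaining, &minVal);
    if (sink < 0) stop("assignment problem infeasible");
    u[curRow] += minVal;
    for (int i = 0; i < n; i++)
      if (SR[i] && i != curRow) u[i] += minVal - shortest[col4row[i]];
    for (int j = 0; j < n; j++)
      if (SC[j]) v[j] -= minVal - shortest[j];
    int j = sink;
    for (;;) {
      int i = path[j];
      row4col[j] = i;
      std::swap(col4row[i], j);
      if (i == curRow) break;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; i++) out[i] = col4row[i] + 1;  // 1-based for R
  return out;
}
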
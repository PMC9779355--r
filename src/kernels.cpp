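#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double BIG = 1e15;  // finite stand-in for "no source" in the EDT

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher 2012).
static void dt1d(std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (in cell units) to the nearest TRUE cell.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix src) {
  const int nr = src.nrow(), nc = src.ncol();
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      g(i, j) = src(i, j) ? 0.0 : BIG;
  // columns
  std::vector<double> f(nr), d(nr);
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = g(i, j);
    dt1d(f, d);
    for (int i = 0; i < nr; i++) g(i, j) = d[i];
  }
  // rows
  std::vector<double> fr(nc), dr(nc);
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) fr[j] = g(i, j);
    dt1d(fr, dr);
    for (int j = 0; j < nc; j++) g(i, j) = dr[j];
  }
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      g(i, j) = std::sqrt(g(i, j));
  return g;
}

// Multi-source Dijkstra over the 8- (or 4-) connected lattice.
// Step cost a->b = d(a,b) * (R_a + R_b) / 2, d = cellsize or sqrt(2)*cellsize.
// resistance: NA = blocked. sources: 0-based linear (column-major) indices.
// Returns accumulated cost and 0-based predecessor index (-1 = none/source).
// [[Rcpp::export]]
List cpp_cost_distance(NumericMatrix resistance, IntegerVector sources,
                       double cellsize, bool diagonal) {
  const int nr = resistance.nrow(), nc = resistance.ncol();
  const int n = nr * nc;
  NumericVector cost(n, INF);
  IntegerVector pred(n, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int k = 0; k < sources.size(); k++) {
    int s = sources[k];
    if (s < 0 || s >= n) stop("source index out of range");
    if (NumericVector::is_na(resistance[s]))
      stop("source cell lies on a masked resistance cell");
    cost[s] = 0.0;
    pq.push(Node(0.0, s));
  }
  const int di[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
  const int dj[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };
  const int nnb = diagonal ? 8 : 4;
  const int order4[4] = { 0, 2, 4, 6 };
  const double sq2 = std::sqrt(2.0);
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    double c = top.first;
    int u = top.second;
    if (c > cost[u]) continue;
    int ui = u % nr, uj = u / nr;
    double ru = resistance[u];
    for (int k = 0; k < nnb; k++) {
      int kk = diagonal ? k : order4[k];
      int vi = ui + di[kk], vj = uj + dj[kk];
      if (vi < 0 || vi >= nr || vj < 0 || vj >= nc) continue;
      int v = vi + vj * nr;
      double rv = resistance[v];
      if (NumericVector::is_na(rv)) continue;
      double step = (kk % 2 == 1 ? sq2 : 1.0) * cellsize * 0.5 * (ru + rv);
      double nc2 = c + step;
      if (nc2 < cost[v]) {
        cost[v] = nc2;
        pred[v] = u;
        pq.push(Node(nc2, v));
      }
    }
  }
  NumericMatrix cm(nr, nc);
  IntegerMatrix pm(nr, nc);
  for (int k = 0; k < n; k++) { cm[k] = cost[k]; pm[k] = pred[k]; }
  return List::create(_["cost"] = cm, _["pred"] = pm);
}

// Connected-component labels of equal-valued cells; NA cells unlabelled (0).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix vals, bool diagonal) {
  const int nr = vals.nrow(), nc = vals.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
  const int dj[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };
  const int nnb = diagonal ? 8 : 4;
  const int order4[4] = { 0, 2, 4, 6 };
  int next = 0;
  std::vector<int> stack;
  for (int start = 0; start < nr * nc; start++) {
    if (lab[start] != 0) continue;
    if (IntegerMatrix::is_na(vals[start])) continue;
    int code = vals[start];
    next++;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      int ui = u % nr, uj = u / nr;
      for (int k = 0; k < nnb; k++) {
        int kk = diagonal ? k : order4[k];
        int vi = ui + di[kk], vj = uj + dj[kk];
        if (vi < 0 || vi >= nr || vj < 0 || vj >= nc) continue;
        int v = vi + vj * nr;
        if (lab[v] != 0) continue;
        if (IntegerMatrix::is_na(vals[v])) continue;
        if (vals[v] != code) continue;
        lab[v] = next;
        stack.push_back(v);
      }
    }
  }
  return lab;
}
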
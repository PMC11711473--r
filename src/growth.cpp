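#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Value-rule ids kept in one place; must stay in sync with gnm_rules() in R.
enum Rule {
  SPATIAL, NEIGHBORS, MATCHING,
  CLU_AVG, CLU_MIN, CLU_MAX, CLU_DIFF, CLU_PROD,
  DEG_AVG, DEG_MIN, DEG_MAX, DEG_DIFF, DEG_PROD
};

static int rule_id(const std::string &rule) {
  if (rule == "spatial")   return SPATIAL;
  if (rule == "neighbors") return NEIGHBORS;
  if (rule == "matching")  return MATCHING;
  if (rule == "clu-avg")   return CLU_AVG;
  if (rule == "clu-min")   return CLU_MIN;
  if (rule == "clu-max")   return CLU_MAX;
  if (rule == "clu-diff")  return CLU_DIFF;
  if (rule == "clu-prod")  return CLU_PROD;
  if (rule == "deg-avg")   return DEG_AVG;
  if (rule == "deg-min")   return DEG_MIN;
  if (rule == "deg-max")   return DEG_MAX;
  if (rule == "deg-diff")  return DEG_DIFF;
  if (rule == "deg-prod")  return DEG_PROD;
  stop("unknown value rule: '%s'", rule);
  return -1;
}

// Degree vector from a 0/1 adjacency held as row-major vector<int>.
static void degrees(const std::vector<int> &A, int n, std::vector<int> &k) {
  for (int i = 0; i < n; ++i) {
    int d = 0;
    for (int j = 0; j < n; ++j) d += A[i * n + j];
    k[i] = d;
  }
}

// Local clustering coefficient (binary, 0 when degree < 2).
static void clustering(const std::vector<int> &A, int n,
                       const std::vector<int> &k, std::vector<double> &c) {
  for (int i = 0; i < n; ++i) {
    if (k[i] < 2) { c[i] = 0.0; continue; }
    int t = 0;
    for (int u = 0; u < n; ++u) {
      if (!A[i * n + u]) continue;
      for (int v = u + 1; v < n; ++v)
        if (A[i * n + v] && A[u * n + v]) ++t;
    }
    c[i] = 2.0 * t / (double(k[i]) * (k[i] - 1));
  }
}

// Common-neighbour counts for all pairs; self pairs untouched (left 0).
static void common_neighbors(const std::vector<int> &A, int n,
                             std::vector<int> &cn) {
  std::fill(cn.begin(), cn.end(), 0);
  for (int l = 0; l < n; ++l) {
    // wedge counting through centre l
    std::vector<int> nb;
    for (int i = 0; i < n; ++i) if (A[l * n + i]) nb.push_back(i);
    for (size_t a = 0; a < nb.size(); ++a)
      for (size_t b = a + 1; b < nb.size(); ++b) {
        cn[nb[a] * n + nb[b]] += 1;
        cn[nb[b] * n + nb[a]] += 1;
      }
  }
}

// Fill K (value matrix) for the given rule on the current adjacency.
static void value_fill(const std::vector<int> &A, int n, int rule,
                       std::vector<double> &K) {
  std::vector<int> k(n);
  degrees(A, n, k);
  if (rule == SPATIAL) {
    std::fill(K.begin(), K.end(), 1.0);
    for (int i = 0; i < n; ++i) K[i * n + i] = 0.0;
    return;
  }
  if (rule == NEIGHBORS || rule == MATCHING) {
    std::vector<int> cn(n * n);
    common_neighbors(A, n, cn);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (i == j) { K[i * n + j] = 0.0; continue; }
        int c = cn[i * n + j];
        if (rule == NEIGHBORS) {
          K[i * n + j] = double(c);
        } else {
          // union of neighbourhoods excluding the pair itself
          int uni = (k[i] - A[i * n + j]) + (k[j] - A[i * n + j]) - c;
          K[i * n + j] = uni > 0 ? double(c) / double(uni) : 0.0;
        }
      }
    return;
  }
  std::vector<double> x(n);
  if (rule >= CLU_AVG && rule <= CLU_PROD) {
    clustering(A, n, k, x);
  } else {
    for (int i = 0; i < n; ++i) x[i] = double(k[i]);
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) { K[i * n + j] = 0.0; continue; }
      double a = x[i], b = x[j], v = 0.0;
      switch (rule) {
      case CLU_AVG: case DEG_AVG:  v = 0.5 * (a + b);   break;
      case CLU_MIN: case DEG_MIN:  v = std::min(a, b);  break;
      case CLU_MAX: case DEG_MAX:  v = std::max(a, b);  break;
      case CLU_DIFF: case DEG_DIFF: v = std::fabs(a - b); break;
      case CLU_PROD: case DEG_PROD: v = a * b;          break;
      }
      K[i * n + j] = v;
    }
}

// [[Rcpp::export]]
NumericMatrix value_matrix_cpp(IntegerMatrix adj, std::string rule) {
  int n = adj.nrow();
  int r = rule_id(rule);
  std::vector<int> A(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A[i * n + j] = adj(i, j);
  std::vector<double> K(n * n, 0.0);
  value_fill(A, n, r, K);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = K[i * n + j];
  return out;
}

// Pairwise value for one pair under the current adjacency, from cached
// degree / clustering vectors. Rules needing common-neighbour counts
// compute them on the fly in O(deg).
static double pair_value(const std::vector<int> &A, int n, int rule,
                         const std::vector<int> &k,
                         const std::vector<double> &clu, int i, int j) {
  switch (rule) {
  case SPATIAL: return 1.0;
  case NEIGHBORS: case MATCHING: {
    int c = 0;
    for (int l = 0; l < n; ++l)
      if (A[i * n + l] && A[j * n + l]) ++c;
    if (rule == NEIGHBORS) return double(c);
    int uni = (k[i] - A[i * n + j]) + (k[j] - A[i * n + j]) - c;
    return uni > 0 ? double(c) / double(uni) : 0.0;
  }
  default: break;
  }
  double a, b;
  if (rule >= CLU_AVG && rule <= CLU_PROD) { a = clu[i]; b = clu[j]; }
  else { a = double(k[i]); b = double(k[j]); }
  switch (rule) {
  case CLU_AVG: case DEG_AVG:  return 0.5 * (a + b);
  case CLU_MIN: case DEG_MIN:  return std::min(a, b);
  case CLU_MAX: case DEG_MAX:  return std::max(a, b);
  case CLU_DIFF: case DEG_DIFF: return std::fabs(a - b);
  default:                      return a * b; // *_PROD
  }
}

static double clustering_of(const std::vector<int> &A, int n, int i,
                            int ki) {
  if (ki < 2) return 0.0;
  int t = 0;
  for (int u = 0; u < n; ++u) {
    if (!A[i * n + u]) continue;
    for (int v = u + 1; v < n; ++v)
      if (A[i * n + v] && A[u * n + v]) ++t;
  }
  return 2.0 * t / (double(ki) * (ki - 1));
}

// Iterative growth: each absent pair (i < j) carries the score
// s_ij = d_ij^eta * (K_ij + eps)^gamma; one edge per iteration is drawn
// by inverse-CDF over the deterministic pair ordering using the R RNG.
// After an addition only the affected scores are recomputed: the value
// term of a pair can change only when the neighbourhood, degree or
// clustering of one of its endpoints changed, i.e. pairs touching the
// new edge's endpoints (and, for clustering rules, their common
// neighbours). This incremental update is exactly equivalent to a full
// per-iteration recomputation (tested against it).
// [[Rcpp::export]]
List grow_network_cpp(IntegerMatrix seed, NumericMatrix dist,
                      std::string rule, double eta, double gamma,
                      double eps, int m_target) {
  int n = seed.nrow();
  int r = rule_id(rule);
  if (eps <= 0) stop("epsilon must be positive");

  std::vector<int> A(n * n);
  int m_seed = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      A[i * n + j] = seed(i, j);
      if (j > i && seed(i, j)) ++m_seed;
    }
  int n_add = m_target - m_seed;
  if (n_add < 0) stop("m_target (%d) below seed edge count (%d)", m_target, m_seed);

  int n_pairs = n * (n - 1) / 2;
  if (m_target > n_pairs) stop("m_target exceeds the number of node pairs");

  std::vector<double> deta(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double d = dist(i, j);
      if (!(d > 0)) stop("off-diagonal distances must be positive");
      deta[i * n + j] = std::pow(d, eta);
    }

  std::vector<int> k(n);
  degrees(A, n, k);
  std::vector<double> clu(n, 0.0);
  bool need_clu = (r >= CLU_AVG && r <= CLU_PROD);
  if (need_clu) clustering(A, n, k, clu);

  // s holds scores of absent pairs (0 for present/self), upper triangle.
  std::vector<double> s(n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (A[i * n + j]) continue;
      double kv = pair_value(A, n, r, k, clu, i, j);
      s[i * n + j] = deta[i * n + j] * std::pow(kv + eps, gamma);
    }

  IntegerMatrix tr_edge(n_add, 2);
  NumericMatrix tr_stat(n_add, 2); // prob at selection, Euclidean length

  RNGScope scope;
  std::vector<int> touched;

  for (int it = 0; it < n_add; ++it) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) tot += s[i * n + j];
    if (!(tot > 0) || !R_finite(tot)) stop("all wiring scores vanished");

    double u = unif_rand() * tot, acc = 0.0;
    int si = -1, sj = -1;
    for (int i = 0; i < n && si < 0; ++i)
      for (int j = i + 1; j < n; ++j) {
        acc += s[i * n + j];
        if (u <= acc && s[i * n + j] > 0) { si = i; sj = j; break; }
      }
    if (si < 0) { // numerical edge: take the last positive-score pair
      for (int i = n - 1; i >= 0 && si < 0; --i)
        for (int j = n - 1; j > i; --j)
          if (s[i * n + j] > 0) { si = i; sj = j; break; }
    }

    tr_edge(it, 0) = si + 1;
    tr_edge(it, 1) = sj + 1;
    tr_stat(it, 0) = s[si * n + sj] / tot;
    tr_stat(it, 1) = dist(si, sj);

    A[si * n + sj] = A[sj * n + si] = 1;
    s[si * n + sj] = 0.0;
    k[si] += 1; k[sj] += 1;

    if (r == SPATIAL) continue;

    touched.clear();
    touched.push_back(si);
    touched.push_back(sj);
    if (need_clu) {
      for (int w = 0; w < n; ++w)
        if (A[si * n + w] && A[sj * n + w]) touched.push_back(w);
      for (size_t t = 0; t < touched.size(); ++t) {
        int w = touched[t];
        clu[w] = clustering_of(A, n, w, k[w]);
      }
    }
    std::vector<bool> is_touched(n, false);
    for (size_t t = 0; t < touched.size(); ++t) is_touched[touched[t]] = true;
    for (size_t t = 0; t < touched.size(); ++t) {
      int w = touched[t];
      for (int j = 0; j < n; ++j) {
        if (j == w) continue;
        int lo = std::min(w, j), hi = std::max(w, j);
        if (A[lo * n + hi]) { s[lo * n + hi] = 0.0; continue; }
        double kv = pair_value(A, n, r, k, clu, lo, hi);
        s[lo * n + hi] = deta[lo * n + hi] * std::pow(kv + eps, gamma);
      }
    }
  }

  IntegerMatrix adj(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) adj(i, j) = A[i * n + j];

  return List::create(_["adjacency"] = adj,
                      _["edges"] = tr_edge,
                      _["stats"] = tr_stat,
                      _["m_seed"] = m_seed);
}
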
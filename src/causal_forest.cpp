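// Honest causal forest with gradient-style splitting.
//
// Trees are grown on centered data: Wc = W - e(X), Yc = Y - m(X).
// Within a node the local effect is the no-intercept least-squares slope
//   tau = sum(Wc * Yc) / sum(Wc^2),
// and splits maximize the between-child heterogeneity of that slope via the
// pseudo-outcome rho_i = Wc_i * (Yc_i - Wc_i * tau_parent) (CART criterion
// sum_L^2/n_L + sum_R^2/n_R on rho). Honesty: structure is learned on one
// half of a cluster-level subsample, leaf effects are estimated on the other
// half; degenerate leaves fall back to the nearest valid ancestor.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double kMinVar = 1e-10;
constexpr int kMaxDepthTracked = 50;

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& Wc;
  const std::vector<double>& Yc;
  int mtry;
  int min_node_size;
  std::mt19937_64& rng;
  IntegerMatrix& split_counts;  // p x kMaxDepthTracked, shared across trees

  std::vector<int> split_var;   // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right, parent, depth;
  std::vector<double> rho;      // per-row pseudo-outcome, indexed by row id

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& Wc_,
              const std::vector<double>& Yc_, int mtry_, int min_node_size_,
              std::mt19937_64& rng_, IntegerMatrix& counts_)
      : X(X_), Wc(Wc_), Yc(Yc_), mtry(mtry_), min_node_size(min_node_size_),
        rng(rng_), split_counts(counts_), rho(X_.nrow(), 0.0) {}

  int new_node(int parent_id, int d) {
    split_var.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    parent.push_back(parent_id);
    depth.push_back(d);
    return static_cast<int>(split_var.size()) - 1;
  }

  // Entry point: rows is the split half; feature order lists are built once
  // per tree, then maintained through splits by stable partitioning.
  int grow_root(const std::vector<int>& rows) {
    int p = X.ncol();
    std::vector<std::vector<int>> sorted(p);
    for (int j = 0; j < p; ++j) {
      sorted[j] = rows;
      const double* xj = &X(0, j);
      std::sort(sorted[j].begin(), sorted[j].end(),
                [xj](int a, int b) { return xj[a] < xj[b]; });
    }
    return grow(std::move(sorted), -1, 1);
  }

  int grow(std::vector<std::vector<int>>&& sorted, int parent_id, int d) {
    int node = new_node(parent_id, d);
    int p = X.ncol();
    int n = static_cast<int>(sorted[0].size());
    if (n < 2 * min_node_size) return node;

    double sw2 = 0.0, swy = 0.0;
    for (int i : sorted[0]) {
      sw2 += Wc[i] * Wc[i];
      swy += Wc[i] * Yc[i];
    }
    if (sw2 < kMinVar) return node;
    double tau = swy / sw2;

    double rho_tot = 0.0;
    for (int i : sorted[0]) {
      rho[i] = Wc[i] * (Yc[i] - Wc[i] * tau);
      rho_tot += rho[i];
    }

    int m = std::min(mtry, p);
    // partial Fisher-Yates draw of m distinct feature indices
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feat[j], feat[U(rng)]);
    }
    feat.resize(m);
    // ascending order so ties in gain resolve to the lowest covariate index
    std::sort(feat.begin(), feat.end());

    double best_gain = -1.0;
    int best_var = -1;
    double best_thr = 0.0;

    for (int j : feat) {
      const std::vector<int>& sj = sorted[j];
      const double* xj = &X(0, j);
      if (xj[sj.front()] == xj[sj.back()]) continue;  // constant in node
      double s_left = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        s_left += rho[sj[k]];
        int n_left = k + 1;
        if (n_left < min_node_size) continue;
        if (n - n_left < min_node_size) break;
        if (xj[sj[k]] == xj[sj[k + 1]]) continue;  // not a boundary
        double s_right = rho_tot - s_left;
        double gain = s_left * s_left / n_left + s_right * s_right / (n - n_left);
        if (gain > best_gain + 1e-14 * std::abs(best_gain)) {
          best_gain = gain;
          best_var = j;
          best_thr = 0.5 * (xj[sj[k]] + xj[sj[k + 1]]);
        }
      }
    }
    if (best_var < 0) return node;

    // stable partition of every feature list preserves sort order
    const double* xv = &X(0, best_var);
    std::vector<std::vector<int>> sorted_l(p), sorted_r(p);
    for (int j = 0; j < p; ++j) {
      std::vector<int>& sj = sorted[j];
      for (int i : sj) {
        if (xv[i] <= best_thr) sorted_l[j].push_back(i);
        else sorted_r[j].push_back(i);
      }
      std::vector<int>().swap(sj);  // free as we go
    }
    if (sorted_l[0].empty() || sorted_r[0].empty()) return node;

    split_var[node] = best_var;
    threshold[node] = best_thr;
    int dd = std::min(d, kMaxDepthTracked);
    split_counts(best_var, dd - 1) += 1;
    left[node] = grow(std::move(sorted_l), node, d + 1);
    right[node] = grow(std::move(sorted_r), node, d + 1);
    return node;
  }
};

int descend(const std::vector<int>& split_var, const std::vector<double>& thr,
            const std::vector<int>& left, const std::vector<int>& right,
            const NumericMatrix& X, int row) {
  int node = 0;
  while (split_var[node] >= 0) {
    node = (X(row, split_var[node]) <= thr[node]) ? left[node] : right[node];
  }
  return node;
}

int descend_list(const IntegerVector& split_var, const NumericVector& thr,
                 const IntegerVector& left, const IntegerVector& right,
                 const NumericMatrix& X, int row) {
  int node = 0;
  while (split_var[node] >= 0) {
    node = (X(row, split_var[node]) <= thr[node]) ? left[node] : right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".grow_causal_forest_cpp")]]
List grow_causal_forest_cpp(NumericMatrix X, NumericVector Wc, NumericVector Yc,
                            IntegerVector cluster, int n_clusters,
                            int num_trees, double subsample_rate,
                            double honesty_fraction, int mtry,
                            int min_node_size, double seed) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> wc(Wc.begin(), Wc.end());
  std::vector<double> yc(Yc.begin(), Yc.end());

  // rows grouped by cluster for fast subsampling
  std::vector<std::vector<int>> cluster_rows(n_clusters);
  for (int i = 0; i < n; ++i) cluster_rows[cluster[i]].push_back(i);

  int k_sites = std::max(1, static_cast<int>(std::ceil(subsample_rate * n_clusters)));
  if (k_sites >= n_clusters && n_clusters > 1) k_sites = n_clusters - 1;

  IntegerMatrix split_counts(p, kMaxDepthTracked);
  List trees(num_trees);

  for (int t = 0; t < num_trees; ++t) {
    std::seed_seq ss{static_cast<unsigned int>(static_cast<int64_t>(seed) & 0x7fffffff),
                     static_cast<unsigned int>(t)};
    std::mt19937_64 rng(ss);

    // cluster-level subsample
    std::vector<int> sites(n_clusters);
    for (int c = 0; c < n_clusters; ++c) sites[c] = c;
    for (int c = 0; c < k_sites; ++c) {
      std::uniform_int_distribution<int> U(c, n_clusters - 1);
      std::swap(sites[c], sites[U(rng)]);
    }
    sites.resize(k_sites);
    std::sort(sites.begin(), sites.end());

    std::vector<int> rows;
    for (int c : sites)
      rows.insert(rows.end(), cluster_rows[c].begin(), cluster_rows[c].end());
    std::shuffle(rows.begin(), rows.end(), rng);

    int m = static_cast<int>(rows.size());
    int n_split = std::max(1, static_cast<int>(std::floor(honesty_fraction * m)));
    if (n_split >= m) n_split = m - 1;
    std::vector<int> split_rows(rows.begin(), rows.begin() + n_split);
    std::vector<int> est_rows(rows.begin() + n_split, rows.end());

    TreeBuilder tb(X, wc, yc, mtry, min_node_size, rng, split_counts);
    tb.grow_root(split_rows);
    int n_nodes = static_cast<int>(tb.split_var.size());

    // honest leaf estimates from the estimation half
    std::vector<double> est_sw2(n_nodes, 0.0), est_swy(n_nodes, 0.0);
    std::vector<int> est_cnt(n_nodes, 0);
    std::vector<int> est_leaf(est_rows.size());
    for (size_t k = 0; k < est_rows.size(); ++k) {
      int i = est_rows[k];
      int leaf = descend(tb.split_var, tb.threshold, tb.left, tb.right, X, i);
      est_leaf[k] = leaf;
      // accumulate along the whole root-to-leaf path for ancestor fallback
      int node = leaf;
      while (node >= 0) {
        est_sw2[node] += wc[i] * wc[i];
        est_swy[node] += wc[i] * yc[i];
        est_cnt[node] += 1;
        node = tb.parent[node];
      }
    }
    std::vector<double> leaf_tau(n_nodes, NA_REAL);
    for (int v = 0; v < n_nodes; ++v) {
      if (tb.split_var[v] >= 0) continue;  // internal
      int node = v;
      double tau = 0.0;
      while (node >= 0) {
        if (est_cnt[node] >= 2 && est_sw2[node] > kMinVar) {
          tau = est_swy[node] / est_sw2[node];
          break;
        }
        node = tb.parent[node];
      }
      leaf_tau[v] = tau;
    }

    trees[t] = List::create(
        _["split_var"] = IntegerVector(tb.split_var.begin(), tb.split_var.end()),
        _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
        _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
        _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
        _["depth"] = IntegerVector(tb.depth.begin(), tb.depth.end()),
        _["leaf_tau"] = NumericVector(leaf_tau.begin(), leaf_tau.end()),
        _["sites"] = IntegerVector(sites.begin(), sites.end()),
        _["split_idx"] = IntegerVector(split_rows.begin(), split_rows.end()),
        _["est_idx"] = IntegerVector(est_rows.begin(), est_rows.end()),
        _["est_leaf"] = IntegerVector(est_leaf.begin(), est_leaf.end()));
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["trees"] = trees, _["split_counts"] = split_counts);
}

// Average leaf effect over trees. With oob = TRUE, row i only uses trees
// whose cluster subsample excluded cluster[i]; rows covered by no tree get NA.
// [[Rcpp::export(name = ".predict_trees_cpp")]]
NumericVector predict_trees_cpp(List trees, NumericMatrix X,
                                bool oob, IntegerVector cluster) {
  int n = X.nrow();
  int T = trees.size();
  std::vector<double> acc(n, 0.0);
  std::vector<int> cnt(n, 0);

  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector split_var = tr["split_var"];
    NumericVector thr = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector leaf_tau = tr["leaf_tau"];

    std::vector<bool> in_bag;
    if (oob) {
      IntegerVector sites = tr["sites"];
      int max_site = 0;
      for (int i = 0; i < n; ++i) max_site = std::max(max_site, cluster[i]);
      in_bag.assign(max_site + 1, false);
      for (int s : sites)
        if (s <= max_site) in_bag[s] = true;
    }
    for (int i = 0; i < n; ++i) {
      if (oob && in_bag[cluster[i]]) continue;
      int leaf = descend_list(split_var, thr, left, right, X, i);
      acc[i] += leaf_tau[leaf];
      cnt[i] += 1;
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (cnt[i] > 0) ? acc[i] / cnt[i] : NA_REAL;
  return out;
}
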
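// Path-dependent TreeSHAP for binary-tree ensembles, computed in double
// precision over trees flattened into node arrays (one concatenated set of
// arrays, with per-tree root offsets). The recursion follows Lundberg's
// polynomial-time algorithm: a path of unique features is maintained with
// "zero" (cover) and "one" (decision) fractions and permutation weights,
// extended on descent and unwound when a feature reappears.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement* path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature) {
  path[unique_depth].feature = feature;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = (unique_depth == 0) ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0) /
                           (unique_depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight *
                      (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(PathElement* path, int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1.0) /
                        ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                               (unique_depth - i) / (unique_depth + 1.0);
    } else {
      path[i].pweight = path[i].pweight * (unique_depth + 1.0) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature = path[i + 1].feature;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement* path, int unique_depth,
                               int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  if (one_fraction != 0.0) {
    for (int i = unique_depth - 1; i >= 0; --i) {
      const double tmp = next_one_portion / ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight -
                         tmp * zero_fraction * (unique_depth - i);
    }
  } else {
    for (int i = unique_depth - 1; i >= 0; --i) {
      total += path[i].pweight / (zero_fraction * (unique_depth - i));
    }
  }
  return total * (unique_depth + 1.0);
}

struct TreeView {
  const int* feature;        // -1 at leaves
  const double* threshold;
  const int* yes;            // global node index
  const int* no;
  const double* value;       // leaf value
  const double* cover;
};

static void tree_shap_recursive(const TreeView& t, const double* x,
                                double* phi, int node, int unique_depth,
                                PathElement* parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature) {
  PathElement* path = parent_path + unique_depth + 1;
  std::copy(parent_path, parent_path + unique_depth + 1, path);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature);

  if (t.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement& el = path[i];
      phi[el.feature] += w * (el.one_fraction - el.zero_fraction) *
                         t.value[node];
    }
    return;
  }

  const int split = t.feature[node];
  // xgboost routes records by float32 comparison; mirror it exactly
  const int hot = (static_cast<float>(x[split]) <
                   static_cast<float>(t.threshold[node]))
                      ? t.yes[node] : t.no[node];
  const int cold = (hot == t.yes[node]) ? t.no[node] : t.yes[node];
  const double w = t.cover[node];
  const double hot_zero_fraction = t.cover[hot] / w;
  const double cold_zero_fraction = t.cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (path[path_index].feature == split) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(t, x, phi, hot, unique_depth + 1, path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split);
  tree_shap_recursive(t, x, phi, cold, unique_depth + 1, path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split);
}

static int node_depth(const TreeView& t, int node) {
  if (t.feature[node] < 0) return 1;
  int dl = node_depth(t, t.yes[node]);
  int dr = node_depth(t, t.no[node]);
  return 1 + (dl > dr ? dl : dr);
}

// cover-weighted expected leaf value of the subtree rooted at `node`, using
// the same cover ratios as the SHAP recursion so the local-accuracy identity
// holds exactly even if stored covers are rounded
static double subtree_mean(const TreeView& t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  const double w = t.cover[node];
  return (t.cover[t.yes[node]] / w) * subtree_mean(t, t.yes[node]) +
         (t.cover[t.no[node]] / w) * subtree_mean(t, t.no[node]);
}

static double tree_predict(const TreeView& t, const double* x, int node) {
  while (t.feature[node] >= 0) {
    node = (static_cast<float>(x[t.feature[node]]) <
            static_cast<float>(t.threshold[node]))
               ? t.yes[node] : t.no[node];
  }
  return t.value[node];
}

// X: n x p feature matrix (column-major, dense, no missing values).
// roots: 0-based global node index of each tree's root.
// feature/threshold/yes/no/value/cover: concatenated node arrays; feature is
// the 0-based column index of the split variable, -1 for leaves; yes/no are
// 0-based global node indices.
// Returns an n x (p + 2) matrix: per-feature attributions, the ensemble base
// value (cover-weighted expected margin, repeated per row), and the margin
// prediction recomputed from the same parsed trees.
// [[Rcpp::export(rng = false)]]
NumericMatrix treeshap_predict(const NumericMatrix& X,
                               const IntegerVector& roots,
                               const IntegerVector& feature,
                               const NumericVector& threshold,
                               const IntegerVector& yes,
                               const IntegerVector& no,
                               const NumericVector& value,
                               const NumericVector& cover) {
  const int n = X.nrow(), p = X.ncol(), ntree = roots.size();
  TreeView t;
  t.feature = feature.begin();
  t.threshold = threshold.begin();
  t.yes = yes.begin();
  t.no = no.begin();
  t.value = value.begin();
  t.cover = cover.begin();

  double base = 0.0;
  int max_depth = 0;
  for (int m = 0; m < ntree; ++m) {
    base += subtree_mean(t, roots[m]);
    int d = node_depth(t, roots[m]);
    if (d > max_depth) max_depth = d;
  }
  // buffer for nested copies of the unique path (shap-style triangular layout)
  std::vector<PathElement> path_buf(
      static_cast<size_t>(max_depth + 2) * (max_depth + 3) / 2 + 4);

  NumericMatrix out(n, p + 2);
  std::vector<double> xrow(p), phi(p);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < p; ++k) xrow[k] = X(i, k);
    std::fill(phi.begin(), phi.end(), 0.0);
    double margin = 0.0;
    for (int m = 0; m < ntree; ++m) {
      tree_shap_recursive(t, xrow.data(), phi.data(), roots[m], 0,
                          path_buf.data(), 1.0, 1.0, -1);
      margin += tree_predict(t, xrow.data(), roots[m]);
    }
    for (int k = 0; k < p; ++k) out(i, k) = phi[k];
    out(i, p) = base;
    out(i, p + 1) = margin;
  }
  return out;
}
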
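// Tree-exact SHAP values for regression trees (path-dependent feature
// perturbation). Implements the polynomial-time algorithm of Lundberg et
// al. for a single tree; forests are averaged on the R side.
//
// Tree encoding (0-based node ids): a node is a leaf iff left[node] < 0;
// numeric splits send x[feature] <= threshold to the left child. `cover`
// holds the (weighted) number of training samples reaching each node and
// must be positive at every node.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1) /
                           static_cast<double>(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i) /
                      static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(std::vector<PathElement> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;

  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1) /
                        static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                         (unique_depth - i) /
                         static_cast<double>(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
                         ((unique_depth - i) /
                          static_cast<double>(unique_depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left;
  const int *right;
  const int *feature;
  const double *threshold;
  const double *value;
  const double *cover;
};

static void tree_shap_recursive(const Tree &tree, const double *x,
                                double *phi, int node, int unique_depth,
                                const std::vector<PathElement> &parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  std::vector<PathElement> path(parent_path.begin(),
                                parent_path.begin() + unique_depth);
  path.push_back(PathElement());
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tree.left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tree.value[node];
    }
    return;
  }

  const int split_feature = tree.feature[node];
  const int left = tree.left[node];
  const int right = tree.right[node];
  const int hot = (x[split_feature] <= tree.threshold[node]) ? left : right;
  const int cold = (hot == left) ? right : left;
  const double hot_zero_fraction = tree.cover[hot] / tree.cover[node];
  const double cold_zero_fraction = tree.cover[cold] / tree.cover[node];
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, hot, unique_depth + 1, path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tree, x, phi, cold, unique_depth + 1, path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_feature);
}

// [[Rcpp::export]]
NumericMatrix treeshap_tree_cpp(IntegerVector left, IntegerVector right,
                                IntegerVector feature,
                                NumericVector threshold, NumericVector value,
                                NumericVector cover, NumericMatrix X) {
  const int n = X.nrow();
  const int p = X.ncol();
  NumericMatrix phi(n, p);
  Tree tree;
  tree.left = INTEGER(left);
  tree.right = INTEGER(right);
  tree.feature = INTEGER(feature);
  tree.threshold = REAL(threshold);
  tree.value = REAL(value);
  tree.cover = REAL(cover);

  std::vector<double> x(p);
  std::vector<double> phirow(p);
  std::vector<PathElement> empty_path;
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < p; ++j) {
      x[j] = X(s, j);
      phirow[j] = 0.0;
    }
    tree_shap_recursive(tree, x.data(), phirow.data(), 0, 0, empty_path, 1.0,
                        1.0, -1);
    for (int j = 0; j < p; ++j) phi(s, j) = phirow[j];
  }
  return phi;
}
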
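// Exact Shapley attributions for gradient-boosted tree ensembles in double
// precision (polynomial-time path algorithm).  Trees are passed as flat
// arrays parsed from the booster's text dump; the decision rule is
// x[feature] < threshold -> yes-child.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; i--) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1.0) / (unique_depth + 1.0);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1.0) /
                               ((i + 1.0) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                               (unique_depth - i) / (unique_depth + 1.0);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1.0)) /
                               (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path,
                               int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) /
                         ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight - tmp * zero_fraction *
                         ((unique_depth - i) / (unique_depth + 1.0));
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

struct Tree {
  const int *feature;      // -1 for leaves
  const double *threshold;
  const int *yes;
  const int *no_;
  const double *value;
  const double *cover;
};

static void tree_shap_recursive(const Tree &tr, const double *x, double *phi,
                                int node, int unique_depth,
                                PathElement *parent_unique_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tr.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) *
                               tr.value[node];
    }
    return;
  }

  const int split_feature = tr.feature[node];
  const int hot = ((float)x[split_feature] < (float)tr.threshold[node]) ? tr.yes[node]
                                                          : tr.no_[node];
  const int cold = (hot == tr.yes[node]) ? tr.no_[node] : tr.yes[node];
  const double w = tr.cover[node];
  const double hot_zero_fraction = tr.cover[hot] / w;
  const double cold_zero_fraction = tr.cover[cold] / w;
  double incoming_zero_fraction = 1;
  double incoming_one_fraction = 1;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tr, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tr, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0,
                      split_feature);
}

// expected margin of one tree under the cover distribution
static double tree_expected_value(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  const double w = tr.cover[node];
  return (tr.cover[tr.yes[node]] * tree_expected_value(tr, tr.yes[node]) +
          tr.cover[tr.no_[node]] * tree_expected_value(tr, tr.no_[node])) / w;
}

static int tree_max_depth(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return 1;
  return 1 + std::max(tree_max_depth(tr, tr.yes[node]),
                      tree_max_depth(tr, tr.no_[node]));
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(NumericMatrix x, List trees) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix phi(n, p);
  double base = 0.0;

  const int ntree = trees.size();
  std::vector<std::vector<int>> feat(ntree), yes(ntree), no_(ntree);
  std::vector<std::vector<double>> thr(ntree), val(ntree), cov(ntree);
  std::vector<Tree> T(ntree);
  int max_depth = 1;
  for (int t = 0; t < ntree; ++t) {
    List tl = trees[t];
    feat[t] = as<std::vector<int>>(tl["feature"]);
    thr[t] = as<std::vector<double>>(tl["threshold"]);
    yes[t] = as<std::vector<int>>(tl["yes"]);
    no_[t] = as<std::vector<int>>(tl["no"]);
    val[t] = as<std::vector<double>>(tl["value"]);
    cov[t] = as<std::vector<double>>(tl["cover"]);
    T[t] = Tree{feat[t].data(), thr[t].data(), yes[t].data(), no_[t].data(),
                val[t].data(), cov[t].data()};
    base += tree_expected_value(T[t], 0);
    max_depth = std::max(max_depth, tree_max_depth(T[t], 0));
  }

  std::vector<PathElement> path((max_depth + 2) * (max_depth + 2));
  std::vector<double> xi(p), phii(p);
  NumericVector margin(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xi[j] = x(i, j);
    std::fill(phii.begin(), phii.end(), 0.0);
    double m = 0.0;
    for (int t = 0; t < ntree; ++t) {
      tree_shap_recursive(T[t], xi.data(), phii.data(), 0, 0, path.data(),
                          1, 1, -1);
      // raw margin by traversal (double precision)
      int node = 0;
      while (T[t].feature[node] >= 0) {
        node = ((float)xi[T[t].feature[node]] < (float)T[t].threshold[node])
                   ? T[t].yes[node] : T[t].no_[node];
      }
      m += T[t].value[node];
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phii[j];
    margin[i] = m;
  }

  return List::create(_["phi"] = phi, _["base"] = base,
                      _["margin_raw"] = margin);
}
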
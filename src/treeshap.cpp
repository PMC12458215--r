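// Path-dependent TreeSHAP for binary decision trees (numeric splits,
// rule: x[feature] <= threshold goes left). Trees are supplied as parallel
// node arrays plus per-node covers (weighted training-sample counts).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature;
  double zero;     // fraction of "zero" (feature-missing) paths that flow through
  double one;      // fraction of "one" (feature-present) paths that flow through
  double pweight;  // permutation weight
};

static void extend_path(std::vector<PathElement>& path, double pz, double po,
                        int pi) {
  int l = (int)path.size();
  path.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    path[i + 1].pweight += po * path[i].pweight * (i + 1.0) / (l + 1.0);
    path[i].pweight = pz * path[i].pweight * (l - i) / (l + 1.0);
  }
}

static double unwound_sum(const std::vector<PathElement>& path, int i) {
  int l = (int)path.size() - 1;
  double one = path[i].one, zero = path[i].zero;
  double next = path[l].pweight;
  double total = 0.0;
  for (int j = l - 1; j >= 0; --j) {
    if (one != 0.0) {
      double tmp = next * (l + 1.0) / ((j + 1.0) * one);
      total += tmp;
      next = path[j].pweight - tmp * zero * (l - j) / (l + 1.0);
    } else {
      total += path[j].pweight * (l + 1.0) / (zero * (l - j));
    }
  }
  return total;
}

static void unwind_path(std::vector<PathElement>& path, int i) {
  int l = (int)path.size() - 1;
  double one = path[i].one, zero = path[i].zero;
  double next = path[l].pweight;
  for (int j = l - 1; j >= 0; --j) {
    if (one != 0.0) {
      double tmp = next * (l + 1.0) / ((j + 1.0) * one);
      next = path[j].pweight - tmp * zero * (l - j) / (l + 1.0);
      path[j].pweight = tmp;
    } else {
      path[j].pweight = path[j].pweight * (l + 1.0) / (zero * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    path[j].feature = path[j + 1].feature;
    path[j].zero = path[j + 1].zero;
    path[j].one = path[j + 1].one;
  }
  path.pop_back();
}

struct Tree {
  IntegerVector left, right, feature;
  NumericVector threshold, value, cover;
};

static void shap_recurse(const Tree& t, const NumericVector& x,
                         NumericVector& phi, std::vector<PathElement> path,
                         int node, double pz, double po, int pi) {
  extend_path(path, pz, po, pi);
  if (t.left[node] < 0) {  // leaf
    for (int i = 1; i < (int)path.size(); ++i) {
      double w = unwound_sum(path, i);
      phi[path[i].feature] += w * (path[i].one - path[i].zero) * t.value[node];
    }
    return;
  }
  int f = t.feature[node];
  int hot = (x[f] <= t.threshold[node]) ? t.left[node] : t.right[node];
  int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)path.size(); ++i)
    if (path[i].feature == f) { k = i; break; }
  if (k >= 0) {
    iz = path[k].zero;
    io = path[k].one;
    unwind_path(path, k);
  }
  double cj = t.cover[node];
  shap_recurse(t, x, phi, path, hot, iz * t.cover[hot] / cj, io, f);
  shap_recurse(t, x, phi, path, cold, iz * t.cover[cold] / cj, 0.0, f);
}

// [[Rcpp::export]]
List treeshap_values(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<Tree> parsed(ntree);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    parsed[t] = Tree{tr["left"], tr["right"], tr["feature"], tr["threshold"],
                     tr["value"], tr["cover"]};
    const Tree& tt = parsed[t];
    // tree base value: cover-weighted mean of leaves = expectation at root
    double num = 0.0, den = 0.0;
    for (int j = 0; j < tt.left.size(); ++j) {
      if (tt.left[j] < 0) { num += tt.cover[j] * tt.value[j]; den += tt.cover[j]; }
    }
    base += num / den;
  }
  base /= ntree;
  for (int r = 0; r < n; ++r) {
    NumericVector x = X(r, _);
    NumericVector acc(p);
    for (int t = 0; t < ntree; ++t) {
      std::vector<PathElement> path;
      path.reserve(32);
      shap_recurse(parsed[t], x, acc, path, 0, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(r, j) = acc[j] / ntree;
  }
  return List::create(_["phi"] = phi, _["base_value"] = base);
}
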
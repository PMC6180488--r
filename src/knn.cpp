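#include <Rcpp.h>
#include <algorithm>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Exact k-nearest-neighbor search (Euclidean, self excluded) over the rows
// of a dense score matrix. Distance ties are broken by row index so results
// are fully reproducible. Returns a n x k matrix of 1-based neighbor rows.
// [[Rcpp::export(name = ".knn_indices_cpp")]]
IntegerMatrix knn_indices_cpp(NumericMatrix scores, int k) {
  const int n = scores.nrow(), d = scores.ncol();
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");
  IntegerMatrix nn(n, k);
  // point-major copy for contiguous distance computation
  std::vector<double> pts(static_cast<size_t>(n) * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) pts[static_cast<size_t>(i) * d + c] = scores(i, c);
  std::vector<double> dist(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    const double *pi = &pts[static_cast<size_t>(i) * d];
    for (int j = 0; j < n; ++j) {
      const double *pj = &pts[static_cast<size_t>(j) * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = pi[c] - pj[c];
        s += diff * diff;
      }
      dist[j] = s;
      idx[j] = j;
    }
    dist[i] = R_PosInf;
    auto cmp = [&dist](int a, int b) {
      if (dist[a] != dist[b]) return dist[a] < dist[b];
      return a < b;
    };
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(), cmp);
    for (int c = 0; c < k; ++c) nn(i, c) = idx[c] + 1;
  }
  return nn;
}

// Jaccard similarity of the endpoint neighbor sets for every undirected
// kNN edge (i, j) with j in nn(i, ). Neighbor sets are the k-NN lists
// themselves (cells excluded). Zero-weight edges are dropped.
// [[Rcpp::export(name = ".jaccard_edges_cpp")]]
DataFrame jaccard_edges_cpp(IntegerMatrix nn) {
  const int n = nn.nrow(), k = nn.ncol();
  // sorted neighbor lists for O(k) intersections
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    nbr[i].reserve(k);
    for (int c = 0; c < k; ++c) nbr[i].push_back(nn(i, c));
    std::sort(nbr[i].begin(), nbr[i].end());
  }
  std::unordered_set<long long> seen;
  seen.reserve(static_cast<size_t>(n) * k);
  std::vector<int> from, to;
  std::vector<double> weight;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < k; ++c) {
      const int j = nn(i, c) - 1;
      const int lo = i < j ? i : j, hi = i < j ? j : i;
      const long long key = static_cast<long long>(lo) * n + hi;
      if (!seen.insert(key).second) continue;
      // merge-count the sorted lists
      size_t a = 0, b = 0;
      int inter = 0;
      const std::vector<int> &va = nbr[lo], &vb = nbr[hi];
      while (a < va.size() && b < vb.size()) {
        if (va[a] == vb[b]) { ++inter; ++a; ++b; }
        else if (va[a] < vb[b]) ++a;
        else ++b;
      }
      if (inter == 0) continue;
      const double w = static_cast<double>(inter) / (2.0 * k - inter);
      from.push_back(lo + 1);
      to.push_back(hi + 1);
      weight.push_back(w);
    }
  }
  return DataFrame::create(_["from"] = from, _["to"] = to,
                           _["weight"] = weight);
}
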
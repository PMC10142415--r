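#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance with early exit past `limit`.
static inline int hamming_limited(const std::string& a, const std::string& b,
                                  int limit) {
  int d = 0;
  const size_t n = a.size();
  for (size_t i = 0; i < n; ++i) {
    if (a[i] != b[i] && ++d > limit) return d;
  }
  return d;
}

// Directional UMI network collapse within pre-sorted groups.
//
// `umi`, `reads` and `group` are parallel vectors ordered by `group`
// (consecutive runs of equal group ids); `reads` is the per-UMI read count
// after exact deduplication. Within a group, UMIs are clustered by the
// directional rule: an edge a -> b exists when Hamming(a, b) == 1 and
// reads(a) >= 2 * reads(b) - 1; clusters are grown breadth-first from the
// highest-count unassigned UMI. Returns the number of surviving clusters per
// group, in order of first appearance of each group id.
// [[Rcpp::export(name = ".directional_collapse_groups")]]
IntegerVector directional_collapse_groups(CharacterVector umi,
                                          IntegerVector reads,
                                          IntegerVector group) {
  const int n = umi.size();
  std::vector<std::string> u(n);
  for (int i = 0; i < n; ++i) u[i] = as<std::string>(umi[i]);

  std::vector<int> out;
  int start = 0;
  while (start < n) {
    int end = start;
    while (end < n && group[end] == group[start]) ++end;
    const int m = end - start;

    // order within group by read count, descending (stable)
    std::vector<int> ord(m);
    for (int i = 0; i < m; ++i) ord[i] = start + i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return reads[a] > reads[b]; });

    std::vector<bool> seen(m, false);
    int clusters = 0;
    std::vector<int> stack;
    for (int oi = 0; oi < m; ++oi) {
      int root = ord[oi];
      if (seen[root - start]) continue;
      ++clusters;
      seen[root - start] = true;
      stack.clear();
      stack.push_back(root);
      while (!stack.empty()) {
        int a = stack.back();
        stack.pop_back();
        for (int b = start; b < end; ++b) {
          if (seen[b - start]) continue;
          if (reads[a] < 2 * reads[b] - 1) continue;
          if (hamming_limited(u[a], u[b], 1) == 1) {
            seen[b - start] = true;
            stack.push_back(b);
          }
        }
      }
    }
    out.push_back(clusters);
    start = end;
  }
  return wrap(out);
}
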
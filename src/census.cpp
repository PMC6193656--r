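#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// ESU enumeration (exclusive-neighborhood extension) of all connected
// induced k-subgraphs, emitting for each occurrence the sorted node tuple
// and the adjacency bit code of the induced subgraph in sorted node order.
// Bit order matches the R side: pairs (1,2),(1,3),...,(1,k),(2,3),... with
// bit b worth 2^b starting at b = 0.

namespace {

struct EsuState {
  int n, k;
  const std::vector<std::vector<int>> *adj;
  const std::unordered_set<long long> *eset;
  std::vector<char> in_sub_nbh; // V_sub plus its open neighborhood
  std::vector<int> sub;
  std::vector<int> occ_nodes;   // flat, k per occurrence (1-based ids)
  std::vector<int> occ_codes;

  bool has_edge(int u, int v) const {
    long long a = u < v ? u : v;
    long long b = u < v ? v : u;
    return eset->count(a * (long long)n + b) > 0;
  }

  void record() {
    std::vector<int> s(sub);
    std::sort(s.begin(), s.end());
    int code = 0, bit = 0;
    for (int i = 0; i < k - 1; ++i)
      for (int j = i + 1; j < k; ++j, ++bit)
        if (has_edge(s[i], s[j])) code |= (1 << bit);
    for (int i = 0; i < k; ++i) occ_nodes.push_back(s[i] + 1);
    occ_codes.push_back(code);
  }

  void extend(std::vector<int> ext, int root) {
    if ((int)sub.size() == k) {
      record();
      return;
    }
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2(ext);
      for (int u : (*adj)[w])
        if (u > root && !in_sub_nbh[u]) ext2.push_back(u);
      sub.push_back(w);
      std::vector<int> newly;
      for (int u : (*adj)[w])
        if (!in_sub_nbh[u]) { in_sub_nbh[u] = 1; newly.push_back(u); }
      extend(ext2, root);
      sub.pop_back();
      for (int u : newly) in_sub_nbh[u] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".esu_census_cpp")]]
List esu_census_cpp(IntegerMatrix edges, int n_nodes, int k) {
  std::vector<std::vector<int>> adj(n_nodes);
  std::unordered_set<long long> eset;
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    adj[u].push_back(v);
    adj[v].push_back(u);
    long long a = u < v ? u : v;
    long long b = u < v ? v : u;
    eset.insert(a * (long long)n_nodes + b);
  }

  EsuState st;
  st.n = n_nodes;
  st.k = k;
  st.adj = &adj;
  st.eset = &eset;
  st.in_sub_nbh.assign(n_nodes, 0);

  if (k >= 2 && n_nodes >= k) {
    for (int v = 0; v < n_nodes; ++v) {
      std::vector<int> ext;
      for (int u : adj[v])
        if (u > v) ext.push_back(u);
      st.sub.assign(1, v);
      st.in_sub_nbh[v] = 1;
      std::vector<int> newly;
      for (int u : adj[v])
        if (!st.in_sub_nbh[u]) { st.in_sub_nbh[u] = 1; newly.push_back(u); }
      st.extend(ext, v);
      st.in_sub_nbh[v] = 0;
      for (int u : newly) st.in_sub_nbh[u] = 0;
    }
  }

  int nocc = (int)st.occ_codes.size();
  IntegerMatrix occ(nocc, k);
  for (int r = 0; r < nocc; ++r)
    for (int c = 0; c < k; ++c) occ(r, c) = st.occ_nodes[(size_t)r * k + c];
  IntegerVector codes(st.occ_codes.begin(), st.occ_codes.end());
  return List::create(_["nodes"] = occ, _["codes"] = codes);
}
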
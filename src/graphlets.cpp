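// Exact graphlet orbit counting by single-pass ESU enumeration of all
// connected induced subgraphs on 2-5 nodes.  Each subgraph is classified by
// its adjacency bit code through lookup tables (code x position -> orbit id)
// built in R from the graphlet/orbit catalog.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Ctx {
  const std::vector<std::vector<int>> *adj;  // sorted neighbor lists, 0-based
  const int *tab3, *tab4, *tab5;             // code-major tables, length 2^C(k,2)*k
  double *counts;                            // n x 73, column-major
  int n;
};

inline bool has_edge(const Ctx &c, int a, int b) {
  const std::vector<int> &na = (*c.adj)[a];
  return std::binary_search(na.begin(), na.end(), b);
}

// record the connected induced subgraph on sub[0..k-1] (ascending order)
void record(const Ctx &c, const int *sub, int k) {
  int code = 0, bit = 0;
  for (int i = 0; i < k - 1; ++i)
    for (int j = i + 1; j < k; ++j) {
      if (has_edge(c, sub[i], sub[j])) code |= (1 << bit);
      ++bit;
    }
  const int *tab = (k == 2) ? nullptr : (k == 3 ? c.tab3 : (k == 4 ? c.tab4 : c.tab5));
  for (int i = 0; i < k; ++i) {
    int orb = (k == 2) ? 0 : tab[code * k + i];
    c.counts[(size_t)orb * c.n + sub[i]] += 1.0;
  }
}

// Wernicke's ESU: enumerate every connected induced subgraph whose minimum
// vertex is v exactly once; record at every size 2..5.
void extend(const Ctx &c, std::vector<int> &sub, std::vector<int> &ext, int v,
            std::vector<char> &insub, std::vector<char> &nbsub) {
  const int k = (int)sub.size();
  if (k >= 2) {
    int tmp[5];
    std::copy(sub.begin(), sub.end(), tmp);
    std::sort(tmp, tmp + k);
    record(c, tmp, k);
  }
  if (k == 5) return;
  std::vector<int> ext_local = ext;
  while (!ext_local.empty()) {
    int w = ext_local.back();
    ext_local.pop_back();
    // extension set for the recursive call: remaining ext plus exclusive
    // neighbors of w (neighbors > v not in sub and not already adjacent to sub)
    std::vector<int> ext2 = ext_local;
    std::vector<int> newly;
    for (int u : (*c.adj)[w]) {
      if (u > v && !insub[u] && !nbsub[u]) {
        ext2.push_back(u);
        newly.push_back(u);
        nbsub[u] = 1;
      }
    }
    sub.push_back(w);
    insub[w] = 1;
    extend(c, sub, ext2, v, insub, nbsub);
    insub[w] = 0;
    sub.pop_back();
    for (int u : newly) nbsub[u] = 0;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_count_orbits(int n, List adjlist, IntegerVector tab3,
                               IntegerVector tab4, IntegerVector tab5) {
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adjlist[i];
    adj[i].assign(a.begin(), a.end());
    std::sort(adj[i].begin(), adj[i].end());
  }
  NumericMatrix counts(n, 73);
  Ctx c{&adj, tab3.begin(), tab4.begin(), tab5.begin(), counts.begin(), n};

  std::vector<char> insub(n, 0), nbsub(n, 0);
  std::vector<int> sub, ext;
  for (int v = 0; v < n; ++v) {
    sub.assign(1, v);
    insub[v] = 1;
    ext.clear();
    std::vector<int> marked;
    for (int u : adj[v])
      if (u > v) {
        ext.push_back(u);
        nbsub[u] = 1;
        marked.push_back(u);
      }
    extend(c, sub, ext, v, insub, nbsub);
    insub[v] = 0;
    for (int u : marked) nbsub[u] = 0;
  }
  return counts;
}
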
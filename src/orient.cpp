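#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Make face windings consistent by breadth-first propagation across shared
// edges: two faces sharing an edge must traverse it in opposite directions.
// F: m x 3, 0-based. Returns the re-wound face matrix (0-based).
// [[Rcpp::export]]
IntegerMatrix cpp_orient_consistent(IntegerMatrix F) {
  int m = F.nrow();
  std::vector<std::array<int, 3>> f(m);
  for (int i = 0; i < m; ++i) f[i] = {F(i, 0), F(i, 1), F(i, 2)};
  // undirected edge -> incident faces
  std::map<std::pair<int, int>, std::vector<int>> emap;
  for (int i = 0; i < m; ++i)
    for (int e = 0; e < 3; ++e) {
      int a = f[i][e], b = f[i][(e + 1) % 3];
      emap[{std::min(a, b), std::max(a, b)}].push_back(i);
    }
  std::vector<int> state(m, 0);  // 0 unvisited, 1 queued/done
  std::vector<int> queue;
  for (int s = 0; s < m; ++s) {
    if (state[s]) continue;
    state[s] = 1;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      int cur = queue.back();
      queue.pop_back();
      for (int e = 0; e < 3; ++e) {
        int a = f[cur][e], b = f[cur][(e + 1) % 3];
        auto &inc = emap[{std::min(a, b), std::max(a, b)}];
        for (int nb : inc) {
          if (nb == cur || state[nb]) continue;
          // neighbour must traverse edge as (b, a); if it has (a, b), flip
          bool same_dir = false;
          for (int e2 = 0; e2 < 3; ++e2)
            if (f[nb][e2] == a && f[nb][(e2 + 1) % 3] == b) same_dir = true;
          if (same_dir) std::swap(f[nb][1], f[nb][2]);
          state[nb] = 1;
          queue.push_back(nb);
        }
      }
    }
  }
  IntegerMatrix out(m, 3);
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = f[i][d];
  return out;
}
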
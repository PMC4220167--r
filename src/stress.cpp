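#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stress centrality of an unweighted undirected simple graph by
// Brandes-style BFS accumulation. For each source s a BFS records shortest
// path counts sigma and predecessor lists; a backward sweep accumulates
// psi[v] = number of shortest continuations from v to nodes farther from s,
// so sigma[v] * psi[v] is the count of shortest s-* paths through v. Each
// unordered pair is seen from both endpoints, hence the final halving.
// Path counts are kept in doubles: counts can exceed integer range on
// hub-dense graphs.
// [[Rcpp::export]]
NumericVector stress_brandes(int n, IntegerMatrix edges) {
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i, 0), b = edges(i, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  NumericVector stress(n);
  std::vector<int> dist(n), order(n), queue(n);
  std::vector<double> sigma(n), psi(n);
  std::vector<std::vector<int>> pred(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(psi.begin(), psi.end(), 0.0);
    for (int v = 0; v < n; ++v) pred[v].clear();

    int head = 0, tail = 0, norder = 0;
    dist[s] = 0;
    sigma[s] = 1.0;
    queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      order[norder++] = v;
      for (int w : adj[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          queue[tail++] = w;
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int i = norder - 1; i > 0; --i) {
      int w = order[i];
      for (int v : pred[w]) psi[v] += 1.0 + psi[w];
      stress[w] += sigma[w] * psi[w];
    }
  }
  for (int v = 0; v < n; ++v) stress[v] /= 2.0;
  return stress;
}
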
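#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Depth-first enumeration of simple paths of length <= tau between given
// node pairs in an undirected weighted graph, accumulating the decay-weighted
// score on the fly (paths are never materialized). Weight matrix W: 0 means
// no edge. decay_form: 1 = exp_decay (prod * alpha^-len),
// 2 = product_power (prod^(alpha*len)).

namespace {

struct Dfs {
  const std::vector<std::vector<int> >& nbr;
  const std::vector<std::vector<double> >& wt;
  std::vector<char>& visited;
  int target, tau, decay_form;
  double alpha;
  double score;
  long long n_paths;

  Dfs(const std::vector<std::vector<int> >& nbr_,
      const std::vector<std::vector<double> >& wt_,
      std::vector<char>& visited_, int target_, int tau_, double alpha_,
      int decay_form_)
      : nbr(nbr_), wt(wt_), visited(visited_), target(target_), tau(tau_),
        decay_form(decay_form_), alpha(alpha_), score(0.0), n_paths(0) {}

  void run(int u, int depth, double prod) {
    // depth = number of edges used to reach u from the source
    visited[u] = 1;
    const std::vector<int>& nb = nbr[u];
    const std::vector<double>& w = wt[u];
    for (size_t k = 0; k < nb.size(); ++k) {
      int v = nb[k];
      double p2 = prod * w[k];
      if (v == target) {
        int len = depth + 1;
        score += (decay_form == 1) ? p2 * std::pow(alpha, -(double)len)
                                   : std::pow(p2, alpha * len);
        ++n_paths;
      } else if (!visited[v] && depth + 1 < tau) {
        run(v, depth + 1, p2);
      }
    }
    visited[u] = 0;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_path_scores(NumericMatrix W, IntegerVector from, IntegerVector to,
                     int tau, double alpha, int decay_form) {
  int n = W.nrow();
  std::vector<std::vector<int> > nbr(n);
  std::vector<std::vector<double> > wt(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double w = W(i, j);
      if (w > 0.0) {
        nbr[i].push_back(j);
        wt[i].push_back(w);
      }
    }
  }
  int m = from.size();
  NumericVector scores(m);
  NumericVector npaths(m);
  std::vector<char> visited(n, 0);
  for (int q = 0; q < m; ++q) {
    Dfs dfs(nbr, wt, visited, to[q], tau, alpha, decay_form);
    dfs.run(from[q], 0, 1.0);
    scores[q] = dfs.score;
    npaths[q] = (double)dfs.n_paths;
  }
  return List::create(_["score"] = scores, _["n_paths"] = npaths);
}
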
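#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <queue>
using namespace Rcpp;

// Bounded breadth-first enumeration of the states reachable from `start`.
// Nodes at max_depth are kept but their unseen successors are dropped
// (and the truncation flag set); edges between enumerated nodes are
// always kept. Returns 1-based node indices for edges.
// [[Rcpp::export]]
List enumerate_cpp(const std::string& start, const CharacterVector& lhs,
                   const CharacterVector& rhs, const int max_depth,
                   const int max_len, const int max_nodes) {
  std::vector<std::string> L(lhs.size()), R(lhs.size());
  for (int r = 0; r < lhs.size(); ++r) {
    L[r] = as<std::string>(lhs[r]);
    R[r] = as<std::string>(rhs[r]);
  }
  std::vector<std::string> nodes;
  std::vector<int> depth;
  std::unordered_map<std::string, int> idx;
  nodes.push_back(start);
  depth.push_back(0);
  idx[start] = 0;
  std::vector<int> ef, er, ep, et;
  bool truncated = false;
  size_t qhead = 0;
  while (qhead < nodes.size()) {
    const std::string s = nodes[qhead];
    const int d = depth[qhead];
    const int n = (int)s.size();
    for (int r = 0; r < (int)L.size(); ++r) {
      const int m = (int)L[r].size();
      for (int p = 0; p + m <= n; ++p) {
        if (s.compare(p, m, L[r]) != 0) continue;
        std::string to;
        to.reserve(n - m + R[r].size());
        to.append(s, 0, p);
        to.append(R[r]);
        to.append(s, p + m, std::string::npos);
        if ((int)to.size() > max_len) { truncated = true; continue; }
        auto it = idx.find(to);
        int j;
        if (it == idx.end()) {
          if (d + 1 > max_depth || (int)nodes.size() >= max_nodes) {
            truncated = true;
            continue;
          }
          j = (int)nodes.size();
          idx[to] = j;
          nodes.push_back(to);
          depth.push_back(d + 1);
        } else {
          j = it->second;
        }
        ef.push_back((int)qhead + 1);
        er.push_back(r + 1);
        ep.push_back(p);
        et.push_back(j + 1);
      }
    }
    ++qhead;
  }
  return List::create(_["nodes"] = wrap(nodes), _["depth"] = wrap(depth),
                      _["ef"] = wrap(ef), _["er"] = wrap(er),
                      _["ep"] = wrap(ep), _["et"] = wrap(et),
                      _["truncated"] = truncated);
}

// Distance of every node to `goal_idx` (1-based) over the directed edge
// set, by reverse breadth-first search. Unreachable nodes get NA.
// [[Rcpp::export]]
IntegerVector reverse_bfs_cpp(const int n_nodes, const IntegerVector& ef,
                              const IntegerVector& et, const int goal_idx) {
  std::vector<std::vector<int> > radj(n_nodes);
  for (int e = 0; e < ef.size(); ++e)
    radj[et[e] - 1].push_back(ef[e] - 1);
  IntegerVector dist(n_nodes, NA_INTEGER);
  std::queue<int> q;
  dist[goal_idx - 1] = 0;
  q.push(goal_idx - 1);
  while (!q.empty()) {
    const int v = q.front(); q.pop();
    for (int u : radj[v]) {
      if (dist[u] == NA_INTEGER) {
        dist[u] = dist[v] + 1;
        q.push(u);
      }
    }
  }
  return dist;
}

// TRUE iff some state w is reachable from a state u by the same two
// (rule, position) applications in either order.
// [[Rcpp::export]]
bool commutative_cpp(const int n_nodes, const IntegerVector& ef,
                     const IntegerVector& er, const IntegerVector& ep,
                     const IntegerVector& et) {
  // key an edge by (from, rule, pos) for O(1) lookup of its target
  std::unordered_map<long long, int> tgt;
  std::vector<std::vector<int> > adj(n_nodes);
  const long long RP = 1024;  // rule and position each < 1024
  for (int e = 0; e < ef.size(); ++e) {
    const long long key = ((long long)(ef[e]) * RP + er[e]) * RP + ep[e];
    tgt[key] = et[e];
    adj[ef[e] - 1].push_back(e);
  }
  for (int u = 0; u < n_nodes; ++u) {
    const std::vector<int>& out = adj[u];
    for (size_t i = 0; i + 1 < out.size(); ++i) {
      for (size_t j = i + 1; j < out.size(); ++j) {
        const int e1 = out[i], e2 = out[j];
        auto w1 = tgt.find(((long long)(et[e1]) * RP + er[e2]) * RP +
                           ep[e2]);
        if (w1 == tgt.end()) continue;
        auto w2 = tgt.find(((long long)(et[e2]) * RP + er[e1]) * RP +
                           ep[e1]);
        if (w2 != tgt.end() && w1->second == w2->second) return true;
      }
    }
  }
  return false;
}
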
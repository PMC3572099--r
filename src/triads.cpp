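#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Directed-edge key helpers: nodes are 0-based, n < 2^20 assumed.
static inline long long dkey(int u, int v, int n) {
  return (long long)u * n + v;
}

// Census of the 13 connected directed triad classes.
// from/to: 0-based directed edge list (no self loops, no multi-edges);
// n: node count; class_of_mask: length-64 integer map from the 6-bit
// adjacency mask (bits: u->v, u->w, v->u, v->w, w->u, w->v) to class 1..13
// (0 = disconnected; never hit here because triples are generated from a
// skeleton edge plus a neighbour). Triple enumeration follows the
// Batagelj-Mrvar scheme: each connected triple is visited exactly once.
// [[Rcpp::export]]
IntegerVector cpp_triad_census(IntegerVector from, IntegerVector to, int n,
                               IntegerVector class_of_mask) {
  int m = from.size();
  std::unordered_set<long long> dir;
  dir.reserve(m * 2);
  std::vector<std::vector<int>> adj(n);
  std::unordered_set<long long> skel;
  skel.reserve(m * 2);
  for (int e = 0; e < m; ++e) {
    int u = from[e], v = to[e];
    dir.insert(dkey(u, v, n));
    int a = std::min(u, v), b = std::max(u, v);
    long long k = dkey(a, b, n);
    if (skel.find(k) == skel.end()) {
      skel.insert(k);
      adj[a].push_back(b);
      adj[b].push_back(a);
    }
  }
  IntegerVector counts(13);
  std::vector<int> mark(n, -1);
  std::vector<int> cand;
  int stamp = 0;
  for (int u = 0; u < n; ++u) {
    for (int v : adj[u]) {
      if (v <= u) continue;
      ++stamp;
      cand.clear();
      for (int w : adj[u]) if (w != v) { if (mark[w] != stamp) { mark[w] = stamp; cand.push_back(w); } }
      for (int w : adj[v]) if (w != u) { if (mark[w] != stamp) { mark[w] = stamp; cand.push_back(w); } }
      for (int w : cand) {
        bool take = (v < w);
        if (!take && u < w && w < v) {
          long long k = dkey(std::min(u, w), std::max(u, w), n);
          take = (skel.find(k) == skel.end());
        }
        if (!take) continue;
        int mask = 0;
        if (dir.count(dkey(u, v, n))) mask |= 1;
        if (dir.count(dkey(u, w, n))) mask |= 2;
        if (dir.count(dkey(v, u, n))) mask |= 4;
        if (dir.count(dkey(v, w, n))) mask |= 8;
        if (dir.count(dkey(w, u, n))) mask |= 16;
        if (dir.count(dkey(w, v, n))) mask |= 32;
        int cls = class_of_mask[mask];
        if (cls >= 1 && cls <= 13) counts[cls - 1]++;
      }
    }
  }
  return counts;
}

static inline int rand_index(int size) {
  int i = (int)(unif_rand() * size);
  return (i >= size) ? size - 1 : i;
}

// Degree-preserving switching randomization of a directed network.
// Unidirectional edges and reciprocal (mutual) pairs are swapped within
// their own subsets, so every node's in- and out-degree and the count of
// reciprocal edges are preserved exactly; swaps creating self loops,
// multi-edges, or new reciprocal pairs are rejected. target swaps =
// q * (number of unidirectional edges + reciprocal pairs), attempts capped.
// [[Rcpp::export]]
List cpp_switch_randomize(IntegerVector from, IntegerVector to, int n,
                          double q, int attempts_factor) {
  int m = from.size();
  std::unordered_set<long long> dir;
  dir.reserve(m * 2);
  for (int e = 0; e < m; ++e) dir.insert(dkey(from[e], to[e], n));

  std::vector<std::pair<int,int>> uni, rec; // rec stores u < v, one per pair
  for (int e = 0; e < m; ++e) {
    int u = from[e], v = to[e];
    if (dir.count(dkey(v, u, n))) {
      if (u < v) rec.push_back({u, v});
    } else {
      uni.push_back({u, v});
    }
  }

  long long target_u = uni.size() < 2 ? 0 : (long long)std::ceil(q * uni.size());
  long long target_r = rec.size() < 2 ? 0 : (long long)std::ceil(q * rec.size());
  long long done_u = 0, done_r = 0;

  if (uni.size() >= 2) {
    long long attempts = 0, cap = attempts_factor * std::max(target_u, 1LL);
    while (done_u < target_u && attempts < cap) {
      ++attempts;
      int i = rand_index(uni.size());
      int j = rand_index(uni.size());
      if (i == j) continue;
      int a = uni[i].first, b = uni[i].second;
      int c = uni[j].first, d = uni[j].second;
      if (a == d || c == b) continue;
      if (dir.count(dkey(a, d, n)) || dir.count(dkey(d, a, n)) ||
          dir.count(dkey(c, b, n)) || dir.count(dkey(b, c, n))) continue;
      dir.erase(dkey(a, b, n));
      dir.erase(dkey(c, d, n));
      dir.insert(dkey(a, d, n));
      dir.insert(dkey(c, b, n));
      uni[i].second = d;
      uni[j].second = b;
      ++done_u;
    }
  }
  if (rec.size() >= 2) {
    long long attempts = 0, cap = attempts_factor * std::max(target_r, 1LL);
    while (done_r < target_r && attempts < cap) {
      ++attempts;
      int i = rand_index(rec.size());
      int j = rand_index(rec.size());
      if (i == j) continue;
      int a = rec[i].first, b = rec[i].second;
      int c = rec[j].first, d = rec[j].second;
      if (a == c || a == d || b == c || b == d) continue;
      if (dir.count(dkey(a, d, n)) || dir.count(dkey(d, a, n)) ||
          dir.count(dkey(c, b, n)) || dir.count(dkey(b, c, n))) continue;
      dir.erase(dkey(a, b, n)); dir.erase(dkey(b, a, n));
      dir.erase(dkey(c, d, n)); dir.erase(dkey(d, c, n));
      dir.insert(dkey(a, d, n)); dir.insert(dkey(d, a, n));
      dir.insert(dkey(c, b, n)); dir.insert(dkey(b, c, n));
      rec[i] = {std::min(a, d), std::max(a, d)};
      rec[j] = {std::min(c, b), std::max(c, b)};
      ++done_r;
    }
  }

  IntegerVector rf(m), rt(m);
  int e = 0;
  for (auto &p : uni) { rf[e] = p.first; rt[e] = p.second; ++e; }
  for (auto &p : rec) {
    rf[e] = p.first;  rt[e] = p.second; ++e;
    rf[e] = p.second; rt[e] = p.first;  ++e;
  }
  return List::create(_["from"] = rf, _["to"] = rt,
                      _["swaps"] = (double)(done_u + done_r),
                      _["target"] = (double)(target_u + target_r));
}
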
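// Exact earth mover's distance: dense transportation problem solved by the
// transportation (network) simplex. Vogel-approximation initial basis with
// lazily cached line minima; rooted-tree bookkeeping (parent/depth) so the
// pivot cycle is found by an LCA walk instead of a tree search; incremental
// dual updates on the detached subtree; candidate-list block pivoting; a
// tiny supply perturbation against degenerate cycling; and a final exact
// re-flow of the optimal basis with the unperturbed marginals so the
// returned cost is exact.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct UF {
  std::vector<int> p;
  explicit UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    p[a] = b; return true;
  }
};

class Transport {
public:
  int m, n, N;
  const double *C;                 // column-major m x n
  std::vector<double> a, b;        // perturbed marginals
  std::vector<int> ei, ej;         // edge endpoints (row, col)
  std::vector<double> ef;          // edge flow
  std::vector<std::vector<int> > adj;
  std::vector<double> u, v;
  std::vector<int> par, pedge, depth;   // rooted tree (root = node 0)
  std::vector<int> stack_, comp, path;
  std::vector<long> cand;
  std::vector<int> mark;
  int token;

  double cost(int i, int j) const { return C[i + (size_t)m * j]; }

  Transport(const double *Cptr, int m_, int n_) : m(m_), n(n_), N(m_ + n_), C(Cptr),
    adj(N), u(m_), v(n_), par(N, -1), pedge(N, -1), depth(N, 0), mark(N, 0), token(0) {}

  void add_edge(int i, int j, double f) {
    int id = (int)ei.size();
    ei.push_back(i); ej.push_back(j); ef.push_back(f);
    adj[i].push_back(id); adj[m + j].push_back(id);
  }

  int other(int id, int x) const { return (x == ei[id]) ? m + ej[id] : ei[id]; }

  // initial basis: nearest-available greedy (row minimum), completed to a
  // spanning tree with zero-flow edges; cheap (O(mn)) and good enough that
  // the simplex needs only a few thousand pivots at ~350x350
  void init_basis() {
    std::vector<double> ra(a), rb(b);
    UF uf(N);
    for (int i = 0; i < m; ++i) {
      while (ra[i] > 0) {
        int best = -1; double bc = 0;
        for (int j = 0; j < n; ++j)
          if (rb[j] > 0 && (best < 0 || cost(i, j) < bc)) { best = j; bc = cost(i, j); }
        if (best < 0) break;
        double f = std::min(ra[i], rb[best]);
        add_edge(i, best, f);
        uf.unite(i, m + best);
        ra[i] -= f; rb[best] -= f;
      }
    }
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j)
        if (uf.find(i) != uf.find(m + j)) { add_edge(i, j, 0.0); uf.unite(i, m + j); }
  }

  // full recompute of duals and the rooted-tree arrays (BFS from node 0)
  void recompute_tree() {
    ++token;
    stack_.clear(); stack_.push_back(0); mark[0] = token;
    u[0] = 0; par[0] = -1; pedge[0] = -1; depth[0] = 0;
    while (!stack_.empty()) {
      int x = stack_.back(); stack_.pop_back();
      for (size_t t = 0; t < adj[x].size(); ++t) {
        int id = adj[x][t];
        int y = other(id, x);
        if (mark[y] == token) continue;
        mark[y] = token;
        par[y] = x; pedge[y] = id; depth[y] = depth[x] + 1;
        if (y >= m) v[y - m] = cost(ei[id], ej[id]) - u[ei[id]];
        else u[y] = cost(ei[id], ej[id]) - v[ej[id]];
        stack_.push_back(y);
      }
    }
  }

  double solve() {
    init_basis();
    recompute_tree();
    double cmax = 0;
    for (size_t p = 0, e = (size_t)m * n; p < e; ++p)
      cmax = std::max(cmax, std::fabs(C[p]));
    const double eps = 1e-10 * (1.0 + cmax);
    const long arcs = (long)m * n;
    int block = (int)std::sqrt((double)arcs); if (block < 64) block = 64;
    long scan_pos = 0;
    const long max_pivots = 2000000L + 200L * (m + n);
    long pivots = 0;
    bool refreshed = false;
    bool sparse = false;  // end-game: negatives rare, cache a wrap's worth
    std::vector<int> up_a, up_b;  // edge lists walking up from bi / bj
    while (true) {
      // entering arc: steepest of the cached candidates (re-validated), or
      // steepest within the first block containing a negative; when blocks
      // come up empty repeatedly, switch to collecting a full wrap of
      // negatives so the dense scan is amortised over many pivots
      long bq = -1; double bred = -eps;
      size_t keep = 0;
      for (size_t t = 0; t < cand.size(); ++t) {
        long q = cand[t];
        double red = C[q] - u[(int)(q % m)] - v[(int)(q / m)];
        if (red < -eps) {
          cand[keep++] = q;
          if (red < bred) { bred = red; bq = q; }
        }
      }
      cand.resize(keep);
      if (bq < 0) {
        long scanned = 0, empty_blocks = 0;
        while (scanned < arcs + block) {
          long end = scan_pos + block;
          for (long p = scan_pos; p < end; ++p) {
            long q = p % arcs;
            double red = C[q] - u[(int)(q % m)] - v[(int)(q / m)];
            if (red < bred) { bred = red; bq = q; }
            if (sparse && red < -eps && cand.size() < 1024) cand.push_back(q);
          }
          scanned += block;
          scan_pos = (scan_pos + block) % arcs;
          if (bq < 0) ++empty_blocks;
          if (bq >= 0 && !sparse) break;
          if (bq >= 0 && sparse && scanned >= arcs) break;
        }
        if (empty_blocks > 8) sparse = true;
      }
      if (bq < 0) {
        if (refreshed) break;
        recompute_tree();  // guard against incremental drift before optimality
        refreshed = true;
        continue;
      }
      refreshed = false;
      int bi = (int)(bq % m), bj = (int)(bq / m);
      // cycle via LCA walk
      up_a.clear(); up_b.clear();
      int x = bi, y = m + bj;
      while (x != y) {
        if (depth[x] >= depth[y]) { up_a.push_back(pedge[x]); x = par[x]; }
        else { up_b.push_back(pedge[y]); y = par[y]; }
      }
      path.clear();
      path.insert(path.end(), up_a.begin(), up_a.end());
      for (size_t t = up_b.size(); t-- > 0; ) path.push_back(up_b[t]);
      double theta = R_PosInf; int leave = -1; size_t leave_pos = 0;
      for (size_t t = 0; t < path.size(); t += 2) {
        if (ef[path[t]] < theta) { theta = ef[path[t]]; leave = path[t]; leave_pos = t; }
      }
      for (size_t t = 0; t < path.size(); ++t) {
        if (t % 2 == 0) ef[path[t]] -= theta; else ef[path[t]] += theta;
      }
      // detach leaving edge; the detached component contains bi if the
      // leaving edge was on bi's side of the cycle
      bool detach_bi = leave_pos < up_a.size();
      int lx = ei[leave], ly = m + ej[leave];
      drop_adj(lx, leave); drop_adj(ly, leave);
      int start = detach_bi ? bi : m + bj;
      int anchor = detach_bi ? m + bj : bi;
      // BFS detached component: shift duals, re-root onto the entering edge
      ++token;
      comp.clear(); stack_.clear();
      stack_.push_back(start); mark[start] = token;
      par[start] = anchor; pedge[start] = leave;  // entering reuses the slot
      depth[start] = depth[anchor] + 1;
      while (!stack_.empty()) {
        int z = stack_.back(); stack_.pop_back();
        comp.push_back(z);
        if (z < m) u[z] += detach_bi ? bred : -bred;
        else v[z - m] += detach_bi ? -bred : bred;
        for (size_t t = 0; t < adj[z].size(); ++t) {
          int id = adj[z][t];
          int w = other(id, z);
          if (mark[w] == token) continue;
          mark[w] = token;
          par[w] = z; pedge[w] = id; depth[w] = depth[z] + 1;
          stack_.push_back(w);
        }
      }
      ei[leave] = bi; ej[leave] = bj; ef[leave] = theta;
      adj[bi].push_back(leave); adj[m + bj].push_back(leave);
      if (++pivots > max_pivots) Rcpp::stop("emd: pivot limit exceeded");
    }
    return reflow();
  }

  void drop_adj(int node, int id) {
    std::vector<int> &A = adj[node];
    for (size_t t = 0; t < A.size(); ++t)
      if (A[t] == id) { A[t] = A.back(); A.pop_back(); return; }
  }

  // exact flows on the optimal basis tree with unperturbed marginals
  double total_supply, total_demand;
  std::vector<double> supply0, demand0;
  double reflow() {
    std::vector<double> net(N);
    for (int i = 0; i < m; ++i) net[i] = supply0[i];
    for (int j = 0; j < n; ++j) net[m + j] = -demand0[j] * total_supply / total_demand;
    std::vector<int> deg(N);
    for (int x = 0; x < N; ++x) deg[x] = (int)adj[x].size();
    std::vector<char> done_edge(ei.size(), 0), done_node(N, 0);
    std::vector<int> leaves;
    for (int x = 0; x < N; ++x) if (deg[x] == 1) leaves.push_back(x);
    double total = 0;
    while (!leaves.empty()) {
      int x = leaves.back(); leaves.pop_back();
      if (done_node[x]) continue;
      int id = -1;
      for (size_t t = 0; t < adj[x].size(); ++t)
        if (!done_edge[adj[x][t]]) { id = adj[x][t]; break; }
      if (id < 0) { done_node[x] = 1; continue; }
      int y = other(id, x);
      double f = (x < m) ? net[x] : -net[x];
      total += f * cost(ei[id], ej[id]);
      net[y] += net[x];
      net[x] = 0; done_node[x] = 1; done_edge[id] = 1;
      if (--deg[y] == 1 && !done_node[y]) leaves.push_back(y);
      --deg[x];
    }
    return total;
  }
};

double emd_core(const double *C, int m, int n,
                const double *supply, const double *demand) {
  if (m <= 0 || n <= 0) Rcpp::stop("emd: empty point set");
  double sa = 0, sb = 0;
  for (int i = 0; i < m; ++i) sa += supply[i];
  for (int j = 0; j < n; ++j) sb += demand[j];
  if (std::fabs(sa - sb) > 1e-9 * std::max(sa, sb))
    Rcpp::stop("emd: total weights differ beyond tolerance");
  Transport T(C, m, n);
  T.supply0.assign(supply, supply + m);
  T.demand0.assign(demand, demand + n);
  T.total_supply = sa; T.total_demand = sb;
  const double delta = sa * 1e-12 / (m + 1.0);
  T.a.resize(m); T.b.resize(n);
  double extra = 0;
  for (int i = 0; i < m; ++i) { T.a[i] = supply[i] + delta * (i + 1); extra += delta * (i + 1); }
  for (int j = 0; j < n; ++j) T.b[j] = demand[j] * (sa + extra) / sb;
  return T.solve();
}

} // namespace

// [[Rcpp::export(name = ".emd_transport")]]
double emd_transport(NumericMatrix cost, NumericVector supply, NumericVector demand) {
  if (supply.size() != cost.nrow() || demand.size() != cost.ncol())
    stop("emd: marginal size mismatch");
  return emd_core(cost.begin(), cost.nrow(), cost.ncol(),
                  supply.begin(), demand.begin());
}

// [[Rcpp::export(name = ".emd_points")]]
double emd_points(NumericVector lon1, NumericVector lat1, NumericVector w1,
                  NumericVector lon2, NumericVector lat2, NumericVector w2) {
  const int m = lon1.size(), n = lon2.size();
  const double R2 = 2.0 * 6371.0, D2R = M_PI / 180.0;
  // half-angle identities: only sqrt/asin per cell, trig per point
  std::vector<double> sp1(m), cp1(m), sl1(m), cl1(m), c1(m);
  std::vector<double> sp2(n), cp2(n), sl2(n), cl2(n), c2(n);
  for (int i = 0; i < m; ++i) {
    sp1[i] = std::sin(lat1[i] * D2R / 2); cp1[i] = std::cos(lat1[i] * D2R / 2);
    sl1[i] = std::sin(lon1[i] * D2R / 2); cl1[i] = std::cos(lon1[i] * D2R / 2);
    c1[i] = std::cos(lat1[i] * D2R);
  }
  for (int j = 0; j < n; ++j) {
    sp2[j] = std::sin(lat2[j] * D2R / 2); cp2[j] = std::cos(lat2[j] * D2R / 2);
    sl2[j] = std::sin(lon2[j] * D2R / 2); cl2[j] = std::cos(lon2[j] * D2R / 2);
    c2[j] = std::cos(lat2[j] * D2R);
  }
  std::vector<double> C((size_t)m * n);
  for (int j = 0; j < n; ++j) {
    double *col = &C[(size_t)m * j];
    for (int i = 0; i < m; ++i) {
      double sp = sp2[j] * cp1[i] - cp2[j] * sp1[i];  // sin((lat2-lat1)/2)
      double sl = sl2[j] * cl1[i] - cl2[j] * sl1[i];  // sin((lon2-lon1)/2)
      double h = sp * sp + c1[i] * c2[j] * sl * sl;
      if (h > 1) h = 1;
      col[i] = R2 * std::asin(std::sqrt(h));
    }
  }
  return emd_core(C.data(), m, n, w1.begin(), w2.begin());
}
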
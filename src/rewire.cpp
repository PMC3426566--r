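// Degree-preserving "crossing" rewiring of a directed graph toward a
// target mean full clustering coefficient (Fagiolo's directed index):
//   C_i = [(A + A')^3]_ii / (2 * (d_tot_i * (d_tot_i - 1) - 2 * d_bidir_i))
// A candidate move picks two links a->b, c->d and replaces them with
// a->d, c->b, which conserves every node's in- and out-degree.  Moves are
// accepted only if they bring the mean clustering strictly closer to the
// target.  The diagonal of (A+A')^3 is updated incrementally: toggling a
// directed edge (u,v) changes the symmetrized matrix W by +/-1 at (u,v)
// and (v,u), and the induced change of [W^3]_ii is
//   2*delta*W_iu*W_iv          for i not in {u, v}
//   2*delta*(W^2)_uv           for i in {u, v}
// (second- and third-order terms vanish because W has an empty diagonal).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct RewireState {
  int N;
  std::vector<int> A, W;          // N x N, column-major
  std::vector<double> tri;        // [W^3]_ii
  std::vector<int> dtot, dbid;
  std::vector<int> efrom, eto;    // edge list

  int& a(int i, int j) { return A[i + (size_t)N * j]; }
  int& w(int i, int j) { return W[i + (size_t)N * j]; }

  double cc_node(int i) const {
    const double den = 2.0 * ((double)dtot[i] * (dtot[i] - 1) - 2.0 * dbid[i]);
    return den > 0 ? tri[i] / den : 0.0;
  }
  double mean_cc() const {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += cc_node(i);
    return s / N;
  }

  // toggle directed edge u->v by delta (+1 add, -1 remove), keep W/tri/dbid
  void toggle(int u, int v, int delta) {
    // triangle counts, using W *before* the update
    const int* Wu = &W[(size_t)N * u];
    const int* Wv = &W[(size_t)N * v];
    double wsq = 0.0;
    for (int i = 0; i < N; ++i) {
      const double prod = (double)Wu[i] * Wv[i];
      wsq += prod;
      if (i != u && i != v) tri[i] += 2.0 * delta * prod;
    }
    tri[u] += 2.0 * delta * wsq;
    tri[v] += 2.0 * delta * wsq;
    w(u, v) += delta;
    w(v, u) += delta;
    a(u, v) += delta;
    if (a(v, u) == 1) { dbid[u] += delta; dbid[v] += delta; }
  }
};

} // namespace

// [[Rcpp::export]]
List rewire_cc_cpp(IntegerMatrix adj, double target, double tol_abs,
                   double max_iter, double max_stall, int seed)
{
  RewireState st;
  st.N = adj.nrow();
  const int N = st.N;
  st.A.assign(adj.begin(), adj.end());
  st.W.resize((size_t)N * N);
  st.tri.assign(N, 0.0);
  st.dtot.assign(N, 0);
  st.dbid.assign(N, 0);

  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      st.w(i, j) = st.a(i, j) + st.a(j, i);
      if (st.a(i, j)) {
        st.dtot[i]++; st.dtot[j]++;
        st.efrom.push_back(i); st.eto.push_back(j);
        if (st.a(j, i)) st.dbid[i]++;
      }
    }
  // full [W^3]_ii once at start
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int j = 0; j < N; ++j) {
      const int wij = st.w(i, j);
      if (!wij) continue;
      double inner = 0.0;
      for (int k = 0; k < N; ++k) inner += (double)st.w(j, k) * st.w(k, i);
      s += wij * inner;
    }
    st.tri[i] = s;
  }

  const size_t n_edges = st.efrom.size();
  std::mt19937_64 rng((unsigned long long)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  std::uniform_int_distribution<size_t> pick(0, n_edges > 0 ? n_edges - 1 : 0);

  double cc = st.mean_cc();
  double best_gap = std::fabs(cc - target);
  double iter = 0.0, stall = 0.0, accepted = 0.0;

  while (best_gap > tol_abs && iter < max_iter && stall < max_stall &&
         n_edges >= 2) {
    iter += 1.0; stall += 1.0;
    const size_t e1 = pick(rng), e2 = pick(rng);
    if (e1 == e2) continue;
    const int a = st.efrom[e1], b = st.eto[e1];
    const int c = st.efrom[e2], d = st.eto[e2];
    // crossed links must be new, non-self and distinct
    if (a == d || c == b || st.a(a, d) || st.a(c, b)) continue;

    st.toggle(a, b, -1); st.toggle(c, d, -1);
    st.toggle(a, d, +1); st.toggle(c, b, +1);
    const double cc_new = st.mean_cc();

    if (std::fabs(cc_new - target) < best_gap) {
      cc = cc_new;
      best_gap = std::fabs(cc - target);
      st.eto[e1] = d; st.eto[e2] = b;
      accepted += 1.0; stall = 0.0;
    } else {  // revert
      st.toggle(a, d, -1); st.toggle(c, b, -1);
      st.toggle(a, b, +1); st.toggle(c, d, +1);
    }
  }

  IntegerMatrix out(N, N);
  std::copy(st.A.begin(), st.A.end(), out.begin());
  return List::create(_["adjacency"] = out, _["cc"] = cc,
                      _["iterations"] = iter, _["accepted"] = accepted,
                      _["converged"] = (best_gap <= tol_abs));
}
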
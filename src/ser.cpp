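#include <Rcpp.h>
using namespace Rcpp;

// Synchronous SER update core.
//
// States: 0 = S (susceptible), 1 = E (excited), 2 = R (refractory).
// A susceptible node i with at least nreq[i] excited neighbours becomes E;
// an excited node always becomes R; a refractory node recovers to S with
// probability p (deterministically when p == 1, in which case no RNG draws
// are made at all, so p = 1 trajectories are seed-independent).
//
// adj:        0-based adjacency lists, one IntegerVector per node
// nreq:       per-node excitation requirement (>= 1; isolated nodes have an
//             empty adjacency list and can never be excited)
// init:       initial state vector at t = 0
// tmax:       number of update steps
// p:          recovery probability in (0, 1]
// record_states: keep the full (tmax+1) x N state matrix
// watch:      0-based node whose excitation times are recorded (-1: none)
// stop_count: stop early once the watched node has been excited this many
//             times (0: never stop early)
//
// Excitation counts tally the steps t in [1, tmax] at which a node is E; an
// initial excitation at t = 0 is not counted. Once no node is excited the
// dynamics can only drift R -> S and never re-excite, so counts are final;
// the loop exits early then (unless the full trajectory was requested, in
// which case the drift is simulated so recorded refractory durations remain
// exact).
// [[Rcpp::export]]
List ser_run_cpp(const List& adj, const IntegerVector& nreq,
                 const IntegerVector& init, const int tmax, const double p,
                 const bool record_states, const int watch,
                 const int stop_count) {
  const int n = adj.size();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) nb[i] = as< std::vector<int> >(adj[i]);

  std::vector<int> cur(init.begin(), init.end()), nxt(n, 0);
  IntegerVector counts(n);
  IntegerMatrix states;
  if (record_states) {
    states = IntegerMatrix(tmax + 1, n);
    for (int i = 0; i < n; ++i) states(0, i) = cur[i];
  }
  std::vector<int> watch_times;
  const bool stoch = p < 1.0;
  int extinct_at = -1;
  int last_t = 0;

  for (int t = 1; t <= tmax; ++t) {
    bool any_e = false;
    for (int i = 0; i < n; ++i) {
      const int s = cur[i];
      if (s == 0) {
        int out = 0;
        const std::vector<int>& ni = nb[i];
        if (!ni.empty()) {
          const int need = nreq[i];
          int cnt = 0;
          for (size_t j = 0; j < ni.size(); ++j) {
            if (cur[ni[j]] == 1 && ++cnt >= need) break;
          }
          if (cnt >= need) out = 1;
        }
        nxt[i] = out;
      } else if (s == 1) {
        nxt[i] = 2;
      } else {
        nxt[i] = (stoch && unif_rand() >= p) ? 2 : 0;
      }
      if (nxt[i] == 1) {
        any_e = true;
        counts[i] += 1;
        if (i == watch) watch_times.push_back(t);
      }
    }
    cur = nxt;
    last_t = t;
    if (record_states) for (int i = 0; i < n; ++i) states(t, i) = cur[i];
    if (watch >= 0 && stop_count > 0 &&
        (int)watch_times.size() >= stop_count) break;
    if (!any_e) {
      if (extinct_at < 0) extinct_at = t;
      if (!record_states) break;
    }
  }

  List out = List::create(
    _["counts"] = counts,
    _["extinct_at"] = extinct_at < 0 ? NA_INTEGER : extinct_at,
    _["steps"] = last_t,
    _["watch_times"] = IntegerVector(watch_times.begin(), watch_times.end()));
  if (record_states) out["states"] = states;
  return out;
}
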
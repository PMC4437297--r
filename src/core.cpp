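#include <Rcpp.h>
using namespace Rcpp;

// Opinion update rules for a single node.
//
// q    current opinion in [-1, 1]
// qbar arithmetic mean of neighbour opinions
// a    stubbornness in [0, 1] (sets the width of the inflexibility range)
// mix  weight of the node's own opinion in the rule-(iii) compromise;
//      mix = a under the "self" convention, 1 - a under "neighbors"
// zero_rule: 0 = "mix" ((1-mix)*qbar for q == 0), 1 = "adopt" (qbar)
//
// For q > 0:
//   (i)   qbar > q               -> qbar        (adopt the more extreme mean)
//   (ii)  (1-a)*q <= qbar <= q   -> q           (inflexibility range)
//   (iii) qbar < (1-a)*q         -> (1-mix)*qbar + mix*q   (compromise)
// Mirror-symmetric for q < 0. Boundary ties belong to rule (ii).
static inline double rule_update(double q, double qbar, double a,
                                 double mix, int zero_rule) {
  if (q > 0.0) {
    if (qbar > q) return qbar;
    if (qbar >= (1.0 - a) * q) return q;
    return (1.0 - mix) * qbar + mix * q;
  } else if (q < 0.0) {
    if (qbar < q) return qbar;
    if (qbar <= (1.0 - a) * q) return q;
    return (1.0 - mix) * qbar + mix * q;
  }
  return zero_rule == 0 ? (1.0 - mix) * qbar : qbar;
}

// One synchronous sweep. xadj/adjncy is 0-based CSR adjacency; nodes with
// degree 0 keep their opinion (no social input).
// [[Rcpp::export]]
NumericVector cpp_step(IntegerVector xadj, IntegerVector adjncy,
                       NumericVector q, double a, double mix,
                       int zero_rule) {
  const int n = q.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int lo = xadj[i], hi = xadj[i + 1];
    if (hi == lo) { out[i] = q[i]; continue; }
    double s = 0.0;
    for (int e = lo; e < hi; ++e) s += q[adjncy[e]];
    out[i] = rule_update(q[i], s / (hi - lo), a, mix, zero_rule);
  }
  return out;
}

// Iterate synchronous sweeps until max |dq| < tol, a period-2 cycle is
// detected (state repeats with period 2 within tol), or max_steps.
// On a cycle the two phases are averaged (time average over the cycle).
// [[Rcpp::export]]
List cpp_relax(IntegerVector xadj, IntegerVector adjncy, NumericVector q0,
               double a, double mix, double tol, int max_steps,
               int zero_rule) {
  const int n = q0.size();
  std::vector<double> prev2(q0.begin(), q0.end());
  std::vector<double> prev(q0.begin(), q0.end());
  std::vector<double> cur(n);
  bool converged = false, cycle = false;
  int steps = 0;
  for (int t = 1; t <= max_steps; ++t) {
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      const int lo = xadj[i], hi = xadj[i + 1];
      double qi = prev[i];
      double qnew;
      if (hi == lo) {
        qnew = qi;
      } else {
        double s = 0.0;
        for (int e = lo; e < hi; ++e) s += prev[adjncy[e]];
        qnew = rule_update(qi, s / (hi - lo), a, mix, zero_rule);
      }
      cur[i] = qnew;
      double d = std::abs(qnew - qi);
      if (d > delta) delta = d;
    }
    steps = t;
    if (delta < tol) { converged = true; break; }
    if (t >= 2) {
      double d2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = std::abs(cur[i] - prev2[i]);
        if (d > d2) d2 = d;
      }
      if (d2 < tol) {  // period-2 cycle: report the cycle average
        for (int i = 0; i < n; ++i) cur[i] = 0.5 * (cur[i] + prev[i]);
        cycle = true;
        break;
      }
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  if (!converged && !cycle) {
    // ran out of steps: return the last computed state
  }
  NumericVector qf(cur.begin(), cur.end());
  return List::create(_["q"] = qf, _["steps"] = steps,
                      _["converged"] = converged, _["cycle"] = cycle);
}

// Avalanche scan: for each trigger (0-based index, opinion 0 < q < q_e in
// the stable state), set its opinion to +1, re-relax, and count previously
// vulnerable nodes (0 < q < q_e) other than the trigger that end above q_e.
//
// Relaxation uses an active-frontier scheme: starting from a relaxed state
// only nodes adjacent to a change can change, so each synchronous sweep
// re-evaluates just the neighbours of the nodes updated in the previous
// sweep, with neighbour sums maintained incrementally. This is exact for
// the synchronous dynamics up to the relaxation tolerance of the input
// state. The stable state is restored between triggers.
// [[Rcpp::export]]
IntegerVector cpp_avalanche_scan(IntegerVector xadj, IntegerVector adjncy,
                                 NumericVector q_stable,
                                 IntegerVector triggers, double a,
                                 double mix, double q_e, double tol,
                                 int max_steps, int zero_rule) {
  const int n = q_stable.size();
  std::vector<double> q(q_stable.begin(), q_stable.end());
  std::vector<double> ssum(n, 0.0);   // sum of neighbour opinions
  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) {
    deg[i] = xadj[i + 1] - xadj[i];
    double s = 0.0;
    for (int e = xadj[i]; e < xadj[i + 1]; ++e) s += q[adjncy[e]];
    ssum[i] = s;
  }
  std::vector<int> stamp(n, -1);      // last sweep id a node was scheduled
  std::vector<int> touched;            // nodes whose q changed (for restore)
  std::vector<char> is_touched(n, 0);
  std::vector<int> frontier, cand;
  std::vector<double> newq;
  IntegerVector out(triggers.size());

  for (int ti = 0; ti < triggers.size(); ++ti) {
    const int trg = triggers[ti];
    touched.clear();
    frontier.clear();
    // perturb
    double old = q[trg];
    q[trg] = 1.0;
    touched.push_back(trg); is_touched[trg] = 1;
    for (int e = xadj[trg]; e < xadj[trg + 1]; ++e)
      ssum[adjncy[e]] += 1.0 - old;
    frontier.push_back(trg);
    int sweep_id = ti * (max_steps + 2);  // unique stamps per trigger/sweep
    for (int t = 0; t < max_steps && !frontier.empty(); ++t) {
      ++sweep_id;
      cand.clear();
      for (size_t fi = 0; fi < frontier.size(); ++fi) {
        const int u = frontier[fi];
        for (int e = xadj[u]; e < xadj[u + 1]; ++e) {
          const int v = adjncy[e];
          if (stamp[v] != sweep_id && deg[v] > 0) {
            stamp[v] = sweep_id;
            cand.push_back(v);
          }
        }
      }
      frontier.clear();
      newq.resize(cand.size());
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        const int v = cand[ci];
        newq[ci] = rule_update(q[v], ssum[v] / deg[v], a, mix, zero_rule);
      }
      // apply simultaneously
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        const int v = cand[ci];
        const double d = newq[ci] - q[v];
        if (std::abs(d) > tol) {
          q[v] = newq[ci];
          if (!is_touched[v]) { is_touched[v] = 1; touched.push_back(v); }
          for (int e = xadj[v]; e < xadj[v + 1]; ++e) ssum[adjncy[e]] += d;
          frontier.push_back(v);
        }
      }
    }
    // count newly extreme, previously vulnerable nodes (excluding trigger)
    int S = 0;
    for (size_t k = 0; k < touched.size(); ++k) {
      const int v = touched[k];
      if (v != trg && q_stable[v] > 0.0 && q_stable[v] < q_e && q[v] > q_e)
        ++S;
    }
    out[ti] = S;
    // restore
    for (size_t k = 0; k < touched.size(); ++k) {
      const int v = touched[k];
      const double d = q_stable[v] - q[v];
      if (d != 0.0) {
        q[v] = q_stable[v];
        for (int e = xadj[v]; e < xadj[v + 1]; ++e) ssum[adjncy[e]] += d;
      }
      is_touched[v] = 0;
    }
  }
  return out;
}
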
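// Compiled core for Boolean network dynamics.
//
// A model is passed from R as a list with fields
//   n        : node count
//   nreg     : in-degree per node (0 => constant gate, table has 1 entry,
//              unless the node is an input, which is never updated)
//   regOff   : offset of each node's regulator slice in `regs`
//   regs     : flattened 0-based regulator indices, declaration order
//   tabOff   : offset of each node's slice in `tabs`
//   tabs     : flattened truth tables; combination index is the binary
//              number with the FIRST regulator as most significant bit
//   isInput  : 1 for environmental inputs (never updated, never noised)
//
// All randomness comes from R's RNG (unif_rand), so set.seed() in R makes
// every routine here replayable.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

struct Net {
  int n;
  std::vector<int> nreg, regOff, tabOff, regs, tabs;
  std::vector<char> isInput;
  std::vector<int> freeIdx; // non-input nodes
};

Net makeNet(const List& m) {
  Net net;
  net.n = as<int>(m["n"]);
  net.nreg = as<std::vector<int> >(m["nreg"]);
  net.regOff = as<std::vector<int> >(m["regOff"]);
  net.tabOff = as<std::vector<int> >(m["tabOff"]);
  net.regs = as<std::vector<int> >(m["regs"]);
  net.tabs = as<std::vector<int> >(m["tabs"]);
  IntegerVector inp = m["isInput"];
  net.isInput.resize(net.n);
  for (int i = 0; i < net.n; ++i) {
    net.isInput[i] = (char)inp[i];
    if (!inp[i]) net.freeIdx.push_back(i);
  }
  return net;
}

inline int gateOut(const Net& net, int i, const std::vector<int>& s) {
  int k = net.nreg[i];
  if (k == 0) return net.tabs[net.tabOff[i]];
  const int* r = &net.regs[net.regOff[i]];
  int idx = 0;
  for (int j = 0; j < k; ++j) idx = (idx << 1) | s[r[j]];
  return net.tabs[net.tabOff[i] + idx];
}

inline void syncNext(const Net& net, const std::vector<int>& s,
                     std::vector<int>& out) {
  out = s; // inputs carried over
  for (size_t j = 0; j < net.freeIdx.size(); ++j) {
    int i = net.freeIdx[j];
    out[i] = gateOut(net, i, s);
  }
}

inline std::string encode(const std::vector<int>& s) {
  std::string key((s.size() + 7) / 8, '\0');
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i]) key[i >> 3] |= (char)(1 << (i & 7));
  return key;
}

inline std::vector<int> asVec(const IntegerVector& st) {
  return std::vector<int>(st.begin(), st.end());
}

IntegerMatrix cycleToMatrix(const std::vector<std::vector<int> >& cyc) {
  int p = (int)cyc.size(), n = (int)cyc[0].size();
  IntegerMatrix m(p, n);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < n; ++j) m(i, j) = cyc[i][j];
  return m;
}

// Build a biased-asynchronous update order for one step.  Conditions are
// evaluated on `s` (state at the start of the step): 0 = IF_OFF,
// 1 = IF_ON, 2 = ALWAYS.  Start-listed nodes that qualify go first in
// listed order; end-listed nodes that qualify go last with the first
// listed updated last; everything else is shuffled uniformly in between.
// A node qualifying for both lists is placed by its start rule.
void buildOrder(const Net& net, const std::vector<int>& s,
                const std::vector<int>& startIdx, const std::vector<int>& startCond,
                const std::vector<int>& endIdx, const std::vector<int>& endCond,
                std::vector<int>& order) {
  order.clear();
  std::vector<char> placed(net.n, 0);
  for (size_t j = 0; j < startIdx.size(); ++j) {
    int i = startIdx[j], c = startCond[j];
    if (c == 2 || s[i] == c) { order.push_back(i); placed[i] = 1; }
  }
  std::vector<int> tail;
  for (size_t j = 0; j < endIdx.size(); ++j) {
    int i = endIdx[j], c = endCond[j];
    if (!placed[i] && (c == 2 || s[i] == c)) { tail.push_back(i); placed[i] = 1; }
  }
  std::vector<int> mid;
  for (size_t j = 0; j < net.freeIdx.size(); ++j) {
    int i = net.freeIdx[j];
    if (!placed[i]) mid.push_back(i);
  }
  for (int i = (int)mid.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(mid[i], mid[j]);
  }
  for (size_t j = 0; j < mid.size(); ++j) order.push_back(mid[j]);
  // first listed end-rule node updates last
  for (int j = (int)tail.size() - 1; j >= 0; --j) order.push_back(tail[j]);
}

} // namespace

// [[Rcpp::export]]
IntegerVector syncStepC(List model, IntegerVector state) {
  Net net = makeNet(model);
  std::vector<int> s = asVec(state), out;
  syncNext(net, s, out);
  IntegerVector res(out.begin(), out.end());
  res.attr("names") = state.attr("names");
  return res;
}

// [[Rcpp::export]]
IntegerVector asyncStepC(List model, IntegerVector state,
                         IntegerVector startIdx, IntegerVector startCond,
                         IntegerVector endIdx, IntegerVector endCond) {
  Net net = makeNet(model);
  std::vector<int> s = asVec(state), order;
  buildOrder(net, s,
             as<std::vector<int> >(startIdx), as<std::vector<int> >(startCond),
             as<std::vector<int> >(endIdx), as<std::vector<int> >(endCond),
             order);
  for (size_t j = 0; j < order.size(); ++j)
    s[order[j]] = gateOut(net, order[j], s);
  IntegerVector res(s.begin(), s.end());
  res.attr("names") = state.attr("names");
  return res;
}

// Deterministic synchronous descent with hash-based cycle detection.
// Returns the attractor cycle, first row = first revisited state.
// [[Rcpp::export]]
IntegerMatrix descendC(List model, IntegerVector state, double maxSteps) {
  Net net = makeNet(model);
  std::vector<int> cur = asVec(state), nxt;
  std::unordered_map<std::string, int> seen;
  std::vector<std::vector<int> > path;
  double budget = maxSteps;
  for (;;) {
    std::string key = encode(cur);
    std::unordered_map<std::string, int>::iterator it = seen.find(key);
    if (it != seen.end()) {
      std::vector<std::vector<int> > cyc(path.begin() + it->second, path.end());
      return cycleToMatrix(cyc);
    }
    seen[key] = (int)path.size();
    path.push_back(cur);
    syncNext(net, cur, nxt);
    cur.swap(nxt);
    if (--budget < 0)
      stop("descent exceeded the step budget; pathological instance");
  }
}

// Exhaustive attractor enumeration over the subspace spanned by freeIdx
// (0-based; all other nodes frozen at `state`).  Classic forward-walk
// labelling with a memoized successor map.
// [[Rcpp::export]]
List enumerateC(List model, IntegerVector state, IntegerVector freeIdx) {
  Net net = makeNet(model);
  std::vector<int> fi = as<std::vector<int> >(freeIdx);
  int m = (int)fi.size();
  if (m > 28) stop("subspace too large to enumerate");
  long nStates = 1L << m;
  std::vector<int> succ(nStates, -1), label(nStates, -2);
  std::vector<int> tmpl = asVec(state), s, nx;
  std::vector<std::vector<int> > attMats; // first state of each attractor kept via cycles
  std::vector<std::vector<std::vector<int> > > attractors;

  // decode helper: bit j of code -> fi[j], MSB first
  for (long c0 = 0; c0 < nStates; ++c0) {
    if (label[c0] != -2) continue;
    std::vector<long> path;
    long x = c0;
    while (label[x] == -2) {
      label[x] = -1;
      path.push_back(x);
      if (succ[x] < 0) {
        s = tmpl;
        for (int j = 0; j < m; ++j) s[fi[j]] = (int)((x >> (m - 1 - j)) & 1);
        syncNext(net, s, nx);
        long code = 0;
        for (int j = 0; j < m; ++j) code = (code << 1) | nx[fi[j]];
        succ[x] = (int)code;
      }
      x = succ[x];
    }
    int id;
    if (label[x] == -1) { // new cycle discovered on this walk
      size_t pos = 0;
      for (size_t i = 0; i < path.size(); ++i)
        if (path[i] == x) { pos = i; break; }
      std::vector<std::vector<int> > cyc;
      for (size_t i = pos; i < path.size(); ++i) {
        s = tmpl;
        for (int j = 0; j < m; ++j) s[fi[j]] = (int)((path[i] >> (m - 1 - j)) & 1);
        cyc.push_back(s);
      }
      attractors.push_back(cyc);
      id = (int)attractors.size() - 1;
    } else {
      id = label[x];
    }
    for (size_t i = 0; i < path.size(); ++i) label[path[i]] = id;
  }
  List out(attractors.size());
  for (size_t a = 0; a < attractors.size(); ++a)
    out[a] = cycleToMatrix(attractors[a]);
  return out;
}

// Noisy-trajectory state-space sampler for one environment context.
// Runs nRnd noisy synchronous trajectories of nSeries steps from uniform
// random initial states (inputs frozen at `state`); at every visited state
// (including the initial one) descends deterministically to its attractor,
// optionally also from every single non-input-node flip of the visited
// state.  Basin memberships are memoized so each state's basin is resolved
// at most once per call.
// [[Rcpp::export]]
List sampleContextC(List model, IntegerVector state, int nRnd, int nSeries,
                    double pNoise, bool scanNeighbors, double maxSteps) {
  Net net = makeNet(model);
  std::vector<int> tmpl = asVec(state);
  std::unordered_map<std::string, int> memo;
  std::vector<std::vector<std::vector<int> > > attractors;

  std::vector<int> cur, nxt, walkState;
  std::vector<std::string> pathKeys;
  std::vector<std::vector<int> > pathStates;
  std::unordered_map<std::string, int> local;

  // descend with memoization; assigns basin ids to every state on the walk
  struct Descender {
    const Net& net;
    std::unordered_map<std::string, int>& memo;
    std::vector<std::vector<std::vector<int> > >& attractors;
    double maxSteps;
    Descender(const Net& n, std::unordered_map<std::string, int>& m,
              std::vector<std::vector<std::vector<int> > >& a, double b)
      : net(n), memo(m), attractors(a), maxSteps(b) {}
    void run(std::vector<int> cur) {
      std::vector<std::string> keys;
      std::vector<std::vector<int> > states;
      std::unordered_map<std::string, int> local;
      std::vector<int> nxt;
      double budget = maxSteps;
      int id = -1;
      for (;;) {
        std::string key = encode(cur);
        std::unordered_map<std::string, int>::iterator it = memo.find(key);
        if (it != memo.end()) { id = it->second; break; }
        std::unordered_map<std::string, int>::iterator jt = local.find(key);
        if (jt != local.end()) { // new attractor cycle
          std::vector<std::vector<int> > cyc(states.begin() + jt->second,
                                             states.end());
          attractors.push_back(cyc);
          id = (int)attractors.size() - 1;
          break;
        }
        local[key] = (int)states.size();
        keys.push_back(key);
        states.push_back(cur);
        syncNext(net, cur, nxt);
        cur.swap(nxt);
        if (--budget < 0)
          stop("descent exceeded the step budget; pathological instance");
      }
      for (size_t i = 0; i < keys.size(); ++i) memo[keys[i]] = id;
    }
  } desc(net, memo, attractors, maxSteps);

  for (int r = 0; r < nRnd; ++r) {
    cur = tmpl;
    for (size_t j = 0; j < net.freeIdx.size(); ++j)
      cur[net.freeIdx[j]] = (unif_rand() < 0.5) ? 1 : 0;
    for (int t = 0; t <= nSeries; ++t) {
      desc.run(cur);
      if (scanNeighbors) {
        for (size_t j = 0; j < net.freeIdx.size(); ++j) {
          walkState = cur;
          int i = net.freeIdx[j];
          walkState[i] = 1 - walkState[i];
          desc.run(walkState);
        }
      }
      if (t == nSeries) break;
      syncNext(net, cur, nxt);
      cur.swap(nxt);
      if (pNoise > 0) {
        for (size_t j = 0; j < net.freeIdx.size(); ++j)
          if (unif_rand() < pNoise) {
            int i = net.freeIdx[j];
            cur[i] = 1 - cur[i];
          }
      }
    }
  }
  List out(attractors.size());
  for (size_t a = 0; a < attractors.size(); ++a)
    out[a] = cycleToMatrix(attractors[a]);
  return out;
}

// Stochastic time course shared by all experiment drivers.
//   inputProb : (nSteps x #inputIdx) matrix of per-step ON-probabilities;
//               a negative entry means "hold the current value".
//   kd*       : per-step override targets (bit 0 = KD, 1 = OE) applied
//               after the engine update.
//   engine    : 0 synchronous, 1 random-order async, 2 biased async.
//   pNoise    : per-step flip probability for non-input nodes (synchronous
//               noise; engines 1-2 are run with 0).
//   stopIdx/stopBit : optional state signature; the run stops (after
//               recording) at the first state matching it.
// Returns list(states = (steps+1 x n) matrix, stopped, stoppedAt).
// [[Rcpp::export]]
List runCourseC(List model, IntegerVector state, int nSteps,
                IntegerVector inputIdx, NumericMatrix inputProb,
                IntegerVector kdIdx, IntegerVector kdBit, NumericVector kdProb,
                double pNoise, int engine,
                IntegerVector startIdx, IntegerVector startCond,
                IntegerVector endIdx, IntegerVector endCond,
                IntegerVector stopIdx, IntegerVector stopBit) {
  Net net = makeNet(model);
  std::vector<int> cur = asVec(state), nxt, order;
  std::vector<int> sIdx = as<std::vector<int> >(startIdx);
  std::vector<int> sCond = as<std::vector<int> >(startCond);
  std::vector<int> eIdx = as<std::vector<int> >(endIdx);
  std::vector<int> eCond = as<std::vector<int> >(endCond);
  IntegerMatrix traj(nSteps + 1, net.n);
  for (int j = 0; j < net.n; ++j) traj(0, j) = cur[j];
  bool stopped = false;
  int stoppedAt = NA_INTEGER, t;

  // a stop signature matching the initial state stops immediately
  if (stopIdx.size() > 0) {
    bool hit = true;
    for (int j = 0; j < stopIdx.size(); ++j)
      if (cur[stopIdx[j]] != stopBit[j]) { hit = false; break; }
    if (hit) {
      stopped = true;
      stoppedAt = 0;
      IntegerMatrix cut(1, net.n);
      for (int j = 0; j < net.n; ++j) cut(0, j) = traj(0, j);
      return List::create(_["states"] = cut, _["stopped"] = true,
                          _["stoppedAt"] = 0);
    }
  }

  for (t = 1; t <= nSteps; ++t) {
    // 1. environmental inputs for this step
    for (int j = 0; j < inputIdx.size(); ++j) {
      double p = inputProb(t - 1, j);
      if (p < 0) continue;
      cur[inputIdx[j]] = (p >= 1.0) ? 1 : (p <= 0.0 ? 0 : (unif_rand() < p ? 1 : 0));
    }
    // 2. engine update
    if (engine == 0) {
      syncNext(net, cur, nxt);
      cur.swap(nxt);
    } else {
      buildOrder(net, cur, (engine == 2) ? sIdx : std::vector<int>(),
                 (engine == 2) ? sCond : std::vector<int>(),
                 (engine == 2) ? eIdx : std::vector<int>(),
                 (engine == 2) ? eCond : std::vector<int>(), order);
      for (size_t j = 0; j < order.size(); ++j)
        cur[order[j]] = gateOut(net, order[j], cur);
    }
    // 3. synchronous noise
    if (pNoise > 0) {
      for (size_t j = 0; j < net.freeIdx.size(); ++j)
        if (unif_rand() < pNoise) {
          int i = net.freeIdx[j];
          cur[i] = 1 - cur[i];
        }
    }
    // 4. knockdown / overexpression overrides win within their step
    for (int j = 0; j < kdIdx.size(); ++j)
      if (kdProb[j] >= 1.0 || unif_rand() < kdProb[j])
        cur[kdIdx[j]] = kdBit[j];
    for (int j = 0; j < net.n; ++j) traj(t, j) = cur[j];
    if (stopIdx.size() > 0) {
      bool hit = true;
      for (int j = 0; j < stopIdx.size(); ++j)
        if (cur[stopIdx[j]] != stopBit[j]) { hit = false; break; }
      if (hit) { stopped = true; stoppedAt = t; break; }
    }
  }
  int kept = stopped ? stoppedAt : nSteps;
  IntegerMatrix out(kept + 1, net.n);
  for (int i = 0; i <= kept; ++i)
    for (int j = 0; j < net.n; ++j) out(i, j) = traj(i, j);
  return List::create(_["states"] = out, _["stopped"] = stopped,
                      _["stoppedAt"] = stoppedAt);
}
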
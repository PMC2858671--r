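#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Internal C++ workers for the hot loops: balanced min-cut bisection
// (Fiduccia-Mattheyses) and Maslov-Sneppen degree-preserving rewiring.
// Both draw from R's RNG so set.seed() governs reproducibility.

static int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// [[Rcpp::export]]
List fm_bisect_core(int n, IntegerVector ptr, IntegerVector adj,
                    double balance_tol, int restarts, int max_passes) {
  // ptr: CSR row pointers (length n+1), adj: neighbour indices (0-based)
  double maxdiff = balance_tol * n;
  if (maxdiff < 1.0) maxdiff = 1.0;
  // moves may overshoot the balance window by one node during a pass;
  // only states inside the window are recorded as candidate cuts
  double slack = std::max(maxdiff, 2.0);

  std::vector<int> best_side(n, 0);
  long best_cut = -1;

  std::vector<int> side(n), perm(n), gain(n), order(n);
  std::vector<char> locked(n);
  std::vector<int> moved;
  moved.reserve(n);

  for (int r = 0; r < restarts; ++r) {
    // random balanced initial partition
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = runif_int(i + 1);
      std::swap(perm[i], perm[j]);
    }
    int szA = n / 2;
    for (int i = 0; i < n; ++i) side[perm[i]] = (i < szA) ? 0 : 1;
    int sizeA = szA;

    // initial cut and gains: gain(v) = ext(v) - int(v)
    long cut = 0;
    for (int v = 0; v < n; ++v) {
      int g = 0;
      for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
        if (side[adj[k]] != side[v]) { ++g; ++cut; } else { --g; }
      }
      gain[v] = g;
    }
    cut /= 2;

    for (int pass = 0; pass < max_passes; ++pass) {
      std::fill(locked.begin(), locked.end(), 0);
      moved.clear();
      long run_cut = cut, run_best = cut;
      int run_best_idx = -1; // prefix length achieving run_best
      int curA = sizeA;

      for (int step = 0; step < n; ++step) {
        // pick unlocked max-gain vertex whose move keeps the balance
        int v = -1, gbest = 0;
        for (int u = 0; u < n; ++u) {
          if (locked[u]) continue;
          int newA = curA + (side[u] == 0 ? -1 : 1);
          double diff = std::abs(2.0 * newA - n);
          if (diff > slack) continue;
          if (v < 0 || gain[u] > gbest) { v = u; gbest = gain[u]; }
        }
        if (v < 0) break;
        // apply move
        int from = side[v];
        side[v] = 1 - from;
        curA += (from == 0) ? -1 : 1;
        run_cut -= gain[v];
        gain[v] = -gain[v];
        locked[v] = 1;
        for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
          int u = adj[k];
          if (side[u] == from) gain[u] += 2; else gain[u] -= 2;
        }
        moved.push_back(v);
        if (run_cut < run_best &&
            std::abs(2.0 * curA - n) <= maxdiff) {
          run_best = run_cut;
          run_best_idx = step;
        }
      }

      // roll back moves after the best prefix
      for (int s = (int)moved.size() - 1; s > run_best_idx; --s) {
        int v = moved[s];
        int from = side[v];
        side[v] = 1 - from;
        gain[v] = -gain[v];
        for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
          int u = adj[k];
          if (side[u] == side[v]) gain[u] -= 2; else gain[u] += 2;
        }
      }
      sizeA = 0;
      for (int i = 0; i < n; ++i) if (side[i] == 0) ++sizeA;
      bool improved = run_best < cut;
      cut = run_best_idx >= 0 ? run_best : cut;
      if (!improved) break;
    }

    if (best_cut < 0 || cut < best_cut) {
      best_cut = cut;
      best_side.assign(side.begin(), side.end());
    }
  }

  return List::create(_["side"] = IntegerVector(best_side.begin(), best_side.end()),
                      _["cut"] = (double)best_cut);
}

// [[Rcpp::export]]
List maslov_rewire_core(IntegerMatrix edges, int n, double target_swaps,
                        double max_attempts) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  auto key = [n](int a, int b) {
    if (a > b) std::swap(a, b);
    return (long long)a * n + b;
  };
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0);
    eb[i] = edges(i, 1);
    present.insert(key(ea[i], eb[i]));
  }

  double accepted = 0, attempts = 0;
  while (accepted < target_swaps && attempts < max_attempts) {
    ++attempts;
    int i = runif_int(m), j = runif_int(m);
    if (i == j) continue;
    int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
    if (unif_rand() < 0.5) std::swap(c, d); // random orientation
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;               // self-loop
    if (a == c && b == d) continue;               // same edge
    long long k1 = key(a, d), k2 = key(c, b);
    if (k1 == k2) continue;
    if (present.count(k1) || present.count(k2)) continue; // multi-edge
    present.erase(key(a, b));
    present.erase(key(c, d));
    present.insert(k1);
    present.insert(k2);
    ea[i] = a; eb[i] = d;
    ea[j] = c; eb[j] = b;
    ++accepted;
  }

  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    int a = ea[i], b = eb[i];
    if (a > b) std::swap(a, b);
    out(i, 0) = a;
    out(i, 1) = b;
  }
  return List::create(_["edges"] = out, _["accepted"] = accepted,
                      _["attempts"] = attempts);
}
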
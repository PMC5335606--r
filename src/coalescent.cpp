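#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
using namespace Rcpp;

// Serial-sampling coalescent for a small number of demes.
//
// Events are processed looking backwards in time (time 0 = present, units =
// generations). Within a deme of haploid size N each pair of active lineages
// coalesces at rate 1/N per generation; total deme rate k(k-1)/(2N).
// Leaves enter the process at their sampling times. A "move" event relocates
// each active lineage of the source deme to the destination deme with
// probability `frac` (frac >= 1 moves all lineages without consuming
// random numbers, so fully deterministic pulses stay reproducible).
//
// All randomness comes from R's RNG (RNGScope), so set.seed() governs.

// [[Rcpp::export]]
List sim_genealogy_cpp(NumericVector samp_time, IntegerVector samp_deme,
                       NumericVector init_size,
                       NumericVector ev_time, IntegerVector ev_type,
                       IntegerVector ev_deme, IntegerVector ev_dest,
                       NumericVector ev_size, NumericVector ev_frac) {
  const int n = samp_time.size();
  const int ndeme = init_size.size();
  const int nev = ev_time.size();
  const int nnode = 2 * n - 1;

  // activation order
  std::vector<int> act_order(n);
  for (int i = 0; i < n; ++i) act_order[i] = i;
  std::stable_sort(act_order.begin(), act_order.end(),
                   [&](int a, int b) { return samp_time[a] < samp_time[b]; });

  std::vector<double> N(init_size.begin(), init_size.end());
  std::vector<std::vector<int>> deme(ndeme);
  IntegerVector parent(nnode, NA_INTEGER);
  NumericVector node_time(nnode);
  IntegerVector node_deme(nnode);
  for (int i = 0; i < n; ++i) {
    node_time[i] = samp_time[i];
    node_deme[i] = samp_deme[i];
  }

  int next_act = 0, next_ev = 0, node_count = n, active = 0;
  double t = 0.0;
  const double INF = R_PosInf;

  while (!(next_act == n && active == 1)) {
    double rate = 0.0;
    std::vector<double> drate(ndeme, 0.0);
    for (int d = 0; d < ndeme; ++d) {
      double k = (double)deme[d].size();
      if (k >= 2.0 && N[d] > 0.0) {
        drate[d] = k * (k - 1.0) / (2.0 * N[d]);
        rate += drate[d];
      }
    }
    double t_sched = INF;
    bool is_act = false;
    if (next_ev < nev) t_sched = ev_time[next_ev];
    if (next_act < n && samp_time[act_order[next_act]] <= t_sched) {
      t_sched = samp_time[act_order[next_act]];
      is_act = true;
    }
    double t_coal = (rate > 0.0) ? t + R::exp_rand() / rate : INF;

    if (t_coal < t_sched) {
      // coalescence: pick deme proportional to rate, then a uniform pair
      double u = R::unif_rand() * rate;
      int d = 0;
      for (; d < ndeme - 1; ++d) {
        if (u < drate[d]) break;
        u -= drate[d];
      }
      while (drate[d] <= 0.0) ++d;  // guard against numeric edge
      int k = (int)deme[d].size();
      int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = deme[d][i], b = deme[d][j];
      int nd = node_count++;
      parent[a] = nd; parent[b] = nd;
      node_time[nd] = t_coal; node_deme[nd] = d;
      // swap-remove the two children, then add the ancestor
      int hi = std::max(i, j), lo = std::min(i, j);
      deme[d][hi] = deme[d].back(); deme[d].pop_back();
      deme[d][lo] = deme[d].back(); deme[d].pop_back();
      deme[d].push_back(nd);
      active -= 1;
      t = t_coal;
    } else {
      if (t_sched == INF)
        stop("unreachable deme: remaining lineages can never find a common ancestor");
      t = t_sched;
      if (is_act) {
        while (next_act < n && samp_time[act_order[next_act]] <= t) {
          int leaf = act_order[next_act++];
          deme[samp_deme[leaf]].push_back(leaf);
          ++active;
        }
      } else {
        int e = next_ev++;
        if (ev_type[e] == 0) {           // resize
          N[ev_deme[e]] = ev_size[e];
        } else {                         // lineage move
          std::vector<int>& src = deme[ev_deme[e]];
          std::vector<int>& dst = deme[ev_dest[e]];
          double frac = ev_frac[e];
          if (frac >= 1.0) {
            for (size_t q = 0; q < src.size(); ++q) dst.push_back(src[q]);
            src.clear();
          } else if (frac > 0.0) {
            std::vector<int> keep;
            for (size_t q = 0; q < src.size(); ++q) {
              if (R::unif_rand() < frac) dst.push_back(src[q]);
              else keep.push_back(src[q]);
            }
            src.swap(keep);
          }
        }
      }
    }
  }

  return List::create(_["parent"] = parent, _["time"] = node_time,
                      _["deme"] = node_deme);
}

// Finite-sites two-state mutation drop. Branch i has expected
// rate_site_gen * L * (t[parent[i]] - t[i]) mutations (Poisson); each
// mutation hits a uniform site in 1..L and toggles the 0/1 state of every
// leaf below the branch. Root state is all-zeros. Returns the states at
// every site hit at least once (columns sorted by site index).

// [[Rcpp::export]]
List drop_mutations_cpp(IntegerVector parent, NumericVector node_time,
                        int n_leaves, double rate_site_gen, int L) {
  const int nnode = parent.size();
  // children adjacency
  std::vector<std::vector<int>> ch(nnode);
  for (int i = 0; i < nnode; ++i)
    if (parent[i] != NA_INTEGER) ch[parent[i]].push_back(i);

  std::vector<int> mut_node, mut_site;
  for (int i = 0; i < nnode; ++i) {
    if (parent[i] == NA_INTEGER) continue;
    double blen = node_time[parent[i]] - node_time[i];
    if (blen <= 0.0) continue;
    int m = (int)R::rpois(rate_site_gen * (double)L * blen);
    for (int k = 0; k < m; ++k) {
      int s = (int)(R::unif_rand() * L); if (s >= L) s = L - 1;
      mut_node.push_back(i);
      mut_site.push_back(s + 1);  // 1-based site
    }
  }

  // map sites -> columns, sorted ascending
  std::vector<int> sites(mut_site);
  std::sort(sites.begin(), sites.end());
  sites.erase(std::unique(sites.begin(), sites.end()), sites.end());
  const int S = (int)sites.size();
  std::map<int, int> col;
  for (int s = 0; s < S; ++s) col[sites[s]] = s;

  IntegerMatrix X(n_leaves, S);
  std::vector<int> stack;
  for (size_t m = 0; m < mut_node.size(); ++m) {
    int c = col[mut_site[m]];
    stack.clear();
    stack.push_back(mut_node[m]);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_leaves) X(v, c) ^= 1;
      else for (size_t q = 0; q < ch[v].size(); ++q) stack.push_back(ch[v][q]);
    }
  }

  return List::create(_["X"] = X,
                      _["sites"] = IntegerVector(sites.begin(), sites.end()),
                      _["n_mutations"] = (int)mut_node.size());
}

// Per-column state counts aggregated into the quantities the summary panel
// needs: per-population segregating sites, total within-population pairwise
// differences, and total between-population pairwise differences.
// States are small non-negative integers (0/1 for simulated data, 0..3 for
// nucleotide data read from FASTA).

// [[Rcpp::export]]
List count_stats_cpp(IntegerMatrix X, IntegerVector pop, int npop,
                     int nstate) {
  const int n = X.nrow(), S = X.ncol();
  IntegerVector npp(npop);
  for (int i = 0; i < n; ++i) npp[pop[i]]++;
  IntegerVector seg(npop);
  NumericVector within(npop);
  NumericMatrix between(npop, npop);
  std::vector<double> cnt(npop * nstate);

  for (int s = 0; s < S; ++s) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) cnt[pop[i] * nstate + X(i, s)] += 1.0;
    for (int p = 0; p < npop; ++p) {
      double np = npp[p], same = 0.0;
      int states = 0;
      for (int a = 0; a < nstate; ++a) {
        double c = cnt[p * nstate + a];
        if (c > 0.0) ++states;
        same += c * (c - 1.0) / 2.0;
      }
      if (states >= 2) seg[p]++;
      within[p] += np * (np - 1.0) / 2.0 - same;
      for (int q = p + 1; q < npop; ++q) {
        double cross = 0.0;
        for (int a = 0; a < nstate; ++a)
          cross += cnt[p * nstate + a] * cnt[q * nstate + a];
        between(p, q) += npp[p] * (double)npp[q] - cross;
      }
    }
  }
  return List::create(_["n"] = npp, _["seg"] = seg, _["within"] = within,
                      _["between"] = between);
}

// Distinct-row pattern ids (1-based, in order of first appearance).

// [[Rcpp::export]]
IntegerVector hap_ids_cpp(IntegerMatrix X) {
  const int n = X.nrow(), S = X.ncol();
  IntegerVector ids(n);
  std::map<std::vector<int>, int> seen;
  std::vector<int> row(S);
  int next_id = 1;
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < S; ++s) row[s] = X(i, s);
    auto it = seen.find(row);
    if (it == seen.end()) { seen[row] = next_id; ids[i] = next_id++; }
    else ids[i] = it->second;
  }
  return ids;
}
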
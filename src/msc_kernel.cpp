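#include <Rcpp.h>
using namespace Rcpp;

// Per-population coalescent summaries for fixed gene trees swept through the
// population segments defined by a delimitation model and its tau vector.
//
// For guide node u (1-based id over tips then internals):
//   * u is a population iff u is split, or u is a maximal collapsed clade
//     root (parent split, or u is the collapsed root of the guide tree).
//   * its segment is [s_u, e_u) with s_u = tau_u if split else 0, and
//     e_u = tau_parent (the parent of a population node is always split),
//     or infinity at the root.
// Events (gene-tree coalescences) are precomputed per locus and per guide
// node as the sorted ages of coalescences whose species set has its MRCA
// inside clade(u); n0[l][u] counts the locus' sampled tips inside clade(u).
// A configuration is infeasible when some event with MRCA exactly at a
// split node u is younger than tau_u (a coalescence across populations that
// have not yet merged).
//
// Returns per locus and population the coalescence count c and the
// integral B = sum over segment intervals of n(n-1) dt, plus feasibility.
// [[Rcpp::export(name = ".msc_summaries_cpp")]]
List msc_summaries_cpp(List ev,            // [locus][node] sorted event ages
                       IntegerMatrix n0,   // locus x node tip counts
                       NumericMatrix emin, // locus x node min own-MRCA event age
                       LogicalVector split,// by node id (tips FALSE)
                       NumericVector tau,  // by node id (NA unless split)
                       IntegerVector parent, // by node id, 0 at root
                       int ntip) {
  const int M = split.size();
  const int L = ev.size();
  IntegerMatrix cmat(L, M);
  NumericMatrix Bmat(L, M);
  bool feasible = true;

  // feasibility: every split node's tau must not exceed its youngest
  // own-MRCA coalescence at any locus
  for (int u = 0; u < M && feasible; ++u) {
    if (!split[u]) continue;
    double tu = tau[u];
    if (parent[u] > 0) {
      double tp = tau[parent[u] - 1];
      if (!(tu < tp)) feasible = false;   // tau order violated
    }
    for (int l = 0; l < L; ++l) {
      if (emin(l, u) < tu) { feasible = false; break; }
    }
  }
  if (!feasible) {
    return List::create(_["c"] = cmat, _["B"] = Bmat, _["feasible"] = false);
  }

  for (int u = 0; u < M; ++u) {
    bool is_pop;
    if (split[u]) is_pop = true;
    else if (parent[u] == 0) is_pop = true;               // collapsed root
    else is_pop = split[parent[u] - 1];                   // maximal collapsed
    if (!is_pop) continue;
    double s_u = split[u] ? tau[u] : 0.0;
    double e_u = (parent[u] == 0) ? R_PosInf : tau[parent[u] - 1];
    for (int l = 0; l < L; ++l) {
      List evl = ev[l];
      NumericVector ages = evl[u];
      int n = n0(l, u);
      if (n < 1) continue;
      double t = s_u, B = 0.0;
      int c = 0, i = 0;
      const int K = ages.size();
      // events at or below the segment start happened in sub-populations
      while (i < K && ages[i] <= s_u) { --n; ++i; }
      while (i < K && ages[i] < e_u) {
        if (n > 1) B += (double)n * (n - 1) * (ages[i] - t);
        t = ages[i];
        --n; ++c; ++i;
      }
      if (R_finite(e_u) && n > 1) B += (double)n * (n - 1) * (e_u - t);
      cmat(l, u) = c;
      Bmat(l, u) = B;
    }
  }
  return List::create(_["c"] = cmat, _["B"] = Bmat, _["feasible"] = true);
}
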
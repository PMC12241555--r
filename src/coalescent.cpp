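// Structured-coalescent engine: independent non-recombining loci under a
// multi-population demography with piecewise-exponential sizes, population
// splits (mass lineage moves), admixture pulses, time-limited symmetric
// migration, and dated (ancient) samples. Times are in generations, looking
// backwards from the present; population indices are 0-based.
//
// Mutations follow the infinite-sites approximation: Poisson numbers of
// derived mutations are dropped on branches with rate mu * locus_len * blen.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Epoch {
  double t0;     // epoch start (backwards time, generations)
  double N0;     // diploid size at t0
  double alpha;  // forward growth rate; N(t) = N0 * exp(-alpha * (t - t0))
};

struct DemEvent {
  double time;
  int kind;      // 0 = move_all (split, backwards), 1 = pulse
  int from, to;
  double prob;   // pulse probability (ignored for move_all)
};

struct MigEdge {
  int from, to;
  double rate;   // backwards rate: lineage in `from` jumps to `to`
  double t0, t1; // active on [t0, t1)
};

struct Demog {
  int npop;
  std::vector< std::vector<Epoch> > epochs;
  std::vector<DemEvent> events;
  std::vector<MigEdge> mig;
};

static Demog parse_demog(const List& dl) {
  Demog D;
  D.npop = as<int>(dl["npop"]);
  NumericMatrix ep = dl["epochs"]; // pop, t0, N0, alpha
  D.epochs.assign(D.npop, std::vector<Epoch>());
  for (int i = 0; i < ep.nrow(); ++i) {
    int p = (int) ep(i, 0);
    if (p < 0 || p >= D.npop) stop("epoch for unknown population");
    Epoch e; e.t0 = ep(i, 1); e.N0 = ep(i, 2); e.alpha = ep(i, 3);
    if (e.N0 <= 0) stop("non-positive population size");
    D.epochs[p].push_back(e);
  }
  for (int p = 0; p < D.npop; ++p) {
    if (D.epochs[p].empty()) stop("population without epochs");
    std::sort(D.epochs[p].begin(), D.epochs[p].end(),
              [](const Epoch& a, const Epoch& b) { return a.t0 < b.t0; });
    if (D.epochs[p][0].t0 != 0.0) stop("first epoch must start at time 0");
  }
  NumericMatrix ev = dl["events"]; // time, kind, from, to, prob
  for (int i = 0; i < ev.nrow(); ++i) {
    DemEvent e;
    e.time = ev(i, 0); e.kind = (int) ev(i, 1);
    e.from = (int) ev(i, 2); e.to = (int) ev(i, 3); e.prob = ev(i, 4);
    if (e.time < 0) stop("negative event time");
    D.events.push_back(e);
  }
  std::stable_sort(D.events.begin(), D.events.end(),
                   [](const DemEvent& a, const DemEvent& b) { return a.time < b.time; });
  NumericMatrix mg = dl["mig"]; // from, to, rate, t0, t1
  for (int i = 0; i < mg.nrow(); ++i) {
    MigEdge m;
    m.from = (int) mg(i, 0); m.to = (int) mg(i, 1);
    m.rate = mg(i, 2); m.t0 = mg(i, 3); m.t1 = mg(i, 4);
    if (m.rate > 0) D.mig.push_back(m);
  }
  return D;
}

// Waiting time to next coalescence among k lineages in an exponentially
// changing population, from current time t inside epoch e (inverse-CDF).
static double coal_wait(const Epoch& e, double t, int k) {
  double C = 0.5 * (double) k * (double) (k - 1);
  double E = exp_rand();
  if (e.alpha == 0.0) return E * 2.0 * e.N0 / C;
  double s0 = t - e.t0;
  double rhs = 1.0 + E * 2.0 * e.N0 * e.alpha * std::exp(-e.alpha * s0) / C;
  if (rhs <= 0.0) return R_PosInf;
  return std::log(rhs) / e.alpha;
}

struct SimContext {
  Demog D;
  std::vector<int> spop;
  std::vector<double> sage;
  std::vector<int> pend_order;   // sample indices with age > 0, sorted by age
  std::vector<double> bps;       // sorted unique breakpoints > 0
  int n;                          // haplotypes
};

static SimContext make_context(const List& demog, const IntegerVector& sample_pop,
                               const NumericVector& sample_age) {
  SimContext C;
  C.D = parse_demog(demog);
  C.n = sample_pop.size();
  if (C.n < 2) stop("need at least two haplotypes");
  C.spop.assign(sample_pop.begin(), sample_pop.end());
  C.sage.assign(sample_age.begin(), sample_age.end());
  for (int i = 0; i < C.n; ++i) {
    if (C.spop[i] < 0 || C.spop[i] >= C.D.npop) stop("sample in unknown population");
    if (C.sage[i] < 0) stop("negative sample age");
    if (C.sage[i] > 0) C.pend_order.push_back(i);
  }
  std::sort(C.pend_order.begin(), C.pend_order.end(),
            [&](int a, int b) { return C.sage[a] < C.sage[b]; });
  std::vector<double> bp;
  for (size_t i = 0; i < C.D.events.size(); ++i) bp.push_back(C.D.events[i].time);
  for (int p = 0; p < C.D.npop; ++p)
    for (size_t j = 1; j < C.D.epochs[p].size(); ++j) bp.push_back(C.D.epochs[p][j].t0);
  for (size_t i = 0; i < C.D.mig.size(); ++i) {
    bp.push_back(C.D.mig[i].t0);
    bp.push_back(C.D.mig[i].t1);
  }
  for (size_t i = 0; i < C.pend_order.size(); ++i) bp.push_back(C.sage[C.pend_order[i]]);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
  for (size_t i = 0; i < bp.size(); ++i) if (bp[i] > 0) C.bps.push_back(bp[i]);
  return C;
}

// One genealogy. Nodes 0..n-1 are samples; internal nodes are appended in
// coalescence (time) order so a parent's index always exceeds its child's.
static void sim_tree(const SimContext& C, std::vector<int>& parent,
                     std::vector<double>& ntime) {
  const Demog& D = C.D;
  int n = C.n, nnodes = 2 * n - 1;
  parent.assign(nnodes, -1);
  ntime.assign(nnodes, 0.0);
  std::vector< std::vector<int> > P(D.npop);
  for (int i = 0; i < n; ++i) ntime[i] = C.sage[i];
  int active = 0;
  for (int i = 0; i < n; ++i)
    if (C.sage[i] == 0.0) { P[C.spop[i]].push_back(i); ++active; }
  size_t pp = 0, bi = 0, ei = 0;
  std::vector<size_t> epi(D.npop, 0);
  double t = 0.0;
  int next_node = n;
  long iter = 0;
  while (!(active == 1 && pp == C.pend_order.size())) {
    if (++iter > 100000000L) stop("coalescent did not terminate");
    double nbp = (bi < C.bps.size()) ? C.bps[bi] : R_PosInf;
    double tbest = R_PosInf;
    int btype = -1, bpop = -1;
    for (int p = 0; p < D.npop; ++p) {
      int k = (int) P[p].size();
      if (k < 2) continue;
      while (epi[p] + 1 < D.epochs[p].size() && D.epochs[p][epi[p] + 1].t0 <= t) ++epi[p];
      double dt = coal_wait(D.epochs[p][epi[p]], t, k);
      if (t + dt < tbest) { tbest = t + dt; btype = 0; bpop = p; }
    }
    double mrate = 0.0;
    for (size_t m = 0; m < D.mig.size(); ++m) {
      const MigEdge& e = D.mig[m];
      if (t >= e.t0 && t < e.t1) mrate += e.rate * (double) P[e.from].size();
    }
    if (mrate > 0.0) {
      double dtm = exp_rand() / mrate;
      if (t + dtm < tbest) { tbest = t + dtm; btype = 1; }
    }
    if (tbest < nbp) {
      t = tbest;
      if (btype == 0) {
        std::vector<int>& L = P[bpop];
        int k = (int) L.size();
        int i1 = (int) (unif_rand() * k); if (i1 == k) i1 = k - 1;
        int i2 = (int) (unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
        if (i2 >= i1) ++i2;
        int a = L[i1], b = L[i2];
        int nd = next_node++;
        parent[a] = nd; parent[b] = nd; ntime[nd] = t;
        L[i1] = nd;
        L[i2] = L.back(); L.pop_back();
        --active;
      } else {
        double u = unif_rand() * mrate, acc = 0.0;
        for (size_t m = 0; m < D.mig.size(); ++m) {
          const MigEdge& e = D.mig[m];
          if (!(t >= e.t0 && t < e.t1)) continue;
          acc += e.rate * (double) P[e.from].size();
          if (u <= acc || m == D.mig.size() - 1) {
            if (P[e.from].empty()) continue;
            int k = (int) P[e.from].size();
            int i1 = (int) (unif_rand() * k); if (i1 == k) i1 = k - 1;
            int lin = P[e.from][i1];
            P[e.from][i1] = P[e.from].back(); P[e.from].pop_back();
            P[e.to].push_back(lin);
            break;
          }
        }
      }
    } else {
      if (!R_finite(nbp))
        stop("lineages cannot coalesce: demography is not fully connected");
      t = nbp; ++bi;
      while (pp < C.pend_order.size() && C.sage[C.pend_order[pp]] <= t) {
        int s = C.pend_order[pp];
        P[C.spop[s]].push_back(s);
        ++active; ++pp;
      }
      while (ei < D.events.size() && D.events[ei].time <= t) {
        const DemEvent& e = D.events[ei];
        if (e.kind == 0) {
          for (size_t j = 0; j < P[e.from].size(); ++j) P[e.to].push_back(P[e.from][j]);
          P[e.from].clear();
        } else {
          std::vector<int> keep;
          for (size_t j = 0; j < P[e.from].size(); ++j) {
            if (unif_rand() < e.prob) P[e.to].push_back(P[e.from][j]);
            else keep.push_back(P[e.from][j]);
          }
          P[e.from].swap(keep);
        }
        ++ei;
      }
    }
  }
  if (next_node != nnodes) stop("internal error: incomplete genealogy");
}

// Per-node descendant counts in `ncat` sample categories. Rows are nodes.
static void descendant_counts(const SimContext& C, const std::vector<int>& parent,
                              const IntegerVector& category, int ncat,
                              std::vector<int>& cnt) {
  int n = C.n, nnodes = 2 * n - 1;
  cnt.assign((size_t) nnodes * ncat, 0);
  for (int s = 0; s < n; ++s) cnt[(size_t) s * ncat + category[s]] = 1;
  for (int i = 0; i < nnodes - 1; ++i) {
    int pa = parent[i];
    for (int j = 0; j < ncat; ++j) cnt[(size_t) pa * ncat + j] += cnt[(size_t) i * ncat + j];
  }
}

// Joint SFS over sample categories, accumulated across loci into a flat
// column-major array with dims[j] cells per category (counts 0..dims[j]-1).
// [[Rcpp::export]]
List cpp_sim_sfs(List demog, IntegerVector sample_pop, NumericVector sample_age,
                 IntegerVector category, IntegerVector dims,
                 int n_loci, double locus_len, double mu) {
  SimContext C = make_context(demog, sample_pop, sample_age);
  int ncat = dims.size();
  for (int i = 0; i < C.n; ++i)
    if (category[i] < 0 || category[i] >= ncat) stop("bad sample category");
  std::vector<double> stride(ncat);
  double ncell = 1.0;
  for (int j = 0; j < ncat; ++j) { stride[j] = ncell; ncell *= dims[j]; }
  if (ncell > 5e7) stop("joint SFS too large");
  NumericVector sfs((R_xlen_t) ncell);
  double nsites = 0.0;
  std::vector<int> parent; std::vector<double> ntime; std::vector<int> cnt;
  int nnodes = 2 * C.n - 1;
  for (int l = 0; l < n_loci; ++l) {
    sim_tree(C, parent, ntime);
    descendant_counts(C, parent, category, ncat, cnt);
    for (int i = 0; i < nnodes - 1; ++i) {
      double blen = ntime[parent[i]] - ntime[i];
      if (blen <= 0) continue;
      double nm = R::rpois(mu * locus_len * blen);
      if (nm > 0) {
        double idx = 0;
        for (int j = 0; j < ncat; ++j) idx += stride[j] * cnt[(size_t) i * ncat + j];
        sfs[(R_xlen_t) idx] += nm;
        nsites += nm;
      }
    }
  }
  return List::create(_["sfs"] = sfs, _["n_sites"] = nsites);
}

// Per-branch mutation table: one row per mutated branch with the descendant
// count in each category plus the mutation count. Used when several SFS
// projections (e.g. disjoint sample subsets) are tallied from one simulation.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_branch_sites(List demog, IntegerVector sample_pop,
                                   NumericVector sample_age, IntegerVector category,
                                   int ncat, int n_loci, double locus_len, double mu) {
  SimContext C = make_context(demog, sample_pop, sample_age);
  for (int i = 0; i < C.n; ++i)
    if (category[i] < 0 || category[i] >= ncat) stop("bad sample category");
  std::vector<int> rows;
  std::vector<int> parent; std::vector<double> ntime; std::vector<int> cnt;
  int nnodes = 2 * C.n - 1;
  for (int l = 0; l < n_loci; ++l) {
    sim_tree(C, parent, ntime);
    descendant_counts(C, parent, category, ncat, cnt);
    for (int i = 0; i < nnodes - 1; ++i) {
      double blen = ntime[parent[i]] - ntime[i];
      if (blen <= 0) continue;
      int nm = (int) R::rpois(mu * locus_len * blen);
      if (nm > 0) {
        for (int j = 0; j < ncat; ++j) rows.push_back(cnt[(size_t) i * ncat + j]);
        rows.push_back(nm);
      }
    }
  }
  int nr = (int) (rows.size() / (ncat + 1));
  IntegerMatrix out(nr, ncat + 1);
  for (int r = 0; r < nr; ++r)
    for (int j = 0; j <= ncat; ++j) out(r, j) = rows[(size_t) r * (ncat + 1) + j];
  return out;
}

// Raw genealogies (parent pointers + node times in generations) per locus.
// [[Rcpp::export]]
List cpp_sim_trees(List demog, IntegerVector sample_pop, NumericVector sample_age,
                   int n_loci) {
  SimContext C = make_context(demog, sample_pop, sample_age);
  List out(n_loci);
  std::vector<int> parent; std::vector<double> ntime;
  for (int l = 0; l < n_loci; ++l) {
    sim_tree(C, parent, ntime);
    out[l] = List::create(_["parent"] = IntegerVector(parent.begin(), parent.end()),
                          _["time"] = NumericVector(ntime.begin(), ntime.end()));
  }
  return out;
}

// Haplotype 0/1 genotypes for one locus (infinite sites; colliding positions
// dropped and counted as multi-hit).
// [[Rcpp::export]]
List cpp_sim_genotypes(List demog, IntegerVector sample_pop, NumericVector sample_age,
                       double locus_len, double mu) {
  SimContext C = make_context(demog, sample_pop, sample_age);
  int n = C.n, nnodes = 2 * n - 1;
  std::vector<int> parent; std::vector<double> ntime;
  sim_tree(C, parent, ntime);
  // children lists for descendant-leaf collection
  std::vector< std::vector<int> > children(nnodes);
  for (int i = 0; i < nnodes - 1; ++i) children[parent[i]].push_back(i);
  std::vector<int> mut_node;
  std::vector<double> mut_pos;
  for (int i = 0; i < nnodes - 1; ++i) {
    double blen = ntime[parent[i]] - ntime[i];
    if (blen <= 0) continue;
    int nm = (int) R::rpois(mu * locus_len * blen);
    for (int m = 0; m < nm; ++m) {
      mut_node.push_back(i);
      mut_pos.push_back(std::floor(unif_rand() * locus_len) + 1.0);
    }
  }
  std::vector<size_t> ord(mut_pos.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return mut_pos[a] < mut_pos[b]; });
  std::vector<size_t> keep;
  int multihit = 0;
  for (size_t i = 0; i < ord.size(); ++i) {
    if (!keep.empty() && mut_pos[ord[i]] == mut_pos[keep.back()]) { ++multihit; continue; }
    keep.push_back(ord[i]);
  }
  int S = (int) keep.size();
  IntegerMatrix G(n, S);
  NumericVector pos(S);
  std::vector<int> stack;
  for (int s = 0; s < S; ++s) {
    pos[s] = mut_pos[keep[s]];
    stack.clear();
    stack.push_back(mut_node[keep[s]]);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      if (nd < n) G(nd, s) = 1;
      else for (size_t c = 0; c < children[nd].size(); ++c) stack.push_back(children[nd][c]);
    }
  }
  return List::create(_["pos"] = pos, _["geno"] = G, _["n_multihit"] = multihit);
}
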
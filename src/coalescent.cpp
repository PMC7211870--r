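// Backwards-in-time coalescent simulation of microsatellite loci under a
// generalized stepwise mutation model (GSM), with the two demographic
// topologies used for the badger introduction analysis:
//   scenario 1 (divergence):  pop3 splits from pop2 at t_recent; pop1 and
//                             pop2 merge into the ancestral population at
//                             t_deep.
//   scenario 2 (admixture):   pop3 is founded at t_recent by admixture,
//                             each pop3 lineage tracing back to pop1 with
//                             probability ra and to pop2 otherwise; pop1 and
//                             pop2 merge at t_deep.
// Time is measured in generations; a continuous-time Kingman approximation
// is used (pairwise coalescence rate k(k-1)/(4N) per generation for diploid
// effective size N).  Allele states live on a bounded ladder of 40
// contiguous states with reflecting boundaries; each mutation moves the
// state by a geometrically distributed number of motif steps in a uniformly
// chosen direction.  All randomness comes from R's RNG so set.seed() in R
// controls everything.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

static const int LADDER = 40;             // contiguous allele states
static const int ROOT_STATE = LADDER / 2; // ladder midpoint for the MRCA

static inline int reflect_state(int s) {
  while (s < 0 || s > LADDER - 1) {
    if (s < 0) s = -s;
    else s = 2 * (LADDER - 1) - s;
  }
  return s;
}

// Growing binary tree built during the coalescent phase.
struct CoalTree {
  std::vector<double> time;  // node times (tips at 0)
  std::vector<int> left, right; // children, -1 for tips
  int add_tip() {
    time.push_back(0.0); left.push_back(-1); right.push_back(-1);
    return (int)time.size() - 1;
  }
  int add_internal(double t, int a, int b) {
    time.push_back(t); left.push_back(a); right.push_back(b);
    return (int)time.size() - 1;
  }
};

// Coalesce lineages in `act` within a population of diploid size N over
// [t_start, t_end); returns when one lineage remains or t_end is reached.
static void coalesce_interval(std::vector<int>& act, double N,
                              double t_start, double t_end, CoalTree& tr) {
  double t = t_start;
  while ((int)act.size() >= 2) {
    double k = (double)act.size();
    double rate = k * (k - 1.0) / (4.0 * N);
    t += R::rexp(1.0 / rate);
    if (t >= t_end) return;
    int m = (int)act.size();
    int i = (int)(R::unif_rand() * m); if (i == m) i = m - 1;
    int j = (int)(R::unif_rand() * (m - 1)); if (j == m - 1) j = m - 2;
    if (j >= i) j++;
    int a = act[i], b = act[j];
    // swap-with-last removal, larger index first
    int hi = i > j ? i : j, lo = i > j ? j : i;
    act[hi] = act.back(); act.pop_back();
    act[lo] = act.back(); act.pop_back();
    act.push_back(tr.add_internal(t, a, b));
  }
}

// Drop mutations from the root towards the tips; returns tip states.
static void mutate_tree(const CoalTree& tr, int root, double mu, double P,
                        std::vector<int>& state) {
  int nn = (int)tr.time.size();
  state.assign(nn, 0);
  std::vector<int> stack;
  state[root] = ROOT_STATE;
  stack.push_back(root);
  while (!stack.empty()) {
    int nd = stack.back(); stack.pop_back();
    for (int child : {tr.left[nd], tr.right[nd]}) {
      if (child < 0) continue;
      double blen = tr.time[nd] - tr.time[child];
      int s = state[nd];
      int nmut = (int)R::rpois(mu * blen);
      for (int m = 0; m < nmut; m++) {
        int step = 1 + (int)R::rgeom(P);
        if (R::unif_rand() < 0.5) step = -step;
        s = reflect_state(s + step);
      }
      state[child] = s;
      stack.push_back(child);
    }
  }
}

// Simulate one locus; fills `out` (length n1+n2+n3) with ladder states in
// tip order pop1, pop2, pop3.  Optionally records internal-node times.
static void sim_locus_states(int scenario, double N1, double N2, double N3,
                             double t_recent, double t_deep, double ra,
                             double N_anc, double mu, double P,
                             int n1, int n2, int n3,
                             std::vector<int>& out,
                             std::vector<double>* coal_times = nullptr) {
  CoalTree tr;
  std::vector<int> p1, p2, p3;
  for (int i = 0; i < n1; i++) p1.push_back(tr.add_tip());
  for (int i = 0; i < n2; i++) p2.push_back(tr.add_tip());
  for (int i = 0; i < n3; i++) p3.push_back(tr.add_tip());
  int ntips = n1 + n2 + n3;

  // epoch 1: three separate populations
  coalesce_interval(p1, N1, 0.0, t_recent, tr);
  coalesce_interval(p2, N2, 0.0, t_recent, tr);
  coalesce_interval(p3, N3, 0.0, t_recent, tr);

  // recent event: pop3 lineages trace back into pop2 (divergence) or are
  // split between pop1 and pop2 (admixture, probability ra to pop1)
  if (scenario == 1) {
    for (int id : p3) p2.push_back(id);
  } else {
    for (int id : p3) {
      if (R::unif_rand() < ra) p1.push_back(id); else p2.push_back(id);
    }
  }
  p3.clear();

  // epoch 2: two populations until the deep split
  coalesce_interval(p1, N1, t_recent, t_deep, tr);
  coalesce_interval(p2, N2, t_recent, t_deep, tr);

  // deep event: merge into the ancestral population
  for (int id : p2) p1.push_back(id);
  p2.clear();
  coalesce_interval(p1, N_anc, t_deep, R_PosInf, tr);
  int root = p1[0];

  std::vector<int> state;
  mutate_tree(tr, root, mu, P, state);
  out.assign(state.begin(), state.begin() + ntips);
  if (coal_times) {
    coal_times->clear();
    for (int i = ntips; i < (int)tr.time.size(); i++)
      coal_times->push_back(tr.time[i]);
  }
}

//' @noRd
// [[Rcpp::export(name = ".sim_locus_cpp")]]
IntegerVector sim_locus_cpp(int scenario, double N1, double N2, double N3,
                            double t_recent, double t_deep, double ra,
                            double N_anc, double mu, double P,
                            IntegerVector n_genes, int motif, int allele_base) {
  std::vector<int> st;
  sim_locus_states(scenario, N1, N2, N3, t_recent, t_deep, ra, N_anc,
                   mu, P, n_genes[0], n_genes[1], n_genes[2], st);
  IntegerVector out(st.size());
  for (size_t i = 0; i < st.size(); i++) out[i] = allele_base + motif * st[i];
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sim_single_pop_cpp")]]
List sim_single_pop_cpp(int n_genes, double N, double mu, double P,
                        int motif, int allele_base) {
  CoalTree tr;
  std::vector<int> act;
  for (int i = 0; i < n_genes; i++) act.push_back(tr.add_tip());
  coalesce_interval(act, N, 0.0, R_PosInf, tr);
  std::vector<int> state;
  mutate_tree(tr, act[0], mu, P, state);
  IntegerVector sizes(n_genes);
  for (int i = 0; i < n_genes; i++) sizes[i] = allele_base + motif * state[i];
  NumericVector times(tr.time.size() - n_genes);
  for (int i = n_genes; i < (int)tr.time.size(); i++) times[i - n_genes] = tr.time[i];
  return List::create(_["sizes"] = sizes, _["coal_times"] = times);
}

// ---- summary statistics on simulated genes ------------------------------

// Weir & Cockerham (1984) two-population variance components for one locus.
// Genes are paired consecutively into diploids.  Accumulates a, b, c sums.
static void wc_pair_components(const int* gA, int nA2, const int* gB, int nB2,
                               double& accA, double& accB, double& accC) {
  int nA = nA2 / 2, nB = nB2 / 2;
  if (nA < 1 || nB < 1) return;
  std::unordered_map<int, int> idx;
  std::vector<int> alleles;
  for (int i = 0; i < nA2; i++)
    if (!idx.count(gA[i])) { idx[gA[i]] = (int)alleles.size(); alleles.push_back(gA[i]); }
  for (int i = 0; i < nB2; i++)
    if (!idx.count(gB[i])) { idx[gB[i]] = (int)alleles.size(); alleles.push_back(gB[i]); }
  int K = (int)alleles.size();
  if (K < 2) return; // monomorphic locus carries no information
  std::vector<double> pA(K, 0), pB(K, 0), hA(K, 0), hB(K, 0);
  for (int i = 0; i < nA2; i++) pA[idx[gA[i]]] += 1.0;
  for (int i = 0; i < nB2; i++) pB[idx[gB[i]]] += 1.0;
  for (int k = 0; k < K; k++) { pA[k] /= nA2; pB[k] /= nB2; }
  for (int i = 0; i < nA; i++) {
    int a = gA[2 * i], b = gA[2 * i + 1];
    if (a != b) { hA[idx[a]] += 1.0; hA[idx[b]] += 1.0; }
  }
  for (int i = 0; i < nB; i++) {
    int a = gB[2 * i], b = gB[2 * i + 1];
    if (a != b) { hB[idx[a]] += 1.0; hB[idx[b]] += 1.0; }
  }
  double nbar = (nA + nB) / 2.0;
  double nc = (nA + nB) - ((double)nA * nA + (double)nB * nB) / (nA + nB);
  for (int k = 0; k < K; k++) {
    double h1 = hA[k] / nA, h2 = hB[k] / nB;
    double pbar = (nA * pA[k] + nB * pB[k]) / (nA + nB);
    double s2 = (nA * (pA[k] - pbar) * (pA[k] - pbar) +
                 nB * (pB[k] - pbar) * (pB[k] - pbar)) / nbar;
    double hbar = (nA * h1 + nB * h2) / (nA + nB);
    double a = (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2.0 - hbar / 4.0) / (nbar - 1.0));
    double b = (nbar / (nbar - 1.0)) *
      (pbar * (1 - pbar) - s2 / 2.0 - (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
    double c = hbar / 2.0;
    accA += a; accB += b; accC += c;
  }
}

// 15 summaries for a loci x genes matrix of allele sizes, three populations.
// Layout: na_1..3, he_1..3, m_1..3, fst_12, fst_13, fst_23,
//         dmu2_12, dmu2_13, dmu2_23
//' @noRd
// [[Rcpp::export(name = ".summaries_from_genes_cpp")]]
NumericVector summaries_from_genes_cpp(IntegerMatrix genes,
                                       IntegerVector n_genes, int motif) {
  int L = genes.nrow();
  int off[3] = {0, n_genes[0], n_genes[0] + n_genes[1]};
  int cnt[3] = {n_genes[0], n_genes[1], n_genes[2]};
  NumericVector out(15);
  // per-population means of Na, unbiased gene diversity, M-ratio
  for (int p = 0; p < 3; p++) {
    double sna = 0, she = 0, sm = 0;
    for (int l = 0; l < L; l++) {
      std::unordered_map<int, int> counts;
      int mn = 0, mx = 0; bool first = true;
      for (int g = 0; g < cnt[p]; g++) {
        int a = genes(l, off[p] + g);
        counts[a]++;
        if (first) { mn = mx = a; first = false; }
        else { if (a < mn) mn = a; if (a > mx) mx = a; }
      }
      double g2 = cnt[p];
      double sump2 = 0;
      for (auto& kv : counts) {
        double pr = kv.second / g2; sump2 += pr * pr;
      }
      sna += (double)counts.size();
      she += (g2 / (g2 - 1.0)) * (1.0 - sump2);
      double r = (mx - mn) / (double)motif;
      sm += counts.size() / (r + 1.0);
    }
    out[p] = sna / L;          // mean allele number
    out[3 + p] = she / L;      // mean genic diversity
    out[6 + p] = sm / L;       // mean M-ratio
  }
  // pairwise theta and delta-mu-squared, pairs (1,2), (1,3), (2,3)
  int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  std::vector<int> buf;
  for (int q = 0; q < 3; q++) {
    int A = pairs[q][0], B = pairs[q][1];
    double accA = 0, accB = 0, accC = 0, sdmu = 0;
    for (int l = 0; l < L; l++) {
      std::vector<int> gA(cnt[A]), gB(cnt[B]);
      for (int g = 0; g < cnt[A]; g++) gA[g] = genes(l, off[A] + g);
      for (int g = 0; g < cnt[B]; g++) gB[g] = genes(l, off[B] + g);
      wc_pair_components(gA.data(), cnt[A], gB.data(), cnt[B], accA, accB, accC);
      double mA = 0, mB = 0;
      for (int g = 0; g < cnt[A]; g++) mA += gA[g];
      for (int g = 0; g < cnt[B]; g++) mB += gB[g];
      mA /= cnt[A]; mB /= cnt[B];
      double d = (mA - mB) / motif;
      sdmu += d * d;
    }
    double denom = accA + accB + accC;
    out[9 + q] = (denom > 0) ? accA / denom : 0.0;
    out[12 + q] = sdmu / L;
  }
  return out;
}

// Simulate full datasets for a matrix of parameter draws and return their
// summary vectors.  demog columns: N1 N2 N3 t_recent t_deep ra N_anc.
// mu and P are draws x loci matrices of per-locus mutation parameters.
//' @noRd
// [[Rcpp::export(name = ".simulate_summaries_cpp")]]
NumericMatrix simulate_summaries_cpp(IntegerVector scenario,
                                     NumericMatrix demog,
                                     NumericMatrix mu, NumericMatrix P,
                                     IntegerVector n_genes,
                                     int motif, int allele_base) {
  int ndraw = scenario.size();
  int L = mu.ncol();
  int ntot = n_genes[0] + n_genes[1] + n_genes[2];
  NumericMatrix out(ndraw, 15);
  IntegerMatrix genes(L, ntot);
  std::vector<int> st;
  for (int d = 0; d < ndraw; d++) {
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
    for (int l = 0; l < L; l++) {
      sim_locus_states(scenario[d], demog(d, 0), demog(d, 1), demog(d, 2),
                       demog(d, 3), demog(d, 4), demog(d, 5), demog(d, 6),
                       mu(d, l), P(d, l),
                       n_genes[0], n_genes[1], n_genes[2], st);
      for (int g = 0; g < ntot; g++) genes(l, g) = allele_base + motif * st[g];
    }
    NumericVector s = summaries_from_genes_cpp(genes, n_genes, motif);
    for (int k = 0; k < 15; k++) out(d, k) = s[k];
  }
  return out;
}

// Simulate one full dataset and return the loci x genes allele-size matrix.
//' @noRd
// [[Rcpp::export(name = ".simulate_genes_cpp")]]
IntegerMatrix simulate_genes_cpp(int scenario, NumericVector demog,
                                 NumericVector mu, NumericVector P,
                                 IntegerVector n_genes,
                                 int motif, int allele_base) {
  int L = mu.size();
  int ntot = n_genes[0] + n_genes[1] + n_genes[2];
  IntegerMatrix genes(L, ntot);
  std::vector<int> st;
  for (int l = 0; l < L; l++) {
    sim_locus_states(scenario, demog[0], demog[1], demog[2], demog[3],
                     demog[4], demog[5], demog[6], mu[l], P[l],
                     n_genes[0], n_genes[1], n_genes[2], st);
    for (int g = 0; g < ntot; g++) genes(l, g) = allele_base + motif * st[g];
  }
  return genes;
}
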
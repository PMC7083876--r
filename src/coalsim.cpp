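// Coalescent simulation of unlinked microsatellite loci under a
// piecewise-constant demography, with a generalized stepwise mutation model.
//
// Time axis: generations before present, epoch i active on
// [start[i], start[i+1]); diploid effective sizes, so k lineages coalesce at
// rate choose(k,2) / (2 * Ne). All randomness goes through R's RNG stream so
// that set.seed() in R makes every simulation reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Waiting time to the next coalescence for j lineages starting at time t0,
// carrying the exponential clock across epoch boundaries by memorylessness
// (equivalent to the usual time-rescaling argument).
static double next_coal_time(double t0, int j,
                             const double* start, const double* ne, int n_ep) {
  double t = t0;
  int e = n_ep - 1;
  while (e > 0 && start[e] > t) --e;
  const double pairs = 0.5 * j * (j - 1);
  for (;;) {
    double rate = pairs / (2.0 * ne[e]);
    double w = R::exp_rand() / rate;
    if (e == n_ep - 1 || t + w < start[e + 1]) return t + w;
    t = start[e + 1];
    ++e;
  }
}

// Kingman coalescent: nodes 0..n-1 are tips (time 0), node n-1+i is created
// at the i-th merge; the root is node 2n-2. parent[root] = -1.
static void sim_tree(int n, const double* start, const double* ne, int n_ep,
                     std::vector<int>& parent, std::vector<double>& time) {
  int n_nodes = 2 * n - 1;
  parent.assign(n_nodes, -1);
  time.assign(n_nodes, 0.0);
  if (n == 1) return;
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int k = n, next_node = n;
  while (k > 1) {
    t = next_coal_time(t, k, start, ne, n_ep);
    int i = (int)(unif_rand() * k);
    int a = active[i];
    active[i] = active[--k];
    int j2 = (int)(unif_rand() * k);
    int b = active[j2];
    parent[a] = next_node;
    parent[b] = next_node;
    time[next_node] = t;
    active[j2] = next_node;
    ++next_node;
  }
}

// Net allele-size displacement from nmut mutations.
// GSM (q_multi < 0): |S| ~ Geometric on {1,2,...} with P(|S|=s) =
//   (1-p) p^(s-1); the multistep fraction is exactly p.
// TPM (q_multi >= 0): |S| = 1 with prob 1-p, else |S| = 2 + G with
//   G ~ Geom(1-q_multi) (number of failures), so Var(|S| | multistep) =
//   q/(1-q)^2 can be matched to a target variance.
static int net_steps(int nmut, double p, double q_multi) {
  int net = 0;
  for (int m = 0; m < nmut; ++m) {
    int s;
    if (q_multi < 0.0) {
      s = (p > 0.0) ? 1 + (int)R::rgeom(1.0 - p) : 1;
    } else {
      if (unif_rand() < 1.0 - p) s = 1;
      else s = 2 + (int)R::rgeom(1.0 - q_multi);
    }
    net += (unif_rand() < 0.5) ? s : -s;
  }
  return net;
}

// Drop mutations on a tree and propagate allele sizes root -> tips.
// Node indices as produced by sim_tree: every parent index exceeds its
// children's, so a single reverse sweep suffices.
static void mutate_tree(const std::vector<int>& parent,
                        const std::vector<double>& time,
                        double mu, double p, double q_multi, int root_allele,
                        std::vector<int>& allele) {
  int n_nodes = (int)parent.size();
  allele.assign(n_nodes, root_allele);
  for (int v = n_nodes - 2; v >= 0; --v) {
    double len = time[parent[v]] - time[v];
    int nmut = (mu > 0.0 && len > 0.0) ? (int)R::rpois(mu * len) : 0;
    allele[v] = allele[parent[v]] + net_steps(nmut, p, q_multi);
  }
}

// [[Rcpp::export(name = ".cpp_sim_genealogy")]]
List cpp_sim_genealogy(int n, NumericVector epoch_start, NumericVector epoch_ne) {
  if (n < 1) stop("n_lineages must be >= 1");
  std::vector<int> parent;
  std::vector<double> time;
  sim_tree(n, epoch_start.begin(), epoch_ne.begin(), epoch_start.size(),
           parent, time);
  IntegerVector par(parent.begin(), parent.end());
  for (int i = 0; i < par.size(); ++i) par[i] += 1;  // 1-based, 0 -> NA below
  par[2 * n - 2] = NA_INTEGER;
  if (n == 1) par[0] = NA_INTEGER;
  return List::create(_["parent"] = par,
                      _["time"] = NumericVector(time.begin(), time.end()),
                      _["n_tips"] = n);
}

// [[Rcpp::export(name = ".cpp_mutate_genealogy")]]
IntegerVector cpp_mutate_genealogy(IntegerVector parent, NumericVector time,
                                   int n_tips, double mu, double p,
                                   double q_multi, int root_allele) {
  int n_nodes = parent.size();
  std::vector<int> par(n_nodes);
  for (int i = 0; i < n_nodes; ++i)
    par[i] = (parent[i] == NA_INTEGER) ? -1 : parent[i] - 1;
  std::vector<double> tm(time.begin(), time.end());
  std::vector<int> allele;
  mutate_tree(par, tm, mu, p, q_multi, root_allele, allele);
  return IntegerVector(allele.begin(), allele.begin() + n_tips);
}

// Simulate one locus: n_copies tip allele sizes.
static void sim_locus(int n_copies, const double* start, const double* ne,
                      int n_ep, double mu, double p, double q_multi,
                      int root_allele, std::vector<int>& parent,
                      std::vector<double>& time, std::vector<int>& allele) {
  sim_tree(n_copies, start, ne, n_ep, parent, time);
  mutate_tree(parent, time, mu, p, q_multi, root_allele, allele);
  allele.resize(n_copies);  // keep tip states only
}

// [[Rcpp::export(name = ".cpp_sim_dataset")]]
IntegerMatrix cpp_sim_dataset(int n_copies, int n_loci,
                              NumericVector epoch_start, NumericVector epoch_ne,
                              double mu, double p, double q_multi,
                              int root_allele) {
  IntegerMatrix out(n_copies, n_loci);
  std::vector<int> parent, allele;
  std::vector<double> time;
  for (int l = 0; l < n_loci; ++l) {
    sim_locus(n_copies, epoch_start.begin(), epoch_ne.begin(),
              epoch_start.size(), mu, p, q_multi, root_allele,
              parent, time, allele);
    for (int i = 0; i < n_copies; ++i) out(i, l) = allele[i];
  }
  return out;
}

// Per-locus summaries from sorted gene copies:
// k (allele count), proportion of alleles at frequency < low_freq,
// M = k / (range + 1), unbiased expected heterozygosity.
struct LocusStats { double k, prop_low, m_ratio, he; };

static LocusStats locus_stats(std::vector<int>& a, double low_freq) {
  std::sort(a.begin(), a.end());
  int n = (int)a.size();
  int k = 0, n_low = 0;
  double sum_p2 = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && a[j] == a[i]) ++j;
    int cnt = j - i;
    ++k;
    double f = (double)cnt / n;
    if (f < low_freq) ++n_low;
    sum_p2 += f * f;
    i = j;
  }
  LocusStats s;
  s.k = k;
  s.prop_low = (double)n_low / k;
  s.m_ratio = (double)k / (a.back() - a.front() + 1);
  s.he = (n > 1) ? (double)n / (n - 1) * (1.0 - sum_p2) : 0.0;
  return s;
}

// Batched dataset-level ABC summaries. Each row of `par` is one dataset:
//   col 0: model (2 = two epochs, 3 = three epochs)
//   cols 1-3: ne1, ne2, ne3 (ne3 ignored for 2-epoch models)
//   cols 4-5: t2, t3 (epoch start times; t3 ignored for 2-epoch)
//   col 6: mu, col 7: p_multistep, col 8: q_multi (< 0 for GSM law)
// Returns one row per dataset: mean k, mean prop low-freq alleles, mean M.
// [[Rcpp::export(name = ".cpp_batch_summaries")]]
NumericMatrix cpp_batch_summaries(NumericMatrix par, int n_copies, int n_loci,
                                  double low_freq, int root_allele) {
  int n_sets = par.nrow();
  NumericMatrix out(n_sets, 3);
  std::vector<int> parent, allele;
  std::vector<double> time;
  double start[3], ne[3];
  for (int d = 0; d < n_sets; ++d) {
    int n_ep = (int)par(d, 0);
    start[0] = 0.0; ne[0] = par(d, 1);
    start[1] = par(d, 4); ne[1] = par(d, 2);
    start[2] = par(d, 5); ne[2] = par(d, 3);
    double mu = par(d, 6), p = par(d, 7), q = par(d, 8);
    double sk = 0, sl = 0, sm = 0;
    for (int l = 0; l < n_loci; ++l) {
      sim_locus(n_copies, start, ne, n_ep, mu, p, q, root_allele,
                parent, time, allele);
      LocusStats s = locus_stats(allele, low_freq);
      sk += s.k; sl += s.prop_low; sm += s.m_ratio;
    }
    out(d, 0) = sk / n_loci;
    out(d, 1) = sl / n_loci;
    out(d, 2) = sm / n_loci;
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batched mean allele count per dataset (diversity-loss simulations).
// [[Rcpp::export(name = ".cpp_batch_mean_k")]]
NumericVector cpp_batch_mean_k(NumericMatrix par, int n_copies, int n_loci,
                               int root_allele) {
  int n_sets = par.nrow();
  NumericVector out(n_sets);
  std::vector<int> parent, allele;
  std::vector<double> time;
  double start[3], ne[3];
  for (int d = 0; d < n_sets; ++d) {
    int n_ep = (int)par(d, 0);
    start[0] = 0.0; ne[0] = par(d, 1);
    start[1] = par(d, 4); ne[1] = par(d, 2);
    start[2] = par(d, 5); ne[2] = par(d, 3);
    double mu = par(d, 6), p = par(d, 7), q = par(d, 8);
    double sk = 0;
    for (int l = 0; l < n_loci; ++l) {
      sim_locus(n_copies, start, ne, n_ep, mu, p, q, root_allele,
                parent, time, allele);
      LocusStats s = locus_stats(allele, 0.05);
      sk += s.k;
    }
    out[d] = sk / n_loci;
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batched mean expected heterozygosity per dataset (loss comparisons).
// [[Rcpp::export(name = ".cpp_batch_mean_he")]]
NumericVector cpp_batch_mean_he(NumericMatrix par, int n_copies, int n_loci,
                                int root_allele) {
  int n_sets = par.nrow();
  NumericVector out(n_sets);
  std::vector<int> parent, allele;
  std::vector<double> time;
  double start[3], ne[3];
  for (int d = 0; d < n_sets; ++d) {
    int n_ep = (int)par(d, 0);
    start[0] = 0.0; ne[0] = par(d, 1);
    start[1] = par(d, 4); ne[1] = par(d, 2);
    start[2] = par(d, 5); ne[2] = par(d, 3);
    double mu = par(d, 6), p = par(d, 7), q = par(d, 8);
    double sh = 0;
    for (int l = 0; l < n_loci; ++l) {
      sim_locus(n_copies, start, ne, n_ep, mu, p, q, root_allele,
                parent, time, allele);
      LocusStats s = locus_stats(allele, 0.05);
      sh += s.he;
    }
    out[d] = sh / n_loci;
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Equilibrium (constant-Ne) replicates for the heterozygosity-excess test:
// one locus per replicate at scaled mutation rate theta = 4*Ne*mu.
// Returns k and unbiased He per replicate.
// [[Rcpp::export(name = ".cpp_equilibrium_k_he")]]
NumericMatrix cpp_equilibrium_k_he(int n_copies, int n_rep, double theta,
                                   double p, double q_multi) {
  const double ne_fix = 1000.0;
  double mu = theta / (4.0 * ne_fix);
  double start[1] = {0.0}, ne[1] = {ne_fix};
  NumericMatrix out(n_rep, 2);
  std::vector<int> parent, allele;
  std::vector<double> time;
  for (int r = 0; r < n_rep; ++r) {
    sim_locus(n_copies, start, ne, 1, mu, p, q_multi, 50, parent, time, allele);
    LocusStats s = locus_stats(allele, 0.05);
    out(r, 0) = s.k;
    out(r, 1) = s.he;
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
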
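#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured coalescent for a single non-recombining locus.
//
// Lineages are traced backward in time through a set of demes. Waiting times
// between events are exponential with total rate = sum over demes of
// k_i*(k_i-1)/2 / N_i (coalescence; N_i in gene copies) plus, when more than
// one deme is open, k_total * (n_open-1) * m (migration; m is the backward
// per-pair per-generation migration rate). Demographic events interrupt the
// exponential clock at fixed times:
//   type 0: size change    -- deme a takes size x (gene copies)
//   type 1: merge          -- lineages in deme a move to deme b, deme a closes
//   type 2: migration set  -- global per-pair rate becomes x
// Mutations are laid on the realized genealogy afterwards: each branch gets
// Poisson(mu * length) mutations, stepwise +/-1 for microsatellites (model 0)
// or one new segregating column per mutation under infinite sites (model 1).
//
// Uses R's RNG so set.seed() in R gives bit-identical output.

static void fail(const char* msg) { Rcpp::stop(msg); }

// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(IntegerVector deme_of_sample,
                   NumericVector deme_sizes,
                   NumericMatrix events,
                   double mig0,
                   double mu,
                   int model,
                   int ancestral_allele) {
  const int n = deme_of_sample.size();
  const int nd = deme_sizes.size();
  if (n < 1) fail("need at least one sampled gene copy");
  const int n_nodes = 2 * n - 1;

  std::vector<int> parent(n_nodes, -1);
  std::vector<double> ntime(n_nodes, 0.0);

  // lineage state
  std::vector<int> lin_node;   lin_node.reserve(n);
  std::vector<int> lin_deme;   lin_deme.reserve(n);
  std::vector<double> size(nd);
  std::vector<bool> open(nd, true);
  std::vector<int> k(nd, 0);
  for (int d = 0; d < nd; ++d) size[d] = deme_sizes[d];
  for (int i = 0; i < n; ++i) {
    int d = deme_of_sample[i];
    if (d < 0 || d >= nd) fail("sample assigned to unknown deme");
    lin_node.push_back(i);
    lin_deme.push_back(d);
    k[d]++;
  }

  double mig = mig0;
  double t = 0.0;
  int next_node = n;
  int ev = 0;
  const int n_ev = events.nrow();
  long long guard = 0;

  while ((int)lin_node.size() > 1) {
    if (++guard > 200000000LL) fail("event budget exceeded in coalescent simulation");
    int n_open = 0;
    for (int d = 0; d < nd; ++d) if (open[d]) ++n_open;
    double coal_tot = 0.0;
    for (int d = 0; d < nd; ++d)
      if (k[d] > 1) coal_tot += 0.5 * k[d] * (k[d] - 1) / size[d];
    double mig_tot = (n_open > 1 && mig > 0.0)
      ? (double)lin_node.size() * (n_open - 1) * mig : 0.0;
    double tot = coal_tot + mig_tot;

    double t_ev = (ev < n_ev) ? events(ev, 0) : R_PosInf;
    if (tot <= 0.0) {
      if (!R_FINITE(t_ev))
        fail("lineages isolated with zero total rate and no remaining events");
      t = t_ev;
    } else {
      double dt = exp_rand() / tot;
      if (t + dt >= t_ev) {
        t = t_ev;
      } else {
        t += dt;
        double u = unif_rand() * tot;
        if (u < coal_tot) {
          // coalescence: pick deme, then an unordered lineage pair within it
          int dsel = -1;
          double acc = 0.0;
          for (int d = 0; d < nd; ++d) {
            if (k[d] > 1) {
              acc += 0.5 * k[d] * (k[d] - 1) / size[d];
              if (u < acc) { dsel = d; break; }
            }
          }
          if (dsel < 0) dsel = nd - 1;
          int i1 = (int)(unif_rand() * k[dsel]); if (i1 >= k[dsel]) i1 = k[dsel] - 1;
          int i2 = (int)(unif_rand() * (k[dsel] - 1)); if (i2 >= k[dsel] - 1) i2 = k[dsel] - 2;
          if (i2 >= i1) ++i2;
          // map within-deme indices to lineage indices
          int a = -1, b = -1, seen = 0;
          for (size_t j = 0; j < lin_node.size(); ++j) {
            if (lin_deme[j] == dsel) {
              if (seen == i1) a = (int)j;
              if (seen == i2) b = (int)j;
              ++seen;
            }
          }
          int nn = next_node++;
          ntime[nn] = t;
          parent[lin_node[a]] = nn;
          parent[lin_node[b]] = nn;
          lin_node[a] = nn;
          int last = (int)lin_node.size() - 1;
          lin_node[b] = lin_node[last]; lin_deme[b] = lin_deme[last];
          lin_node.pop_back(); lin_deme.pop_back();
          k[dsel]--;
        } else {
          // migration: uniform lineage, uniform other open deme
          int j = (int)(unif_rand() * lin_node.size());
          if (j >= (int)lin_node.size()) j = (int)lin_node.size() - 1;
          int from = lin_deme[j];
          int pick = (int)(unif_rand() * (n_open - 1));
          if (pick >= n_open - 1) pick = n_open - 2;
          int to = -1, seen = 0;
          for (int d = 0; d < nd; ++d) {
            if (open[d] && d != from) {
              if (seen == pick) { to = d; break; }
              ++seen;
            }
          }
          if (to < 0) continue;
          lin_deme[j] = to;
          k[from]--; k[to]++;
        }
        continue;
      }
    }

    // at an event time: apply every event scheduled here
    while (ev < n_ev && events(ev, 0) <= t) {
      int type = (int)events(ev, 1);
      int a = (int)events(ev, 2);
      int b = (int)events(ev, 3);
      double x = events(ev, 4);
      if (type == 0) {
        if (a < 0 || a >= nd) fail("size change on unknown deme");
        if (x < 1.0) fail("deme size below one gene copy");
        size[a] = x;
      } else if (type == 1) {
        if (a < 0 || a >= nd || b < 0 || b >= nd) fail("merge on unknown deme");
        if (!open[b]) fail("merge target deme already closed");
        for (size_t j = 0; j < lin_node.size(); ++j)
          if (lin_deme[j] == a) { lin_deme[j] = b; k[a]--; k[b]++; }
        open[a] = false;
      } else if (type == 2) {
        mig = x;
      } else fail("unknown event type");
      ++ev;
    }
  }

  const int root = lin_node[0];
  // branch lengths and mutation overlay
  double tree_len = 0.0;
  for (int v = 0; v < n_nodes; ++v)
    if (v != root && parent[v] >= 0) tree_len += ntime[parent[v]] - ntime[v];

  int n_mut_total = 0;
  List out;
  if (model == 0) {
    // stepwise mutation: walk from root down
    std::vector<int> allele(n_nodes, ancestral_allele);
    // process nodes in order of decreasing time (root first); internal nodes
    // were created in increasing time order, so iterate them backwards
    std::vector<int> order;
    order.reserve(n_nodes);
    for (int v = n_nodes - 1; v >= 0; --v) if (v != root) order.push_back(v);
    for (size_t idx = 0; idx < order.size(); ++idx) {
      int v = order[idx];
      double len = ntime[parent[v]] - ntime[v];
      int nm = (int)R::rpois(mu * len);
      n_mut_total += nm;
      int a = allele[parent[v]];
      for (int m2 = 0; m2 < nm; ++m2) a += (unif_rand() < 0.5) ? -1 : 1;
      if (a < 1) a = 1;  // repeat scores stay positive
      allele[v] = a;
    }
    IntegerVector res(n);
    for (int i = 0; i < n; ++i) res[i] = allele[i];
    out = List::create(_["alleles"] = res,
                       _["tree_length"] = tree_len,
                       _["n_mutations"] = n_mut_total);
  } else {
    // infinite sites: one new column per mutation, derived below its branch
    std::vector<int> mut_node;
    for (int v = 0; v < n_nodes; ++v) {
      if (v == root || parent[v] < 0) continue;
      double len = ntime[parent[v]] - ntime[v];
      int nm = (int)R::rpois(mu * len);
      for (int m2 = 0; m2 < nm; ++m2) mut_node.push_back(v);
    }
    n_mut_total = (int)mut_node.size();
    IntegerMatrix geno(n, n_mut_total);
    // ancestor flags per sample via parent climbing
    for (int i = 0; i < n; ++i) {
      std::vector<char> isanc(n_nodes, 0);
      int v = i;
      while (v >= 0) { isanc[v] = 1; v = parent[v]; }
      for (int j = 0; j < n_mut_total; ++j) geno(i, j) = isanc[mut_node[j]] ? 1 : 0;
    }
    out = List::create(_["genotypes"] = geno,
                       _["tree_length"] = tree_len,
                       _["n_mutations"] = n_mut_total);
  }
  return out;
}
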
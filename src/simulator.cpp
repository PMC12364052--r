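// Cell-based forward simulation of one germinal center: a birth-death-
// mutation process on nucleotide sequences with carrying-capacity
// regulation. Uses the direct (total-rate) Gillespie construction, which is
// distribution-identical to per-cell first-reaction waiting-time
// competition with exponential clocks. Per-cell rates are held in Fenwick
// trees for O(log N) categorical sampling and updates.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Fenwick {
  std::vector<double> t;
  int n;
  explicit Fenwick(int n_) : t(n_ + 1, 0.0), n(n_) {}
  void add(int i, double v) { for (++i; i <= n; i += i & -i) t[i] += v; }
  double total() const {
    double s = 0; for (int i = n; i > 0; i -= i & -i) s += t[i]; return s;
  }
  // smallest index with prefix sum > u
  int sample(double u) const {
    int pos = 0;
    int logn = 1; while ((1 << logn) <= n) ++logn;
    for (int k = 1 << logn; k > 0; k >>= 1) {
      if (pos + k <= n && t[pos + k] <= u) { pos += k; u -= t[pos]; }
    }
    return pos; // 0-based
  }
};

struct Genotype {
  std::vector<uint8_t> seq;
  double affinity;
  double mutsum;   // total relative mutability (multiplier not applied)
  double lambda;   // intrinsic birth rate from affinity
  int n_stops;
};

struct ShmTables {
  const double *full, *L2, *L1, *R1, *R2;              // mutabilities
  const double *sfull, *sL2, *sL1, *sR1, *sR2;         // substitution, col-major
  int L; // sequence length
  double pos_mut(const uint8_t *s, int j) const {
    if (j >= 2 && j < L - 2)
      return full[((int)s[j-2]*256) + ((int)s[j-1]*64) + ((int)s[j]*16) +
                  ((int)s[j+1]*4) + s[j+2]];
    if (j == 0) return L2[((int)s[0]*16) + ((int)s[1]*4) + s[2]];
    if (j == 1) return L1[((int)s[0]*64) + ((int)s[1]*16) + ((int)s[2]*4) + s[3]];
    if (j == L - 2)
      return R1[((int)s[L-4]*64) + ((int)s[L-3]*16) + ((int)s[L-2]*4) + s[L-1]];
    return R2[((int)s[L-3]*16) + ((int)s[L-2]*4) + s[L-1]];
  }
  // substitution probability of base b at position j (tables are n x 4,
  // column-major with column stride nrow)
  void sub_row(const uint8_t *s, int j, double out[4]) const {
    const double *tab; int idx, nrow;
    if (j >= 2 && j < L - 2) {
      tab = sfull; nrow = 1024;
      idx = ((int)s[j-2]*256) + ((int)s[j-1]*64) + ((int)s[j]*16) +
            ((int)s[j+1]*4) + s[j+2];
    } else if (j == 0) {
      tab = sL2; nrow = 64; idx = ((int)s[0]*16) + ((int)s[1]*4) + s[2];
    } else if (j == 1) {
      tab = sL1; nrow = 256;
      idx = ((int)s[0]*64) + ((int)s[1]*16) + ((int)s[2]*4) + s[3];
    } else if (j == L - 2) {
      tab = sR1; nrow = 256;
      idx = ((int)s[L-4]*64) + ((int)s[L-3]*16) + ((int)s[L-2]*4) + s[L-1];
    } else {
      tab = sR2; nrow = 64; idx = ((int)s[L-3]*16) + ((int)s[L-2]*4) + s[L-1];
    }
    for (int b = 0; b < 4; ++b) out[b] = tab[idx + b * nrow];
  }
};

struct Sim {
  // model
  std::vector<uint8_t> naive;
  ShmTables shm;
  double multiplier;
  const int *codon_aa;       // 64 entries, -1 = stop
  const double *dms;         // L/3 x 20, column-major
  int n_codons;
  double xc, xh, yc, yh;
  bool zero_birth_nonfunc;

  // config
  double N0, T, mu_f, mu_s;
  int cap_method; // 0 birth, 1 death, 2 hard
  int init_pop, min_viable;

  std::vector<Genotype> genos;

  double sigmoid(double x) const {
    double z = xc * (x - xh);
    double s = (z >= 0) ? 1.0 / (1.0 + std::exp(-z))
                        : std::exp(z) / (1.0 + std::exp(z));
    return yc * s + yh;
  }
  int aa_at(const std::vector<uint8_t> &s, int cs) const {
    int c = ((int)s[3*cs]*16) + ((int)s[3*cs+1]*4) + s[3*cs+2];
    return codon_aa[c];
  }
  double affinity_full(const std::vector<uint8_t> &s) const {
    double a = 0;
    for (int cs = 0; cs < n_codons; ++cs) {
      int aa = aa_at(s, cs);
      if (aa >= 0) a += dms[cs + aa * n_codons];
    }
    return a;
  }
  double mutsum_full(const std::vector<uint8_t> &s) const {
    double m = 0;
    for (int j = 0; j < shm.L; ++j) m += shm.pos_mut(s.data(), j);
    return m;
  }
  int make_naive_genotype() {
    Genotype g;
    g.seq = naive;
    g.n_stops = 0;
    g.affinity = affinity_full(g.seq); // 0 by construction of the DMS table
    g.mutsum = mutsum_full(g.seq);
    g.lambda = sigmoid(g.affinity);
    genos.push_back(std::move(g));
    return (int)genos.size() - 1;
  }
  // returns index of the mutated genotype
  int mutate_genotype(int gi, int *out_pos) {
    // choose position proportional to per-position mutability
    const Genotype &g = genos[gi];
    double u = unif_rand() * g.mutsum;
    int pos = shm.L - 1;
    double acc = 0;
    for (int j = 0; j < shm.L; ++j) {
      acc += shm.pos_mut(g.seq.data(), j);
      if (u < acc) { pos = j; break; }
    }
    double pr[4];
    shm.sub_row(g.seq.data(), pos, pr);
    double v = unif_rand() * (pr[0] + pr[1] + pr[2] + pr[3]);
    int b = 3; double a2 = 0;
    for (int k = 0; k < 4; ++k) { a2 += pr[k]; if (v < a2) { b = k; break; } }

    Genotype h = g; // copy
    int cs = pos / 3;
    int old_aa = aa_at(h.seq, cs);
    h.seq[pos] = (uint8_t)b;
    int new_aa = aa_at(h.seq, cs);
    // incremental mutability update over the 5-mer window around pos
    int lo = std::max(0, pos - 2), hi = std::min(shm.L - 1, pos + 2);
    double d = 0;
    for (int j = lo; j <= hi; ++j)
      d += shm.pos_mut(h.seq.data(), j) - shm.pos_mut(g.seq.data(), j);
    h.mutsum = g.mutsum + d;
    if (old_aa < 0 && new_aa >= 0) {
      h.n_stops = g.n_stops - 1;
      if (h.n_stops == 0) { h.affinity = affinity_full(h.seq); h.lambda = sigmoid(h.affinity); }
    } else if (old_aa >= 0 && new_aa < 0) {
      h.n_stops = g.n_stops + 1; // affinity and lambda frozen at last functional value
    } else if (g.n_stops == 0 && old_aa != new_aa) {
      h.affinity = g.affinity + dms[cs + new_aa * n_codons] - dms[cs + old_aa * n_codons];
      h.lambda = sigmoid(h.affinity);
    }
    genos.push_back(std::move(h));
    *out_pos = pos;
    return (int)genos.size() - 1;
  }
};

} // namespace

// [[Rcpp::export]]
List sim_gc_cpp(IntegerVector naive, IntegerVector codon_aa, NumericMatrix dms_eff,
                List shm_model, double multiplier,
                NumericVector resp, double N0, int cap_method, int init_pop,
                double T, double mu_f, double mu_s, int min_viable,
                int max_tries, int sample_size, bool zero_birth_nonfunc,
                bool record_truth, bool record_trajectory) {
  Sim S;
  S.naive.assign(naive.begin(), naive.end());
  S.n_codons = (int)S.naive.size() / 3;
  S.codon_aa = INTEGER(codon_aa);
  NumericMatrix de = dms_eff;
  S.dms = REAL(de);
  NumericVector m_full = shm_model["full"], m_L2 = shm_model["L2"],
                m_L1 = shm_model["L1"], m_R1 = shm_model["R1"],
                m_R2 = shm_model["R2"];
  NumericMatrix s_full = shm_model["s_full"], s_L2 = shm_model["s_L2"],
                s_L1 = shm_model["s_L1"], s_R1 = shm_model["s_R1"],
                s_R2 = shm_model["s_R2"];
  S.shm.full = REAL(m_full); S.shm.L2 = REAL(m_L2); S.shm.L1 = REAL(m_L1);
  S.shm.R1 = REAL(m_R1); S.shm.R2 = REAL(m_R2);
  S.shm.sfull = REAL(s_full); S.shm.sL2 = REAL(s_L2); S.shm.sL1 = REAL(s_L1);
  S.shm.sR1 = REAL(s_R1); S.shm.sR2 = REAL(s_R2);
  S.shm.L = (int)S.naive.size();
  S.multiplier = multiplier;
  S.xc = resp[0]; S.xh = resp[1]; S.yc = resp[2]; S.yh = resp[3];
  S.zero_birth_nonfunc = zero_birth_nonfunc;
  S.N0 = N0; S.T = T; S.mu_f = mu_f; S.mu_s = mu_s;
  S.cap_method = cap_method; S.init_pop = init_pop; S.min_viable = min_viable;

  // node table (per attempt)
  std::vector<int> par; std::vector<double> ntime, naff;
  std::vector<uint8_t> nevent; // 0 root/init, 1 birth, 2 mutation
  std::vector<int> ngeno;      // genotype at node creation (for leaves)

  std::vector<int> cell_node, cell_geno;
  std::vector<double> traj_t; std::vector<int> traj_n;
  int n_tries = 0;

  for (;;) {
    if (++n_tries > max_tries)
      stop("run_gc: retry budget (%d) exhausted; parameter set appears "
           "non-viable (xc=%g xh=%g yc=%g yh=%g N0=%g init=%d T=%g mu_f=%g)",
           max_tries, S.xc, S.xh, S.yc, S.yh, N0, init_pop, T, mu_f);
    S.genos.clear();
    par.clear(); ntime.clear(); naff.clear(); nevent.clear(); ngeno.clear();
    cell_node.clear(); cell_geno.clear();
    traj_t.clear(); traj_n.clear();

    int g0 = S.make_naive_genotype();
    if (S.genos[g0].mutsum <= 0 && multiplier > 0)
      stop("naive sequence has zero total mutability");

    auto new_node = [&](int p, double t, double a, uint8_t ev, int gi) {
      par.push_back(p); ntime.push_back(t); naff.push_back(a);
      nevent.push_back(ev); ngeno.push_back(gi);
      return (int)par.size() - 1;
    };
    int root = new_node(-1, 0.0, S.genos[g0].affinity, 0, g0);
    cell_node.push_back(root); cell_geno.push_back(g0);
    // zero-time binary expansion, splitting one cell at a time (FIFO)
    std::size_t split_at = 0;
    while ((int)cell_node.size() < init_pop) {
      int v = cell_node[split_at];
      int c1 = new_node(v, 0.0, S.genos[g0].affinity, 0, g0);
      int c2 = new_node(v, 0.0, S.genos[g0].affinity, 0, g0);
      cell_node[split_at] = c1;
      cell_node.push_back(c2); cell_geno.push_back(g0);
      ++split_at;
    }

    int cap = std::max({(int)(4 * N0), 2 * init_pop, 1024});
    Fenwick f_lam(cap), f_mu(cap), f_mut(cap);
    auto cell_rates = [&](int gi, double *lam, double *mu, double *mut) {
      const Genotype &g = S.genos[gi];
      bool func = g.n_stops == 0;
      *lam = (!func && S.zero_birth_nonfunc) ? 0.0 : g.lambda;
      *mu = func ? S.mu_f : S.mu_s;
      *mut = S.multiplier * g.mutsum;
    };
    for (std::size_t i = 0; i < cell_node.size(); ++i) {
      double lam, mu, mut;
      cell_rates(cell_geno[i], &lam, &mu, &mut);
      f_lam.add((int)i, lam); f_mu.add((int)i, mu); f_mut.add((int)i, mut);
    }
    auto remove_cell = [&](int i) {
      int last = (int)cell_node.size() - 1;
      double lam, mu, mut;
      cell_rates(cell_geno[i], &lam, &mu, &mut);
      f_lam.add(i, -lam); f_mu.add(i, -mu); f_mut.add(i, -mut);
      if (i != last) {
        cell_rates(cell_geno[last], &lam, &mu, &mut);
        f_lam.add(last, -lam); f_mu.add(last, -mu); f_mut.add(last, -mut);
        f_lam.add(i, lam); f_mu.add(i, mu); f_mut.add(i, mut);
        cell_node[i] = cell_node[last]; cell_geno[i] = cell_geno[last];
      }
      cell_node.pop_back(); cell_geno.pop_back();
    };

    double t = 0.0;
    bool reached_T = false;
    for (;;) {
      int N = (int)cell_node.size();
      if (N == 0) break; // extinct -> retry
      if (N >= cap) stop("population exceeded internal capacity buffer");
      double sum_lam = f_lam.total(), sum_mu = f_mu.total(),
             sum_mut = f_mut.total();
      double m = 1.0;
      if (S.cap_method == 0) {
        if (sum_lam <= 0) stop("capacity factor: zero total birth rate");
        m = std::pow(sum_mu / sum_lam, (double)N / S.N0);
      } else if (S.cap_method == 1) {
        if (sum_mu <= 0) stop("capacity factor: zero total death rate");
        m = std::pow(sum_lam / sum_mu, (double)N / S.N0);
      }
      double Rb = (S.cap_method == 0) ? m * sum_lam : sum_lam;
      double Rd = (S.cap_method == 1) ? m * sum_mu : sum_mu;
      double Rm = sum_mut;
      double Rtot = Rb + Rd + Rm;
      if (Rtot <= 0) { t = S.T; reached_T = true; break; } // frozen state
      double dt = exp_rand() / Rtot;
      if (t + dt >= S.T) { t = S.T; reached_T = true; break; }
      t += dt;
      double u = unif_rand() * Rtot;
      if (u < Rb) {
        int i = f_lam.sample(unif_rand() * sum_lam);
        if (i >= (int)cell_node.size()) i = (int)cell_node.size() - 1;
        int v = cell_node[i]; int gi = cell_geno[i];
        double a = S.genos[gi].affinity;
        int c1 = new_node(v, t, a, 1, gi);
        int c2 = new_node(v, t, a, 1, gi);
        double lam, mu, mut; cell_rates(gi, &lam, &mu, &mut);
        cell_node[i] = c1;
        int j = (int)cell_node.size();
        cell_node.push_back(c2); cell_geno.push_back(gi);
        f_lam.add(j, lam); f_mu.add(j, mu); f_mut.add(j, mut);
        if (S.cap_method == 2 && (int)cell_node.size() > (int)S.N0) {
          int k = (int)std::floor(unif_rand() * cell_node.size());
          if (k >= (int)cell_node.size()) k = (int)cell_node.size() - 1;
          remove_cell(k);
        }
      } else if (u < Rb + Rd) {
        int i = f_mu.sample(unif_rand() * sum_mu);
        if (i >= (int)cell_node.size()) i = (int)cell_node.size() - 1;
        remove_cell(i);
      } else {
        int i = f_mut.sample(unif_rand() * sum_mut);
        if (i >= (int)cell_node.size()) i = (int)cell_node.size() - 1;
        int v = cell_node[i]; int gi = cell_geno[i];
        int pos;
        int gj = S.mutate_genotype(gi, &pos);
        int w = new_node(v, t, S.genos[gj].affinity, 2, gj);
        double lam0, mu0, mut0, lam1, mu1, mut1;
        cell_rates(gi, &lam0, &mu0, &mut0);
        cell_rates(gj, &lam1, &mu1, &mut1);
        cell_node[i] = w; cell_geno[i] = gj;
        f_lam.add(i, lam1 - lam0); f_mu.add(i, mu1 - mu0);
        f_mut.add(i, mut1 - mut0);
      }
      if (record_trajectory) {
        traj_t.push_back(t); traj_n.push_back((int)cell_node.size());
      }
    }
    if (reached_T && (int)cell_node.size() >= min_viable) break;
  }

  int N_final = (int)cell_node.size();
  int k = std::min(sample_size, N_final);
  // uniform sample without replacement (partial Fisher-Yates on indices)
  std::vector<int> idx(N_final);
  for (int i = 0; i < N_final; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (N_final - i));
    if (j >= N_final) j = N_final - 1;
    std::swap(idx[i], idx[j]);
  }
  std::vector<int> leaf_node(k), leaf_geno(k);
  for (int i = 0; i < k; ++i) {
    leaf_node[i] = cell_node[idx[i]];
    leaf_geno[i] = cell_geno[idx[i]];
  }

  // ---- induced (sampled) tree over leaf_node + ancestors ----
  int n_nodes = (int)par.size();
  std::vector<uint8_t> mark(n_nodes, 0);
  std::vector<int> nmarked_children(n_nodes, 0);
  std::vector<int> path_mut(k, 0);
  for (int i = 0; i < k; ++i) {
    int v = leaf_node[i];
    while (v >= 0 && !mark[v]) { mark[v] = 1; v = par[v]; }
  }
  for (int i = 0; i < k; ++i) {
    int v = leaf_node[i];
    while (v >= 0) {
      if (nevent[v] == 2) ++path_mut[i];
      v = par[v];
    }
  }
  for (int v = 0; v < n_nodes; ++v)
    if (mark[v] && par[v] >= 0) ++nmarked_children[par[v]];
  std::vector<uint8_t> keep(n_nodes, 0);
  for (int i = 0; i < k; ++i) keep[leaf_node[i]] = 1;
  keep[0] = 1; // root
  for (int v = 0; v < n_nodes; ++v)
    if (mark[v] && nmarked_children[v] >= 2) keep[v] = 1;
  // a sampled leaf that is also an ancestor of another sampled leaf cannot
  // occur: leaves are living cells at T, and living cells are tree tips.
  std::vector<int> kept; kept.reserve(2 * k);
  for (int v = 0; v < n_nodes; ++v) if (keep[v]) kept.push_back(v);
  int n_kept = (int)kept.size();
  std::vector<int> kept_id(n_nodes, -1);
  // ape numbering: tips 1..k (sample order), root k+1, other internals k+2..
  for (int i = 0; i < k; ++i) kept_id[leaf_node[i]] = i + 1;
  if (kept_id[0] < 0) kept_id[0] = k + 1; // root, unless it is itself a tip
  int next_id = k + 2;
  for (int v : kept)
    if (kept_id[v] < 0) kept_id[v] = next_id++;
  std::vector<int> edge_from, edge_to; std::vector<double> edge_len;
  std::vector<double> out_time(n_kept), out_aff(n_kept);
  for (int v : kept) {
    int id = kept_id[v];
    // sampled leaves are cells alive at sampling time: they sit at T
    double tv = (id <= k) ? S.T : ntime[v];
    out_time[id - 1] = tv; out_aff[id - 1] = naff[v];
    if (v == 0) continue;
    int p = par[v];
    while (!keep[p]) p = par[p];
    edge_from.push_back(kept_id[p]); edge_to.push_back(id);
    edge_len.push_back(tv - ntime[p]);
  }

  // sampled sequences and mutation counts
  CharacterVector seqs(k);
  IntegerVector nmut(k), pmut(k);
  const char *bases = "ACGT";
  for (int i = 0; i < k; ++i) {
    const std::vector<uint8_t> &s = S.genos[leaf_geno[i]].seq;
    std::string str(s.size(), 'A');
    int nd = 0;
    for (std::size_t j = 0; j < s.size(); ++j) {
      str[j] = bases[s[j]];
      if (s[j] != S.naive[j]) ++nd;
    }
    seqs[i] = str;
    nmut[i] = nd;
    pmut[i] = path_mut[i];
  }

  // living-population snapshot at T
  NumericVector live_aff(N_final), live_lam(N_final), live_mu(N_final);
  LogicalVector live_func(N_final);
  for (int i = 0; i < N_final; ++i) {
    const Genotype &g = S.genos[cell_geno[i]];
    bool func = g.n_stops == 0;
    live_aff[i] = g.affinity;
    live_lam[i] = (!func && S.zero_birth_nonfunc) ? 0.0 : g.lambda;
    live_mu[i] = func ? mu_f : mu_s;
    live_func[i] = func;
  }

  List tree = List::create(
    _["edge_from"] = edge_from, _["edge_to"] = edge_to,
    _["edge_length"] = edge_len, _["n_tip"] = k,
    _["node_time"] = out_time, _["node_affinity"] = out_aff);

  List out = List::create(
    _["tree"] = tree, _["sequences"] = seqs, _["n_mutations"] = nmut,
    _["path_mutations"] = pmut, _["n_living"] = N_final,
    _["living_affinity"] = live_aff, _["living_lambda"] = live_lam,
    _["living_mu"] = live_mu, _["living_functional"] = live_func,
    _["n_tries"] = n_tries);
  if (record_trajectory)
    out["trajectory"] = DataFrame::create(_["time"] = traj_t, _["n"] = traj_n);
  if (record_truth)
    out["truth"] = List::create(
      _["parent"] = IntegerVector(par.begin(), par.end()),
      _["time"] = NumericVector(ntime.begin(), ntime.end()),
      _["affinity"] = NumericVector(naff.begin(), naff.end()),
      _["event"] = IntegerVector(nevent.begin(), nevent.end()));
  return out;
}
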
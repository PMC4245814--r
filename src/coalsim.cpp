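// Structured-coalescent simulator with founder events, deterministic
// exponential size trajectories, symmetric migration, and infinite-sites
// mutation.  Time is measured backwards from the present in generations;
// population sizes are haploid effective sizes, so k lineages in a deme of
// current size N(t) coalesce at rate choose(k,2)/N(t).
//
// A deme d is described by
//   N[d]        size at the present,
//   g[d]        backward decline rate: N_d(t) = N[d] * exp(-g[d] * t),
//               g = log(N/f)/tau for a deme founded by f individuals tau
//               generations ago (g < 0 is allowed: a deme founded by more
//               individuals than its present size shrank since founding),
//   t_end[d]    time at which the deme merges into merge_to[d] (Inf = never),
//   merge_to[d] 0-based index of the source deme (-1 if none).
//
// mig[i][j] is the backward per-lineage rate at which a lineage in deme i
// jumps to deme j (= forward immigration into i from j, as migrant counts).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  // nodes 0..n-1 are leaves; internal nodes appended in coalescence order
  std::vector<int> parent;
  std::vector<double> time;
  std::vector<int> left, right; // children of internal nodes (-1 for leaves)
  int n_leaves;
};

// waiting time (absolute) to next coalescence in deme d given k lineages,
// starting from absolute time t.  Returns R_PosInf if no event occurs in
// finite time (possible when g < 0 and the hazard integral converges).
double coal_time(double t, int k, double N, double g, double E) {
  if (k < 2) return R_PosInf;
  double C = 0.5 * (double)k * (double)(k - 1);
  if (g == 0.0) return t + E * N / C;
  double A = std::exp(g * t) + g * N * E / C;
  if (A <= 0.0) return R_PosInf;
  return std::log(A) / g;
}

// Simulate one genealogy for all samples.  sample_deme gives the starting
// deme of each leaf.  Fills `tree` and, if region_count != nullptr, the
// per-node counts of descendant leaves per region (regions in sample_region).
void simulate_tree(const std::vector<double> &N, const std::vector<double> &g,
                   const std::vector<double> &t_end,
                   const std::vector<int> &merge_to,
                   const NumericMatrix &mig,
                   const std::vector<int> &sample_deme, Tree &tree,
                   const std::vector<int> *sample_region, int n_regions,
                   std::vector<std::vector<int> > *region_count) {
  int D = (int)N.size();
  int n = (int)sample_deme.size();
  tree.n_leaves = n;
  int n_nodes = 2 * n - 1;
  tree.parent.assign(n_nodes, -1);
  tree.time.assign(n_nodes, 0.0);
  tree.left.assign(n_nodes, -1);
  tree.right.assign(n_nodes, -1);
  if (region_count) {
    region_count->assign(n_nodes, std::vector<int>(n_regions, 0));
    for (int i = 0; i < n; ++i) (*region_count)[i][(*sample_region)[i]] = 1;
  }

  std::vector<std::vector<int> > lin(D); // active lineages per deme
  for (int i = 0; i < n; ++i) lin[sample_deme[i]].push_back(i);
  std::vector<bool> alive(D, true);

  int total = n;
  int next_node = n;
  double t = 0.0;

  while (total > 1) {
    // next demographic boundary
    double t_bound = R_PosInf;
    for (int d = 0; d < D; ++d)
      if (alive[d] && t_end[d] < t_bound) t_bound = t_end[d];

    // propose coalescence per deme and migrations
    double best = R_PosInf;
    int ev_type = -1, ev_a = -1, ev_b = -1; // 0 = coal in deme a, 1 = mig a->b
    for (int d = 0; d < D; ++d) {
      if (!alive[d]) continue;
      int k = (int)lin[d].size();
      if (k >= 2) {
        double s = coal_time(t, k, N[d], g[d], exp_rand());
        if (s < best) { best = s; ev_type = 0; ev_a = d; }
      }
      if (k >= 1) {
        for (int d2 = 0; d2 < D; ++d2) {
          if (d2 == d || !alive[d2]) continue;
          double m = mig(d, d2);
          if (m > 0.0) {
            double s = t + exp_rand() / (m * k);
            if (s < best) { best = s; ev_type = 1; ev_a = d; ev_b = d2; }
          }
        }
      }
    }

    if (best >= t_bound) {
      if (!R_FINITE(t_bound))
        stop("non-coalescing configuration: no events possible");
      // merge every deme ending at this boundary
      t = t_bound;
      for (int d = 0; d < D; ++d) {
        if (alive[d] && t_end[d] <= t_bound) {
          int tgt = merge_to[d];
          if (tgt < 0 || !alive[tgt])
            stop("demography error: merge target not available");
          for (size_t i = 0; i < lin[d].size(); ++i)
            lin[tgt].push_back(lin[d][i]);
          lin[d].clear();
          alive[d] = false;
        }
      }
      continue;
    }

    t = best;
    if (ev_type == 1) { // migration
      std::vector<int> &src = lin[ev_a];
      int idx = (int)std::floor(unif_rand() * src.size());
      if (idx >= (int)src.size()) idx = (int)src.size() - 1;
      lin[ev_b].push_back(src[idx]);
      src[idx] = src.back();
      src.pop_back();
    } else { // coalescence
      std::vector<int> &src = lin[ev_a];
      int k = (int)src.size();
      int i = (int)std::floor(unif_rand() * k);
      int j = (int)std::floor(unif_rand() * (k - 1));
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      int a = src[i], b = src[j];
      int node = next_node++;
      tree.time[node] = t;
      tree.left[node] = a;
      tree.right[node] = b;
      tree.parent[a] = node;
      tree.parent[b] = node;
      if (region_count)
        for (int r = 0; r < n_regions; ++r)
          (*region_count)[node][r] =
              (*region_count)[a][r] + (*region_count)[b][r];
      src[j] = node;
      src[i] = src.back();
      src.pop_back();
      --total;
    }
  }
}

void unpack_demography(const List &demog, std::vector<double> &N,
                       std::vector<double> &g, std::vector<double> &t_end,
                       std::vector<int> &merge_to, NumericMatrix &mig) {
  NumericVector N_ = demog["N"], g_ = demog["g"], te_ = demog["t_end"];
  IntegerVector mt_ = demog["merge_to"];
  mig = as<NumericMatrix>(demog["mig"]);
  N = as<std::vector<double> >(N_);
  g = as<std::vector<double> >(g_);
  t_end = as<std::vector<double> >(te_);
  merge_to.resize(mt_.size());
  for (int i = 0; i < mt_.size(); ++i) merge_to[i] = mt_[i]; // already 0-based
}

// Tajima's D from S, mean pairwise diversity (total, not per site) and n
double tajima_d(double S, double k_hat, int n) {
  if (S < 1 || n < 3) return NA_REAL;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double denom = std::sqrt(e1 * S + e2 * S * (S - 1.0));
  if (denom <= 0.0) return NA_REAL;
  return (k_hat - S / a1) / denom;
}

double sd_vec(const std::vector<double> &x) {
  size_t n = x.size();
  if (n < 2) return 0.0;
  double m = 0.0;
  for (size_t i = 0; i < n; ++i) m += x[i];
  m /= n;
  double s = 0.0;
  for (size_t i = 0; i < n; ++i) s += (x[i] - m) * (x[i] - m);
  return std::sqrt(s / (n - 1));
}

// Pairwise-difference AMOVA Fst for two haploid groups from per-site derived
// counts (complete data).  Equivalent to the distance-matrix computation.
double fst_counts(const std::vector<int> &dx, const std::vector<int> &dy,
                  int nx, int ny) {
  double ssd_wp = 0.0, ssd_t = 0.0;
  int n = nx + ny;
  for (size_t s = 0; s < dx.size(); ++s) {
    double a = dx[s], b = dy[s], d = a + b;
    ssd_wp += a * (nx - a) / nx + b * (ny - b) / ny;
    ssd_t += d * (n - d) / n;
  }
  double ssd_ap = ssd_t - ssd_wp;
  double sw = ssd_wp / (n - 2.0);
  double nc = n - ((double)nx * nx + (double)ny * ny) / n;
  double sa = (ssd_ap / 1.0 - sw) / nc;
  double tot = sa + sw;
  if (tot == 0.0) return 0.0;
  return sa / tot;
}

} // namespace

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// Simulate genealogies only; returns per-locus parent/time vectors.
// [[Rcpp::export]]
List cpp_sim_trees(List demog, IntegerVector sample_deme, int n_loci) {
  std::vector<double> N, g, t_end;
  std::vector<int> merge_to;
  NumericMatrix mig;
  unpack_demography(demog, N, g, t_end, merge_to, mig);
  std::vector<int> sd(sample_deme.begin(), sample_deme.end());

  RNGScope scope;
  List out(n_loci);
  Tree tree;
  for (int l = 0; l < n_loci; ++l) {
    simulate_tree(N, g, t_end, merge_to, mig, sd, tree, nullptr, 0, nullptr);
    out[l] = List::create(_["parent"] = IntegerVector(tree.parent.begin(),
                                                      tree.parent.end()),
                          _["time"] = NumericVector(tree.time.begin(),
                                                    tree.time.end()),
                          _["n_leaves"] = tree.n_leaves);
  }
  return out;
}

// Simulate genealogies + infinite-sites mutations and return, per locus, the
// segregating sites as derived-allele membership over leaves plus positions.
// [[Rcpp::export]]
List cpp_sim_haplotypes(List demog, IntegerVector sample_deme,
                        IntegerVector locus_len, double mu) {
  std::vector<double> N, g, t_end;
  std::vector<int> merge_to;
  NumericMatrix mig;
  unpack_demography(demog, N, g, t_end, merge_to, mig);
  std::vector<int> sd(sample_deme.begin(), sample_deme.end());
  int n = (int)sd.size();

  RNGScope scope;
  int n_loci = locus_len.size();
  List out(n_loci);
  Tree tree;
  int n_capped = 0;
  for (int l = 0; l < n_loci; ++l) {
    int L = locus_len[l];
    simulate_tree(N, g, t_end, merge_to, mig, sd, tree, nullptr, 0, nullptr);
    int n_nodes = 2 * n - 1;
    std::vector<double> cum(n_nodes, 0.0);
    double tot = 0.0;
    for (int i = 0; i < n_nodes - 1; ++i) { // root (last node) excluded
      tot += tree.time[tree.parent[i]] - tree.time[i];
      cum[i] = tot;
    }
    cum[n_nodes - 1] = tot;
    int m = (int)R::rpois(mu * L * tot);
    if (m > L) { m = L; ++n_capped; } // finite-sites cap, negligible at low theta
    // distinct positions via partial Fisher-Yates
    std::vector<int> pos_pool(L);
    for (int i = 0; i < L; ++i) pos_pool[i] = i;
    IntegerVector positions(m);
    for (int k = 0; k < m; ++k) {
      int idx = k + (int)std::floor(unif_rand() * (L - k));
      if (idx >= L) idx = L - 1;
      std::swap(pos_pool[k], pos_pool[idx]);
      positions[k] = pos_pool[k];
    }
    LogicalMatrix derived(n, m);
    for (int k = 0; k < m; ++k) {
      double u = unif_rand() * tot;
      int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (b >= n_nodes - 1) b = n_nodes - 2;
      // collect leaves under branch b
      std::vector<int> stack;
      stack.push_back(b);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        if (v < n) derived(v, k) = true;
        else { stack.push_back(tree.left[v]); stack.push_back(tree.right[v]); }
      }
    }
    out[l] = List::create(_["positions"] = positions, _["derived"] = derived);
  }
  out.attr("n_capped") = n_capped;
  return out;
}

// Simulate a full multi-locus dataset and return the concatenated per-site
// derived counts per region (rows = segregating sites).
// [[Rcpp::export]]
List cpp_sim_counts(List demog, IntegerVector sample_deme,
                    IntegerVector sample_region, int n_regions,
                    IntegerVector locus_len, double mu) {
  std::vector<double> N, g, t_end;
  std::vector<int> merge_to;
  NumericMatrix mig;
  unpack_demography(demog, N, g, t_end, merge_to, mig);
  std::vector<int> sd(sample_deme.begin(), sample_deme.end());
  std::vector<int> sr(sample_region.begin(), sample_region.end());
  int n = (int)sd.size();

  RNGScope scope;
  std::vector<std::vector<int> > counts; // per site, per region derived count
  Tree tree;
  std::vector<std::vector<int> > region_count;
  int n_loci = locus_len.size();
  for (int l = 0; l < n_loci; ++l) {
    int L = locus_len[l];
    simulate_tree(N, g, t_end, merge_to, mig, sd, tree, &sr, n_regions,
                  &region_count);
    int n_nodes = 2 * n - 1;
    std::vector<double> cum(n_nodes, 0.0);
    double tot = 0.0;
    for (int i = 0; i < n_nodes - 1; ++i) {
      tot += tree.time[tree.parent[i]] - tree.time[i];
      cum[i] = tot;
    }
    cum[n_nodes - 1] = tot;
    int m = (int)R::rpois(mu * L * tot);
    if (m > L) m = L;
    for (int k = 0; k < m; ++k) {
      double u = unif_rand() * tot;
      int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (b >= n_nodes - 1) b = n_nodes - 2;
      counts.push_back(region_count[b]);
    }
  }
  int S = (int)counts.size();
  IntegerMatrix M(S, n_regions);
  for (int s = 0; s < S; ++s)
    for (int r = 0; r < n_regions; ++r) M(s, r) = counts[s][r];
  return List::create(_["counts"] = M);
}

// The full named summary-statistic vector (values only; names added in R)
// from per-site regional derived counts of complete haploid data.
// Layout (regions indexed 0..4 = JP,HI,WUS,EUS,SP):
//  [0:29]   per region: S, pi, prS, K_sd, H_sd, TajD   (6 x 5)
//  [30:34]  pooled sample: S, pi, K_sd, H_sd, TajD
//  [35:38]  log(S_i/S_JP), i = HI,WUS,EUS,SP (0 when undefined)
//  [39:42]  prS_i/S_i, i = HI,WUS,EUS,SP (0 when S_i = 0)
//  [43:46]  mean_S, sd_S, mean_pi, sd_pi over regions
//  [47:56]  pairwise between-region pi, pairs in row-major upper-tri order
//  [57:66]  pairwise region Fst, same order
// [[Rcpp::export]]
NumericVector cpp_statvec_counts(IntegerMatrix counts, IntegerVector n_region,
                                 double total_sites) {
  int R_ = n_region.size();
  int S = counts.nrow();
  NumericVector out(67);
  std::vector<std::vector<int> > d(R_, std::vector<int>(S));
  for (int r = 0; r < R_; ++r)
    for (int s = 0; s < S; ++s) d[r][s] = counts(s, r);

  int n_tot = 0;
  for (int r = 0; r < R_; ++r) n_tot += n_region[r];

  std::vector<double> S_r(R_), pi_r(R_);
  // per-region stats
  for (int r = 0; r < R_; ++r) {
    int n = n_region[r];
    double Sr = 0.0, khat = 0.0, prS = 0.0;
    double sumK = 0.0, sumK2 = 0.0, sumH = 0.0, sumH2 = 0.0;
    for (int s = 0; s < S; ++s) {
      int dd = d[r][s];
      bool seg = dd > 0 && dd < n;
      double K = seg ? 2.0 : 1.0;
      double H = n >= 2 ? 2.0 * dd * (n - dd) / ((double)n * (n - 1)) : 0.0;
      sumK += K; sumK2 += K * K; sumH += H; sumH2 += H * H;
      khat += H;
      if (seg) {
        Sr += 1.0;
        int d_oth = 0, anc_oth = 0;
        for (int r2 = 0; r2 < R_; ++r2) {
          if (r2 == r) continue;
          d_oth += d[r2][s];
          anc_oth += n_region[r2] - d[r2][s];
        }
        if (d_oth == 0 || anc_oth == 0) prS += 1.0;
      }
    }
    // monomorphic sites (not in `counts`) contribute K = 1, H = 0
    double n_mono = total_sites - S;
    double nsite = total_sites;
    double meanK = (sumK + n_mono) / nsite;
    double varK = (sumK2 + n_mono - nsite * meanK * meanK) /
                  std::max(1.0, nsite - 1.0);
    double meanH = sumH / nsite;
    double varH = (sumH2 - nsite * meanH * meanH) / std::max(1.0, nsite - 1.0);
    double D = tajima_d(Sr, khat, n);
    out[6 * r + 0] = Sr;
    out[6 * r + 1] = khat / nsite;
    out[6 * r + 2] = prS;
    out[6 * r + 3] = std::sqrt(std::max(0.0, varK));
    out[6 * r + 4] = std::sqrt(std::max(0.0, varH));
    out[6 * r + 5] = ISNAN(D) ? 0.0 : D;
    S_r[r] = Sr;
    pi_r[r] = khat / nsite;
  }

  // pooled sample
  {
    double Sp = 0.0, khat = 0.0, sumK = 0.0, sumK2 = 0.0, sumH = 0.0,
           sumH2 = 0.0;
    for (int s = 0; s < S; ++s) {
      int dd = 0;
      for (int r = 0; r < R_; ++r) dd += d[r][s];
      bool seg = dd > 0 && dd < n_tot;
      double K = seg ? 2.0 : 1.0;
      double H = 2.0 * dd * (n_tot - dd) / ((double)n_tot * (n_tot - 1));
      sumK += K; sumK2 += K * K; sumH += H; sumH2 += H * H;
      khat += H;
      if (seg) Sp += 1.0;
    }
    double n_mono = total_sites - S, nsite = total_sites;
    double meanK = (sumK + n_mono) / nsite;
    double varK = (sumK2 + n_mono - nsite * meanK * meanK) /
                  std::max(1.0, nsite - 1.0);
    double meanH = sumH / nsite;
    double varH = (sumH2 - nsite * meanH * meanH) / std::max(1.0, nsite - 1.0);
    double D = tajima_d(Sp, khat, n_tot);
    out[30] = Sp;
    out[31] = khat / nsite;
    out[32] = std::sqrt(std::max(0.0, varK));
    out[33] = std::sqrt(std::max(0.0, varH));
    out[34] = ISNAN(D) ? 0.0 : D;
  }

  // log ratios and prS/S for colonized regions (indices 1..4)
  for (int i = 1; i < R_; ++i) {
    double Si = S_r[i], Sjp = S_r[0];
    out[35 + (i - 1)] = (Si > 0 && Sjp > 0) ? std::log(Si / Sjp) : 0.0;
    out[39 + (i - 1)] = Si > 0 ? out[6 * i + 2] / Si : 0.0;
  }

  // mean/sd over regions
  {
    double mS = 0.0, mpi = 0.0;
    for (int r = 0; r < R_; ++r) { mS += S_r[r]; mpi += pi_r[r]; }
    mS /= R_; mpi /= R_;
    out[43] = mS;
    out[44] = sd_vec(S_r);
    out[45] = mpi;
    out[46] = sd_vec(pi_r);
  }

  // pairwise pi and Fst
  int idx = 0;
  for (int a = 0; a < R_; ++a) {
    for (int b = a + 1; b < R_; ++b) {
      int na = n_region[a], nb = n_region[b];
      double pib = 0.0;
      for (int s = 0; s < S; ++s) {
        double da = d[a][s], db = d[b][s];
        pib += (da * (nb - db) + (na - da) * db) / ((double)na * nb);
      }
      out[47 + idx] = pib / total_sites;
      out[57 + idx] = fst_counts(d[a], d[b], na, nb);
      ++idx;
    }
  }
  return out;
}

// Convenience: simulate and summarize in one call (used for reference tables).
// [[Rcpp::export]]
NumericVector cpp_sim_statvec(List demog, IntegerVector sample_deme,
                              IntegerVector sample_region, int n_regions,
                              IntegerVector locus_len, double mu) {
  List cc = cpp_sim_counts(demog, sample_deme, sample_region, n_regions,
                           locus_len, mu);
  IntegerMatrix M = cc["counts"];
  IntegerVector n_region(n_regions);
  for (int i = 0; i < sample_region.size(); ++i) n_region[sample_region[i]]++;
  double total_sites = 0.0;
  for (int l = 0; l < locus_len.size(); ++l) total_sites += locus_len[l];
  return cpp_statvec_counts(M, n_region, total_sites);
}
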
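// Individual-based forward simulation of TE invasions under the piRNA
// cluster trap model. Diploid Wright-Fisher population, discrete
// non-overlapping generations, fecundity selection, per-chromosome
// recombination (Poisson crossovers, no interference) and biased
// transposition. All randomness flows through R's RNG so that set.seed()
// at the R level gives byte-identical reruns.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Ins {
  int pos;
  int bias;
};

static inline bool ins_before(const Ins& a, const Ins& b) { return a.pos < b.pos; }

// uniform integer in [lo, hi)
static inline int runif_int(int lo, int hi) {
  int v = lo + (int)(unif_rand() * (double)(hi - lo));
  if (v >= hi) v = hi - 1;
  return v;
}

struct GenomeCpp {
  std::vector<int> cb;              // chromosome boundaries, size nchrom+1, cb[0] = 0
  std::vector<int> cs, ce;          // cluster intervals [cs, ce), sorted, disjoint
  std::vector<double> lambda;       // expected crossovers per chromosome per meiosis
  std::vector<long long> ccum;      // cumulative cluster bp
  std::vector<int> gs, ge;          // non-cluster (gap) intervals
  std::vector<long long> gcum;      // cumulative gap bp
  long long g;                      // genome size
  long long cbp;                    // total cluster bp
  double f;                         // cluster fraction
  double pc[201];                   // bias -> cluster insertion probability

  bool is_cluster(int pos) const {
    // last cluster with start <= pos
    int lo = 0, hi = (int)cs.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cs[mid] <= pos) lo = mid + 1; else hi = mid;
    }
    if (lo == 0) return false;
    return pos < ce[lo - 1];
  }

  int sample_cluster_pos() const {
    long long r = (long long)(unif_rand() * (double)cbp);
    if (r >= cbp) r = cbp - 1;
    // interval k with ccum[k] <= r < ccum[k+1]
    int k = (int)(std::upper_bound(ccum.begin(), ccum.end(), r) - ccum.begin()) - 1;
    return cs[k] + (int)(r - ccum[k]);
  }

  int sample_gap_pos() const {
    long long tot = g - cbp;
    long long r = (long long)(unif_rand() * (double)tot);
    if (r >= tot) r = tot - 1;
    int k = (int)(std::upper_bound(gcum.begin(), gcum.end(), r) - gcum.begin()) - 1;
    return gs[k] + (int)(r - gcum[k]);
  }

  // sample a site for a new insertion with the given bias
  int sample_site(int bias) const {
    double p = pc[bias + 100];
    if (p > 0.0 && unif_rand() < p) return sample_cluster_pos();
    if (g - cbp == 0) return sample_cluster_pos();  // degenerate f -> 1 never allowed upstream
    if (p >= 1.0) return sample_cluster_pos();
    return sample_gap_pos();
  }
};

static GenomeCpp build_genome(const IntegerVector& chrom_bounds,
                              const IntegerVector& cluster_start,
                              const IntegerVector& cluster_end,
                              const NumericVector& xover_lambda) {
  GenomeCpp G;
  G.cb.assign(chrom_bounds.begin(), chrom_bounds.end());
  G.cs.assign(cluster_start.begin(), cluster_start.end());
  G.ce.assign(cluster_end.begin(), cluster_end.end());
  G.lambda.assign(xover_lambda.begin(), xover_lambda.end());
  G.g = G.cb.back();
  G.cbp = 0;
  G.ccum.resize(G.cs.size() + 1);
  G.ccum[0] = 0;
  for (size_t k = 0; k < G.cs.size(); ++k) {
    G.cbp += G.ce[k] - G.cs[k];
    G.ccum[k + 1] = G.cbp;
  }
  // complement intervals
  G.gcum.clear(); G.gs.clear(); G.ge.clear();
  long long acc = 0;
  int cur = 0;
  for (size_t k = 0; k <= G.cs.size(); ++k) {
    int stop = (k < G.cs.size()) ? G.cs[k] : (int)G.g;
    if (stop > cur) {
      G.gs.push_back(cur);
      G.ge.push_back(stop);
      G.gcum.push_back(acc);
      acc += stop - cur;
    }
    if (k < G.cs.size()) cur = G.ce[k];
  }
  G.gcum.push_back(acc);
  G.f = (double)G.cbp / (double)G.g;
  for (int b = -100; b <= 100; ++b) {
    double a = (b / 100.0 + 1.0) / 2.0;
    double s = a * G.f + (1.0 - a) * (1.0 - G.f);
    G.pc[b + 100] = (G.cbp == 0) ? 0.0 : (s > 0.0 ? a * G.f / s : 1.0);
  }
  return G;
}

// One gamete: random assortment + recombination per chromosome, then
// transposition (suppressed entirely when the parent carries a cluster
// insertion). New insertions landing on an occupied gamete site are
// discarded.
static void make_gamete(const std::vector<Ins>& A, const std::vector<Ins>& B,
                        int n_par, bool regulated, const GenomeCpp& G, double u,
                        std::vector<Ins>& out) {
  out.clear();
  size_t iA = 0, iB = 0;
  int nchrom = (int)G.cb.size() - 1;
  std::vector<int> bp;
  for (int c = 0; c < nchrom; ++c) {
    int start = G.cb[c], end = G.cb[c + 1];
    bool useA = unif_rand() < 0.5;
    int k = (G.lambda[c] > 0.0) ? (int)R::rpois(G.lambda[c]) : 0;
    bp.resize(k);
    for (int j = 0; j < k; ++j) bp[j] = runif_int(start, end);
    std::sort(bp.begin(), bp.end());
    int segStart = start;
    for (int j = 0; j <= k; ++j) {
      int segEnd = (j < k) ? bp[j] : end;
      while (iA < A.size() && A[iA].pos < segStart) ++iA;
      while (iB < B.size() && B[iB].pos < segStart) ++iB;
      if (useA) {
        while (iA < A.size() && A[iA].pos < segEnd) out.push_back(A[iA++]);
      } else {
        while (iB < B.size() && B[iB].pos < segEnd) out.push_back(B[iB++]);
      }
      useA = !useA;
      segStart = segEnd;
    }
  }
  if (!regulated && u > 0.0 && n_par > 0) {
    int k = (int)R::rpois(u * (double)n_par / 2.0);
    int nA = (int)A.size();
    for (int e = 0; e < k; ++e) {
      int idx = runif_int(0, n_par);
      const Ins& donor = (idx < nA) ? A[idx] : B[idx - nA];
      Ins ni;
      ni.pos = G.sample_site(donor.bias);
      ni.bias = donor.bias;
      std::vector<Ins>::iterator it =
        std::lower_bound(out.begin(), out.end(), ni, ins_before);
      if (it == out.end() || it->pos != ni.pos) out.insert(it, ni);
    }
  }
}

static inline int draw_weighted(const std::vector<double>& cumw, double tot) {
  double r = unif_rand() * tot;
  int idx = (int)(std::upper_bound(cumw.begin(), cumw.end(), r) - cumw.begin());
  if (idx >= (int)cumw.size()) idx = (int)cumw.size() - 1;
  return idx;
}

// status codes: 0 ongoing, 1 inactive (cluster insertion fixed), 2 fail-0, 3 fail-w
// stop_mode: 0 run to max_gen; 1 stop once every individual is regulated;
//            2 stop at first fixation of a cluster insertion
// [[Rcpp::export]]
List run_invasion_cpp(IntegerVector chrom_bounds,
                      IntegerVector cluster_start, IntegerVector cluster_end,
                      NumericVector xover_lambda,
                      int N, double u, double x, bool cluster_neutral, double beta,
                      int max_gen, int stop_mode,
                      IntegerVector hap0, IntegerVector pos0, IntegerVector bias0,
                      IntegerVector track_bias) {
  GenomeCpp G = build_genome(chrom_bounds, cluster_start, cluster_end, xover_lambda);
  int H = 2 * N;
  std::vector< std::vector<Ins> > haps(H), next(H);
  for (int r = 0; r < hap0.size(); ++r) {
    Ins ins; ins.pos = pos0[r]; ins.bias = bias0[r];
    haps[hap0[r]].push_back(ins);
  }
  for (int h = 0; h < H; ++h) std::sort(haps[h].begin(), haps[h].end(), ins_before);

  int ntrack = track_bias.size();
  int ncol = 8 + ntrack;
  std::vector<double> rows;
  rows.reserve((size_t)ncol * 256);

  std::vector<int> n(N), cl(N);
  std::vector<double> w(N), cumw(N);
  std::vector<double> trk(ntrack);

  int status = 0;
  int first_cluster_gen = -1, all_reg_gen = -1, fix_gen = -1;
  int gen = 0;

  for (gen = 0; ; ++gen) {
    long long tot_n = 0, tot_cl = 0;
    double sum_w = 0.0, min_w = R_PosInf, totw = 0.0;
    int n_reg = 0;
    std::fill(trk.begin(), trk.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      const std::vector<Ins>& a = haps[2 * i];
      const std::vector<Ins>& b = haps[2 * i + 1];
      int ni = (int)(a.size() + b.size());
      int ci = 0;
      for (size_t j = 0; j < a.size(); ++j) if (G.is_cluster(a[j].pos)) ++ci;
      for (size_t j = 0; j < b.size(); ++j) if (G.is_cluster(b[j].pos)) ++ci;
      if (ntrack > 0) {
        for (size_t j = 0; j < a.size(); ++j)
          for (int t = 0; t < ntrack; ++t) if (a[j].bias == track_bias[t]) trk[t] += 1.0;
        for (size_t j = 0; j < b.size(); ++j)
          for (int t = 0; t < ntrack; ++t) if (b[j].bias == track_bias[t]) trk[t] += 1.0;
      }
      int neff = cluster_neutral ? (ni - ci) : ni;
      double wi = 1.0 - x * (double)neff + beta * (double)ci;
      if (wi < 0.0) wi = 0.0;
      n[i] = ni; cl[i] = ci; w[i] = wi;
      tot_n += ni; tot_cl += ci;
      sum_w += wi;
      if (wi < min_w) min_w = wi;
      if (ci > 0) ++n_reg;
      totw += wi;
      cumw[i] = totw;
    }
    double frac_reg = (double)n_reg / (double)N;
    if (first_cluster_gen < 0 && tot_cl > 0) first_cluster_gen = gen;
    if (all_reg_gen < 0 && n_reg == N) all_reg_gen = gen;

    // fixation of a cluster insertion: some exact position present on >= 1
    // haplotype of every individual; only possible when all are regulated
    int fixed = 0;
    if (n_reg == N && fix_gen < 0) {
      std::vector<Ins> cand;
      for (size_t j = 0; j < haps[0].size(); ++j)
        if (G.is_cluster(haps[0][j].pos)) cand.push_back(haps[0][j]);
      for (size_t j = 0; j < haps[1].size(); ++j)
        if (G.is_cluster(haps[1][j].pos)) cand.push_back(haps[1][j]);
      for (size_t j = 0; j < cand.size() && !fixed; ++j) {
        bool everywhere = true;
        for (int i = 1; i < N && everywhere; ++i) {
          bool has = false;
          for (int h = 0; h < 2 && !has; ++h) {
            const std::vector<Ins>& v = haps[2 * i + h];
            std::vector<Ins>::const_iterator it =
              std::lower_bound(v.begin(), v.end(), cand[j], ins_before);
            has = (it != v.end() && it->pos == cand[j].pos);
          }
          everywhere = has;
        }
        if (everywhere) fixed = 1;
      }
      if (fixed) fix_gen = gen;
    } else if (fix_gen >= 0) {
      fixed = 1;
    }

    rows.push_back((double)gen);
    rows.push_back((double)tot_n / (double)N);
    rows.push_back((double)tot_cl / (double)N);
    rows.push_back((double)tot_cl);
    rows.push_back(sum_w / (double)N);
    rows.push_back(min_w);
    rows.push_back(frac_reg);
    rows.push_back((double)fixed);
    for (int t = 0; t < ntrack; ++t) rows.push_back(trk[t] / (double)N);

    if (tot_n == 0) { status = 2; break; }
    if (totw <= 0.0) { status = 3; break; }
    if (fix_gen >= 0 && stop_mode == 2) { status = 1; break; }
    if (all_reg_gen >= 0 && stop_mode == 1) { status = 0; break; }
    if (gen >= max_gen) { status = (fix_gen >= 0) ? 1 : 0; break; }

    // breed the next generation
    for (int i = 0; i < N; ++i) {
      int p1 = draw_weighted(cumw, totw);
      int p2 = draw_weighted(cumw, totw);
      make_gamete(haps[2 * p1], haps[2 * p1 + 1], n[p1], cl[p1] > 0, G, u, next[2 * i]);
      make_gamete(haps[2 * p2], haps[2 * p2 + 1], n[p2], cl[p2] > 0, G, u, next[2 * i + 1]);
    }
    haps.swap(next);
    if (gen % 64 == 0) Rcpp::checkUserInterrupt();
  }

  int nrow = (int)(rows.size() / ncol);
  NumericMatrix traj(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c)
      traj(r, c) = rows[(size_t)r * ncol + c];

  return List::create(
    _["trajectory"] = traj,
    _["status"] = status,
    _["first_cluster_gen"] = first_cluster_gen,
    _["all_regulated_gen"] = all_reg_gen,
    _["fixation_gen"] = fix_gen,
    _["last_gen"] = gen);
}

// [[Rcpp::export]]
LogicalVector is_cluster_cpp(IntegerVector pos,
                             IntegerVector chrom_bounds,
                             IntegerVector cluster_start, IntegerVector cluster_end) {
  GenomeCpp G = build_genome(chrom_bounds, cluster_start, cluster_end,
                             NumericVector(chrom_bounds.size() - 1));
  LogicalVector out(pos.size());
  for (int i = 0; i < pos.size(); ++i) out[i] = G.is_cluster(pos[i]);
  return out;
}

// n independent insertion sites for a TE of the given bias
// [[Rcpp::export]]
IntegerVector sample_sites_cpp(int n, int bias,
                               IntegerVector chrom_bounds,
                               IntegerVector cluster_start, IntegerVector cluster_end) {
  GenomeCpp G = build_genome(chrom_bounds, cluster_start, cluster_end,
                             NumericVector(chrom_bounds.size() - 1));
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = G.sample_site(bias);
  return out;
}

// single meiosis + transposition from one diploid parent; exposed for testing
// [[Rcpp::export]]
List make_gamete_cpp(IntegerVector posA, IntegerVector biasA,
                     IntegerVector posB, IntegerVector biasB,
                     IntegerVector chrom_bounds,
                     IntegerVector cluster_start, IntegerVector cluster_end,
                     NumericVector xover_lambda, double u) {
  GenomeCpp G = build_genome(chrom_bounds, cluster_start, cluster_end, xover_lambda);
  std::vector<Ins> A(posA.size()), B(posB.size()), out;
  for (int i = 0; i < posA.size(); ++i) { A[i].pos = posA[i]; A[i].bias = biasA[i]; }
  for (int i = 0; i < posB.size(); ++i) { B[i].pos = posB[i]; B[i].bias = biasB[i]; }
  std::sort(A.begin(), A.end(), ins_before);
  std::sort(B.begin(), B.end(), ins_before);
  bool regulated = false;
  for (size_t i = 0; i < A.size() && !regulated; ++i) regulated = G.is_cluster(A[i].pos);
  for (size_t i = 0; i < B.size() && !regulated; ++i) regulated = G.is_cluster(B[i].pos);
  make_gamete(A, B, (int)(A.size() + B.size()), regulated, G, u, out);
  IntegerVector p(out.size()), b(out.size());
  for (size_t i = 0; i < out.size(); ++i) { p[i] = out[i].pos; b[i] = out[i].bias; }
  return List::create(_["position"] = p, _["bias"] = b);
}

// fitness-proportional parent draws (the engine's sampling routine); 1-based
// [[Rcpp::export]]
IntegerVector sample_parents_cpp(NumericVector w, int ndraws) {
  int n = w.size();
  std::vector<double> cumw(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double wi = w[i] < 0.0 ? 0.0 : w[i];
    tot += wi;
    cumw[i] = tot;
  }
  if (tot <= 0.0) stop("no individual has positive fitness (fail-w)");
  IntegerVector out(ndraws);
  for (int d = 0; d < ndraws; ++d) out[d] = draw_weighted(cumw, tot) + 1;
  return out;
}
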
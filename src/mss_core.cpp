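// Core Monte-Carlo engine: random gene-set scoring by 2-means patient
// clustering + two-sided Fisher exact test, with full-search and
// early-stopping drivers.  All randomness is counter-based (per-iteration
// streams derived from a master seed and the iteration index), so results
// are identical regardless of execution order or worker count.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// counter-based RNG (splitmix64)

static inline uint64_t splitmix64(uint64_t& s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t u64() { return splitmix64(s); }
  // 53-bit uniform in [0, 1)
  double unif() { return (u64() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(u64() % (uint64_t)n); }
};

// independent stream for (master, a, b); used per iteration index
static inline uint64_t stream_seed(uint64_t master, uint64_t a, uint64_t b) {
  uint64_t s = master;
  splitmix64(s);
  s ^= (a + 0x632BE59BD9B4E019ULL) * 0x9E3779B97F4A7C15ULL;
  splitmix64(s);
  s ^= (b + 0xD1B54A32D192ED03ULL) * 0xBF58476D1CE4E5B9ULL;
  uint64_t out = splitmix64(s);
  return out;
}

// ---------------------------------------------------------------------------
// two-sided Fisher exact test for a 2x2 table, conditional on margins;
// two-sided p = sum of hypergeometric point masses <= observed (1 + 1e-7)

static inline double lchoose_(double n, double k) {
  return ::lgamma(n + 1.0) - ::lgamma(k + 1.0) - ::lgamma(n - k + 1.0);
}

static double fisher_two_sided(int a, int b, int c, int d) {
  const int m = a + b, n2 = c + d, k = a + c;
  const int lo = std::max(0, k - n2), hi = std::min(k, m);
  if (lo >= hi) return 1.0;  // degenerate support
  const double lnorm = lchoose_(m + n2, k);
  const double lobs = lchoose_(m, a) + lchoose_(n2, k - a) - lnorm;
  const double cutoff = lobs + std::log1p(1e-7);
  double p = 0.0;
  for (int x = lo; x <= hi; ++x) {
    const double lx = lchoose_(m, x) + lchoose_(n2, k - x) - lnorm;
    if (lx <= cutoff) p += std::exp(lx);
  }
  return p > 1.0 ? 1.0 : p;
}

// [[Rcpp::export]]
NumericVector cpp_fisher_p(IntegerVector a, IntegerVector b, IntegerVector c,
                           IntegerVector d) {
  const R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = fisher_two_sided(a[i], b[i], c[i], d[i]);
  return out;
}

// ---------------------------------------------------------------------------
// k-means, k = 2, Euclidean, kmeans++ init; points are columns of X (d x n)

struct KmScratch {
  std::vector<double> c1, c2, w, dist2;
  std::vector<int> assign, best;
};

// one restart; returns total within-cluster SS, assignment in scr.assign
static double kmeans2_once(const double* X, int d, int n, Rng& rng, int maxit,
                           KmScratch& scr) {
  scr.c1.assign(d, 0.0);
  scr.c2.assign(d, 0.0);
  scr.w.assign(d, 0.0);
  scr.dist2.assign(n, 0.0);
  scr.assign.assign(n, 0);
  // kmeans++ for k = 2: first centre uniform, second w.p. proportional to
  // squared distance from the first
  const int i1 = rng.below(n);
  double tot = 0.0;
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    const double* xj = X + (size_t)j * d;
    const double* x1 = X + (size_t)i1 * d;
    for (int g = 0; g < d; ++g) {
      const double diff = xj[g] - x1[g];
      s += diff * diff;
    }
    scr.dist2[j] = s;
    tot += s;
  }
  if (tot <= 0.0) return 0.0;  // all points identical: single cluster
  double u = rng.unif() * tot;
  int i2 = n - 1;
  for (int j = 0; j < n; ++j) {
    u -= scr.dist2[j];
    if (u <= 0.0) { i2 = j; break; }
  }
  if (i2 == i1) i2 = (i1 + 1) % n;
  std::copy(X + (size_t)i1 * d, X + (size_t)(i1 + 1) * d, scr.c1.begin());
  std::copy(X + (size_t)i2 * d, X + (size_t)(i2 + 1) * d, scr.c2.begin());

  for (int iter = 0; iter < maxit; ++iter) {
    // assignment step via the separating direction w = c1 - c2:
    // |x - c1|^2 < |x - c2|^2  <=>  x.w > (|c1|^2 - |c2|^2) / 2
    double b = 0.0;
    for (int g = 0; g < d; ++g) {
      scr.w[g] = scr.c1[g] - scr.c2[g];
      b += (scr.c1[g] + scr.c2[g]) * scr.w[g];
    }
    b *= 0.5;
    int changed = 0, n1 = 0;
    for (int j = 0; j < n; ++j) {
      const double* xj = X + (size_t)j * d;
      double dot = 0.0;
      for (int g = 0; g < d; ++g) dot += xj[g] * scr.w[g];
      const int as = (dot >= b) ? 0 : 1;
      if (as != scr.assign[j]) ++changed;
      scr.assign[j] = as;
      n1 += (as == 0);
    }
    if (changed == 0 && iter > 0) break;
    if (n1 == 0 || n1 == n) break;  // empty cluster: degenerate, stop
    // update step
    std::fill(scr.c1.begin(), scr.c1.end(), 0.0);
    std::fill(scr.c2.begin(), scr.c2.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double* xj = X + (size_t)j * d;
      double* ck = (scr.assign[j] == 0) ? scr.c1.data() : scr.c2.data();
      for (int g = 0; g < d; ++g) ck[g] += xj[g];
    }
    for (int g = 0; g < d; ++g) {
      scr.c1[g] /= n1;
      scr.c2[g] /= (n - n1);
    }
  }
  // within-cluster SS of the final assignment (centroids of that assignment)
  int n1 = 0;
  std::fill(scr.c1.begin(), scr.c1.end(), 0.0);
  std::fill(scr.c2.begin(), scr.c2.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const double* xj = X + (size_t)j * d;
    double* ck = (scr.assign[j] == 0) ? scr.c1.data() : scr.c2.data();
    for (int g = 0; g < d; ++g) ck[g] += xj[g];
    n1 += (scr.assign[j] == 0);
  }
  if (n1 > 0)
    for (int g = 0; g < d; ++g) scr.c1[g] /= n1;
  if (n - n1 > 0)
    for (int g = 0; g < d; ++g) scr.c2[g] /= (n - n1);
  double wss = 0.0;
  for (int j = 0; j < n; ++j) {
    const double* xj = X + (size_t)j * d;
    const double* ck = (scr.assign[j] == 0) ? scr.c1.data() : scr.c2.data();
    for (int g = 0; g < d; ++g) {
      const double diff = xj[g] - ck[g];
      wss += diff * diff;
    }
  }
  return wss;
}

// fuzzy c-means, c = 2, fuzzifier m = 2, hard assignment by max membership
static double fcm2_once(const double* X, int d, int n, Rng& rng, int maxit,
                        KmScratch& scr) {
  scr.c1.assign(d, 0.0);
  scr.c2.assign(d, 0.0);
  scr.assign.assign(n, 0);
  std::vector<double> u1(n, 0.5), u1_old(n);
  const int i1 = rng.below(n);
  int i2 = rng.below(n);
  if (i2 == i1) i2 = (i1 + 1) % n;
  std::copy(X + (size_t)i1 * d, X + (size_t)(i1 + 1) * d, scr.c1.begin());
  std::copy(X + (size_t)i2 * d, X + (size_t)(i2 + 1) * d, scr.c2.begin());
  double obj = 0.0;
  const double eps = 1e-12;
  for (int iter = 0; iter < maxit; ++iter) {
    u1_old = u1;
    obj = 0.0;
    for (int j = 0; j < n; ++j) {
      const double* xj = X + (size_t)j * d;
      double d1 = eps, d2 = eps;
      for (int g = 0; g < d; ++g) {
        const double a = xj[g] - scr.c1[g], b = xj[g] - scr.c2[g];
        d1 += a * a;
        d2 += b * b;
      }
      // m = 2: u1 = (1/d1) / (1/d1 + 1/d2) = d2 / (d1 + d2)
      u1[j] = d2 / (d1 + d2);
      obj += u1[j] * u1[j] * d1 + (1.0 - u1[j]) * (1.0 - u1[j]) * d2;
    }
    // centroid update, weights u^2
    double s1 = 0.0, s2 = 0.0;
    std::fill(scr.c1.begin(), scr.c1.end(), 0.0);
    std::fill(scr.c2.begin(), scr.c2.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double* xj = X + (size_t)j * d;
      const double w1 = u1[j] * u1[j], w2 = (1.0 - u1[j]) * (1.0 - u1[j]);
      s1 += w1;
      s2 += w2;
      for (int g = 0; g < d; ++g) {
        scr.c1[g] += w1 * xj[g];
        scr.c2[g] += w2 * xj[g];
      }
    }
    if (s1 > 0)
      for (int g = 0; g < d; ++g) scr.c1[g] /= s1;
    if (s2 > 0)
      for (int g = 0; g < d; ++g) scr.c2[g] /= s2;
    double delta = 0.0;
    for (int j = 0; j < n; ++j)
      delta = std::max(delta, std::fabs(u1[j] - u1_old[j]));
    if (iter > 0 && delta < 1e-4) break;
  }
  for (int j = 0; j < n; ++j) scr.assign[j] = (u1[j] > 0.5) ? 0 : 1;
  return obj;
}

static void cluster_best(const double* X, int d, int n, Rng& rng, int nrestart,
                         int maxit, bool fuzzy, KmScratch& scr) {
  double best_obj = R_PosInf;
  for (int r = 0; r < nrestart; ++r) {
    const double obj = fuzzy ? fcm2_once(X, d, n, rng, maxit, scr)
                             : kmeans2_once(X, d, n, rng, maxit, scr);
    if (obj < best_obj) {
      best_obj = obj;
      scr.best = scr.assign;
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_cluster2(NumericMatrix X, double seed, int nrestart,
                           int maxit, bool fuzzy) {
  const int d = X.nrow(), n = X.ncol();
  KmScratch scr;
  Rng rng(stream_seed((uint64_t)seed, 0, 0));
  cluster_best(REAL(X), d, n, rng, nrestart, maxit, fuzzy, scr);
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) out[j] = scr.best[j] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// score one gene set against all random patient sets

// E: full expression block (nrowE genes x columns samples), column-major.
// cr/rd: 0-based sample-column indices, ncr x nsets / nrd x nsets.
static double score_one(const double* E, int nrowE, const int* genes, int gsz,
                        const int* cr, int ncr, const int* rd, int nrd,
                        int nsets, Rng& rng, int nrestart, int maxit,
                        bool fuzzy, double pfloor, double* pvec,
                        KmScratch& scr, std::vector<double>& Xbuf) {
  const int n = ncr + nrd;
  Xbuf.resize((size_t)gsz * n);
  double psum = 0.0;
  for (int s = 0; s < nsets; ++s) {
    for (int j = 0; j < n; ++j) {
      const int col = (j < ncr) ? cr[(size_t)s * ncr + j]
                                : rd[(size_t)s * nrd + (j - ncr)];
      double* xj = Xbuf.data() + (size_t)j * gsz;
      const double* ecol = E + (size_t)col * nrowE;
      for (int g = 0; g < gsz; ++g) xj[g] = ecol[genes[g]];
    }
    cluster_best(Xbuf.data(), gsz, n, rng, nrestart, maxit, fuzzy, scr);
    int a = 0, b = 0;
    for (int j = 0; j < ncr; ++j) a += (scr.best[j] == 0);
    for (int j = ncr; j < n; ++j) b += (scr.best[j] == 0);
    const int c = ncr - a, dd = nrd - b;
    double p;
    if (a + b == 0 || c + dd == 0)
      p = 1.0;  // a cluster is empty: no partition information
    else
      p = fisher_two_sided(a, b, c, dd);
    if (p < pfloor) p = pfloor;
    if (pvec) pvec[s] = p;
    psum += p;
  }
  return (double)nsets / psum;  // reciprocal of the mean p
}

// score externally supplied gene sets (columns of gene_idx, 0-based)
// [[Rcpp::export]]
List cpp_score_given(NumericMatrix expr, IntegerMatrix gene_idx,
                     IntegerMatrix cr_idx, IntegerMatrix rd_idx, double seed,
                     int nrestart, int maxit, bool fuzzy, bool return_p) {
  const int gsz = gene_idx.nrow(), nrgs = gene_idx.ncol();
  const int ncr = cr_idx.nrow(), nrd = rd_idx.nrow(), nsets = cr_idx.ncol();
  NumericVector scores(nrgs), mean_p(nrgs);
  NumericMatrix pmat = return_p ? NumericMatrix(nsets, nrgs)
                                : NumericMatrix(0, 0);
  KmScratch scr;
  std::vector<double> Xbuf;
  std::vector<double> pv(nsets);
  for (int i = 0; i < nrgs; ++i) {
    Rng rng(stream_seed((uint64_t)seed, (uint64_t)i + 1, 0));
    const double sc = score_one(
        REAL(expr), expr.nrow(), INTEGER(gene_idx) + (size_t)i * gsz, gsz,
        INTEGER(cr_idx), ncr, INTEGER(rd_idx), nrd, nsets, rng, nrestart,
        maxit, fuzzy, 1e-300, pv.data(), scr, Xbuf);
    scores[i] = sc;
    double m = 0.0;
    for (int s = 0; s < nsets; ++s) m += pv[s];
    mean_p[i] = m / nsets;
    if (return_p)
      for (int s = 0; s < nsets; ++s) pmat(s, i) = pv[s];
  }
  List out = List::create(_["scores"] = scores, _["mean_p"] = mean_p);
  if (return_p) out["p_mat"] = pmat;
  return out;
}

// draw `size` distinct gene indices in [0, S) by partial Fisher-Yates
static void draw_genes(int S, int size, Rng& rng, std::vector<int>& pool,
                       int* out) {
  pool.resize(S);
  for (int t = 0; t < S; ++t) pool[t] = t;
  for (int t = 0; t < size; ++t) {
    const int j = t + rng.below(S - t);
    std::swap(pool[t], pool[j]);
    out[t] = pool[t];
  }
}

// full run: sample and score n_rgs random gene sets
// [[Rcpp::export]]
List cpp_run_full(NumericMatrix expr, int size, int n_rgs,
                  IntegerMatrix cr_idx, IntegerMatrix rd_idx, double seed,
                  int nrestart, int maxit, bool fuzzy) {
  const int S = expr.nrow();
  const int ncr = cr_idx.nrow(), nrd = rd_idx.nrow(), nsets = cr_idx.ncol();
  IntegerMatrix gene_idx(size, n_rgs);
  NumericVector scores(n_rgs), mean_p(n_rgs);
  KmScratch scr;
  std::vector<double> Xbuf;
  std::vector<int> pool;
  for (int i = 0; i < n_rgs; ++i) {
    Rng rng(stream_seed((uint64_t)seed, (uint64_t)i + 1, 0));
    int* genes = INTEGER(gene_idx) + (size_t)i * size;
    draw_genes(S, size, rng, pool, genes);
    scores[i] = score_one(REAL(expr), S, genes, size, INTEGER(cr_idx), ncr,
                          INTEGER(rd_idx), nrd, nsets, rng, nrestart, maxit,
                          fuzzy, 1e-300, nullptr, scr, Xbuf);
    mean_p[i] = 1.0 / scores[i];
    if ((i + 1) % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["scores"] = scores, _["mean_p"] = mean_p,
                      _["gene_idx"] = gene_idx);
}

// ---------------------------------------------------------------------------
// early-stopping run: maintain a running gilded set and its most-frequent
// gene list; stop once the list is unchanged for T consecutive iterations
// (checked after a warm-up).

typedef std::pair<double, long long> ScoreKey;  // (score, -iteration index)

// [[Rcpp::export]]
List cpp_run_early_stop(NumericMatrix expr, int size, int top_m, int T,
                        int warmup, int cap, int gilded_min,
                        double gilded_frac, IntegerMatrix cr_idx,
                        IntegerMatrix rd_idx, double seed, int nrestart,
                        int maxit, bool fuzzy) {
  const int S = expr.nrow();
  const int ncr = cr_idx.nrow(), nrd = rd_idx.nrow(), nsets = cr_idx.ncol();
  KmScratch scr;
  std::vector<double> Xbuf;
  std::vector<int> pool;
  std::vector<int> all_genes;        // genes of every scored RGS
  all_genes.reserve((size_t)size * 1024);
  std::set<ScoreKey> top;            // running gilded set, worst first
  std::priority_queue<ScoreKey> rest;  // best-first heap of non-gilded
  std::vector<int> freq(S, 0);
  std::vector<double> sumsc(S, 0.0);
  std::vector<int> ranked(S), prev_list, cur_list;
  int stable = 0, stopped_at = 0;
  bool converged = false;

  auto add_set = [&](const ScoreKey& k) {
    top.insert(k);
    const long long i = -k.second;  // 1-based iteration index
    const int* g = all_genes.data() + (size_t)(i - 1) * size;
    for (int t = 0; t < size; ++t) {
      ++freq[g[t]];
      sumsc[g[t]] += k.first;
    }
  };
  auto drop_worst = [&]() {
    const ScoreKey k = *top.begin();
    top.erase(top.begin());
    const long long i = -k.second;
    const int* g = all_genes.data() + (size_t)(i - 1) * size;
    for (int t = 0; t < size; ++t) {
      --freq[g[t]];
      sumsc[g[t]] -= k.first;
    }
    rest.push(k);
  };

  for (int i = 1; i <= cap; ++i) {
    Rng rng(stream_seed((uint64_t)seed, (uint64_t)i, 0));
    all_genes.resize((size_t)i * size);
    int* genes = all_genes.data() + (size_t)(i - 1) * size;
    draw_genes(S, size, rng, pool, genes);
    const double sc = score_one(REAL(expr), S, genes, size, INTEGER(cr_idx),
                                ncr, INTEGER(rd_idx), nrd, nsets, rng,
                                nrestart, maxit, fuzzy, 1e-300, nullptr, scr,
                                Xbuf);
    const size_t K = std::max(gilded_min,
                              (int)std::llround(gilded_frac * (double)i));
    const ScoreKey key(sc, -(long long)i);
    if (top.size() < K) {
      add_set(key);
    } else if (key > *top.begin()) {
      drop_worst();
      add_set(key);
    } else {
      rest.push(key);
    }
    while (top.size() < K && !rest.empty()) {
      add_set(rest.top());
      rest.pop();
    }

    if (i >= warmup) {
      // current top_m most frequent genes (freq desc, summed score desc,
      // gene index asc -- gene rows are passed sorted by gene id)
      const int m = std::min(top_m, S);
      for (int g = 0; g < S; ++g) ranked[g] = g;
      std::partial_sort(ranked.begin(), ranked.begin() + m, ranked.end(),
                        [&](int x, int y) {
                          if (freq[x] != freq[y]) return freq[x] > freq[y];
                          if (sumsc[x] != sumsc[y]) return sumsc[x] > sumsc[y];
                          return x < y;
                        });
      cur_list.assign(ranked.begin(), ranked.begin() + m);
      std::sort(cur_list.begin(), cur_list.end());
      if (i > warmup && cur_list == prev_list)
        ++stable;
      else
        stable = 0;
      prev_list = cur_list;
      if (stable >= T) {
        stopped_at = i;
        converged = true;
        break;
      }
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  if (!converged) stopped_at = cap;

  const int K = (int)top.size();
  IntegerMatrix gilded_idx(size, K);
  NumericVector gilded_scores(K);
  int col = 0;
  for (auto it = top.rbegin(); it != top.rend(); ++it, ++col) {  // best first
    const long long i = -it->second;
    const int* g = all_genes.data() + (size_t)(i - 1) * size;
    for (int t = 0; t < size; ++t) gilded_idx(t, col) = g[t];
    gilded_scores[col] = it->first;
  }
  return List::create(_["stopped_at"] = stopped_at, _["converged"] = converged,
                      _["gilded_idx"] = gilded_idx,
                      _["gilded_scores"] = gilded_scores);
}

// ---------------------------------------------------------------------------

// deterministic child-seed derivation, result in [1, 2^31 - 1]
// [[Rcpp::export]]
double cpp_hash_seed(double seed, double tag) {
  const uint64_t h = stream_seed((uint64_t)seed, (uint64_t)tag, 0x5eedULL);
  return (double)(h % 2147483646ULL) + 1.0;
}
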
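#include <Rcpp.h>
using namespace Rcpp;

// Phylogenetic alpha/beta metrics under taxa-label randomization.
//
// All functions take the community as a samples x taxa abundance matrix and
// the patristic distance matrix over the same taxa (tree tip order). A null
// replicate is a permutation `perm` of taxon indices (0-based): taxon t is
// looked up at distance row/column perm[t], i.e. tip labels are shuffled
// across the distance matrix while abundances stay put.

struct SampleIdx {
  std::vector<int> idx;      // present taxa (abundance > 0)
  std::vector<double> w;     // relative abundances over present taxa
};

static std::vector<SampleIdx> index_samples(const NumericMatrix& comm) {
  int ns = comm.nrow(), nt = comm.ncol();
  std::vector<SampleIdx> out(ns);
  for (int s = 0; s < ns; ++s) {
    double tot = 0.0;
    for (int t = 0; t < nt; ++t) {
      double a = comm(s, t);
      if (a > 0) { out[s].idx.push_back(t); tot += a; }
    }
    out[s].w.reserve(out[s].idx.size());
    for (int k = 0; k < (int) out[s].idx.size(); ++k)
      out[s].w.push_back(comm(s, out[s].idx[k]) / tot);
  }
  return out;
}

// MPD and MNTD for one sample under permutation p (identity for observed).
static void alpha_one(const SampleIdx& sm, const NumericMatrix& dist,
                      const int* p, bool weighted,
                      double& mpd, double& mntd) {
  int n = sm.idx.size();
  if (n < 2) { mpd = NA_REAL; mntd = NA_REAL; return; }
  double sum_d = 0.0, sum_w = 0.0, mntd_acc = 0.0;
  for (int a = 0; a < n; ++a) {
    int ia = p[sm.idx[a]];
    double mind = R_PosInf;
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      int ib = p[sm.idx[b]];
      double d = dist(ia, ib);
      if (d < mind) mind = d;
      if (b > a) {
        if (weighted) {
          double ww = sm.w[a] * sm.w[b];
          sum_d += ww * d; sum_w += ww;
        } else {
          sum_d += d; sum_w += 1.0;
        }
      }
    }
    mntd_acc += weighted ? sm.w[a] * mind : mind;
  }
  mpd = sum_d / sum_w;
  mntd = weighted ? mntd_acc : mntd_acc / n;
}

// [[Rcpp::export]]
List cpp_ses_alpha(NumericMatrix comm, NumericMatrix dist,
                   IntegerMatrix perms, bool weighted) {
  int ns = comm.nrow(), nt = comm.ncol(), nrep = perms.nrow();
  std::vector<SampleIdx> sm = index_samples(comm);
  std::vector<int> ident(nt);
  for (int t = 0; t < nt; ++t) ident[t] = t;

  NumericVector mpd_obs(ns), mntd_obs(ns);
  NumericVector mpd_m(ns, 0.0), mpd_s2(ns, 0.0), mntd_m(ns, 0.0), mntd_s2(ns, 0.0);
  for (int s = 0; s < ns; ++s)
    alpha_one(sm[s], dist, ident.data(), weighted, mpd_obs[s], mntd_obs[s]);

  // Null moments accumulate deviations from the observed value: this keeps
  // shuffle-invariant samples at exactly zero variance (no cancellation).
  std::vector<int> p(nt);
  for (int r = 0; r < nrep; ++r) {
    for (int t = 0; t < nt; ++t) p[t] = perms(r, t);
    for (int s = 0; s < ns; ++s) {
      if ((int) sm[s].idx.size() < 2) continue;
      double a, b;
      alpha_one(sm[s], dist, p.data(), weighted, a, b);
      a -= mpd_obs[s]; b -= mntd_obs[s];
      mpd_m[s] += a; mpd_s2[s] += a * a;
      mntd_m[s] += b; mntd_s2[s] += b * b;
    }
    if (r % 50 == 0) Rcpp::checkUserInterrupt();
  }
  for (int s = 0; s < ns; ++s) {
    if ((int) sm[s].idx.size() < 2) {
      mpd_m[s] = NA_REAL; mpd_s2[s] = NA_REAL;
      mntd_m[s] = NA_REAL; mntd_s2[s] = NA_REAL;
      continue;
    }
    double mm = mpd_m[s] / nrep, sm2 = mpd_s2[s] / nrep - mm * mm;
    mpd_m[s] = mm + mpd_obs[s];
    mpd_s2[s] = sqrt(std::max(sm2, 0.0) * nrep / std::max(nrep - 1, 1));
    mm = mntd_m[s] / nrep; sm2 = mntd_s2[s] / nrep - mm * mm;
    mntd_m[s] = mm + mntd_obs[s];
    mntd_s2[s] = sqrt(std::max(sm2, 0.0) * nrep / std::max(nrep - 1, 1));
  }
  return List::create(_["mpd_obs"] = mpd_obs, _["mntd_obs"] = mntd_obs,
                      _["mpd_null_mean"] = mpd_m, _["mpd_null_sd"] = mpd_s2,
                      _["mntd_null_mean"] = mntd_m, _["mntd_null_sd"] = mntd_s2);
}

// betaMNTD matrix for one permutation. minmat(s, t) = min distance from
// taxon t to any taxon present in sample s (0 if t itself is present).
static void beta_one(const std::vector<SampleIdx>& sm, const NumericMatrix& dist,
                     const int* p, bool weighted, int nt, NumericMatrix& out) {
  int ns = sm.size();
  std::vector<double> minmat((size_t) ns * nt);
  for (int s = 0; s < ns; ++s) {
    const std::vector<int>& idx = sm[s].idx;
    for (int t = 0; t < nt; ++t) {
      int it = p[t];
      double mind = R_PosInf;
      for (int k = 0; k < (int) idx.size(); ++k) {
        double d = dist(it, p[idx[k]]);
        if (d < mind) { mind = d; if (mind == 0.0) break; }
      }
      minmat[(size_t) s * nt + t] = mind;
    }
  }
  for (int a = 0; a < ns; ++a) {
    out(a, a) = 0.0;
    for (int b = a + 1; b < ns; ++b) {
      double acc_a = 0.0, acc_b = 0.0;
      const SampleIdx& A = sm[a];
      const SampleIdx& B = sm[b];
      for (int k = 0; k < (int) A.idx.size(); ++k) {
        double m = minmat[(size_t) b * nt + A.idx[k]];
        acc_a += weighted ? A.w[k] * m : m;
      }
      for (int k = 0; k < (int) B.idx.size(); ++k) {
        double m = minmat[(size_t) a * nt + B.idx[k]];
        acc_b += weighted ? B.w[k] * m : m;
      }
      if (!weighted) {
        acc_a /= A.idx.size();
        acc_b /= B.idx.size();
      }
      double v = 0.5 * (acc_a + acc_b);
      out(a, b) = v; out(b, a) = v;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_beta_mntd(NumericMatrix comm, NumericMatrix dist, bool weighted) {
  int ns = comm.nrow(), nt = comm.ncol();
  std::vector<SampleIdx> sm = index_samples(comm);
  std::vector<int> ident(nt);
  for (int t = 0; t < nt; ++t) ident[t] = t;
  NumericMatrix out(ns, ns);
  beta_one(sm, dist, ident.data(), weighted, nt, out);
  return out;
}

// [[Rcpp::export]]
List cpp_beta_nti(NumericMatrix comm, NumericMatrix dist,
                  IntegerMatrix perms, bool weighted) {
  int ns = comm.nrow(), nt = comm.ncol(), nrep = perms.nrow();
  std::vector<SampleIdx> sm = index_samples(comm);
  std::vector<int> ident(nt);
  for (int t = 0; t < nt; ++t) ident[t] = t;

  NumericMatrix obs(ns, ns), nmean(ns, ns), nsd(ns, ns), tmp(ns, ns);
  beta_one(sm, dist, ident.data(), weighted, nt, obs);

  std::vector<double> sum((size_t) ns * ns, 0.0), sum2((size_t) ns * ns, 0.0);
  std::vector<int> p(nt);
  for (int r = 0; r < nrep; ++r) {
    for (int t = 0; t < nt; ++t) p[t] = perms(r, t);
    beta_one(sm, dist, p.data(), weighted, nt, tmp);
    for (int a = 0; a < ns; ++a)
      for (int b = a + 1; b < ns; ++b) {
        double v = tmp(a, b) - obs(a, b);  // centered: see cpp_ses_alpha
        sum[(size_t) a * ns + b] += v;
        sum2[(size_t) a * ns + b] += v * v;
      }
    Rcpp::checkUserInterrupt();
  }
  for (int a = 0; a < ns; ++a) {
    nmean(a, a) = 0.0; nsd(a, a) = 0.0;
    for (int b = a + 1; b < ns; ++b) {
      double m = sum[(size_t) a * ns + b] / nrep;
      double v = sum2[(size_t) a * ns + b] / nrep - m * m;
      double sd = sqrt(std::max(v, 0.0) * nrep / std::max(nrep - 1, 1));
      nmean(a, b) = m + obs(a, b); nmean(b, a) = nmean(a, b);
      nsd(a, b) = sd; nsd(b, a) = sd;
    }
  }
  return List::create(_["obs"] = obs, _["null_mean"] = nmean, _["null_sd"] = nsd);
}
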
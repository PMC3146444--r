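// Gibbs sampler for the Bayesian admixture model with correlated (or
// independent) cluster allele frequencies.
//
// Latent structure: each gene copy has a cluster-of-origin z sampled
// categorically given the individual's ancestry vector Q and the cluster
// allele frequencies P; P gets a conjugate Dirichlet update (prior
// lambda, or PA*(1-F_k)/F_k under the correlated model); Q gets a
// conjugate Dirichlet(alpha + copy counts) update, clamped to a unit
// vector for learning samples; alpha, the drift parameters F_k and the
// ancestral frequencies PA are updated by Metropolis steps.
//
// All randomness flows through R's RNG so set.seed() makes runs
// bit-reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double P_FLOOR = 1e-9;

// Dirichlet draw via gamma variates; floored and renormalised so that no
// probability underflows to exactly zero.
static void rdirichlet_into(const std::vector<double>& shape, std::vector<double>& out) {
  const int A = shape.size();
  double tot = 0.0;
  for (int a = 0; a < A; ++a) {
    double g = R::rgamma(shape[a] > 0 ? shape[a] : P_FLOOR, 1.0);
    out[a] = g;
    tot += g;
  }
  if (tot <= 0) {
    for (int a = 0; a < A; ++a) out[a] = 1.0 / A;
    return;
  }
  double tot2 = 0.0;
  for (int a = 0; a < A; ++a) {
    out[a] = out[a] / tot;
    if (out[a] < P_FLOOR) out[a] = P_FLOOR;
    tot2 += out[a];
  }
  for (int a = 0; a < A; ++a) out[a] /= tot2;
}

// log Dirichlet(x; shape) density (unnormalised over the simplex is not
// enough: Metropolis ratios for F and PA need the normalising constant).
static double ldirichlet(const std::vector<double>& x, const std::vector<double>& shape) {
  double s = 0.0, lg = 0.0, ll = 0.0;
  for (size_t a = 0; a < x.size(); ++a) {
    s += shape[a];
    lg += R::lgammafn(shape[a]);
    ll += (shape[a] - 1.0) * std::log(x[a]);
  }
  return R::lgammafn(s) - lg + ll;
}

// [[Rcpp::export(name = ".admix_gibbs_cpp")]]
List admix_gibbs_cpp(IntegerMatrix geno_idx,  // n x 2L, 1-based allele index, NA missing
                     IntegerVector n_alleles, // per-locus registry sizes
                     int K, int burn_in, int n_sweeps, int thin,
                     bool correlated, double lambda,
                     double alpha_init, double alpha_max, double alpha_prop_sd,
                     double f_prior_mean, double f_prior_sd, double f_prop_sd,
                     double pa_prop_conc,
                     IntegerVector ref_cluster,  // 0 free, 1..K clamped
                     bool store_q_samples) {
  const int n = geno_idx.nrow();
  const int L = n_alleles.size();
  if (geno_idx.ncol() != 2 * L) stop("geno_idx must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");

  // ---- state ----
  NumericMatrix Q(n, K);
  std::vector<std::vector<std::vector<double> > > P(K), counts(K);
  std::vector<std::vector<double> > PA(L);
  std::vector<double> F(K, f_prior_mean > 0 ? f_prior_mean : 0.01);
  double alpha = alpha_init;

  // overall allele frequencies for initialisation of P and PA
  for (int l = 0; l < L; ++l) {
    const int A = n_alleles[l];
    std::vector<double> tot(A, 1.0);  // +1 pseudocount
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 2; ++c) {
        int a = geno_idx(i, 2 * l + c);
        if (a != NA_INTEGER) tot[a - 1] += 1.0;
      }
    }
    double s = 0.0;
    for (int a = 0; a < A; ++a) s += tot[a];
    PA[l].resize(A);
    for (int a = 0; a < A; ++a) PA[l][a] = tot[a] / s;
  }
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    counts[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l] = PA[l];
      counts[k][l].assign(n_alleles[l], 0.0);
    }
  }
  for (int i = 0; i < n; ++i) {
    if (ref_cluster[i] > 0) {
      for (int k = 0; k < K; ++k) Q(i, k) = (k == ref_cluster[i] - 1) ? 1.0 : 0.0;
    } else {
      for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
    }
  }

  // gamma prior on F (mean f_prior_mean, sd f_prior_sd)
  const double f_shape = (f_prior_mean / f_prior_sd) * (f_prior_mean / f_prior_sd);
  const double f_rate = f_prior_mean / (f_prior_sd * f_prior_sd);

  int n_free = 0;
  for (int i = 0; i < n; ++i) if (ref_cluster[i] == 0) ++n_free;

  // ---- accumulators ----
  const int total_sweeps = burn_in + n_sweeps;
  const int n_samp = n_sweeps / thin;
  NumericMatrix q_sum(n, K);
  std::vector<std::vector<std::vector<double> > > p_sum(K);
  for (int k = 0; k < K; ++k) {
    p_sum[k].resize(L);
    for (int l = 0; l < L; ++l) p_sum[k][l].assign(n_alleles[l], 0.0);
  }
  NumericVector alpha_trace(n_samp), lnl_trace(n_samp);
  NumericVector q_samples(store_q_samples ? (R_xlen_t)n_samp * n * K : 0);
  int samp = 0;

  std::vector<double> work(K), nik(K), shape(64), newp(64);

  for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
    // -- sample latent origins z; accumulate ancestry and allele counts --
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(counts[k][l].begin(), counts[k][l].end(), 0.0);

    for (int i = 0; i < n; ++i) {
      std::fill(nik.begin(), nik.end(), 0.0);
      const int clamp = ref_cluster[i];
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno_idx(i, 2 * l + c);
          if (a == NA_INTEGER) continue;
          int z;
          if (clamp > 0 || K == 1) {
            z = (clamp > 0) ? clamp - 1 : 0;
          } else {
            double tot = 0.0;
            for (int k = 0; k < K; ++k) {
              work[k] = Q(i, k) * P[k][l][a - 1];
              tot += work[k];
            }
            double u = R::unif_rand() * tot;
            z = K - 1;
            double acc = 0.0;
            for (int k = 0; k < K; ++k) {
              acc += work[k];
              if (u <= acc) { z = k; break; }
            }
          }
          counts[z][l][a - 1] += 1.0;
          nik[z] += 1.0;
        }
      }
      // -- Q update (conjugate), clamped for references --
      if (clamp == 0 && K > 1) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          work[k] = R::rgamma(alpha + nik[k], 1.0);
          tot += work[k];
        }
        if (tot <= 0) { for (int k = 0; k < K; ++k) work[k] = 1.0 / K; tot = 1.0; }
        for (int k = 0; k < K; ++k) {
          double q = work[k] / tot;
          if (q < 1e-12) q = 1e-12;
          Q(i, k) = q;
        }
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += Q(i, k);
        for (int k = 0; k < K; ++k) Q(i, k) /= s;
      }
    }

    // -- P update (conjugate Dirichlet) --
    for (int k = 0; k < K; ++k) {
      const double fk = F[k];
      for (int l = 0; l < L; ++l) {
        const int A = n_alleles[l];
        shape.resize(A);
        newp.resize(A);
        for (int a = 0; a < A; ++a) {
          double prior = correlated ? PA[l][a] * (1.0 - fk) / fk : lambda;
          shape[a] = prior + counts[k][l][a];
        }
        rdirichlet_into(shape, newp);
        for (int a = 0; a < A; ++a) P[k][l][a] = newp[a];
      }
    }

    // -- alpha Metropolis (symmetric Dirichlet prior scale of Q) --
    if (K > 1 && n_free > 0) {
      double slogq = 0.0;
      for (int i = 0; i < n; ++i) {
        if (ref_cluster[i] != 0) continue;
        for (int k = 0; k < K; ++k) slogq += std::log(Q(i, k));
      }
      double prop = alpha + R::norm_rand() * alpha_prop_sd;
      if (prop > 0 && prop <= alpha_max) {
        double ll_cur = n_free * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                        (alpha - 1.0) * slogq;
        double ll_new = n_free * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                        (prop - 1.0) * slogq;
        if (std::log(R::unif_rand()) < ll_new - ll_cur) alpha = prop;
      }
    }

    if (correlated) {
      // -- F_k Metropolis --
      for (int k = 0; k < K; ++k) {
        double prop = F[k] + R::norm_rand() * f_prop_sd;
        if (prop <= 0.0 || prop >= 1.0) continue;
        double ll_cur = 0.0, ll_new = 0.0;
        for (int l = 0; l < L; ++l) {
          const int A = n_alleles[l];
          std::vector<double> sc(A), sn(A);
          for (int a = 0; a < A; ++a) {
            sc[a] = PA[l][a] * (1.0 - F[k]) / F[k];
            sn[a] = PA[l][a] * (1.0 - prop) / prop;
          }
          ll_cur += ldirichlet(P[k][l], sc);
          ll_new += ldirichlet(P[k][l], sn);
        }
        ll_cur += (f_shape - 1.0) * std::log(F[k]) - f_rate * F[k];
        ll_new += (f_shape - 1.0) * std::log(prop) - f_rate * prop;
        if (std::log(R::unif_rand()) < ll_new - ll_cur) F[k] = prop;
      }
      // -- PA Metropolis per locus (Dirichlet random-walk proposal) --
      for (int l = 0; l < L; ++l) {
        const int A = n_alleles[l];
        if (A < 2) continue;
        std::vector<double> cur = PA[l], prop(A), sh(A);
        for (int a = 0; a < A; ++a) sh[a] = pa_prop_conc * cur[a];
        rdirichlet_into(sh, prop);
        double lr = 0.0;
        // likelihood of P[k][l] under each PA, plus Dirichlet(lambda) prior
        for (int k = 0; k < K; ++k) {
          std::vector<double> sc(A), sn(A);
          for (int a = 0; a < A; ++a) {
            sc[a] = cur[a] * (1.0 - F[k]) / F[k];
            sn[a] = prop[a] * (1.0 - F[k]) / F[k];
          }
          lr += ldirichlet(P[k][l], sn) - ldirichlet(P[k][l], sc);
        }
        for (int a = 0; a < A; ++a)
          lr += (lambda - 1.0) * (std::log(prop[a]) - std::log(cur[a]));
        // Hastings correction for the asymmetric proposal
        std::vector<double> sh_rev(A);
        for (int a = 0; a < A; ++a) sh_rev[a] = pa_prop_conc * prop[a];
        lr += ldirichlet(cur, sh_rev) - ldirichlet(prop, sh);
        if (std::log(R::unif_rand()) < lr) PA[l] = prop;
      }
    }

    // -- record --
    if (sweep > burn_in && (sweep - burn_in) % thin == 0) {
      double lnl = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          for (int c = 0; c < 2; ++c) {
            int a = geno_idx(i, 2 * l + c);
            if (a == NA_INTEGER) continue;
            double pr = 0.0;
            for (int k = 0; k < K; ++k) pr += Q(i, k) * P[k][l][a - 1];
            lnl += std::log(pr);
          }
        }
      }
      alpha_trace[samp] = alpha;
      lnl_trace[samp] = lnl;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) {
          q_sum(i, k) += Q(i, k);
          if (store_q_samples)
            q_samples[(R_xlen_t)samp * n * K + (R_xlen_t)i * K + k] = Q(i, k);
        }
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < n_alleles[l]; ++a)
            p_sum[k][l][a] += P[k][l][a];
      ++samp;
    }
  }

  // ---- summaries ----
  NumericMatrix q_mean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      q_mean(i, k) = q_sum(i, k) / n_samp;
  // exact renormalisation so each row sums to 1 to machine precision
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += q_mean(i, k);
    if (s > 0) for (int k = 0; k < K; ++k) q_mean(i, k) /= s;
  }
  List p_mean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a)
        pm(k, a) = p_sum[k][l][a] / n_samp;
    p_mean[l] = pm;
  }
  List out = List::create(
    _["q_mean"] = q_mean,
    _["p_mean"] = p_mean,
    _["alpha_trace"] = alpha_trace,
    _["lnL_trace"] = lnl_trace,
    _["n_samples"] = n_samp);
  if (store_q_samples) {
    q_samples.attr("dim") = IntegerVector::create(K, n, n_samp);
    // note: fastest index is k, then i, then sample -> dim (K, n, n_samp)
    out["q_samples"] = q_samples;
  }
  return out;
}
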
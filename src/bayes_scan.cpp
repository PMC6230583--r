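// Reversible-jump MCMC core for the Bayesian Fst genome scan.
//
// Model: for locus i and deme j with alt-allele count n_ij out of N_ij
// haploid samples, the likelihood is beta-binomial (Dirichlet-multinomial
// with two alleles) with concentration theta_ij * (p_i, 1 - p_i), where
// theta_ij = 1/Fst_ij - 1 and logit(Fst_ij) = alpha_i + beta_j. Priors:
// p_i ~ Uniform(0,1) (random-walk update on the logit scale),
// beta_j ~ Normal(beta_mu, beta_sd^2), alpha_i ~ Normal(0, alpha_sd^2)
// when included. A reversible jump toggles inclusion of alpha_i with prior
// odds `prior_odds` in favour of the neutral (excluded) model; the
// inclusion proposal draws alpha* from its prior so the proposal density
// cancels against the prior in the acceptance ratio.
//
// Uses R's RNG throughout so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// log beta-binomial likelihood term (binomial coefficient omitted: constant)
static inline double ll_term(double n, double N, double p, double x) {
  // x = alpha_i + beta_j on the logit-Fst scale; theta = exp(-x)
  double theta = std::exp(-clamp(x, -18.0, 18.0));
  double a = theta * p, b = theta * (1.0 - p);
  return R::lbeta(n + a, N - n + b) - R::lbeta(a, b);
}

struct State {
  int L, J;
  NumericMatrix n, N;     // L x J
  NumericVector p;        // ancestral freq per locus
  NumericVector alpha;    // locus effect (0 when excluded)
  LogicalVector inc;      // alpha included?
  NumericVector beta;     // deme effect
  NumericMatrix ll;       // cached loglik, L x J
  double beta_mu, beta_sd, alpha_sd, log_prior_inc_odds;

  double row_ll(int i, double pi, double ai, const NumericVector &bt) const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += ll_term(n(i, j), N(i, j), pi, ai + bt[j]);
    return s;
  }
  void refresh_row(int i) {
    double ai = inc[i] ? alpha[i] : 0.0;
    for (int j = 0; j < J; ++j) ll(i, j) = ll_term(n(i, j), N(i, j), p[i], ai + beta[j]);
  }
  double row_sum(int i) const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += ll(i, j);
    return s;
  }
};

// one full sweep; acc_* accumulate acceptance counts
static void sweep(State &st, NumericVector &s_p, NumericVector &s_a,
                  NumericVector &s_b, NumericVector &acc_p,
                  NumericVector &acc_a, NumericVector &acc_b,
                  NumericVector &try_p, NumericVector &try_a,
                  NumericVector &try_b) {
  int L = st.L, J = st.J;

  // p_i updates (uniform prior on p; RW on logit scale needs the Jacobian)
  for (int i = 0; i < L; ++i) {
    double lp = std::log(st.p[i] / (1.0 - st.p[i]));
    double lp2 = lp + R::norm_rand() * s_p[i];
    double p2 = 1.0 / (1.0 + std::exp(-clamp(lp2, -12.0, 12.0)));
    double ai = st.inc[i] ? st.alpha[i] : 0.0;
    double ll_new = st.row_ll(i, p2, ai, st.beta);
    double logA = ll_new - st.row_sum(i)
      + std::log(p2 * (1.0 - p2)) - std::log(st.p[i] * (1.0 - st.p[i]));
    try_p[i] += 1;
    if (std::log(unif_rand()) < logA) {
      st.p[i] = p2;
      st.refresh_row(i);
      acc_p[i] += 1;
    }
  }

  // beta_j updates
  for (int j = 0; j < J; ++j) {
    double b2 = st.beta[j] + R::norm_rand() * s_b[j];
    double d = 0.0;
    for (int i = 0; i < L; ++i) {
      double ai = st.inc[i] ? st.alpha[i] : 0.0;
      d += ll_term(st.n(i, j), st.N(i, j), st.p[i], ai + b2) - st.ll(i, j);
    }
    double logA = d
      + R::dnorm(b2, st.beta_mu, st.beta_sd, 1)
      - R::dnorm(st.beta[j], st.beta_mu, st.beta_sd, 1);
    try_b[j] += 1;
    if (std::log(unif_rand()) < logA) {
      double old = st.beta[j];
      st.beta[j] = b2;
      for (int i = 0; i < st.L; ++i) {
        double ai = st.inc[i] ? st.alpha[i] : 0.0;
        st.ll(i, j) = ll_term(st.n(i, j), st.N(i, j), st.p[i], ai + b2);
      }
      (void)old;
      acc_b[j] += 1;
    }
  }

  // alpha_i random-walk updates (included loci only)
  for (int i = 0; i < L; ++i) {
    if (!st.inc[i]) continue;
    double a2 = st.alpha[i] + R::norm_rand() * s_a[i];
    double ll_new = st.row_ll(i, st.p[i], a2, st.beta);
    double logA = ll_new - st.row_sum(i)
      + R::dnorm(a2, 0.0, st.alpha_sd, 1) - R::dnorm(st.alpha[i], 0.0, st.alpha_sd, 1);
    try_a[i] += 1;
    if (std::log(unif_rand()) < logA) {
      st.alpha[i] = a2;
      st.refresh_row(i);
      acc_a[i] += 1;
    }
  }

  // reversible jump: toggle alpha inclusion (proposal = prior, so densities
  // cancel; only the likelihood ratio and prior model odds remain)
  for (int i = 0; i < L; ++i) {
    if (st.inc[i]) {
      double ll_new = st.row_ll(i, st.p[i], 0.0, st.beta);
      double logA = ll_new - st.row_sum(i) - st.log_prior_inc_odds;
      if (std::log(unif_rand()) < logA) {
        st.inc[i] = false;
        st.alpha[i] = 0.0;
        st.refresh_row(i);
      }
    } else {
      double a_star = R::norm_rand() * st.alpha_sd;
      double ll_new = st.row_ll(i, st.p[i], a_star, st.beta);
      double logA = ll_new - st.row_sum(i) + st.log_prior_inc_odds;
      if (std::log(unif_rand()) < logA) {
        st.inc[i] = true;
        st.alpha[i] = a_star;
        st.refresh_row(i);
      }
    }
  }
}

// [[Rcpp::export]]
List bayescan_mcmc(NumericMatrix n_alt, NumericMatrix N_tot,
                   int n_pilot, int pilot_len, int n_iter,
                   int sample_size, int thinning,
                   double prior_odds, double beta_mu, double beta_sd,
                   double alpha_sd) {
  int L = n_alt.nrow(), J = n_alt.ncol();
  if (J < 2) stop("bayes scan needs at least 2 demes");
  State st;
  st.L = L; st.J = J; st.n = n_alt; st.N = N_tot;
  st.p = NumericVector(L);
  st.alpha = NumericVector(L, 0.0);
  st.inc = LogicalVector(L, false);
  st.beta = NumericVector(J, beta_mu);
  st.ll = NumericMatrix(L, J);
  st.beta_mu = beta_mu; st.beta_sd = beta_sd; st.alpha_sd = alpha_sd;
  // prior_odds = P(excluded)/P(included); log odds of inclusion is -log(odds)
  st.log_prior_inc_odds = -std::log(prior_odds);

  for (int i = 0; i < L; ++i) {
    double tot = 0.0, cnt = 0.0;
    for (int j = 0; j < J; ++j) { tot += n_alt(i, j); cnt += N_tot(i, j); }
    st.p[i] = clamp(tot / cnt, 0.02, 0.98);
    st.refresh_row(i);
  }

  NumericVector s_p(L, 0.5), s_a(L, 0.5), s_b(J, 0.3);
  NumericVector acc_p(L), acc_a(L), acc_b(J), try_p(L), try_a(L), try_b(J);

  // pilot runs: adapt proposal scales toward acceptance in [0.25, 0.45]
  for (int pr = 0; pr < n_pilot; ++pr) {
    std::fill(acc_p.begin(), acc_p.end(), 0.0);
    std::fill(acc_a.begin(), acc_a.end(), 0.0);
    std::fill(acc_b.begin(), acc_b.end(), 0.0);
    std::fill(try_p.begin(), try_p.end(), 0.0);
    std::fill(try_a.begin(), try_a.end(), 0.0);
    std::fill(try_b.begin(), try_b.end(), 0.0);
    for (int it = 0; it < pilot_len; ++it)
      sweep(st, s_p, s_a, s_b, acc_p, acc_a, acc_b, try_p, try_a, try_b);
    for (int i = 0; i < L; ++i) {
      if (try_p[i] > 0) {
        double r = acc_p[i] / try_p[i];
        if (r > 0.45) s_p[i] *= 1.4; else if (r < 0.25) s_p[i] /= 1.4;
      }
      if (try_a[i] > 0) {
        double r = acc_a[i] / try_a[i];
        if (r > 0.45) s_a[i] *= 1.4; else if (r < 0.25) s_a[i] /= 1.4;
      }
    }
    for (int j = 0; j < J; ++j) {
      if (try_b[j] > 0) {
        double r = acc_b[j] / try_b[j];
        if (r > 0.45) s_b[j] *= 1.4; else if (r < 0.25) s_b[j] /= 1.4;
      }
    }
  }

  // convergence check on the final pilot's acceptance rates
  double worst_lo = 1.0, worst_hi = 0.0;
  for (int i = 0; i < L; ++i) {
    if (try_p[i] > 0) {
      double r = acc_p[i] / try_p[i];
      worst_lo = std::min(worst_lo, r); worst_hi = std::max(worst_hi, r);
    }
  }
  for (int j = 0; j < J; ++j) {
    if (try_b[j] > 0) {
      double r = acc_b[j] / try_b[j];
      worst_lo = std::min(worst_lo, r); worst_hi = std::max(worst_hi, r);
    }
  }
  if (n_pilot > 0 && (worst_lo < 0.05 || worst_hi > 0.9)) {
    stop("pilot adaptation did not converge: acceptance rates span [%f, %f] "
         "outside [0.05, 0.9]; increase pilot runs or lengths",
         worst_lo, worst_hi);
  }

  // main chain
  NumericVector inc_sum(L), alpha_sum(L), fst_sum(L), beta_sum(J);
  int kept = 0;
  std::fill(acc_p.begin(), acc_p.end(), 0.0);
  std::fill(acc_a.begin(), acc_a.end(), 0.0);
  std::fill(acc_b.begin(), acc_b.end(), 0.0);
  std::fill(try_p.begin(), try_p.end(), 0.0);
  std::fill(try_a.begin(), try_a.end(), 0.0);
  std::fill(try_b.begin(), try_b.end(), 0.0);
  for (int it = 1; it <= n_iter; ++it) {
    sweep(st, s_p, s_a, s_b, acc_p, acc_a, acc_b, try_p, try_a, try_b);
    if (it % thinning == 0 && kept < sample_size) {
      ++kept;
      for (int i = 0; i < L; ++i) {
        if (st.inc[i]) inc_sum[i] += 1;
        alpha_sum[i] += st.alpha[i];
        double mean_b = 0.0;
        for (int j = 0; j < J; ++j) mean_b += st.beta[j];
        mean_b /= J;
        fst_sum[i] += 1.0 / (1.0 + std::exp(-((st.inc[i] ? st.alpha[i] : 0.0) + mean_b)));
      }
      for (int j = 0; j < J; ++j) beta_sum[j] += st.beta[j];
    }
  }
  if (kept == 0) stop("no samples retained: check n_iter/thinning/sample_size");

  return List::create(
    _["post_prob"] = inc_sum / double(kept),
    _["alpha_mean"] = alpha_sum / double(kept),
    _["fst_mean"] = fst_sum / double(kept),
    _["beta_mean"] = beta_sum / double(kept),
    _["n_samples"] = kept
  );
}
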
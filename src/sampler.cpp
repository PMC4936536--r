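#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 0.0) return x + log1p(std::exp(-x));
  return log1p(std::exp(x));
}

// binomial log-likelihood kernel for one unit (normalizing constant omitted)
static inline double llk(double y, double n, double eta) {
  return y * eta - n * softplus(eta);
}

static double icar_quad(const NumericVector& v, const IntegerVector& idx,
                        const IntegerVector& ptr) {
  // sum over edges (i<j) of (v_i - v_j)^2, plus v_i^2 for islands
  double q = 0.0;
  int n = v.size();
  for (int i = 0; i < n; ++i) {
    int deg = ptr[i + 1] - ptr[i];
    if (deg == 0) { q += v[i] * v[i]; continue; }
    for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
      int j = idx[k];
      if (j > i) { double d = v[i] - v[j]; q += d * d; }
    }
  }
  return q;
}

static inline double sumsq(const NumericVector& v) {
  double s = 0.0;
  for (int i = 0; i < v.size(); ++i) s += v[i] * v[i];
  return s;
}

// Metropolis-within-Gibbs sampler for the two-level multiscale convolution
// model (independent or shared). Adjacency is passed in CSR form with
// 0-based indices; `parent` maps fine units to coarse units (0-based).
// [[Rcpp::export(name = ".mwg_sampler")]]
List mwg_sampler(NumericVector y1, NumericVector n1, NumericVector x1,
                 NumericVector y2, NumericVector n2, NumericVector x2,
                 IntegerVector adj1_idx, IntegerVector adj1_ptr,
                 IntegerVector adj2_idx, IntegerVector adj2_ptr,
                 IntegerVector parent, bool shared,
                 double sd_upper, double slope_sd,
                 int n_iter, int burn_in, int thin, int adapt_until,
                 double target_site, double target_block,
                 int rank1, int rank2,
                 List init, List update_flags,
                 double lc1, double lc2) {
  const int N1 = y1.size(), N2 = y2.size();

  // state
  double b01 = as<double>(init["beta01"]), b02 = as<double>(init["beta02"]);
  double b11 = as<double>(init["beta11"]), b12 = as<double>(init["beta12"]);
  NumericVector v1 = clone(as<NumericVector>(init["v1"]));
  NumericVector v2 = clone(as<NumericVector>(init["v2"]));
  NumericVector e1 = clone(as<NumericVector>(init["eps1"]));
  NumericVector e2 = clone(as<NumericVector>(init["eps2"]));
  double sv1 = as<double>(init["sigma_v1"]), sv2 = as<double>(init["sigma_v2"]);
  double se1 = as<double>(init["sigma_eps1"]), se2 = as<double>(init["sigma_eps2"]);

  const bool up_v = as<bool>(update_flags["v"]);
  const bool up_e = as<bool>(update_flags["eps"]);
  const bool up_beta = as<bool>(update_flags["beta"]);
  const bool up_slope = as<bool>(update_flags["slope"]);
  const bool up_sigma = as<bool>(update_flags["sigma"]);
  const bool recenter1 = as<bool>(update_flags["recenter1"]);
  const bool recenter2 = as<bool>(update_flags["recenter2"]);

  std::vector< std::vector<int> > children(N2);
  for (int i = 0; i < N1; ++i) children[parent[i]].push_back(i);

  // linear predictors
  NumericVector eta1(N1), eta2(N2);
  for (int i = 0; i < N1; ++i) {
    eta1[i] = b01 + b11 * x1[i] + v1[i] + e1[i] + (shared ? v2[parent[i]] : 0.0);
  }
  for (int j = 0; j < N2; ++j) eta2[j] = b02 + b12 * x2[j] + v2[j] + e2[j];

  // adaptive log proposal scales
  double ls_e1 = log(0.5), ls_e2 = log(0.5);
  double ls_b1 = log(0.1), ls_b2 = log(0.1);
  double ls_sv1 = log(0.5), ls_sv2 = log(0.5);
  double ls_se1 = log(0.5), ls_se2 = log(0.5);
  double ls_t[6] = {log(0.1), log(0.1), log(0.1), log(0.1), log(0.1), log(0.1)};
  double ls_swap[2] = {log(0.1), log(0.1)};
  double ls_r[4] = {log(0.3), log(0.3), log(0.3), log(0.3)};

  // fixed quadratic forms of the covariates over the adjacency graphs,
  // used by the slope/spatial-effect translation moves
  double qx1 = icar_quad(x1, adj1_idx, adj1_ptr);
  double qx2 = icar_quad(x2, adj2_idx, adj2_ptr);
  double sx1 = sumsq(x1), sx2 = sumsq(x2);

  const int n_ret = (n_iter > burn_in) ? (n_iter - burn_in + thin - 1) / thin : 0;
  const int npar = 8 + 2 * (N1 + N2);
  NumericMatrix draws(n_ret, npar);
  NumericVector dev1(n_ret), dev2(n_ret);

  // acceptance bookkeeping (post-burn-in)
  double acc_v1 = 0, try_v1 = 0, acc_v2 = 0, try_v2 = 0;
  double acc_e1 = 0, try_e1 = 0, acc_e2 = 0, try_e2 = 0;
  double acc_b1 = 0, try_b1 = 0, acc_b2 = 0, try_b2 = 0;
  double acc_s = 0, try_s = 0;

  RNGScope scope;
  int ret = 0;

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= adapt_until && it <= burn_in;
    const double gamma = adapting ? std::min(0.25, 2.0 / std::sqrt((double)it)) : 0.0;

    // (i) spatial effects: independence proposal from the ICAR full
    // conditional; prior and proposal cancel, leaving the likelihood ratio
    if (up_v) {
      for (int i = 0; i < N1; ++i) {
        int deg = adj1_ptr[i + 1] - adj1_ptr[i];
        double m = 0.0, sdc;
        if (deg > 0) {
          for (int k = adj1_ptr[i]; k < adj1_ptr[i + 1]; ++k) m += v1[adj1_idx[k]];
          m /= deg;
          sdc = sv1 / std::sqrt((double)deg);
        } else {
          sdc = sv1;
        }
        double prop = R::rnorm(m, sdc);
        double en = eta1[i] + (prop - v1[i]);
        double lr = llk(y1[i], n1[i], en) - llk(y1[i], n1[i], eta1[i]);
        if (it > burn_in) try_v1 += 1;
        if (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr)) {
          v1[i] = prop; eta1[i] = en;
          if (it > burn_in) acc_v1 += 1;
        }
      }
      for (int j = 0; j < N2; ++j) {
        int deg = adj2_ptr[j + 1] - adj2_ptr[j];
        double m = 0.0, sdc;
        if (deg > 0) {
          for (int k = adj2_ptr[j]; k < adj2_ptr[j + 1]; ++k) m += v2[adj2_idx[k]];
          m /= deg;
          sdc = sv2 / std::sqrt((double)deg);
        } else {
          sdc = sv2;
        }
        double prop = R::rnorm(m, sdc);
        double delta = prop - v2[j];
        double lr = llk(y2[j], n2[j], eta2[j] + delta) - llk(y2[j], n2[j], eta2[j]);
        if (shared) {
          for (size_t c = 0; c < children[j].size(); ++c) {
            int i = children[j][c];
            lr += llk(y1[i], n1[i], eta1[i] + delta) - llk(y1[i], n1[i], eta1[i]);
          }
        }
        if (it > burn_in) try_v2 += 1;
        if (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr)) {
          v2[j] = prop; eta2[j] += delta;
          if (shared) {
            for (size_t c = 0; c < children[j].size(); ++c) eta1[children[j][c]] += delta;
          }
          if (it > burn_in) acc_v2 += 1;
        }
      }
    }

    // (ii) exchangeable effects: single-site random-walk Metropolis
    if (up_e) {
      double s = std::exp(ls_e1);
      int acc_sweep = 0;
      for (int i = 0; i < N1; ++i) {
        double prop = e1[i] + R::rnorm(0.0, s);
        double en = eta1[i] + (prop - e1[i]);
        double lr = llk(y1[i], n1[i], en) - llk(y1[i], n1[i], eta1[i]) +
          (e1[i] * e1[i] - prop * prop) / (2.0 * se1 * se1);
        if (it > burn_in) try_e1 += 1;
        if (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr)) {
          e1[i] = prop; eta1[i] = en; acc_sweep += 1;
          if (it > burn_in) acc_e1 += 1;
        }
      }
      if (adapting) ls_e1 += gamma * ((double)acc_sweep / N1 - target_site);
      s = std::exp(ls_e2);
      acc_sweep = 0;
      for (int j = 0; j < N2; ++j) {
        double prop = e2[j] + R::rnorm(0.0, s);
        double en = eta2[j] + (prop - e2[j]);
        double lr = llk(y2[j], n2[j], en) - llk(y2[j], n2[j], eta2[j]) +
          (e2[j] * e2[j] - prop * prop) / (2.0 * se2 * se2);
        if (it > burn_in) try_e2 += 1;
        if (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr)) {
          e2[j] = prop; eta2[j] = en; acc_sweep += 1;
          if (it > burn_in) acc_e2 += 1;
        }
      }
      if (adapting) ls_e2 += gamma * ((double)acc_sweep / N2 - target_site);
    }

    // (iii) regression coefficients: random-walk Metropolis, jointly per level
    if (up_beta) {
      double s = std::exp(ls_b1);
      double d0 = R::rnorm(0.0, s);
      double d1 = up_slope ? R::rnorm(0.0, s) : 0.0;
      double lr = 0.0;
      for (int i = 0; i < N1; ++i) {
        lr += llk(y1[i], n1[i], eta1[i] + d0 + d1 * x1[i]) - llk(y1[i], n1[i], eta1[i]);
      }
      if (up_slope) {
        lr += (b11 * b11 - (b11 + d1) * (b11 + d1)) / (2.0 * slope_sd * slope_sd);
      }
      if (it > burn_in) try_b1 += 1;
      bool acc = lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr);
      if (acc) {
        b01 += d0; b11 += d1;
        for (int i = 0; i < N1; ++i) eta1[i] += d0 + d1 * x1[i];
        if (it > burn_in) acc_b1 += 1;
      }
      if (adapting) ls_b1 += gamma * ((acc ? 1.0 : 0.0) - (up_slope ? target_block : target_site));

      s = std::exp(ls_b2);
      d0 = R::rnorm(0.0, s);
      d1 = up_slope ? R::rnorm(0.0, s) : 0.0;
      lr = 0.0;
      for (int j = 0; j < N2; ++j) {
        lr += llk(y2[j], n2[j], eta2[j] + d0 + d1 * x2[j]) - llk(y2[j], n2[j], eta2[j]);
      }
      if (up_slope) {
        lr += (b12 * b12 - (b12 + d1) * (b12 + d1)) / (2.0 * slope_sd * slope_sd);
      }
      if (it > burn_in) try_b2 += 1;
      acc = lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr);
      if (acc) {
        b02 += d0; b12 += d1;
        for (int j = 0; j < N2; ++j) eta2[j] += d0 + d1 * x2[j];
        if (it > burn_in) acc_b2 += 1;
      }
      if (adapting) ls_b2 += gamma * ((acc ? 1.0 : 0.0) - (up_slope ? target_block : target_site));
    }

    // (iv) standard deviations: random walk on log sigma, uniform prior
    // support (0, sd_upper); the +log(sigma'/sigma) term is the Jacobian.
    // Repeated within the sweep (with the rescale and swap moves below)
    // because the sigma/field geometry mixes more slowly than the rest.
    for (int rep = 0; rep < 3; ++rep) {
    if (up_sigma) {
      struct SigmaUpd { double* sigma; double* ls; double quad; double rank; };
      double q_v1 = icar_quad(v1, adj1_idx, adj1_ptr);
      double q_v2 = icar_quad(v2, adj2_idx, adj2_ptr);
      double q_e1 = sumsq(e1), q_e2 = sumsq(e2);
      SigmaUpd upd[4] = {
        {&sv1, &ls_sv1, q_v1, (double)rank1},
        {&sv2, &ls_sv2, q_v2, (double)rank2},
        {&se1, &ls_se1, q_e1, (double)N1},
        {&se2, &ls_se2, q_e2, (double)N2}
      };
      for (int u = 0; u < 4; ++u) {
        double s = *upd[u].sigma;
        double prop = s * std::exp(R::rnorm(0.0, std::exp(*upd[u].ls)));
        bool acc = false;
        if (prop < sd_upper) {
          double lr = (-upd[u].quad / (2.0 * prop * prop) - upd[u].rank * std::log(prop))
                    - (-upd[u].quad / (2.0 * s * s) - upd[u].rank * std::log(s))
                    + std::log(prop / s);
          acc = lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr);
        }
        if (it > burn_in) { try_s += 1; if (acc) acc_s += 1; }
        if (acc) *upd[u].sigma = prop;
        if (adapting) *upd[u].ls += gamma * ((acc ? 1.0 : 0.0) - target_site);
      }
    }

    // joint rescale moves: (sigma, field) -> (c*sigma, c*field). The prior
    // density is scale-invariant up to -dim*log(c) which cancels against
    // the Jacobian except for a single log(c), so acceptance is the
    // likelihood ratio plus log(c); these moves traverse the ridge between
    // each standard deviation and the magnitude of its field
    if (up_sigma && (up_v || up_e)) {
      for (int m = 0; m < 4; ++m) {
        bool is_v = m < 2;
        if ((is_v && !up_v) || (!is_v && !up_e)) continue;
        int lev = m % 2;  // 0 = fine, 1 = coarse
        NumericVector& f = is_v ? (lev == 0 ? v1 : v2) : (lev == 0 ? e1 : e2);
        double* sig = is_v ? (lev == 0 ? &sv1 : &sv2) : (lev == 0 ? &se1 : &se2);
        int n = lev == 0 ? N1 : N2;
        double c = std::exp(R::rnorm(0.0, std::exp(ls_r[m])));
        double sp = c * (*sig);
        bool acc = false;
        if (sp < sd_upper) {
          double lr = std::log(c);
          if (lev == 0) {
            for (int i = 0; i < N1; ++i) {
              lr += llk(y1[i], n1[i], eta1[i] + (c - 1.0) * f[i]) -
                llk(y1[i], n1[i], eta1[i]);
            }
          } else {
            for (int j = 0; j < N2; ++j) {
              lr += llk(y2[j], n2[j], eta2[j] + (c - 1.0) * f[j]) -
                llk(y2[j], n2[j], eta2[j]);
            }
            if (is_v && shared) {
              for (int i = 0; i < N1; ++i) {
                lr += llk(y1[i], n1[i], eta1[i] + (c - 1.0) * f[parent[i]]) -
                  llk(y1[i], n1[i], eta1[i]);
              }
            }
          }
          acc = lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr);
        }
        if (acc) {
          if (lev == 0) {
            for (int i = 0; i < N1; ++i) eta1[i] += (c - 1.0) * f[i];
          } else {
            for (int j = 0; j < N2; ++j) eta2[j] += (c - 1.0) * f[j];
            if (is_v && shared) {
              for (int i = 0; i < N1; ++i) eta1[i] += (c - 1.0) * f[parent[i]];
            }
          }
          for (int i = 0; i < n; ++i) f[i] *= c;
          *sig = sp;
        }
        if (adapting) ls_r[m] += gamma * ((acc ? 1.0 : 0.0) - target_site);
      }
    }

    // swap moves between the two heterogeneity fields: v_i += t,
    // eps_i -= t leaves the predictor untouched, so acceptance is the
    // prior ratio; this mixes the CH/UH decomposition (and hence the two
    // standard deviations), which single-site updates traverse slowly
    if (up_v && up_e) {
      for (int lev = 0; lev < 2; ++lev) {
        NumericVector& v = lev == 0 ? v1 : v2;
        NumericVector& e = lev == 0 ? e1 : e2;
        const IntegerVector& aidx = lev == 0 ? adj1_idx : adj2_idx;
        const IntegerVector& aptr = lev == 0 ? adj1_ptr : adj2_ptr;
        double sv = lev == 0 ? sv1 : sv2;
        double se = lev == 0 ? se1 : se2;
        int n = lev == 0 ? N1 : N2;
        double s = std::exp(ls_swap[lev]);
        int acc_sweep = 0;
        for (int i = 0; i < n; ++i) {
          double t = R::rnorm(0.0, s);
          int deg = aptr[i + 1] - aptr[i];
          double dq;
          if (deg == 0) {
            dq = 2.0 * t * v[i] + t * t;
          } else {
            double nbsum = 0.0;
            for (int k = aptr[i]; k < aptr[i + 1]; ++k) nbsum += v[aidx[k]];
            dq = 2.0 * t * (deg * v[i] - nbsum) + deg * t * t;
          }
          double lr = -dq / (2.0 * sv * sv)
            - (-2.0 * t * e[i] + t * t) / (2.0 * se * se);
          if (lev == 1 && shared) {
            // v2 also feeds the fine-level predictors (eps2 does not)
            for (size_t c = 0; c < children[i].size(); ++c) {
              int ic = children[i][c];
              lr += llk(y1[ic], n1[ic], eta1[ic] + t) - llk(y1[ic], n1[ic], eta1[ic]);
            }
          }
          if (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr)) {
            v[i] += t; e[i] -= t; acc_sweep += 1;
            if (lev == 1 && shared) {
              for (size_t c = 0; c < children[i].size(); ++c) eta1[children[i][c]] += t;
            }
          }
        }
        if (adapting) ls_swap[lev] += gamma * ((double)acc_sweep / n - target_site);
      }
    }

    }  // end sigma/rescale/swap repeats

    // translation moves along the posterior ridges between the regression
    // coefficients and the random-effect fields: each shifts a coefficient
    // and compensates in eps_k or v_k so the linear predictor (and hence
    // the likelihood) is unchanged except where noted; acceptance is the
    // prior ratio. These interweaving moves leave the posterior invariant
    // and decorrelate beta0k/beta1k from the random-effect means.
    if (up_beta && up_e) {
      // beta0k += delta, eps_k -= delta
      for (int lev = 0; lev < 2; ++lev) {
        double* b0 = lev == 0 ? &b01 : &b02;
        NumericVector& e = lev == 0 ? e1 : e2;
        double se = lev == 0 ? se1 : se2;
        int n = lev == 0 ? N1 : N2;
        double delta = R::rnorm(0.0, std::exp(ls_t[lev]));
        double esum = 0.0;
        for (int i = 0; i < n; ++i) esum += e[i];
        double lr = (2.0 * delta * esum - n * delta * delta) / (2.0 * se * se);
        bool acc = lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr);
        if (acc) {
          *b0 += delta;
          for (int i = 0; i < n; ++i) e[i] -= delta;
        }
        if (adapting) ls_t[lev] += gamma * ((acc ? 1.0 : 0.0) - target_site);
      }
    }
    if (up_beta && up_slope && up_e) {
      // beta1k += delta, eps_k -= delta * x_k
      for (int lev = 0; lev < 2; ++lev) {
        double* b1 = lev == 0 ? &b11 : &b12;
        NumericVector& e = lev == 0 ? e1 : e2;
        const NumericVector& x = lev == 0 ? x1 : x2;
        double se = lev == 0 ? se1 : se2;
        double sx = lev == 0 ? sx1 : sx2;
        int n = lev == 0 ? N1 : N2;
        double delta = R::rnorm(0.0, std::exp(ls_t[2 + lev]));
        double exs = 0.0;
        for (int i = 0; i < n; ++i) exs += e[i] * x[i];
        double lr = (2.0 * delta * exs - delta * delta * sx) / (2.0 * se * se)
          + ((*b1) * (*b1) - (*b1 + delta) * (*b1 + delta))
            / (2.0 * slope_sd * slope_sd);
        bool acc = lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr);
        if (acc) {
          *b1 += delta;
          for (int i = 0; i < n; ++i) e[i] -= delta * x[i];
        }
        if (adapting) ls_t[2 + lev] += gamma * ((acc ? 1.0 : 0.0) - target_site);
      }
    }
    if (up_beta && up_slope && up_v) {
      // beta1k += delta, v_k -= delta * x_k; the covariates are
      // standardized (mean zero) so eta_k is unchanged; in the shared model
      // the level-2 move perturbs the fine-level predictors through the
      // inherited v2 term and picks up that likelihood ratio
      for (int lev = 0; lev < 2; ++lev) {
        double* b1 = lev == 0 ? &b11 : &b12;
        NumericVector& v = lev == 0 ? v1 : v2;
        const NumericVector& x = lev == 0 ? x1 : x2;
        const IntegerVector& aidx = lev == 0 ? adj1_idx : adj2_idx;
        const IntegerVector& aptr = lev == 0 ? adj1_ptr : adj2_ptr;
        double sv = lev == 0 ? sv1 : sv2;
        double qx = lev == 0 ? qx1 : qx2;
        int n = lev == 0 ? N1 : N2;
        double delta = R::rnorm(0.0, std::exp(ls_t[4 + lev]));
        // cross term sum over edges of (v_i - v_j)(x_i - x_j), islands v_i x_i
        double cvx = 0.0;
        for (int i = 0; i < n; ++i) {
          int deg = aptr[i + 1] - aptr[i];
          if (deg == 0) { cvx += v[i] * x[i]; continue; }
          for (int k = aptr[i]; k < aptr[i + 1]; ++k) {
            int j = aidx[k];
            if (j > i) cvx += (v[i] - v[j]) * (x[i] - x[j]);
          }
        }
        double lr = (2.0 * delta * cvx - delta * delta * qx) / (2.0 * sv * sv)
          + ((*b1) * (*b1) - (*b1 + delta) * (*b1 + delta))
            / (2.0 * slope_sd * slope_sd);
        if (lev == 1 && shared) {
          for (int i = 0; i < N1; ++i) {
            double en = eta1[i] - delta * x2[parent[i]];
            lr += llk(y1[i], n1[i], en) - llk(y1[i], n1[i], eta1[i]);
          }
        }
        bool acc = lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr);
        if (acc) {
          *b1 += delta;
          for (int i = 0; i < n; ++i) v[i] -= delta * x[i];
          if (lev == 1 && shared) {
            for (int i = 0; i < N1; ++i) eta1[i] -= delta * x2[parent[i]];
          }
        }
        if (adapting) ls_t[4 + lev] += gamma * ((acc ? 1.0 : 0.0) - target_site);
      }
    }

    // (v) recentring: shift v_k to mean zero, absorbing the shift into the
    // intercept(s); posterior-invariant on island-free graphs
    if (recenter1) {
      double m = Rcpp::mean(v1);
      for (int i = 0; i < N1; ++i) v1[i] -= m;
      b01 += m;
    }
    if (recenter2) {
      double m = Rcpp::mean(v2);
      for (int j = 0; j < N2; ++j) v2[j] -= m;
      b02 += m;
      if (shared) b01 += m;  // v2 also enters every fine-level predictor
    }

    if (it > burn_in && ((it - burn_in - 1) % thin == 0)) {
      double d1s = 0.0, d2s = 0.0;
      for (int i = 0; i < N1; ++i) d1s += llk(y1[i], n1[i], eta1[i]);
      for (int j = 0; j < N2; ++j) d2s += llk(y2[j], n2[j], eta2[j]);
      dev1[ret] = -2.0 * (d1s + lc1);
      dev2[ret] = -2.0 * (d2s + lc2);
      if (!R_finite(dev1[ret]) || !R_finite(dev2[ret])) {
        stop("non-finite deviance at iteration %d", it);
      }
      draws(ret, 0) = b01; draws(ret, 1) = b02;
      draws(ret, 2) = b11; draws(ret, 3) = b12;
      draws(ret, 4) = sv1; draws(ret, 5) = sv2;
      draws(ret, 6) = se1; draws(ret, 7) = se2;
      int off = 8;
      for (int i = 0; i < N1; ++i) draws(ret, off + i) = v1[i];
      off += N1;
      for (int j = 0; j < N2; ++j) draws(ret, off + j) = v2[j];
      off += N2;
      for (int i = 0; i < N1; ++i) draws(ret, off + i) = e1[i];
      off += N1;
      for (int j = 0; j < N2; ++j) draws(ret, off + j) = e2[j];
      ++ret;
    }
  }

  NumericVector acc_rates = NumericVector::create(
    _["v1"] = try_v1 > 0 ? acc_v1 / try_v1 : NA_REAL,
    _["v2"] = try_v2 > 0 ? acc_v2 / try_v2 : NA_REAL,
    _["eps1"] = try_e1 > 0 ? acc_e1 / try_e1 : NA_REAL,
    _["eps2"] = try_e2 > 0 ? acc_e2 / try_e2 : NA_REAL,
    _["beta1"] = try_b1 > 0 ? acc_b1 / try_b1 : NA_REAL,
    _["beta2"] = try_b2 > 0 ? acc_b2 / try_b2 : NA_REAL,
    _["sigma"] = try_s > 0 ? acc_s / try_s : NA_REAL);

  return List::create(
    _["draws"] = draws,
    _["dev1"] = dev1,
    _["dev2"] = dev2,
    _["acceptance"] = acc_rates,
    _["scales"] = NumericVector::create(
      _["eps1"] = std::exp(ls_e1), _["eps2"] = std::exp(ls_e2),
      _["beta1"] = std::exp(ls_b1), _["beta2"] = std::exp(ls_b2),
      _["sigma_v1"] = std::exp(ls_sv1), _["sigma_v2"] = std::exp(ls_sv2),
      _["sigma_eps1"] = std::exp(ls_se1), _["sigma_eps2"] = std::exp(ls_se2)));
}
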
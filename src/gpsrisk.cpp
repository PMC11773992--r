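#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Greedy sequential clustering of fixes: assign each fix (time order) to
// the nearest existing centroid within radius_km, else open a new cluster.
// Centroids are dwell-weighted running means of raw coordinates; with a
// few-hundred-metre radius the planar update is exact to well below GPS
// noise.
// [[Rcpp::export]]
List cluster_greedy_cpp(NumericVector lat, NumericVector lon,
                        NumericVector dwell, double radius_km,
                        double earth_radius_km) {
  int n = lat.size();
  std::vector<double> clat, clon, cw;
  IntegerVector assign(n);
  const double rad = M_PI / 180.0;
  for (int i = 0; i < n; ++i) {
    int best = -1;
    double best_d = radius_km;
    for (size_t k = 0; k < clat.size(); ++k) {
      double dlat = (lat[i] - clat[k]) * rad;
      double dlon = (lon[i] - clon[k]) * rad;
      double a = std::sin(dlat / 2) * std::sin(dlat / 2) +
                 std::cos(lat[i] * rad) * std::cos(clat[k] * rad) *
                     std::sin(dlon / 2) * std::sin(dlon / 2);
      double d = 2.0 * earth_radius_km * std::asin(std::min(1.0, std::sqrt(a)));
      if (d <= best_d) {
        best_d = d;
        best = (int)k;
      }
    }
    double w = dwell[i] > 0 ? dwell[i] : 1e-9;
    if (best < 0) {
      clat.push_back(lat[i]);
      clon.push_back(lon[i]);
      cw.push_back(w);
      assign[i] = (int)clat.size();
    } else {
      double tot = cw[best] + w;
      clat[best] = (clat[best] * cw[best] + lat[i] * w) / tot;
      clon[best] = (clon[best] * cw[best] + lon[i] * w) / tot;
      cw[best] = tot;
      assign[i] = best + 1;
    }
  }
  // report dwell totals (not the tie-break epsilon weights)
  NumericVector tot_dwell(clat.size());
  for (int i = 0; i < n; ++i) tot_dwell[assign[i] - 1] += dwell[i];
  return List::create(_["lat"] = NumericVector(clat.begin(), clat.end()),
                      _["lon"] = NumericVector(clon.begin(), clon.end()),
                      _["dwell"] = tot_dwell, _["assignment"] = assign);
}

// Marginal negative log-likelihood of the random-intercept logistic model,
// integrating each group's likelihood over u ~ N(0, sigma^2) by adaptive
// Gauss-Hermite quadrature centred at the group's posterior mode with
// curvature-based scaling. Groups must be contiguous: grp_start/grp_len are
// 0-based offsets into y / rows of eta0 = X beta (precomputed in R).
//
// log L_i = log sqrt(2) + log tau_i +
//           logsumexp_k [ log w_k + z_k^2 + l_i(u_k) + log phi(u_k; 0, sigma) ]
// with u_k = mu_i + sqrt(2) tau_i z_k, tau_i^2 = -1 / d2/du2 [l_i + log phi].
// [[Rcpp::export]]
double glmm_nll_cpp(NumericVector eta0, NumericVector y,
                    IntegerVector grp_start, IntegerVector grp_len,
                    double sigma, NumericVector gh_z, NumericVector gh_logw) {
  int G = grp_start.size();
  int K = gh_z.size();
  double nll = 0.0;
  const double log_sigma = std::log(sigma);
  const double inv_s2 = 1.0 / (sigma * sigma);
  for (int g = 0; g < G; ++g) {
    int s = grp_start[g], m = grp_len[g];
    // Newton iterations for the posterior mode of u
    double u = 0.0;
    for (int it = 0; it < 50; ++it) {
      double grad = -u * inv_s2, hess = -inv_s2;
      for (int t = 0; t < m; ++t) {
        double e = eta0[s + t] + u;
        double p = 1.0 / (1.0 + std::exp(-e));
        grad += y[s + t] - p;
        hess -= p * (1.0 - p);
      }
      double step = grad / hess;
      u -= step;
      if (std::fabs(step) < 1e-12) break;
    }
    double hess = -inv_s2;
    for (int t = 0; t < m; ++t) {
      double e = eta0[s + t] + u;
      double p = 1.0 / (1.0 + std::exp(-e));
      hess -= p * (1.0 - p);
    }
    double tau = 1.0 / std::sqrt(-hess);
    // adaptive GH sum in log space
    double mx = -INFINITY;
    std::vector<double> terms(K);
    for (int k = 0; k < K; ++k) {
      double uk = u + M_SQRT2 * tau * gh_z[k];
      double ll = 0.0;
      for (int t = 0; t < m; ++t) {
        double e = eta0[s + t] + uk;
        // log p = -log(1+exp(-e)); log(1-p) = -log(1+exp(e))
        ll += y[s + t] > 0.5 ? -std::log1p(std::exp(-e))
                             : -std::log1p(std::exp(e));
      }
      double logphi = -0.5 * std::log(2.0 * M_PI) - log_sigma -
                      0.5 * uk * uk * inv_s2;
      terms[k] = gh_logw[k] + gh_z[k] * gh_z[k] + ll + logphi;
      if (terms[k] > mx) mx = terms[k];
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(terms[k] - mx);
    nll -= 0.5 * std::log(2.0) + std::log(tau) + mx + std::log(sum);
  }
  return nll;
}

// Plain logistic negative log-likelihood (the sigma -> 0 branch).
// [[Rcpp::export]]
double logistic_nll_cpp(NumericVector eta, NumericVector y) {
  double nll = 0.0;
  int n = eta.size();
  for (int i = 0; i < n; ++i) {
    nll += y[i] > 0.5 ? std::log1p(std::exp(-eta[i]))
                      : std::log1p(std::exp(eta[i]));
  }
  return nll;
}

// Marginal nll together with its analytic gradient w.r.t. (beta, log sigma).
// Uses the score identity d/dtheta log L_i = E_posterior[d/dtheta log f(y,u)];
// the posterior expectations are evaluated with the same adaptive
// Gauss-Hermite nodes, so the gradient is exact up to quadrature error.
// [[Rcpp::export]]
List glmm_nll_grad_cpp(NumericMatrix X, NumericVector y,
                       IntegerVector grp_start, IntegerVector grp_len,
                       NumericVector beta, double log_sigma,
                       NumericVector gh_z, NumericVector gh_logw) {
  int G = grp_start.size();
  int K = gh_z.size();
  int p = X.ncol();
  int n = X.nrow();
  double sigma = std::exp(log_sigma);
  const double inv_s2 = 1.0 / (sigma * sigma);
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta0[i] = e;
  }
  double nll = 0.0;
  NumericVector grad(p + 1); // d nll / d beta, d nll / d log sigma
  std::vector<double> terms(K), uks(K);
  for (int g = 0; g < G; ++g) {
    int s = grp_start[g], m = grp_len[g];
    double u = 0.0;
    for (int it = 0; it < 50; ++it) {
      double gr = -u * inv_s2, he = -inv_s2;
      for (int t = 0; t < m; ++t) {
        double e = eta0[s + t] + u;
        double pr = 1.0 / (1.0 + std::exp(-e));
        gr += y[s + t] - pr;
        he -= pr * (1.0 - pr);
      }
      double step = gr / he;
      u -= step;
      if (std::fabs(step) < 1e-12) break;
    }
    double he = -inv_s2;
    for (int t = 0; t < m; ++t) {
      double e = eta0[s + t] + u;
      double pr = 1.0 / (1.0 + std::exp(-e));
      he -= pr * (1.0 - pr);
    }
    double tau = 1.0 / std::sqrt(-he);
    double mx = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double uk = u + M_SQRT2 * tau * gh_z[k];
      uks[k] = uk;
      double ll = 0.0;
      for (int t = 0; t < m; ++t) {
        double e = eta0[s + t] + uk;
        ll += y[s + t] > 0.5 ? -std::log1p(std::exp(-e))
                             : -std::log1p(std::exp(e));
      }
      double logphi = -0.5 * std::log(2.0 * M_PI) - log_sigma -
                      0.5 * uk * uk * inv_s2;
      terms[k] = gh_logw[k] + gh_z[k] * gh_z[k] + ll + logphi;
      if (terms[k] > mx) mx = terms[k];
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(terms[k] - mx);
    nll -= 0.5 * std::log(2.0) + std::log(tau) + mx + std::log(sum);
    // posterior-weighted scores
    double gsig = 0.0;
    for (int k = 0; k < K; ++k) {
      double w = std::exp(terms[k] - mx) / sum;
      if (w < 1e-14) continue;
      double uk = uks[k];
      for (int t = 0; t < m; ++t) {
        double e = eta0[s + t] + uk;
        double pr = 1.0 / (1.0 + std::exp(-e));
        double r = w * (y[s + t] - pr);
        for (int j = 0; j < p; ++j) grad[j] -= r * X(s + t, j);
      }
      gsig -= w * (uk * uk * inv_s2 - 1.0);
    }
    grad[p] += gsig;
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}
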
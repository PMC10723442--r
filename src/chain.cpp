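// Per-gene Metropolis-Hastings / SSVS chain for the grouped-observation
// negative binomial regression. Proposal mechanics mirror the exported R
// operations (mhUpdatePhi, mhUpdateGammaBetaBetween, mhUpdateBetaWithin,
// enforceSumToZero); this is the production path for full-length chains.
//
// State kept incremental: raw linear predictor eta per covered cell, theta =
// exp(clamped eta), per-spot theta sums, and per-spot log-likelihood terms.
// A single-coefficient proposal touches only the cells where its covariate
// column is non-zero and the spots containing them. The NB log pmf is
// evaluated with cached lgamma(y_i + phi) terms, which only change when the
// dispersion moves.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampEta(double e) {
  if (e > 30.0) return 30.0;
  if (e < -30.0) return -30.0;
  return e;
}

// [[Rcpp::export]]
List chain_nb_ssvs(IntegerVector y, NumericVector s, List members,
                   NumericMatrix X, IntegerVector celltype_cols,
                   double a_phi, double b_phi, double sigma_beta_sq,
                   double pi_gamma, int n_iter, int n_burn, int thin,
                   double phi_prop_sd, double beta_prop_sd,
                   bool regularize, bool update_phi, bool prior_only,
                   double phi_init, double beta0_init) {
  const int N = y.size();
  const int Mc = X.nrow();
  const int L = X.ncol();
  const double sb = std::sqrt(sigma_beta_sq);
  const double logodds = std::log(pi_gamma / (1.0 - pi_gamma));

  std::vector<int> cell_spot(Mc, -1);
  std::vector<double> ncell(N, 0.0);
  for (int i = 0; i < N; ++i) {
    IntegerVector m = members[i];
    ncell[i] = m.size();
    if (m.size() == 0) stop("empty spot in membership");
    for (int k = 0; k < m.size(); ++k) cell_spot[m[k]] = i;
  }

  // compressed covariate columns (cell-type dummies are sparse)
  std::vector< std::vector<int> > colnz(L);
  std::vector< std::vector<double> > colval(L);
  for (int l = 0; l < L; ++l) {
    for (int m = 0; m < Mc; ++m) {
      double v = X(m, l);
      if (v != 0.0) {
        colnz[l].push_back(m);
        colval[l].push_back(v);
      }
    }
  }

  std::vector<bool> is_celltype(L, false);
  for (int k = 0; k < celltype_cols.size(); ++k)
    is_celltype[celltype_cols[k]] = true;

  double beta0 = beta0_init, phi = phi_init;
  std::vector<double> beta(L, 0.0);
  std::vector<int> gamma(L, regularize ? 0 : 1);
  std::vector<double> eta(Mc), theta(Mc), spotSum(N), ll(N);
  double llTot = 0.0;

  // NB log-pmf caches: lgamma(y+1) is fixed; lgamma(y+phi) and lgamma(phi)
  // follow the current dispersion
  std::vector<double> lgy1(N), lgyphi(N);
  double lgphi = std::lgamma(phi);
  for (int i = 0; i < N; ++i) {
    lgy1[i] = std::lgamma((double)y[i] + 1.0);
    lgyphi[i] = std::lgamma((double)y[i] + phi);
  }

  auto llTermCached = [&](int i, double ssum) -> double {
    if (prior_only) return 0.0;
    double mu = s[i] * ssum / ncell[i];
    return lgyphi[i] - lgy1[i] - lgphi +
      phi * std::log(phi / (mu + phi)) +
      (double)y[i] * std::log(mu / (mu + phi));
  };

  auto llTermPhi = [&](int i, double ph, double lgyph_i, double lgph,
                       double ssum) -> double {
    if (prior_only) return 0.0;
    double mu = s[i] * ssum / ncell[i];
    return lgyph_i - lgy1[i] - lgph +
      ph * std::log(ph / (mu + ph)) +
      (double)y[i] * std::log(mu / (mu + ph));
  };

  auto recomputeAll = [&]() {
    for (int m = 0; m < Mc; ++m) eta[m] = beta0;
    for (int l = 0; l < L; ++l)
      if (beta[l] != 0.0) {
        const std::vector<int>& nz = colnz[l];
        const std::vector<double>& xv = colval[l];
        for (size_t k = 0; k < nz.size(); ++k)
          eta[nz[k]] += beta[l] * xv[k];
      }
    for (int m = 0; m < Mc; ++m) theta[m] = std::exp(clampEta(eta[m]));
    std::fill(spotSum.begin(), spotSum.end(), 0.0);
    for (int m = 0; m < Mc; ++m) spotSum[cell_spot[m]] += theta[m];
    llTot = 0.0;
    for (int i = 0; i < N; ++i) {
      ll[i] = llTermCached(i, spotSum[i]);
      llTot += ll[i];
    }
  };
  recomputeAll();
  if (!std::isfinite(llTot))
    stop("non-finite log-posterior at initialization");

  std::vector<double> newTheta(Mc), newSpotSum(N), newLl(N), newLgyphi(N);
  std::vector<int> touched;
  touched.reserve(N);
  std::vector<char> isTouched(N, 0);
  std::vector<int> allRows(Mc);
  std::vector<double> allOnes(Mc, 1.0);
  for (int m = 0; m < Mc; ++m) allRows[m] = m;

  int nonfinite_rejects = 0;

  // stage a delta on coefficient l (-1 = intercept); returns delta loglik
  auto proposeCoef = [&](double delta, const std::vector<int>& affected,
                         const std::vector<double>& xval) -> double {
    touched.clear();
    for (size_t k = 0; k < affected.size(); ++k) {
      int m = affected[k];
      double th = std::exp(clampEta(eta[m] + delta * xval[k]));
      newTheta[m] = th;
      int i = cell_spot[m];
      if (!isTouched[i]) {
        isTouched[i] = 1;
        touched.push_back(i);
        newSpotSum[i] = spotSum[i];
      }
      newSpotSum[i] += th - theta[m];
    }
    double dll = 0.0;
    for (size_t k = 0; k < touched.size(); ++k) {
      int i = touched[k];
      newLl[i] = llTermCached(i, newSpotSum[i]);
      dll += newLl[i] - ll[i];
    }
    return dll;
  };

  auto commitCoef = [&](double delta, const std::vector<int>& affected,
                        const std::vector<double>& xval) {
    for (size_t k = 0; k < affected.size(); ++k) {
      int m = affected[k];
      eta[m] += delta * xval[k];
      theta[m] = newTheta[m];
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      int i = touched[k];
      llTot += newLl[i] - ll[i];
      spotSum[i] = newSpotSum[i];
      ll[i] = newLl[i];
    }
  };

  auto clearTouched = [&]() {
    for (size_t k = 0; k < touched.size(); ++k) isTouched[touched[k]] = 0;
  };

  auto shuffleIdx = [&](std::vector<int>& v) {
    for (int k = (int)v.size() - 1; k > 0; --k) {
      int j = (int)std::floor(R::unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(v[k], v[j]);
    }
  };

  int U = (n_iter > n_burn) ? (n_iter - n_burn) / thin : 0;
  NumericVector out_beta0(U), out_phi(U);
  NumericMatrix out_beta(U, L);
  IntegerMatrix out_gamma(U, L);

  int acc_phi = 0, try_phi = 0, acc_bet = 0, try_bet = 0,
      acc_wit = 0, try_wit = 0;
  std::vector<int> perm(L), act;
  act.reserve(L + 1);

  int u = 0;
  for (int it = 0; it < n_iter; ++it) {
    // 1. dispersion: random walk on log(phi) with Jacobian
    if (update_phi) {
      ++try_phi;
      double phiNew = std::exp(std::log(phi) + R::norm_rand() * phi_prop_sd);
      double lgphiNew = std::lgamma(phiNew);
      double dll = 0.0;
      bool ok = true;
      for (int i = 0; i < N; ++i) {
        newLgyphi[i] = std::lgamma((double)y[i] + phiNew);
        newLl[i] = llTermPhi(i, phiNew, newLgyphi[i], lgphiNew, spotSum[i]);
        if (!std::isfinite(newLl[i])) { ok = false; break; }
        dll += newLl[i] - ll[i];
      }
      if (ok) {
        double la = dll +
          (a_phi - 1.0) * (std::log(phiNew) - std::log(phi)) -
          b_phi * (phiNew - phi) +
          (std::log(phiNew) - std::log(phi));
        if (std::isfinite(la) && std::log(R::unif_rand()) < la) {
          phi = phiNew;
          lgphi = lgphiNew;
          llTot += dll;
          for (int i = 0; i < N; ++i) {
            ll[i] = newLl[i];
            lgyphi[i] = newLgyphi[i];
          }
          ++acc_phi;
        }
      } else {
        ++nonfinite_rejects;
      }
    }

    // 2. between-model add/delete for every selectable covariate
    if (regularize && L > 0) {
      for (int l = 0; l < L; ++l) perm[l] = l;
      shuffleIdx(perm);
      for (int k = 0; k < L; ++k) {
        int l = perm[k];
        ++try_bet;
        if (gamma[l] == 0) {
          double bnew = R::norm_rand() * sb;  // slab draw; slab cancels
          double dll = proposeCoef(bnew, colnz[l], colval[l]);
          double la = dll + logodds;
          if (std::isfinite(la) && std::log(R::unif_rand()) < la) {
            commitCoef(bnew, colnz[l], colval[l]);
            gamma[l] = 1;
            beta[l] = bnew;
            ++acc_bet;
          } else if (!std::isfinite(la)) ++nonfinite_rejects;
        } else {
          double dll = proposeCoef(-beta[l], colnz[l], colval[l]);
          double la = dll - logodds;
          if (std::isfinite(la) && std::log(R::unif_rand()) < la) {
            commitCoef(-beta[l], colnz[l], colval[l]);
            gamma[l] = 0;
            beta[l] = 0.0;
            ++acc_bet;
          } else if (!std::isfinite(la)) ++nonfinite_rejects;
        }
        clearTouched();
      }
    }

    // 3. within-model random walk for the intercept and active covariates
    act.clear();
    act.push_back(-1);
    for (int l = 0; l < L; ++l) if (gamma[l] == 1) act.push_back(l);
    shuffleIdx(act);
    for (size_t k = 0; k < act.size(); ++k) {
      int l = act[k];
      ++try_wit;
      double delta = R::norm_rand() * beta_prop_sd;
      const std::vector<int>& aff = (l < 0) ? allRows : colnz[l];
      const std::vector<double>& xv = (l < 0) ? allOnes : colval[l];
      double dll = proposeCoef(delta, aff, xv);
      double cur = (l < 0) ? beta0 : beta[l];
      double la = dll + R::dnorm(cur + delta, 0.0, sb, 1) -
        R::dnorm(cur, 0.0, sb, 1);
      if (std::isfinite(la) && std::log(R::unif_rand()) < la) {
        commitCoef(delta, aff, xv);
        if (l < 0) beta0 += delta; else beta[l] += delta;
        ++acc_wit;
      } else if (!std::isfinite(la)) ++nonfinite_rejects;
      clearTouched();
    }

    // 4. sum-to-zero re-centering of active cell-type coefficients.
    // Applied only when every cell type present among the covered cells is
    // active: then each cell's dummy contribution drops by the mean while
    // the intercept gains it, so the move is exactly likelihood-invariant.
    // With a partially active type set the state is identified without the
    // constraint and re-centering would perturb the posterior.
    {
      bool invariant = true;
      for (int l = 0; l < L; ++l)
        if (is_celltype[l] && !colnz[l].empty() && gamma[l] == 0) {
          invariant = false;
          break;
        }
      double ctr = 0.0;
      int nact = 0;
      for (int l = 0; l < L; ++l)
        if (is_celltype[l] && gamma[l] == 1) { ctr += beta[l]; ++nact; }
      if (invariant && nact > 0 && ctr != 0.0) {
        // every covered cell carries exactly one active dummy, so its
        // linear predictor is unchanged; eta/theta/ll need no update
        ctr /= nact;
        for (int l = 0; l < L; ++l)
          if (is_celltype[l] && gamma[l] == 1) beta[l] -= ctr;
        beta0 += ctr;
      }
    }

    if (it >= n_burn && ((it - n_burn + 1) % thin) == 0 && u < U) {
      out_beta0[u] = beta0;
      out_phi[u] = phi;
      for (int l = 0; l < L; ++l) {
        out_beta(u, l) = beta[l];
        out_gamma(u, l) = gamma[l];
      }
      ++u;
    }
  }

  return List::create(
    _["beta0"] = out_beta0, _["beta"] = out_beta,
    _["gamma"] = out_gamma, _["phi"] = out_phi,
    _["diagnostics"] = List::create(
      _["accept_phi"] = try_phi ? (double)acc_phi / try_phi : NA_REAL,
      _["accept_between"] = try_bet ? (double)acc_bet / try_bet : NA_REAL,
      _["accept_within"] = try_wit ? (double)acc_wit / try_wit : NA_REAL,
      _["nonfinite_rejects"] = nonfinite_rejects));
}
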
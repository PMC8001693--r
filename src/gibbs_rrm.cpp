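// Single-site Gibbs sampler for the Legendre random regression model
//   y = X b + H q + Z a + W p + e
// Location effects are sampled level-by-level from their conditional
// normals (residual-update scheme); coefficient covariance matrices from
// inverted Wishart full conditionals; the residual variance from a scaled
// inverted chi-squared. All draws use the R RNG so set.seed() governs the
// whole chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat rwishart_bartlett(double df, const arma::mat& L) {
  // W ~ Wishart(df, L L') via the Bartlett decomposition
  const int k = L.n_rows;
  arma::mat A(k, k, arma::fill::zeros);
  for (int i = 0; i < k; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat riwish(double df, const arma::mat& V, int iter) {
  // Sigma ~ IW(df, V): draw W ~ Wishart(df, V^{-1}) and invert
  arma::mat Vinv, R;
  if (!arma::inv_sympd(Vinv, arma::symmatu(V)))
    stop("non-PSD inverted Wishart scale matrix at iteration %d", iter + 1);
  if (!arma::chol(R, Vinv))
    stop("inverted Wishart scale not positive definite at iteration %d",
         iter + 1);
  arma::mat W = rwishart_bartlett(df, R.t());
  arma::mat S;
  if (!arma::inv_sympd(S, arma::symmatu(W)))
    stop("singular Wishart draw at iteration %d", iter + 1);
  return arma::symmatu(S);
}

struct LevelGroup {
  // records grouped by level (CSR layout) with the constant per-level
  // Phi'Phi cross-products
  std::vector<int> ptr, idx;
  std::vector<arma::mat> ss;
  void build(const arma::ivec& lev, int nlev, const arma::mat& phiT) {
    const int k = phiT.n_rows;
    std::vector<int> count(nlev, 0);
    for (arma::uword r = 0; r < lev.n_elem; ++r) ++count[lev[r] - 1];
    ptr.assign(nlev + 1, 0);
    for (int l = 0; l < nlev; ++l) ptr[l + 1] = ptr[l] + count[l];
    idx.assign(lev.n_elem, 0);
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (arma::uword r = 0; r < lev.n_elem; ++r) idx[fill[lev[r] - 1]++] = r;
    ss.assign(nlev, arma::mat(k, k, arma::fill::zeros));
    for (int l = 0; l < nlev; ++l)
      for (int j = ptr[l]; j < ptr[l + 1]; ++j)
        ss[l] += phiT.col(idx[j]) * phiT.col(idx[j]).t();
  }
};

// draw from N(C^{-1} r, C^{-1}); overwrites r with the draw.
// Hand-rolled lower Cholesky + triangular solves: the conditional
// dimension is tiny (<= 2 * 16 for the joint animal/PE block), so stack
// buffers beat LAPACK dispatch.
#define LONGRRM_MAX_K 32
static void mvn_from_precision(const arma::mat& C, arma::vec& r, int iter) {
  const int k = C.n_rows;
  double L[LONGRRM_MAX_K * LONGRRM_MAX_K];
  double w[LONGRRM_MAX_K];
  // C = L L', L lower (column-major in k x k buffer)
  for (int j = 0; j < k; ++j) {
    double diag = C(j, j);
    for (int m = 0; m < j; ++m) diag -= L[j + m * k] * L[j + m * k];
    if (diag <= 0.0)
      stop("non-PD conditional precision at iteration %d", iter + 1);
    const double dj = std::sqrt(diag);
    L[j + j * k] = dj;
    for (int i = j + 1; i < k; ++i) {
      double s = C(i, j);
      for (int m = 0; m < j; ++m) s -= L[i + m * k] * L[j + m * k];
      L[i + j * k] = s / dj;
    }
  }
  // mean = C^{-1} r: forward then backward solve
  for (int i = 0; i < k; ++i) {
    double s = r[i];
    for (int m = 0; m < i; ++m) s -= L[i + m * k] * w[m];
    w[i] = s / L[i + i * k];
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = w[i];
    for (int m = i + 1; m < k; ++m) s -= L[m + i * k] * r[m];
    r[i] = s / L[i + i * k];
  }
  // add L'^{-1} z, z ~ N(0, I)
  for (int i = 0; i < k; ++i) w[i] = R::rnorm(0.0, 1.0);
  for (int i = k - 1; i >= 0; --i) {
    double s = w[i];
    for (int m = i + 1; m < k; ++m) s -= L[m + i * k] * w[m];
    w[i] = s / L[i + i * k];
    r[i] += w[i];
  }
}

// sample all levels of one iid-prior regression effect, updating e in place
static void sample_group(arma::mat& u, const LevelGroup& g,
                         const arma::mat& phiT, arma::vec& e,
                         const arma::mat& prior_prec, double sigma_e2,
                         int iter) {
  const int nlev = u.n_rows;
  const int k = phiT.n_rows;
  arma::vec r(k), d(k);
  const double* px = phiT.memptr();
  double* ex = e.memptr();
  for (int l = 0; l < nlev; ++l) {
    arma::vec uold = u.row(l).t();
    r.zeros();
    for (int j = g.ptr[l]; j < g.ptr[l + 1]; ++j) {
      const int rr = g.idx[j];
      const double* c = px + (size_t)rr * k;
      const double ev = ex[rr];
      for (int m = 0; m < k; ++m) r[m] += c[m] * ev;
    }
    r = (r + g.ss[l] * uold) / sigma_e2;
    arma::mat C = g.ss[l] / sigma_e2 + prior_prec;
    mvn_from_precision(C, r, iter);
    d = r - uold;
    for (int j = g.ptr[l]; j < g.ptr[l + 1]; ++j) {
      const int rr = g.idx[j];
      const double* c = px + (size_t)rr * k;
      double acc = 0.0;
      for (int m = 0; m < k; ++m) acc += c[m] * d[m];
      ex[rr] -= acc;
    }
    u.row(l) = r.t();
  }
}

// [[Rcpp::export(name = ".gibbs_rrm_cpp")]]
List gibbs_rrm_cpp(const arma::vec& y,
                   const arma::mat& phi,        // n x k record covariates
                   const arma::ivec& ys, int n_ys,
                   const arma::vec& et,
                   const arma::ivec& hys, int n_hys,
                   const arma::ivec& anim, int n_anim,
                   const arma::ivec& pe, int n_pe,
                   const arma::ivec& pe_anim,   // animal index per PE level
                   const arma::ivec& Ai, const arma::ivec& Ap,
                   const arma::vec& Ax,
                   List priors, List init, List chain, List control) {
  const int n = y.n_elem;
  const int k = phi.n_cols;
  if (2 * k > LONGRRM_MAX_K)
    stop("at most %d coefficients per effect supported", LONGRRM_MAX_K / 2);
  const arma::mat phiT = phi.t();              // k x n, contiguous columns
  const double sigma_b = as<double>(priors["sigma_b"]);
  const double nu_g = as<double>(priors["nu_g"]);
  const double nu_q = as<double>(priors["nu_q"]);
  const double nu_p = as<double>(priors["nu_p"]);
  const arma::mat Vg = as<arma::mat>(priors["V_g"]);
  const arma::mat Vq = as<arma::mat>(priors["V_q"]);
  const arma::mat Vp = as<arma::mat>(priors["V_p"]);
  const double nu_e = as<double>(priors["nu_e"]);
  const double s2_e = as<double>(priors["s2_e"]);

  arma::mat G0 = as<arma::mat>(init["G0"]);
  arma::mat Rq = as<arma::mat>(init["Rq"]);
  arma::mat Rp = as<arma::mat>(init["Rp"]);
  double sigma_e2 = as<double>(init["sigma_e2"]);

  const int n_iter = as<int>(chain["length"]);
  const int burn_in = as<int>(chain["burn_in"]);
  const int thin = as<int>(chain["thin"]);
  const bool upd_loc = as<bool>(control["update_locations"]);
  const bool upd_g = as<bool>(control["update_g"]);
  const bool upd_q = as<bool>(control["update_q"]);
  const bool upd_p = as<bool>(control["update_p"]);
  const bool upd_e = as<bool>(control["update_e"]);
  const bool store_loc = as<bool>(control["store_locations"]);

  LevelGroup g_ys, g_hys, g_anim, g_pe;
  g_ys.build(ys, n_ys, phiT);
  g_hys.build(hys, n_hys, phiT);
  g_anim.build(anim, n_anim, phiT);
  g_pe.build(pe, n_pe, phiT);
  double ss_et = arma::dot(et, et);
  std::vector<int> anim_pe(n_anim, -1);   // PE level of each animal, if any
  for (int l = 0; l < n_pe; ++l) {
    if (pe_anim[l] < 1 || pe_anim[l] > n_anim)
      stop("pe_anim maps outside the pedigree");
    anim_pe[pe_anim[l] - 1] = l;
  }

  arma::mat bys(n_ys, k, arma::fill::zeros);
  double bet = 0.0;
  arma::mat q(n_hys, k, arma::fill::zeros);
  arma::mat a(n_anim, k, arma::fill::zeros);
  arma::mat p(n_pe, k, arma::fill::zeros);
  arma::vec e = y;

  const int n_save = (n_iter - burn_in) / thin;
  const int kk = k * (k + 1) / 2;
  arma::mat dG(n_save, kk), dQ(n_save, kk), dP(n_save, kk);
  arma::vec dE(n_save);
  const int n_loc = n_ys * k + 1 + n_hys * k + n_anim * k + n_pe * k;
  arma::vec loc_sum(n_loc, arma::fill::zeros);
  arma::mat loc_draws;
  if (store_loc) loc_draws.set_size(n_save, n_loc);

  arma::mat G0inv = arma::inv_sympd(arma::symmatu(G0));
  arma::mat Rqinv = arma::inv_sympd(arma::symmatu(Rq));
  arma::mat Rpinv = arma::inv_sympd(arma::symmatu(Rp));
  arma::mat ridge = arma::eye(k, k) / sigma_b;
  arma::mat Ga = a * G0inv;                    // cached G0^{-1} a_j rows

  int isave = 0;
  long swap_prop = 0, swap_acc = 0;
  arma::vec r(k), d(k), unew(k);
  const double* px = phiT.memptr();
  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    if (upd_loc) {
      // fixed year-season-of-birth regressions (vague normal prior)
      sample_group(bys, g_ys, phiT, e, ridge, sigma_e2, it);
      { // embryo-transfer covariate (scalar)
        double c = ss_et / sigma_e2 + 1.0 / sigma_b;
        double rr = (arma::dot(et, e) + ss_et * bet) / sigma_e2;
        double bnew = rr / c + R::rnorm(0.0, 1.0) / std::sqrt(c);
        if (ss_et > 0.0) e -= et * (bnew - bet);
        bet = bnew;
      }
      sample_group(q, g_hys, phiT, e, Rqinv, sigma_e2, it);
      // Additive genetic effects: prior precision A^{-1} (x) G0^{-1}.
      // Animals with their own records are sampled JOINTLY with their
      // permanent-environment vector (one 2k block per cow): the two
      // effects share the same record covariates, so their conditional is
      // a long ridge that single-site scans traverse extremely slowly.
      double* ex = e.memptr();
      for (int i = 0; i < n_anim; ++i) {
        if (anim_pe[i] >= 0) continue;    // handled in the joint block below
        arma::vec uold = a.row(i).t();
        r.zeros();
        for (int j = g_anim.ptr[i]; j < g_anim.ptr[i + 1]; ++j) {
          const int rr = g_anim.idx[j];
          const double* c = px + (size_t)rr * k;
          const double ev = ex[rr];
          for (int m = 0; m < k; ++m) r[m] += c[m] * ev;
        }
        r = (r + g_anim.ss[i] * uold) / sigma_e2;
        double aii = 0.0;
        for (int idx = Ap[i]; idx < Ap[i + 1]; ++idx) {
          const int j = Ai[idx];
          if (j == i) { aii = Ax[idx]; continue; }
          const double v = Ax[idx];
          for (int m = 0; m < k; ++m) r[m] -= v * Ga(j, m);
        }
        arma::mat C = g_anim.ss[i] / sigma_e2 + aii * G0inv;
        mvn_from_precision(C, r, it);
        d = r - uold;
        for (int j = g_anim.ptr[i]; j < g_anim.ptr[i + 1]; ++j) {
          const int rr = g_anim.idx[j];
          const double* c = px + (size_t)rr * k;
          double acc = 0.0;
          for (int m = 0; m < k; ++m) acc += c[m] * d[m];
          ex[rr] -= acc;
        }
        a.row(i) = r.t();
        Ga.row(i) = a.row(i) * G0inv;
      }
      { // joint (a_i, p_l) blocks for recorded cows
        arma::vec r2(2 * k), d2(2 * k), w(k);
        for (int l = 0; l < n_pe; ++l) {
          const int i = pe_anim[l] - 1;
          arma::vec aold = a.row(i).t();
          arma::vec pold = p.row(l).t();
          w.zeros();
          for (int j = g_pe.ptr[l]; j < g_pe.ptr[l + 1]; ++j) {
            const int rr = g_pe.idx[j];
            const double* c = px + (size_t)rr * k;
            const double ev = ex[rr];
            for (int m = 0; m < k; ++m) w[m] += c[m] * ev;
          }
          arma::vec sum_old = g_pe.ss[l] * (aold + pold);
          for (int m = 0; m < k; ++m) {
            r2[m] = (w[m] + sum_old[m]) / sigma_e2;
            r2[k + m] = r2[m];
          }
          double aii = 0.0;
          for (int idx = Ap[i]; idx < Ap[i + 1]; ++idx) {
            const int j = Ai[idx];
            if (j == i) { aii = Ax[idx]; continue; }
            const double v = Ax[idx];
            for (int m = 0; m < k; ++m) r2[m] -= v * Ga(j, m);
          }
          arma::mat C2(2 * k, 2 * k);
          arma::mat Sdat = g_pe.ss[l] / sigma_e2;
          C2.submat(0, 0, k - 1, k - 1) = Sdat + aii * G0inv;
          C2.submat(0, k, k - 1, 2 * k - 1) = Sdat;
          C2.submat(k, 0, 2 * k - 1, k - 1) = Sdat;
          C2.submat(k, k, 2 * k - 1, 2 * k - 1) = Sdat + Rpinv;
          mvn_from_precision(C2, r2, it);
          for (int m = 0; m < k; ++m) {
            d2[m] = r2[m] - aold[m];
            d2[k + m] = r2[k + m] - pold[m];
          }
          for (int j = g_pe.ptr[l]; j < g_pe.ptr[l + 1]; ++j) {
            const int rr = g_pe.idx[j];
            const double* c = px + (size_t)rr * k;
            double acc = 0.0;
            for (int m = 0; m < k; ++m) acc += c[m] * (d2[m] + d2[k + m]);
            ex[rr] -= acc;
          }
          for (int m = 0; m < k; ++m) {
            a(i, m) = r2[m];
            p(l, m) = r2[k + m];
          }
          Ga.row(i) = a.row(i) * G0inv;
        }
      }
    }

    // Scale-swap Metropolis move between the additive and permanent
    // environment blocks: proposes (a, G0) -> (sqrt(c) a, c G0) and
    // (p, Rp) -> (sqrt(d) p, d Rp) jointly. The additive and PE curves are
    // confounded at the cow level, so the conjugate alternation walks the
    // G0/Rp ridge extremely slowly; this move travels along it. The
    // acceptance ratio is exact (prior x likelihood x Jacobian); the
    // Gaussian effect prior cancels against its own rescaled covariance.
    if (upd_loc && upd_g && upd_p && n_pe > 0 && n > 0) {
      // per-coefficient scales: columns 0..k-1 additive, k..2k-1 PE
      const int K2 = 2 * k;
      arma::mat G(n, K2, arma::fill::zeros);
      for (int rr = 0; rr < n; ++rr) {
        const double* c = px + (size_t)rr * k;
        const int ia = anim[rr] - 1, ip = pe[rr] - 1;
        for (int m = 0; m < k; ++m) {
          G(rr, m) = c[m] * a(ia, m);
          G(rr, k + m) = c[m] * p(ip, m);
        }
      }
      arma::mat Mg = G.t() * G;              // 2k x 2k Gram matrix
      arma::vec ge = G.t() * e;
      double See = arma::dot(e, e);
      arma::mat G0cur = G0, Rpcur = Rp;
      arma::vec cum(K2, arma::fill::ones);
      const double tau = as<double>(control["swap_tau"]);
      const int n_moves = as<int>(control["swap_moves"]);
      for (int mv = 0; mv < n_moves; ++mv) {
        // one coefficient at a time, anti-correlated between the additive
        // and PE sides: the move travels along the confounded direction
        // (additive up, permanent environment down) where the likelihood
        // penalty is smallest
        arma::vec cs(K2, arma::fill::ones), s(K2, arma::fill::zeros);
        const int mm = (int)std::floor(R::runif(0.0, 1.0) * k);
        const double delta = R::rnorm(0.0, tau);
        cs[mm] = std::exp(delta);
        cs[k + mm] = std::exp(-delta);
        s[mm] = std::sqrt(cs[mm]) - 1.0;
        s[k + mm] = std::sqrt(cs[k + mm]) - 1.0;
        const double SSEp = See - 2.0 * arma::dot(s, ge) +
          arma::as_scalar(s.t() * Mg * s);
        arma::vec da = arma::sqrt(cs.subvec(0, k - 1));
        arma::vec dp = arma::sqrt(cs.subvec(k, K2 - 1));
        arma::mat G0p = G0cur % (da * da.t());
        arma::mat Rpp = Rpcur % (dp * dp.t());
        arma::mat G0pinv, Rppinv;
        if (!arma::inv_sympd(G0pinv, arma::symmatu(G0p))) continue;
        if (!arma::inv_sympd(Rppinv, arma::symmatu(Rpp))) continue;
        double logA = (See - SSEp) / (2.0 * sigma_e2);
        for (int m = 0; m < k; ++m)
          logA += -0.5 * nu_g * std::log(cs[m]) - 0.5 * nu_p * std::log(cs[k + m]);
        logA += -0.5 * (arma::accu(Vg % G0pinv) -
                        arma::accu(Vg % arma::inv_sympd(arma::symmatu(G0cur))));
        logA += -0.5 * (arma::accu(Vp % Rppinv) -
                        arma::accu(Vp % arma::inv_sympd(arma::symmatu(Rpcur))));
        ++swap_prop;
        if (std::log(R::runif(0.0, 1.0)) < logA) {
          ++swap_acc;
          // e' = e - G s; then G' = G diag(sqrt(c))
          ge = ge - Mg * s;
          arma::vec rt = arma::sqrt(cs);
          ge %= rt;
          Mg = Mg % (rt * rt.t());
          See = SSEp;
          G0cur = G0p; Rpcur = Rpp;
          cum %= cs;
        }
      }
      if (arma::any(cum != 1.0)) {
        arma::vec scum = arma::sqrt(cum) - 1.0;
        e -= G * scum;                       // telescoped with original G
        for (int m = 0; m < k; ++m) {
          a.col(m) *= std::sqrt(cum[m]);
          p.col(m) *= std::sqrt(cum[k + m]);
        }
        G0 = G0cur; Rp = Rpcur;
        G0inv = arma::inv_sympd(arma::symmatu(G0));
        Rpinv = arma::inv_sympd(arma::symmatu(Rp));
        Ga = a * G0inv;
      }
    }

    if (upd_g) {
      arma::mat S(k, k, arma::fill::zeros);
      for (int j = 0; j < n_anim; ++j)
        for (int idx = Ap[j]; idx < Ap[j + 1]; ++idx)
          S += Ax[idx] * (a.row(Ai[idx]).t() * a.row(j));
      G0 = riwish(nu_g + n_anim, Vg + arma::symmatu(S), it);
      G0inv = arma::inv_sympd(G0);
      Ga = a * G0inv;
    }
    if (upd_q) {
      Rq = riwish(nu_q + n_hys, Vq + q.t() * q, it);
      Rqinv = arma::inv_sympd(Rq);
    }
    if (upd_p) {
      Rp = riwish(nu_p + n_pe, Vp + p.t() * p, it);
      Rpinv = arma::inv_sympd(Rp);
    }
    if (upd_e) {
      double sse = arma::dot(e, e);
      sigma_e2 = (nu_e * s2_e + sse) / R::rchisq(nu_e + n);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && isave < n_save) {
      int c = 0;
      for (int i = 0; i < k; ++i)
        for (int j = i; j < k; ++j, ++c) {
          dG(isave, c) = G0(i, j);
          dQ(isave, c) = Rq(i, j);
          dP(isave, c) = Rp(i, j);
        }
      dE(isave) = sigma_e2;
      arma::vec loc(n_loc);
      int off = 0;
      for (int i = 0; i < n_ys; ++i, off += k)
        loc.subvec(off, off + k - 1) = bys.row(i).t();
      loc(off++) = bet;
      for (int i = 0; i < n_hys; ++i, off += k)
        loc.subvec(off, off + k - 1) = q.row(i).t();
      for (int i = 0; i < n_anim; ++i, off += k)
        loc.subvec(off, off + k - 1) = a.row(i).t();
      for (int i = 0; i < n_pe; ++i, off += k)
        loc.subvec(off, off + k - 1) = p.row(i).t();
      loc_sum += loc;
      if (store_loc) loc_draws.row(isave) = loc.t();
      ++isave;
    }
  }

  List out = List::create(
    _["G0"] = dG, _["Rq"] = dQ, _["Rp"] = dP, _["sigma_e2"] = dE,
    _["location_mean"] = loc_sum / std::max(1, isave),
    _["n_saved"] = isave,
    _["swap_acceptance"] = swap_prop > 0 ?
      (double)swap_acc / (double)swap_prop : NA_REAL);
  if (store_loc) out["location_draws"] = loc_draws;
  return out;
}
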
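// Blocked Gibbs sampler for the two-level residual DSEM.
//
// Model, on the rescaled analysis metric, outcomes v = 1..3:
//   y_{vit} = alpha_{vi} + beta_{vi} * t_years + eps_{vit}
//   eps_{it} = Phi eps_{i,t-1} + u_{it},  u_{it} ~ N(0, Sigma_u)
//   eps_{i1} ~ N(0, Sigma_eps)  with  vec(Sigma_eps) = (I - Phi (x) Phi)^{-1} vec(Sigma_u)
//   (alpha_i, beta_i) = Delta' x_i + b_i,  b_i ~ N(0, blockdiag(Sigma_b, diag(s2_trend)))
//
// Data augmentation: missing/phantom cells of y and the latent (alpha_i, beta_i)
// are sampled from their Gaussian full conditionals.  Phi and Sigma_u use
// Metropolis-within-Gibbs with the conjugate transition-only conditional as an
// independence proposal; the stationary initial-occasion terms enter the
// acceptance ratio, so the sampler targets the exact joint posterior including
// the stationary initial density.  All randomness comes from R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat lyap3(const mat& phi, const mat& su) {
  mat K = eye(9, 9) - kron(phi, phi);
  vec v = solve(K, vectorise(su));
  mat S = reshape(v, 3, 3);
  return 0.5 * (S + S.t());
}

static double spec_radius(const mat& phi) {
  cx_vec ev = eig_gen(phi);
  return max(abs(ev));
}

static vec rnorm_vec(uword n) {
  vec z(n);
  for (uword j = 0; j < n; ++j) z(j) = R::norm_rand();
  return z;
}

// x ~ N(P^{-1} h, P^{-1}) with P = R'R (R upper triangular, precomputed)
static vec draw_gauss_chol(const mat& R, const vec& h) {
  vec mu = solve(trimatu(R), solve(trimatl(R.t()), h));
  return mu + solve(trimatu(R), rnorm_vec(h.n_elem));
}

static vec draw_gauss_prec(const mat& P, const vec& h) {
  mat R = chol(symmatu(P));
  return draw_gauss_chol(R, h);
}

// inverse-Wishart(df, S) via Bartlett decomposition, using R's RNG
static mat riwish(double df, const mat& S) {
  const uword d = S.n_rows;
  mat L = chol(symmatu(inv_sympd(symmatu(S))), "lower");
  mat A(d, d, fill::zeros);
  for (uword i = 0; i < d; ++i) A(i, i) = std::sqrt(R::rchisq(df - i));
  for (uword i = 1; i < d; ++i)
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  mat W = L * A;
  return inv_sympd(symmatu(W * W.t()));
}

// sum over persons of log N(eps_{i1}; 0, Sigma_eps), C1 = sum eps_1 eps_1'
static double loglik_init(const mat& se, const mat& C1, double N) {
  double ld, sgn;
  log_det(ld, sgn, se);
  if (sgn <= 0) return -datum::inf;
  return -0.5 * (N * (3.0 * std::log(2.0 * datum::pi) + ld) +
                 trace(solve(se, C1)));
}

// [[Rcpp::export]]
Rcpp::List rdsem_gibbs_cpp(arma::cube Y,               // T x 3 x N, NA pre-filled
                           const arma::ucube& OBS,     // T x 3 x N, 1 = observed
                           const arma::vec& tyears,    // length T (lattice, years)
                           const arma::mat& X,         // N x q, first col = 1
                           const arma::umat& phi_mask, // 3 x 3
                           const arma::uvec& trend_on, // length 3
                           double var_t,               // Var(t) over nominal schedule
                           const Rcpp::List& prior,
                           int n_iter, int n_warmup,
                           const Rcpp::List& init,
                           int n_within, bool verbose) {
  const uword T = Y.n_rows, N = Y.n_slices, q = X.n_cols;

  const double phi_sd    = prior["phi_sd"];
  const bool   phi_trunc = prior["phi_trunc"];
  const double delta_sd  = prior["delta_sd"];
  const double su_df     = prior["su_df"];
  const mat    su_scale  = Rcpp::as<mat>(prior["su_scale"]);
  const double sb_df     = prior["sb_df"];
  const mat    sb_scale  = Rcpp::as<mat>(prior["sb_scale"]);
  const double tv_shape  = prior["tv_shape"];
  const double tv_rate   = prior["tv_rate"];
  const double rho_max   = prior["rho_max"];

  // free Phi coefficients, row-major over the sparsity mask
  std::vector<uword> pv, pu;
  for (uword v = 0; v < 3; ++v)
    for (uword u = 0; u < 3; ++u)
      if (phi_mask(v, u)) { pv.push_back(v); pu.push_back(u); }
  const uword np = pv.size();

  // active components of eta = (alpha_1..3, beta_1..3)
  std::vector<uword> actv = {0, 1, 2};
  for (uword v = 0; v < 3; ++v) if (trend_on(v)) actv.push_back(3 + v);
  const uvec act = conv_to<uvec>::from(actv);
  const uword K = act.n_elem;

  // state
  mat eta   = Rcpp::as<mat>(init["eta"]);     // N x 6
  mat delta = Rcpp::as<mat>(init["delta"]);   // q x 6
  mat phi   = Rcpp::as<mat>(init["phi"]);
  mat su    = Rcpp::as<mat>(init["sigma_u"]);
  mat sb    = Rcpp::as<mat>(init["sigma_b"]); // 3 x 3 intercept block
  vec s2b   = Rcpp::as<vec>(init["s2_trend"]);
  mat se    = lyap3(phi, su);

  const mat XtX = X.t() * X;
  const uword n_keep = (uword)(n_iter - n_warmup);
  const uword ncol_out = np + 6 + 6 * q + 6 + 3 + 9;
  mat out(n_keep, ncol_out, fill::zeros);

  cube imp_sum(T, 3, N, fill::zeros);  // running sum of augmented cells
  double acc_phi = 0.0, acc_su = 0.0;

  // time sums for the eta-precision closed form (transitions t = 1..T-1)
  const double t0 = tyears(0);
  double st1 = 0, st0 = 0, s11 = 0, s10 = 0, s00 = 0;
  for (uword t = 1; t < T; ++t) {
    st1 += tyears(t);               st0 += tyears(t - 1);
    s11 += tyears(t) * tyears(t);   s00 += tyears(t - 1) * tyears(t - 1);
    s10 += tyears(t) * tyears(t - 1);
  }

  const mat I3 = eye(3, 3);
  const uword prog = std::max((uword)1, (uword)n_iter / 10);

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
    // the augmented within-level state (missing cells, person effects) and
    // the (Phi, Sigma_u) blocks are tightly coupled; visiting them n_within
    // times per scan shortens the integrated autocorrelation time
    for (int rep = 0; rep < n_within; ++rep) {
    const mat Wu = inv_sympd(symmatu(su));
    const mat We = inv_sympd(symmatu(se));
    const mat Wup = Wu * phi;

    // eta precision (shared across persons)
    const mat IeP = I3 - phi;                    // I - Phi
    const mat E   = IeP.t() * Wu;
    mat Pfull(6, 6, fill::zeros);
    mat TL = E * IeP * (double)(T - 1) + We;
    mat TR = IeP.t() * (st1 * Wu - st0 * Wup) + t0 * We;
    mat BR = s11 * Wu - s10 * (Wup + Wup.t()) + s00 * (phi.t() * Wup) +
             t0 * t0 * We;
    Pfull.submat(0, 0, 2, 2) = TL;
    Pfull.submat(0, 3, 2, 5) = TR;
    Pfull.submat(3, 0, 5, 2) = TR.t();
    Pfull.submat(3, 3, 5, 5) = BR;
    const mat sb_inv = inv_sympd(symmatu(sb));
    mat Sbinv_full(6, 6, fill::zeros);
    Sbinv_full.submat(0, 0, 2, 2) = sb_inv;
    for (uword v = 0; v < 3; ++v) Sbinv_full(3 + v, 3 + v) = 1.0 / s2b(v);
    mat P_eta = Pfull.submat(act, act) + Sbinv_full.submat(act, act);
    const mat R_eta = chol(symmatu(P_eta));

    mat C1(3, 3, fill::zeros), Cl(3, 3, fill::zeros);
    mat Cc(3, 3, fill::zeros), Ct(3, 3, fill::zeros);

    for (uword i = 0; i < N; ++i) {
      vec a = eta.row(i).cols(0, 2).t();
      vec b = eta.row(i).cols(3, 5).t();
      mat Yi = Y.slice(i).t();                 // 3 x T
      mat eps = Yi;
      for (uword t = 0; t < T; ++t) eps.col(t) -= a + b * tyears(t);

      // ---- impute missing cells: joint draw per person via forward
      // filtering / backward sampling on the 3-dim residual state, with
      // observed components conditioned on exactly.  A joint draw avoids
      // the slow random-walk mixing a single-site sweep would exhibit over
      // the long runs of consecutive phantom occasions between the annual
      // waves. ----
      bool any_mis = false;
      for (uword t = 0; t < T && !any_mis; ++t)
        for (uword v = 0; v < 3; ++v)
          if (!OBS(t, v, i)) { any_mis = true; break; }
      if (any_mis) {
        mat mf(3, T);
        cube Pf(3, 3, T);
        for (uword t = 0; t < T; ++t) {
          vec mp; mat Pp;
          if (t == 0) { mp = zeros<vec>(3); Pp = se; }
          else {
            mp = phi * mf.col(t - 1);
            Pp = symmatu(phi * Pf.slice(t - 1) * phi.t() + su);
          }
          uvec obsv(3); uword no = 0;
          for (uword v = 0; v < 3; ++v) if (OBS(t, v, i)) obsv(no++) = v;
          if (no > 0) {
            uvec ou = obsv.head(no);
            mat Poo = Pp(ou, ou);
            mat Kg = Pp.cols(ou) * inv_sympd(symmatu(Poo));
            vec et = eps.col(t);
            mf.col(t) = mp + Kg * (et(ou) - mp(ou));
            Pp = Pp - Kg * Pp.rows(ou);
            Pp = 0.5 * (Pp + Pp.t());
          } else mf.col(t) = mp;
          Pf.slice(t) = Pp;
        }
        for (uword tt = T; tt-- > 0;) {
          vec cm; mat cC;
          if (tt == T - 1) { cm = mf.col(tt); cC = Pf.slice(tt); }
          else {
            mat Pp1 = symmatu(phi * Pf.slice(tt) * phi.t() + su);
            mat J = Pf.slice(tt) * phi.t() * inv_sympd(Pp1);
            cm = mf.col(tt) + J * (eps.col(tt + 1) - phi * mf.col(tt));
            cC = symmatu(Pf.slice(tt) - J * phi * Pf.slice(tt));
          }
          uvec mis(3); uword nm = 0;
          for (uword v = 0; v < 3; ++v) if (!OBS(tt, v, i)) mis(nm++) = v;
          if (nm == 0) continue;
          uvec mu_ = mis.head(nm);
          mat Cm = cC(mu_, mu_);
          Cm.diag() += 1e-12;
          vec draw = cm(mu_) + chol(symmatu(Cm), "lower") * rnorm_vec(nm);
          for (uword k = 0; k < nm; ++k) {
            eps(mu_(k), tt) = draw(k);
            Yi(mu_(k), tt) = draw(k) + a(mu_(k)) + b(mu_(k)) * tyears(tt);
          }
        }
      }

      // ---- draw (alpha_i, beta_i) ----
      vec y1 = Yi.col(0);
      vec sw(3, fill::zeros), swt1(3, fill::zeros), swt0(3, fill::zeros);
      for (uword t = 1; t < T; ++t) {
        vec w = Yi.col(t) - phi * Yi.col(t - 1);
        sw += w;
        swt1 += tyears(t) * w;
        swt0 += tyears(t - 1) * w;
      }
      vec h6(6);
      vec Wey1 = We * y1;
      h6.subvec(0, 2) = Wey1 + E * sw;
      h6.subvec(3, 5) = t0 * Wey1 + Wu * swt1 - phi.t() * (Wu * swt0);
      vec mu_i = delta.t() * X.row(i).t();            // 6
      vec hp = h6(act) + Sbinv_full.submat(act, act) * mu_i(act);
      vec ei = draw_gauss_chol(R_eta, hp);
      vec eta6(6, fill::zeros);
      eta6(act) = ei;
      eta.row(i) = eta6.t();

      // ---- accumulate residual cross-products with the new eta ----
      a = eta6.subvec(0, 2);
      b = eta6.subvec(3, 5);
      eps = Yi;
      for (uword t = 0; t < T; ++t) eps.col(t) -= a + b * tyears(t);
      C1 += eps.col(0) * eps.col(0).t();
      for (uword t = 1; t < T; ++t) {
        Cl += eps.col(t - 1) * eps.col(t - 1).t();
        Cc += eps.col(t) * eps.col(t - 1).t();
        Ct += eps.col(t) * eps.col(t).t();
      }
      Y.slice(i) = Yi.t();
      if (iter >= n_warmup && rep == n_within - 1) {
        for (uword t = 0; t < T; ++t)
          for (uword v = 0; v < 3; ++v)
            if (!OBS(t, v, i)) imp_sum(t, v, i) += Yi(v, t);
      }
    }

    // ---- Phi (Metropolis-within-Gibbs, independence proposal) ----
    {
      mat Q(np, np);
      vec g(np);
      mat WuCc = Wu * Cc;
      for (uword k = 0; k < np; ++k) {
        g(k) = WuCc(pv[k], pu[k]);
        for (uword l = 0; l < np; ++l)
          Q(k, l) = Wu(pv[k], pv[l]) * Cl(pu[k], pu[l]);
      }
      Q.diag() += 1.0 / (phi_sd * phi_sd);
      vec th = draw_gauss_prec(Q, g);
      bool ok = true;
      if (phi_trunc)
        for (uword k = 0; k < np; ++k) if (std::abs(th(k)) >= 1.0) ok = false;
      mat phi_prop(3, 3, fill::zeros);
      for (uword k = 0; k < np; ++k) phi_prop(pv[k], pu[k]) = th(k);
      if (ok && spec_radius(phi_prop) < rho_max) {
        mat se_prop = lyap3(phi_prop, su);
        double la = loglik_init(se_prop, C1, (double)N) -
                    loglik_init(se, C1, (double)N);
        if (std::log(R::unif_rand()) < la) {
          phi = phi_prop; se = se_prop; acc_phi += 1.0;
        }
      }
    }

    // ---- Sigma_u (Metropolis-within-Gibbs, independence proposal) ----
    {
      mat Su = Ct - phi * Cc.t() - Cc * phi.t() + phi * Cl * phi.t();
      double n_trans = (double)N * (double)(T - 1);
      mat su_prop = riwish(su_df + n_trans, su_scale + symmatu(Su));
      mat se_prop = lyap3(phi, su_prop);
      double la = loglik_init(se_prop, C1, (double)N) -
                  loglik_init(se, C1, (double)N);
      if (std::log(R::unif_rand()) < la) {
        su = su_prop; se = se_prop; acc_su += 1.0;
      }
    }
    }  // end within-level repetitions

    // ---- between-level regression coefficients Delta ----
    {
      mat sbi = inv_sympd(symmatu(sb));
      mat A = eta.cols(0, 2);                         // N x 3
      mat P = kron(sbi, XtX) + eye(3 * q, 3 * q) / (delta_sd * delta_sd);
      vec h = vectorise(X.t() * A * sbi);
      vec d = draw_gauss_prec(P, h);
      for (uword v = 0; v < 3; ++v)
        delta.col(v) = d.subvec(v * q, v * q + q - 1);
      for (uword v = 0; v < 3; ++v) {
        if (!trend_on(v)) { delta.col(3 + v).zeros(); continue; }
        mat Pv = XtX / s2b(v) + eye(q, q) / (delta_sd * delta_sd);
        vec hv = X.t() * eta.col(3 + v) / s2b(v);
        delta.col(3 + v) = draw_gauss_prec(Pv, hv);
      }
    }

    // ---- between-level covariances ----
    {
      mat Rint = eta.cols(0, 2) - X * delta.cols(0, 2);
      sb = riwish(sb_df + (double)N, sb_scale + Rint.t() * Rint);
      for (uword v = 0; v < 3; ++v) {
        if (!trend_on(v)) continue;
        vec r = eta.col(3 + v) - X * delta.col(3 + v);
        double rate = tv_rate + 0.5 * dot(r, r);
        s2b(v) = 1.0 / R::rgamma(tv_shape + 0.5 * (double)N, 1.0 / rate);
      }
    }

    // ---- store ----
    if (iter >= n_warmup) {
      uword r = iter - n_warmup, c = 0;
      for (uword k = 0; k < np; ++k) out(r, c++) = phi(pv[k], pu[k]);
      for (uword v = 0; v < 3; ++v)
        for (uword w = v; w < 3; ++w) out(r, c++) = su(w, v);
      for (uword comp = 0; comp < 6; ++comp)
        for (uword j = 0; j < q; ++j) out(r, c++) = delta(j, comp);
      for (uword v = 0; v < 3; ++v)
        for (uword w = v; w < 3; ++w) out(r, c++) = sb(w, v);
      for (uword v = 0; v < 3; ++v) out(r, c++) = s2b(v);
      // cluster-averaged moments for STDYX standardization
      for (uword v = 0; v < 3; ++v) {
        double m1 = 0, m2 = 0, m3 = 0;
        for (uword i = 0; i < N; ++i) {
          double bb = trend_on(v) ? eta(i, 3 + v) : 0.0;
          double V = bb * bb * var_t + se(v, v);
          double sV = std::sqrt(V);
          m1 += 1.0 / V; m2 += 1.0 / sV; m3 += bb / sV;
        }
        out(r, np + 6 + 6 * q + 9 + v) = m1 / N;
        out(r, np + 6 + 6 * q + 12 + v) = m2 / N;
        out(r, np + 6 + 6 * q + 15 + v) = m3 / N;
      }
    }

    if (verbose && ((iter + 1) % prog == 0))
      Rcpp::Rcout << "  iteration " << iter + 1 << "/" << n_iter
                  << " (phi acc " << acc_phi / ((iter + 1.0) * n_within)
                  << ", sigma_u acc " << acc_su / ((iter + 1.0) * n_within)
                  << ")\n";
  }

  cube imp_mean = imp_sum / (double)n_keep;
  return Rcpp::List::create(
    Rcpp::Named("draws") = out,
    Rcpp::Named("accept_phi") = acc_phi / ((double)n_iter * n_within),
    Rcpp::Named("accept_sigma_u") = acc_su / ((double)n_iter * n_within),
    Rcpp::Named("impute_mean") = imp_mean);
}
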
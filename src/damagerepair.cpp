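// Log-posteriors of the package's three Bayesian models, written as negative
// log densities over unconstrained parameters (all constraining transforms
// and their log-Jacobians are applied here). TMB supplies automatic
// differentiation; sampling is done by the package's own NUTS implementation
// on obj$fn / obj$gr.
//
// model_flag: 1 = mouse joint longitudinal-survival model
//             2 = human varying-coefficient longitudinal model
//             3 = interval-censored deficit-state survival model

#include <TMB.hpp>

// softplus link, overflow-safe
template <class Type>
Type softplus(Type x) {
  return logspace_add(x, Type(0));
}

// stick-breaking: y (K-1 unconstrained) -> simplex a (K), accumulating the
// log-Jacobian into logj
template <class Type>
vector<Type> simplex_transform(const vector<Type>& y, Type& logj) {
  int K = y.size() + 1;
  vector<Type> a(K);
  Type stick = Type(1);
  for (int l = 0; l < K - 1; l++) {
    Type z = invlogit(y(l) - log(Type(K - l - 1)));
    a(l) = stick * z;
    logj += log(stick) + log(z) + log(Type(1) - z);
    stick *= (Type(1) - z);
  }
  a(K - 1) = stick;
  return a;
}

// canonical partial correlations: y -> lower Cholesky factor of a K x K
// correlation matrix; accumulates the y->L log-Jacobian and the
// LKJ(eta) log-density of the resulting factor
template <class Type>
matrix<Type> corr_chol_transform(const vector<Type>& y, int K, Type eta, Type& lp) {
  matrix<Type> L(K, K);
  L.setZero();
  L(0, 0) = Type(1);
  int idx = 0;
  for (int i = 1; i < K; i++) {
    Type rem = Type(1);
    for (int j = 0; j < i; j++) {
      Type z = tanh(y(idx));
      lp += log(Type(1) - z * z);              // dz/dy
      lp += Type(0.5) * log(rem);       // dL_ij/dz_ij
      L(i, j) = z * sqrt(rem);
      rem *= (Type(1) - z * z);
      idx++;
    }
    L(i, i) = sqrt(rem);
    // LKJ density on the Cholesky factor: exponent K - (i+1) + 2*eta - 2
    lp += (Type(K - i - 1) + Type(2) * eta - Type(2)) * log(L(i, i));
  }
  return L;
}

// half-Cauchy(0,1) prior on sigma = exp(log_sigma), including the Jacobian
template <class Type>
Type half_cauchy_logpost(Type log_sigma) {
  Type sigma = exp(log_sigma);
  return log(Type(2)) - log(Type(M_PI)) - log(Type(1) + sigma * sigma) + log_sigma;
}

// half-Normal(0,1) prior on tau = exp(log_tau), including the Jacobian
template <class Type>
Type half_normal_logpost(Type log_tau) {
  Type tau = exp(log_tau);
  return dnorm(tau, Type(0), Type(1), true) + log(Type(2)) + log_tau;
}

// Poisson log-mass with mean avail * lambda * dt; avail == 0 intervals are
// excluded on the R side (their count is necessarily 0 and contributes 0);
// the constant lgamma(y + 1) is supplied precomputed
template <class Type>
Type pois_count_lp(Type y, Type avail, Type lambda, Type dt, Type lgam) {
  Type mu = avail * lambda * dt;
  return y * log(mu) - mu - lgam;
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_INTEGER(model_flag);
  Type lp = Type(0);

  if (model_flag == 1) {
    // ---- mouse joint longitudinal-survival model ----
    DATA_MATRIX(X);        // subject-intervals x 10 standardized design
    DATA_VECTOR(t_std);    // standardized interval-start time
    DATA_IVECTOR(subj);    // 0-based subject index per interval
    DATA_VECTOR(nr);
    DATA_VECTOR(nd);
    DATA_VECTOR(avail_r);  // n(t_j)
    DATA_VECTOR(avail_d);  // N - n(t_j)
    DATA_VECTOR(dt);
    DATA_VECTOR(lgam_nr);  // lgamma(nr + 1), precomputed constants
    DATA_VECTOR(lgam_nd);
    DATA_INTEGER(has_survival);
    DATA_IVECTOR(death);   // 1 = death observed
    DATA_IVECTOR(sexf);    // 1 = female baseline
    DATA_MATRIX(UT);       // n x 6 survival covariates at final time T_i
    DATA_MATRIX(XT);       // design at final time T_i
    DATA_VECTOR(tT_std);
    DATA_MATRIX(BT);       // M-spline basis at T_i
    DATA_MATRIX(UQ);       // survival covariates at quadrature nodes
    DATA_MATRIX(XQ);       // design at quadrature nodes
    DATA_VECTOR(tQ_std);
    DATA_IVECTOR(subjQ);
    DATA_VECTOR(wQ);       // absolute quadrature weights
    // sparse basis at quadrature nodes: cubic M-splines have at most 4
    // nonzero basis functions per point (0-based indices + weights)
    DATA_IMATRIX(BQi);
    DATA_MATRIX(BQw);

    PARAMETER_VECTOR(beta_r);     // 10
    PARAMETER_VECTOR(beta_d);     // 10
    PARAMETER_MATRIX(z);          // 4 x n, non-centered random effects
    PARAMETER_VECTOR(log_sigma);  // 4
    PARAMETER_VECTOR(corr_y);     // 6
    PARAMETER_VECTOR(gamma);      // 6
    PARAMETER(gamma_r);
    PARAMETER(gamma_d);
    PARAMETER_VECTOR(ya_m);       // L-1
    PARAMETER_VECTOR(ya_f);       // L-1

    int n = z.cols();
    matrix<Type> Lc = corr_chol_transform(corr_y, 4, Type(2), lp);
    vector<Type> sigma = exp(vector<Type>(log_sigma));
    matrix<Type> b = Lc * z;  // 4 x n
    for (int i = 0; i < n; i++)
      for (int k = 0; k < 4; k++) b(k, i) *= sigma(k);

    // longitudinal Poisson likelihood
    vector<Type> xbr = X * beta_r;
    vector<Type> xbd = X * beta_d;
    int M = xbr.size();
    for (int m = 0; m < M; m++) {
      int i = subj(m);
      Type eta_r = xbr(m) + b(0, i) + b(1, i) * t_std(m);
      Type eta_d = xbd(m) + b(2, i) + b(3, i) * t_std(m);
      if (avail_r(m) > Type(0))
        lp += pois_count_lp(nr(m), avail_r(m), softplus(eta_r), dt(m), lgam_nr(m));
      if (avail_d(m) > Type(0))
        lp += pois_count_lp(nd(m), avail_d(m), softplus(eta_d), dt(m), lgam_nd(m));
    }

    // survival likelihood: log h(T_i) for deaths minus cumulative hazard
    vector<Type> a_m, a_f;
    if (has_survival == 1) {
      a_m = simplex_transform(vector<Type>(ya_m), lp);
      a_f = simplex_transform(vector<Type>(ya_f), lp);
      vector<Type> ugT = UT * gamma;
      vector<Type> ugQ = UQ * gamma;
      vector<Type> xbrT = XT * beta_r;
      vector<Type> xbdT = XT * beta_d;
      vector<Type> h0Tm = BT * a_m;
      vector<Type> h0Tf = BT * a_f;
      for (int i = 0; i < n; i++) {
        if (death(i) == 1) {
          Type eta_rT = xbrT(i) + b(0, i) + b(1, i) * tT_std(i);
          Type eta_dT = xbdT(i) + b(2, i) + b(3, i) * tT_std(i);
          Type h0 = (sexf(i) == 1) ? h0Tf(i) : h0Tm(i);
          lp += log(h0) + ugT(i) + gamma_r * eta_rT + gamma_d * eta_dT;
        }
      }
      vector<Type> xbrQ = XQ * beta_r;
      vector<Type> xbdQ = XQ * beta_d;
      int Q = xbrQ.size();
      for (int q = 0; q < Q; q++) {
        int i = subjQ(q);
        Type eta_rQ = xbrQ(q) + b(0, i) + b(1, i) * tQ_std(q);
        Type eta_dQ = xbdQ(q) + b(2, i) + b(3, i) * tQ_std(q);
        const vector<Type>& a_sex = (sexf(i) == 1) ? a_f : a_m;
        Type h0 = Type(0);
        for (int k = 0; k < BQi.cols(); k++) {
          if (BQi(q, k) >= 0) h0 += BQw(q, k) * a_sex(BQi(q, k));
        }
        lp -= wQ(q) * h0 * exp(ugQ(q) + gamma_r * eta_rQ + gamma_d * eta_dQ);
      }
    } else {
      // keep the unused survival block proper: standard normal pseudo-priors
      for (int l = 0; l < ya_m.size(); l++)
        lp += dnorm(ya_m(l), Type(0), Type(1), true) +
              dnorm(ya_f(l), Type(0), Type(1), true);
    }

    // priors
    lp += dnorm(beta_r(0), Type(0), Type(3), true);
    lp += dnorm(beta_d(0), Type(0), Type(3), true);
    for (int p = 1; p < beta_r.size(); p++) {
      lp += dnorm(beta_r(p), Type(0), Type(1), true);
      lp += dnorm(beta_d(p), Type(0), Type(1), true);
    }
    for (int i = 0; i < n; i++)
      for (int k = 0; k < 4; k++) lp += dnorm(z(k, i), Type(0), Type(1), true);
    for (int k = 0; k < 4; k++) lp += half_cauchy_logpost(log_sigma(k));
    lp += dnorm(gamma(0), Type(0), Type(3), true);
    for (int p = 1; p < gamma.size(); p++) lp += dnorm(gamma(p), Type(0), Type(1), true);
    lp += dnorm(gamma_r, Type(0), Type(1), true);
    lp += dnorm(gamma_d, Type(0), Type(1), true);
    // Dirichlet(1) on the spline simplexes is constant

    if (has_survival == 1) {
      REPORT(a_m);
      REPORT(a_f);
    }
    matrix<Type> Lcorr = Lc;
    REPORT(Lcorr);

  } else if (model_flag == 2) {
    // ---- human varying-coefficient longitudinal model ----
    DATA_MATRIX(X0);    // subject-intervals x 12 standardized design
    DATA_MATRIX(MULT);  // x 4: (1, sex, t, sex*t), standardized parents
    DATA_MATRIX(TB);    // n x 25 tensor-product basis at (w_i, a0_i)
    DATA_IVECTOR(subj);
    DATA_VECTOR(nr);
    DATA_VECTOR(nd);
    DATA_VECTOR(avail_r);
    DATA_VECTOR(avail_d);
    DATA_VECTOR(dt);
    DATA_VECTOR(lgam_nr);
    DATA_VECTOR(lgam_nd);

    PARAMETER_VECTOR(beta0_r);   // 12
    PARAMETER_VECTOR(beta0_d);   // 12
    PARAMETER_MATRIX(S_r);       // 25 x 4 surface coefficients (5x5 grids)
    PARAMETER_MATRIX(S_d);       // 25 x 4
    PARAMETER_MATRIX(z);         // 2 x n random intercepts, non-centered
    PARAMETER_VECTOR(log_sigma); // 2
    PARAMETER_VECTOR(corr_y);    // 1
    PARAMETER_VECTOR(log_tau);   // 4: (tau_w, tau_b0) x (repair, damage)
    PARAMETER_VECTOR(p_y);       // 2: mixture weight per process

    int n = z.cols();
    matrix<Type> Lc = corr_chol_transform(corr_y, 2, Type(2), lp);
    vector<Type> sigma = exp(vector<Type>(log_sigma));
    matrix<Type> b = Lc * z;
    for (int i = 0; i < n; i++)
      for (int k = 0; k < 2; k++) b(k, i) *= sigma(k);

    matrix<Type> G_r = TB * S_r;  // n x 4 surface values per subject
    matrix<Type> G_d = TB * S_d;
    vector<Type> xbr = X0 * beta0_r;
    vector<Type> xbd = X0 * beta0_d;
    int M = xbr.size();
    for (int m = 0; m < M; m++) {
      int i = subj(m);
      Type eta_r = xbr(m) + b(0, i);
      Type eta_d = xbd(m) + b(1, i);
      for (int k = 0; k < 4; k++) {
        eta_r += MULT(m, k) * G_r(i, k);
        eta_d += MULT(m, k) * G_d(i, k);
      }
      if (avail_r(m) > Type(0))
        lp += pois_count_lp(nr(m), avail_r(m), softplus(eta_r), dt(m), lgam_nr(m));
      if (avail_d(m) > Type(0))
        lp += pois_count_lp(nd(m), avail_d(m), softplus(eta_d), dt(m), lgam_nd(m));
    }

    // 2D random-walk smoothing prior on each 5x5 coefficient grid
    // (grid index: s(i + 5*j), i = wealth axis, j = baseline-age axis)
    for (int proc = 0; proc < 2; proc++) {
      Type tau_w = exp(log_tau(2 * proc));
      Type tau_b = exp(log_tau(2 * proc + 1));
      Type p_w = invlogit(p_y(proc));
      lp += dbeta(p_w, Type(1.5), Type(1.5), true) + log(p_w) + log(Type(1) - p_w);
      lp += half_normal_logpost(log_tau(2 * proc));
      lp += half_normal_logpost(log_tau(2 * proc + 1));
      const matrix<Type>& S = (proc == 0) ? S_r : S_d;
      for (int k = 0; k < 4; k++) {
        for (int j = 0; j < 5; j++) {
          for (int i = 0; i < 5; i++) {
            Type s = S(i + 5 * j, k);
            if (i == 0 && j == 0) {
              lp += dnorm(s, Type(0), Type(1), true);
            } else if (j == 0) {
              lp += dnorm(s, S(i - 1, k), tau_w, true);
            } else if (i == 0) {
              lp += dnorm(s, S(5 * (j - 1), k), tau_b, true);
            } else {
              Type lw = log(p_w) + dnorm(s, S(i - 1 + 5 * j, k), tau_w, true);
              Type lb = log(Type(1) - p_w) + dnorm(s, S(i + 5 * (j - 1), k), tau_b, true);
              lp += logspace_add(lw, lb);
            }
          }
        }
      }
    }

    // priors on fixed effects and random-effect covariance
    lp += dnorm(beta0_r(0), Type(0), Type(3), true);
    lp += dnorm(beta0_d(0), Type(0), Type(3), true);
    for (int p = 1; p < beta0_r.size(); p++) {
      lp += dnorm(beta0_r(p), Type(0), Type(1), true);
      lp += dnorm(beta0_d(p), Type(0), Type(1), true);
    }
    for (int i = 0; i < n; i++)
      for (int k = 0; k < 2; k++) lp += dnorm(z(k, i), Type(0), Type(1), true);
    for (int k = 0; k < 2; k++) lp += half_cauchy_logpost(log_sigma(k));

    matrix<Type> Lcorr = Lc;
    REPORT(Lcorr);

  } else if (model_flag == 3) {
    // ---- interval-censored deficit-state survival model ----
    DATA_IVECTOR(is_right);  // 1 = right-censored record
    DATA_MATRIX(I_lo);       // I-spline basis at T_lower (or censor time)
    DATA_MATRIX(I_hi);       // I-spline basis at T_upper

    PARAMETER(gamma0);
    PARAMETER_VECTOR(ya);    // L-1

    vector<Type> a = simplex_transform(vector<Type>(ya), lp);
    vector<Type> cum_lo = I_lo * a;
    vector<Type> cum_hi = I_hi * a;
    Type scale = exp(gamma0);
    int R = cum_lo.size();
    for (int r = 0; r < R; r++) {
      if (is_right(r) == 1) {
        lp -= scale * cum_lo(r);
      } else {
        // log[ S(T_lower) - S(T_upper) ]
        lp += logspace_sub(-scale * cum_lo(r), -scale * cum_hi(r));
      }
    }
    lp += dnorm(gamma0, Type(0), Type(10), true);
    REPORT(a);
  } else {
    error("unknown model_flag");
  }

  return -lp;
}
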
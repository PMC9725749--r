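test_that("longitudinal log-likelihood matches Poisson closed forms", {
  # n = 0 interval: repair term contributes exactly 0
  p <- binary_panel(list(s1 = rbind(c(0, 0), c(0, 1)), s2 = rbind(c(0, 1), c(1, 1))))
  cnt <- count_transitions(p)
  beta0 <- c(softplus_inverse(0.5), rep(0, 9))
  ll <- longitudinal_loglik(cnt, beta0, beta0)
  # manual: subject 1, n=0: only damage term Pois(2*0.5*1) at k=1;
  # subject 2, n=1: repair Pois(0.5) at 0, damage Pois(0.5) at 1
  manual <- dpois(1, 1, log = TRUE) + dpois(0, 0.5, log = TRUE) +
    dpois(1, 0.5, log = TRUE)
  expect_equal(ll, manual, tolerance = 1e-10)
  # single interval with mean 2 and count 2: log(2^2 e^-2 / 2!)
  p2 <- binary_panel(list(s1 = rbind(c(rep(1, 4), 0), c(rep(0, 2), 1, 1, 0))))
  cnt2 <- count_transitions(p2)  # n = 4, n_r = 2, dt = 1
  lam <- 0.5  # n * lam * dt = 2
  ll2 <- longitudinal_loglik(cnt2, c(softplus_inverse(lam), rep(0, 9)),
                             c(softplus_inverse(1e-9), rep(0, 9)))
  repair_part <- log(2^2 * exp(-2) / 2)
  damage_part <- dpois(0, 1 * 1e-9, log = TRUE)
  expect_equal(ll2, repair_part + damage_part, tolerance = 1e-6)
})

test_that("Poisson rate MLE on simulated intervals is consistent with the truth", {
  tr <- constant_rate_truth(1e-12, 0.03, n_items = 50, schedule = 0:10)
  tr$init_fi <- 0
  co <- simulate_cohort(tr, 300, seed = 77, survival = FALSE,
                        count_model = "poisson")
  cnt <- count_transitions(co$panel)
  nll <- function(lam) -sum(dpois(cnt$n_d, (50 - cnt$n) * lam * cnt$dt, log = TRUE))
  mle <- optimize(nll, c(1e-4, 0.2))$minimum
  se <- mle / sqrt(sum(cnt$n_d))
  expect_lt(abs(mle - 0.03), 3 * se)
})

test_that("the compiled joint posterior agrees with the R likelihood mirror", {
  tr <- ground_truth()
  co <- simulate_cohort(tr, 12, seed = 30)
  cnt <- count_transitions(co$panel)
  std <- tr$standardize
  # two parameter points differing only in beta: the difference of the
  # compiled negative log posteriors must equal the difference of the R
  # log-likelihoods plus the prior difference
  subjects <- unique(cnt$subject_id)
  data <- local({
    N <- attr(cnt, "n_items")
    list(model_flag = 1L, X = damagerepair:::mouse_design_matrix(cnt, std),
         t_std = (cnt$t - std$center[["t"]]) / std$scale[["t"]],
         subj = match(cnt$subject_id, subjects) - 1L,
         nr = cnt$n_r, nd = cnt$n_d, avail_r = cnt$n, avail_d = N - cnt$n,
         dt = cnt$dt, lgam_nr = lgamma(cnt$n_r + 1), lgam_nd = lgamma(cnt$n_d + 1),
         has_survival = 0L,
         death = integer(length(subjects)), sexf = integer(length(subjects)),
         UT = matrix(0, length(subjects), 6), XT = matrix(0, length(subjects), 10),
         tT_std = numeric(length(subjects)),
         BT = matrix(0, length(subjects), 18), UQ = matrix(0, 1, 6),
         XQ = matrix(0, 1, 10), tQ_std = 0, subjQ = 0L, wQ = 0,
         BQi = matrix(-1L, 1, 4), BQw = matrix(0, 1, 4))
  })
  pars <- list(beta_r = rep(0, 10), beta_d = rep(0, 10),
               z = matrix(0, 4, length(subjects)), log_sigma = rep(log(0.3), 4),
               corr_y = rep(0, 6), gamma = rep(0, 6), gamma_r = 0, gamma_d = 0,
               ya_m = rep(0, 17), ya_f = rep(0, 17))
  obj <- TMB::MakeADFun(data = data, parameters = pars, DLL = "damagerepair",
                        silent = TRUE)
  set.seed(2)
  b1 <- rnorm(10, 0, 0.5); b2 <- rnorm(10, 0, 0.5)
  th1 <- obj$par; th2 <- obj$par
  th1[1:10] <- b1; th2[1:10] <- b2
  d_cpp <- as.numeric(obj$fn(th2) - obj$fn(th1))  # negative log posterior
  ll1 <- longitudinal_loglik(cnt, b1, rep(0, 10), standardize = std)
  ll2 <- longitudinal_loglik(cnt, b2, rep(0, 10), standardize = std)
  prior <- function(b) dnorm(b[1], 0, 3, log = TRUE) + sum(dnorm(b[-1], 0, 1, log = TRUE))
  d_r <- -(ll2 + prior(b2)) + (ll1 + prior(b1))
  expect_equal(d_cpp, d_r, tolerance = 1e-6)
  # gradient agrees with finite differences
  set.seed(4)
  pt <- obj$par + rnorm(length(obj$par), 0, 0.1)
  gn <- numDeriv::grad(function(x) as.numeric(obj$fn(x)), pt,
                       method = "simple", method.args = list(eps = 1e-7))
  expect_lt(max(abs(as.numeric(obj$gr(pt)) - gn)) / (1 + max(abs(gn))), 1e-3)
})

test_that("joint fits are reproducible under a fixed seed", {
  tr <- ground_truth()
  co <- simulate_cohort(tr, 14, seed = 21)
  cnt <- count_transitions(co$panel)
  f1 <- fit_mouse_joint(cnt, survival = FALSE, standardize = tr$standardize,
                        chains = 2, iter = 60, warmup = 80, seed = 5,
                        max_treedepth = 8, convergence = "none")
  f2 <- fit_mouse_joint(cnt, survival = FALSE, standardize = tr$standardize,
                        chains = 2, iter = 60, warmup = 80, seed = 5,
                        max_treedepth = 8, convergence = "none")
  expect_identical(f1$draws, f2$draws)
})

test_that("zero observed repairs pull the repair rate far below its prior predictive mean", {
  tr <- constant_rate_truth(1e-12, 0.05, n_items = 40, schedule = 0:6)
  co <- simulate_cohort(tr, 25, seed = 13, survival = FALSE)
  cnt <- count_transitions(co$panel)
  expect_equal(sum(cnt$n_r), 0)
  fit <- fit_mouse_joint(cnt, survival = FALSE, chains = 1, iter = 150,
                         warmup = 200, seed = 7, convergence = "none")
  curve <- rate_curve(fit, times = c(0, 3, 6))
  post_mean <- mean(curve$lambda_r)
  # prior predictive mean of softplus(b0 + ...), b0 ~ N(0,3): > 1 by direct MC
  set.seed(1)
  prior_mean <- mean(softplus(rnorm(4000, 0, 3)))
  expect_lt(post_mean, prior_mean / 10)
})

test_that("posterior survival pieces are proper: simplexes, monotone survival", {
  tr <- ground_truth()
  co <- simulate_cohort(tr, 30, seed = 61)
  cnt <- count_transitions(co$panel)
  fit <- fit_mouse_joint(cnt, standardize = tr$standardize, chains = 1,
                         iter = 120, warmup = 180, seed = 3,
                         convergence = "none")
  L <- length(fit$knots) + 1L
  am <- fit$draws[, paste0("a_male[", 1:L, "]")]
  af <- fit$draws[, paste0("a_female[", 1:L, "]")]
  expect_equal(unname(rowSums(am)), rep(1, nrow(am)), tolerance = 1e-10)
  expect_true(all(am >= 0) && all(af >= 0))
  curve <- rate_curve(fit, profile = list(sex = 0, treatment = 0),
                      times = seq(0, 14, 1), draws = 1:50)
  sv <- hazard_mouse(fit, curve, draws = 1:50)
  expect_equal(unname(sv$survival[, 1]), rep(1, 50))
  expect_true(all(apply(sv$survival, 1, function(v) all(diff(v) <= 1e-12))))
  # correlation draws are valid correlation matrices
  om <- fit$draws[, c("Omega[2,1]", "Omega[3,1]", "Omega[3,2]",
                      "Omega[4,1]", "Omega[4,2]", "Omega[4,3]")]
  expect_true(all(abs(om) <= 1))
})

test_that("dropping the survival component leaves longitudinal posteriors unchanged within MC error", {
  tr <- ground_truth(gamma = rep(0, 6), gamma_r = 0, gamma_d = 0)
  co <- simulate_cohort(tr, 25, seed = 47, count_model = "poisson")
  cnt <- count_transitions(co$panel)
  f_joint <- fit_mouse_joint(cnt, survival = TRUE, standardize = tr$standardize,
                             chains = 1, iter = 200, warmup = 200, seed = 11,
                             convergence = "none")
  f_long <- fit_mouse_joint(cnt, survival = FALSE, standardize = tr$standardize,
                            chains = 1, iter = 200, warmup = 200, seed = 11,
                            convergence = "none")
  for (par in c("beta_r[intercept]", "beta_r[t]", "beta_d[intercept]", "beta_d[t]")) {
    m1 <- mean(f_joint$draws[, par]); m2 <- mean(f_long$draws[, par])
    mcse <- sd(f_long$draws[, par]) / sqrt(50) + sd(f_joint$draws[, par]) / sqrt(50)
    expect_lt(abs(m1 - m2), 4 * mcse + 0.02)
  }
})
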
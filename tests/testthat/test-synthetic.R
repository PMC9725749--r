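test_that("zero rates produce a frozen cohort and same seed reproduces exactly", {
  tr <- constant_rate_truth(1e-12, 1e-12, n_items = 30, schedule = 0:6)
  co <- simulate_cohort(tr, 20, seed = 5)
  cnt <- count_transitions(co$panel)
  expect_equal(sum(cnt$n_d), 0)
  expect_equal(sum(cnt$n_r), 0)
  per_subject_sd <- tapply(fi(co$panel), co$panel$visits$subject_id, sd)
  expect_true(all(per_subject_sd == 0))  # FI constant per subject
  co2 <- simulate_cohort(tr, 20, seed = 5)
  expect_identical(co$panel$deficits, co2$panel$deficits)
  expect_identical(co$panel$covariates, co2$panel$covariates)
  co3 <- simulate_cohort(tr, 20, seed = 6)
  expect_false(identical(co3$panel$covariates$a0, co$panel$covariates$a0))
})

test_that("constant damage rate is recovered by the binned estimator within 3 MC SE", {
  # lambda_d = 0.02 / month, lambda_r = 0, N = 124, dt = 1
  tr <- constant_rate_truth(1e-12, 0.02, n_items = 124, schedule = 0:7)
  tr$init_fi <- 0
  co <- simulate_cohort(tr, 500, seed = 17)
  cnt <- count_transitions(co$panel)
  # mean damage count per interval ~ (N - n)(1 - e^-0.02)
  expect_equal(mean(cnt$n_d / (124 - cnt$n)), 1 - exp(-0.02), tolerance = 0.1)
  br <- binned_rates(cnt, bin_edges = c(15, 26), at = cnt$age)
  bd <- br[br$rate_type == "damage", ]
  target <- (1 - exp(-0.02))  # dt = 1: discretized estimand
  expect_lt(abs(bd$rate - target), 3 * bd$se)
})

test_that("transition counts never exceed available items and conservation holds", {
  tr <- ground_truth()
  co <- simulate_cohort(tr, 40, seed = 23)
  cnt <- count_transitions(co$panel)
  expect_true(all(cnt$n_r <= cnt$n))
  expect_true(all(cnt$n_d <= attr(cnt, "n_items") - cnt$n))
  for (sid in unique(cnt$subject_id)) {
    rows <- cnt[cnt$subject_id == sid, ]
    expect_equal(sum(rows$n_d - rows$n_r),
                 rows$n[nrow(rows)] + rows$n_d[nrow(rows)] - rows$n_r[nrow(rows)] -
                   rows$n[1])
  }
})

test_that("constant rates drive item occupancy to the binomial equilibrium", {
  lam_r <- 0.12; lam_d <- 0.06
  tr <- constant_rate_truth(lam_r, lam_d, n_items = 20, schedule = seq(0, 60, 2))
  tr$init_fi <- 0.5
  co <- simulate_cohort(tr, 1000, seed = 41, survival = FALSE)
  f_final <- fi(co$panel)[co$panel$visits$time == 60]
  # equilibrium occupancy per item with discrete-time flip probabilities
  p_r <- 1 - exp(-lam_r * 2); p_d <- 1 - exp(-lam_d * 2)
  eq <- p_d / (p_d + p_r)
  se <- sqrt(eq * (1 - eq) / (1000 * 20))
  expect_lt(abs(mean(f_final) - eq), 4 * se + 0.005)
})

test_that("survival: zero hazard censors everyone at the final visit", {
  tr <- constant_rate_truth(0.05, 0.02, n_items = 20, schedule = 0:6)
  co <- simulate_cohort(tr, 25, seed = 3)
  expect_true(all(co$panel$covariates$censored == 1))
  last_visit <- tapply(co$panel$visits$time, co$panel$visits$subject_id, max)
  expect_equal(unname(co$panel$covariates$death_time - co$panel$covariates$a0),
               as.numeric(last_visit[co$panel$covariates$subject_id]),
               tolerance = 1e-12)
})

test_that("constant-hazard survival sampling matches the exponential law", {
  tr <- ground_truth(base_hazard = list(breaks = c(100), male = c(0.1, 0.1),
                                        female = c(0.1, 0.1)),
                     gamma = rep(0, 6), gamma_r = 0, gamma_d = 0)
  seg <- data.frame(age_start = 0, age_end = 60, log_mult = 0)
  set.seed(99)
  times <- replicate(1000, simulate_survival(tr, seg, sex = 0)$death_time)
  cens <- times >= 60
  # empirical survival at t = 5 within binomial CI of exp(-0.5)
  p_hat <- mean(times > 5)
  p_true <- exp(-0.5)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 1000))
  expect_lt(mean(cens), 0.01)
})

test_that("stronger damage loading on mortality shortens simulated lifetimes", {
  # the mortality loading acts on the link scale (inverse Softplus), so the
  # check uses damage rates above log(2) where the link is positive
  mk <- function(gd) ground_truth(
    beta_d = c(softplus_inverse(1.0), 0.2, rep(0, 8)), gamma_d = gd)
  co1 <- simulate_cohort(mk(0.3), 150, seed = 8)
  co2 <- simulate_cohort(mk(0.6), 150, seed = 8)
  expect_lt(median(co2$panel$covariates$death_time),
            median(co1$panel$covariates$death_time))
})

test_that("invalid ground truths are rejected", {
  expect_error(ground_truth(re_corr = matrix(1, 4, 4)), "positive definite")
  bad <- diag(4); bad[1, 2] <- 0.5  # asymmetric
  expect_error(ground_truth(re_corr = bad), "symmetric")
  expect_error(ground_truth(schedule = c(0, 2, 2)), "increasing")
  expect_error(ground_truth(base_hazard = list(breaks = 20, male = c(-0.1, 0.2),
                                               female = c(0.1, 0.1))),
               "non-negative")
})

test_that("ground truth round-trips through its config serialization", {
  tr <- ground_truth()
  f <- tempfile(fileext = ".yaml")
  write_ground_truth(tr, f)
  tr2 <- read_ground_truth(f)
  expect_equal(tr2$beta_r, tr$beta_r, tolerance = 1e-12)
  expect_equal(tr2$re_corr, tr$re_corr, tolerance = 1e-12)
  expect_equal(tr2$standardize$center, tr$standardize$center, tolerance = 1e-12)
  co <- simulate_cohort(tr, 5, seed = 2)
  co2 <- simulate_cohort(tr2, 5, seed = 2)
  expect_identical(co$panel$deficits, co2$panel$deficits)
  unlink(f)
})
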
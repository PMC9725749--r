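test_that("state-interval extraction follows the entry/exit/censoring rules", {
  # visits 0..3, deficit 0,1,1,0: damaged spell entering at 1, exit in (2,3]
  p <- binary_panel(list(s1 = cbind(c(0, 1, 1, 0), c(1, 1, 1, 1))),
                    times = list(s1 = 0:3))
  rec <- extract_state_intervals(p)
  dmg <- rec[rec$state == "damaged", ]
  expect_equal(nrow(dmg), 1)
  expect_equal(dmg$entry, 1)
  expect_equal(dmg$t_lower, 1)  # last in-state visit 2 minus entry 1
  expect_equal(dmg$t_upper, 2)  # first out-of-state visit 3 minus entry 1
  # the 1 -> 0 transition at the last visit opens an undamaged spell censored
  # at length 0 (dropped); the all-1 item yields no record (onset unseen)
  expect_equal(nrow(rec), 1)
})

test_that("death while in-state right-censors at the last in-state visit", {
  p <- binary_panel(list(s1 = cbind(c(0, 1, 1))), times = list(s1 = 0:2))
  rec <- extract_state_intervals(p)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$censored, 1L)
  expect_equal(rec$t_censor, 1)  # last visit 2 minus entry 1
  # a run already in-state at the first visit is excluded
  p2 <- binary_panel(list(s1 = cbind(c(1, 1, 1))), times = list(s1 = 0:2))
  expect_equal(nrow(extract_state_intervals(p2)), 0)
})

test_that("midpoint entry option shifts the clock by half the entry interval", {
  p <- binary_panel(list(s1 = cbind(c(0, 1, 1, 0))), times = list(s1 = c(0, 2, 3, 4)))
  r1 <- extract_state_intervals(p, entry = "right")
  r2 <- extract_state_intervals(p, entry = "midpoint")
  d1 <- r1[r1$state == "damaged", ]; d2 <- r2[r2$state == "damaged", ]
  expect_equal(d2$entry, 1)
  expect_equal(d2$t_lower - d1$t_lower, 1)
})

test_that("Turnbull NPMLE reproduces exact-time and exponential oracles", {
  # uncensored-like narrow intervals at distinct times: mass 1/n each
  rec <- data.frame(t_lower = c(1, 2, 3), t_upper = c(1.01, 2.01, 3.01),
                    t_censor = NA_real_, censored = 0L)
  est <- npmle_interval(rec)
  expect_equal(sum(est$intervals$prob), 1, tolerance = 1e-8)
  expect_equal(est$surv(c(0.5, 1.5, 2.5, 3.5)), c(1, 2 / 3, 1 / 3, 0),
               tolerance = 1e-6)
  # exponential truth with interval censoring on a visit grid
  rec2 <- constant_hazard_records(400, 0.5, seq(0, 8, 0.5), seed = 12)
  est2 <- npmle_interval(rec2)
  tg <- c(1, 2, 3)
  expect_lt(max(abs(est2$surv(tg) - exp(-0.5 * tg))), 0.06)
  # self-consistency: total interval-record mass equals the record count
  A_mass <- vapply(seq_len(nrow(rec2)), function(i) {
    if (rec2$censored[i] == 1) return(NA_real_)
    est2$surv(rec2$t_lower[i]) - est2$surv(rec2$t_upper[i])
  }, numeric(1))
  expect_true(all(A_mass[!is.na(A_mass)] > 0))
})

test_that("interval-censored log-likelihood matches closed forms", {
  S_exp <- function(t) exp(-t)
  rec_all <- data.frame(t_lower = 0, t_upper = Inf, t_censor = NA_real_,
                        censored = 0L)
  expect_equal(interval_censored_loglik(rec_all, S_exp), 0)
  rec_c <- data.frame(t_lower = NA_real_, t_upper = NA_real_, t_censor = 2,
                      censored = 1L)
  expect_equal(interval_censored_loglik(rec_c, S_exp), -2)
  rec_bad <- data.frame(t_lower = 2, t_upper = 1, t_censor = NA_real_,
                        censored = 0L)
  expect_error(interval_censored_loglik(rec_bad, S_exp), "t_upper")
})

test_that("generalized log-rank: identical groups give statistic 0 and p = 1", {
  rec <- constant_hazard_records(60, 0.4, seq(0, 10, 1), seed = 7)
  both <- rbind(rec, rec)
  grp <- rep(c("A", "B"), each = nrow(rec))
  out <- generalized_logrank(both, grp, n_permutations = 199, seed = 1)
  expect_equal(out$statistic, 0, tolerance = 1e-18)
  expect_equal(out$p_value, 1)
  expect_error(generalized_logrank(rec, rep("A", nrow(rec)), 199), "2 groups")
  expect_error(generalized_logrank(rec, rep(c("A", "B"), 30), 50), "199")
})

test_that("generalized log-rank separates hazards differing two-fold", {
  r1 <- constant_hazard_records(150, 0.3, seq(0, 12, 1), seed = 21)
  r2 <- constant_hazard_records(150, 0.6, seq(0, 12, 1), seed = 22)
  out <- generalized_logrank(rbind(r1, r2),
                             rep(c("A", "B"), c(nrow(r1), nrow(r2))),
                             n_permutations = 399, seed = 3)
  expect_lt(out$p_value, 0.01)
})

test_that("state-survival knots and fit basics", {
  rec <- constant_hazard_records(300, 0.5, seq(0, 10, 0.25), seed = 31)
  rt <- ifelse(rec$censored == 1, rec$t_censor, (rec$t_lower + rec$t_upper) / 2)
  k <- make_knots_state(rt)
  expect_length(k, 32)
  fit <- fit_state_survival(rec, chains = 1, iter = 150, warmup = 200,
                            seed = 4, convergence = "none")
  a_cols <- paste0("a[", seq_len(length(fit$knots) + 1L), "]")
  expect_equal(unname(rowSums(fit$draws[, a_cols])), rep(1, nrow(fit$draws)),
               tolerance = 1e-10)
  expect_true(all(fit$draws[, a_cols] >= 0))
  sc <- state_survival_curves(fit, times = seq(0, 8, 0.5))
  expect_equal(unname(sc$draws[, 1]), rep(1, nrow(sc$draws)))
  expect_true(all(apply(sc$draws, 1, function(v) all(diff(v) <= 1e-12))))
})

test_that("all-censored records yield survival near 1 over the observation span", {
  rec <- data.frame(subject_id = sprintf("c%03d", 1:40), deficit_id = "d1",
                    state = "damaged", entry = 0, t_lower = NA_real_,
                    t_upper = NA_real_, t_censor = rep(c(2, 3, 4, 5), 10),
                    censored = 1L)
  expect_warning(
    fit <- fit_state_survival(rec, knots = seq(0.5, 5, length.out = 32),
                              chains = 1, iter = 100, warmup = 150, seed = 2,
                              convergence = "none"),
    "censored")
  sc <- state_survival_curves(fit, times = c(1, 2, 4))
  expect_gt(min(sc$summary$`50%`), 0.9)
})

test_that("time-axis rescaling rescales the fitted state-survival curve", {
  rec <- constant_hazard_records(250, 0.5, seq(0, 10, 0.25), seed = 55)
  rec2 <- rec
  rec2$t_lower <- 2 * rec2$t_lower; rec2$t_upper <- 2 * rec2$t_upper
  rec2$t_censor <- 2 * rec2$t_censor
  f1 <- fit_state_survival(rec, chains = 1, iter = 120, warmup = 180, seed = 9,
                           convergence = "none")
  f2 <- fit_state_survival(rec2, chains = 1, iter = 120, warmup = 180, seed = 9,
                           convergence = "none")
  t1 <- c(1, 2, 4)
  s1 <- state_survival_curves(f1, t1)$summary$`50%`
  s2 <- state_survival_curves(f2, 2 * t1)$summary$`50%`
  expect_equal(s1, s2, tolerance = 0.05)
})
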
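test_that("LOCF fills forward, then backward for leading gaps, and is identity without gaps", {
  p <- binary_panel(list(s1 = rbind(c(0), c(NA), c(1))))
  p$deficits[2, 1] <- NA
  out <- impute_locf(p)
  expect_equal(unname(out$deficits[, 1]), c(0, 0, 1))
  p2 <- binary_panel(list(s1 = rbind(c(NA), c(1), c(NA))))
  expect_equal(unname(impute_locf(p2)$deficits[, 1]), c(1, 1, 1))
  p3 <- binary_panel(list(s1 = rbind(c(0, 1), c(1, 0))))
  expect_identical(impute_locf(p3)$deficits, p3$deficits)
  pall <- binary_panel(list(sX = rbind(c(NA), c(NA))))
  expect_error(impute_locf(pall), "sX")
})

test_that("fractional encoding sets the first 4*value ordered bits", {
  expect_equal(encode_fractional(0.75)[1, ], c(1, 1, 1, 0))
  expect_equal(encode_fractional(0)[1, ], c(0, 0, 0, 0))
  expect_equal(encode_fractional(0.5)[1, ], c(1, 1, 0, 0))
  expect_equal(encode_fractional(1)[1, ], c(1, 1, 1, 1))
  expect_error(encode_fractional(0.3), "quarter|0.25|\\{0")
})

test_that("panel expansion quadruples items and preserves every FI value exactly", {
  panel <- impute_locf(tiny_fractional_panel())
  expanded <- expand_fractional(panel)
  expect_equal(ncol(expanded$deficits), 4L * ncol(panel$deficits))
  expect_identical(fi(expanded), fi(panel))
  # randomized fractional panels, exact FI preservation at every visit
  set.seed(31)
  for (rep in 1:5) {
    vals <- matrix(sample(c(0, 0.25, 0.5, 0.75, 1), 6 * 31, replace = TRUE), 6, 31)
    p <- binary_panel(list(a = vals[1:3, ], b = vals[4:6, ]))
    e <- expand_fractional(p)
    expect_identical(fi(e), fi(p))
    expect_true(all(e$deficits %in% c(0, 1)))
  }
})

test_that("visit gap filtering drops the later visit and re-evaluates against the last retained", {
  p <- binary_panel(list(s1 = rbind(0, 1, 0)), times = list(s1 = c(0, 0.05, 1)))
  out <- filter_visits(p, min_gap = 0.1)
  expect_equal(out$visits$time, c(0, 1))
  p2 <- binary_panel(list(s1 = rbind(0, 1, 0)), times = list(s1 = c(21, 22, 25)))
  out2 <- filter_visits(p2, max_gap = 2)
  expect_equal(out2$visits$time, c(21, 22))
  expect_equal(unique(out2$visits$subject_id), "s1")  # retained with 2 visits
  # single-visit subjects are removed
  p3 <- binary_panel(list(s1 = rbind(0, 1), s2 = rbind(1)),
                     times = list(s1 = c(0, 1), s2 = 0))
  expect_message(out3 <- filter_visits(p3), "dropped 1")
  expect_equal(unique(out3$visits$subject_id), "s1")
  # cascade: a removed visit does not shield the next one
  p4 <- binary_panel(list(s1 = rbind(0, 1, 0, 1)),
                     times = list(s1 = c(0, 0.05, 0.08, 1)))
  expect_equal(filter_visits(p4, min_gap = 0.1)$visits$time, c(0, 1))
})

test_that("human cohort selection applies age, gap, wave-count and wealth rules", {
  mk <- function(id, times, age0, wealth, imputed = FALSE) {
    list(visits = data.frame(subject_id = id, time = times),
         deficits = matrix(0, length(times), 3),
         cov = data.frame(subject_id = id, sex = 0, a0 = age0, wealth = wealth,
                          wealth_imputed = imputed))
  }
  subs <- list(
    mk("ok", seq(0, 10, 2), 60, 100),        # kept: 6 waves
    mk("few", seq(0, 8, 2), 60, 100),        # 5 waves -> dropped
    mk("gap", c(0, 2, 4, 6, 8, 13), 60, 100), # 5-year gap -> dropped
    mk("young", seq(0, 10, 2), 49.5, 100),   # baseline 49.5 -> dropped
    mk("edge", seq(0, 10, 2), 50.0, 100),    # baseline 50.0 -> kept
    mk("imp", seq(0, 10, 2), 60, 100, TRUE)) # imputed wealth -> dropped
  panel <- deficit_panel(do.call(rbind, lapply(subs, `[[`, "visits")),
                         do.call(rbind, lapply(subs, `[[`, "deficits")),
                         do.call(rbind, lapply(subs, `[[`, "cov")),
                         units = "years")
  out <- elsa_select(panel)
  expect_setequal(unique(out$visits$subject_id), c("ok", "edge"))
  # identical raw wealth c for everyone -> w = log(2c)
  expect_equal(out$covariates$wealth, rep(log(200), 2), tolerance = 1e-12)
  expect_equal(out$covariates$wealth_raw, rep(100, 2))
})

test_that("pruning flattens only single-visit excursions with 2 flanking visits each side", {
  p <- binary_panel(list(s1 = cbind(c(0, 0, 1, 0, 0), c(1, 1, 0, 1, 1),
                                    c(0, 1, 0, 1, 0))))
  out <- prune_isolated_transitions(p)
  expect_equal(unname(out$deficits[, 1]), rep(0, 5))
  expect_equal(unname(out$deficits[, 2]), rep(1, 5))
  expect_equal(unname(out$deficits[, 3]), c(0, 1, 0, 1, 0))  # insufficient flanks
  # {0,1,0} untouched (pattern requires 2 flanks on each side)
  p2 <- binary_panel(list(s1 = cbind(c(0, 1, 0))))
  expect_identical(prune_isolated_transitions(p2)$deficits, p2$deficits)
  # length-2 excursions are not pruned
  p3 <- binary_panel(list(s1 = cbind(c(0, 0, 1, 1, 0, 0))))
  expect_identical(prune_isolated_transitions(p3)$deficits, p3$deficits)
})

test_that("pruning is idempotent and never increases transition counts", {
  set.seed(91)
  n_trans <- function(panel) {
    sum(abs(apply(panel$deficits, 2, diff)))
  }
  for (rep in 1:10) {
    p <- binary_panel(list(s = matrix(rbinom(8 * 6, 1, 0.4), 8, 6)))
    pr <- prune_isolated_transitions(p)
    expect_lte(n_trans(pr), n_trans(p))
    expect_identical(prune_isolated_transitions(pr)$deficits, pr$deficits)
  }
})

test_that("filters preserve subject and visit order", {
  set.seed(5)
  tr <- constant_rate_truth(0.1, 0.05, n_items = 10, schedule = 0:5)
  co <- simulate_cohort(tr, 6, seed = 2, survival = FALSE)
  out <- filter_visits(co$panel, min_gap = 0.5)
  expect_identical(unique(out$visits$subject_id),
                   unique(co$panel$visits$subject_id))
  for (sid in unique(out$visits$subject_id)) {
    expect_false(is.unsorted(out$visits$time[out$visits$subject_id == sid],
                             strictly = TRUE))
  }
})
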
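#' Ground truth for synthetic cohorts
#'
#' Bundles every generating parameter of the synthetic-cohort generator: the
#' fixed-effect coefficient vectors on the standardized mouse design (rate
#' scale via Softplus), the random-effect covariance (SDs and correlation for
#' the 4-vector of repair/damage intercepts and time-slopes), the mortality
#' loadings, a piecewise-constant baseline hazard per sex, the item count,
#' the visit schedule, and the standardization constants that tie the
#' coefficients to raw covariates.
#'
#' Defaults emulate an aging mouse cohort observed roughly every 4 weeks: 124
#' binary items (a 31-item fractional frailty index expanded 4-fold), 10
#' monthly visits from a baseline age of about 16 months, repair rates around
#' 0.23/month at baseline declining with age, damage rates around 0.04/month
#' rising with age and with the frailty index (so the mean FI is flat to
#' gently rising early and accelerates late), moderately correlated
#' subject-level heterogeneity, and mortality that rises with the frailty
#' index and loads positively on the damage rate and negatively on the
#' repair rate. With monthly visits the per-item transition probabilities
#' stay well inside the Poisson model's domain (`lambda * dt` about 0.25 or
#' less).
#'
#' @param beta_r,beta_d Length-10 coefficient vectors on the standardized
#'   design `(1, t, sex, treatment, f, a0, sex:treatment, sex:t,
#'   treatment:t, sex:treatment:t)`.
#' @param re_sd Length-4 positive SDs of the subject random effects
#'   `(repair intercept, repair slope, damage intercept, damage slope)`.
#' @param re_corr 4 x 4 correlation matrix of the random effects (symmetric
#'   positive definite, unit diagonal).
#' @param gamma Length-6 survival coefficients on
#'   `(1, sex, treatment, sex:treatment, f, a0)`.
#' @param gamma_r,gamma_d Log-hazard loadings on the link-scale (inverse
#'   Softplus) repair and damage rates.
#' @param base_hazard List with `breaks` (increasing ages, first = -Inf
#'   implied) and per-sex rate vectors `male`, `female` (per month, length
#'   `length(breaks) + 1`).
#' @param n_items Total deficit count N.
#' @param schedule Strictly increasing visit times (time since baseline), or
#'   a list of such vectors (one per subject, recycled).
#' @param init_fi Expected frailty index at baseline (items start damaged
#'   independently with this probability).
#' @param age0_mean,age0_sd Baseline-age distribution.
#' @param p_female,p_treated Assignment probabilities for sex and treatment.
#' @param standardize Standardization constants (`center`, `scale` named
#'   vectors over `t, sex, treatment, f, a0`) fixing the scale of
#'   `beta_r`/`beta_d`. The defaults match the default schedule and
#'   covariate distributions.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(
    beta_r = c(-1.75, -0.25, -0.10, 0.15, -0.10, -0.05, 0.00, 0.05, 0.10, 0.00),
    beta_d = c(-2.70, 0.35, 0.10, -0.10, 0.20, 0.05, 0.00, -0.05, -0.10, 0.00),
    re_sd = c(0.30, 0.10, 0.30, 0.10),
    re_corr = default_re_corr(),
    gamma = c(-0.20, 0.00, -0.20, 0.00, 0.50, 0.10),
    gamma_r = -0.30,
    gamma_d = 0.50,
    base_hazard = list(breaks = c(20, 24),
                       male = c(0.02, 0.07, 0.18),
                       female = c(0.015, 0.05, 0.12)),
    n_items = 124L,
    schedule = 0:9,
    init_fi = 0.15,
    age0_mean = 16,
    age0_sd = 1,
    p_female = 0.5,
    p_treated = 0.5,
    standardize = NULL) {
  if (is.null(standardize)) {
    sched1 <- if (is.list(schedule)) schedule[[1L]] else schedule
    standardize <- list(
      center = c(t = mean(sched1), sex = p_female, treatment = p_treated,
                 f = init_fi + 0.05, a0 = age0_mean),
      scale = c(t = stats::sd(sched1), sex = 0.5, treatment = 0.5,
                f = 0.1, a0 = max(age0_sd, 1e-6))
    )
  }
  truth <- structure(
    list(beta_r = beta_r, beta_d = beta_d, re_sd = re_sd, re_corr = re_corr,
         gamma = gamma, gamma_r = gamma_r, gamma_d = gamma_d,
         base_hazard = base_hazard, n_items = as.integer(n_items),
         schedule = schedule, init_fi = init_fi, age0_mean = age0_mean,
         age0_sd = age0_sd, p_female = p_female, p_treated = p_treated,
         standardize = standardize),
    class = "ground_truth")
  validate_ground_truth(truth)
  truth
}

default_re_corr <- function() {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- -0.20  # repair intercept vs slope
  R[3, 4] <- R[4, 3] <- -0.20  # damage intercept vs slope
  R[1, 3] <- R[3, 1] <- -0.30  # repair vs damage intercepts
  R[2, 4] <- R[4, 2] <- 0.10
  R
}

validate_ground_truth <- function(truth) {
  stopifnot(length(truth$beta_r) == 10L, length(truth$beta_d) == 10L,
            length(truth$re_sd) == 4L, all(truth$re_sd >= 0),
            length(truth$gamma) == 6L, truth$n_items >= 1L,
            truth$init_fi >= 0, truth$init_fi <= 1)
  R <- truth$re_corr
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8)) {
    stop("re_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("re_corr is not positive definite", call. = FALSE)
  }
  scheds <- if (is.list(truth$schedule)) truth$schedule else list(truth$schedule)
  for (s in scheds) {
    if (length(s) < 1L || is.unsorted(s, strictly = TRUE)) {
      stop("schedule must be strictly increasing", call. = FALSE)
    }
  }
  bh <- truth$base_hazard
  stopifnot(length(bh$male) == length(bh$breaks) + 1L,
            length(bh$female) == length(bh$breaks) + 1L)
  if (any(c(bh$male, bh$female) < 0)) stop("base_hazard must be non-negative", call. = FALSE)
  invisible(truth)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

piecewise_rate <- function(age, breaks, rates) {
  rates[findInterval(age, breaks) + 1L]
}

#' Simulate a synthetic cohort with known damage/repair dynamics
#'
#' Generates a cohort from a [ground_truth()]: subject covariates, correlated
#' random effects, per-item Bernoulli damage and repair transitions at each
#' visit interval with exact exponential-interval probabilities
#' `1 - exp(-lambda * dt)`, and mortality by inverse-transform sampling of
#' the cumulative hazard. Rates are evaluated at the left endpoint of each
#' interval (frailty index feedback uses the interval-start FI). Transitions
#' are per item, so counts can never exceed the available items; the Poisson
#' likelihood of the fitted models is the small-rate approximation of this
#' process.
#'
#' @param truth A [ground_truth()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param survival If `FALSE`, skip mortality (all subjects censored at their
#'   final scheduled visit).
#' @param count_model `"bernoulli"` (default): each item transitions
#'   independently with the exact exponential-interval probability
#'   `1 - exp(-lambda * dt)` — a valid stochastic process whose per-interval
#'   expected counts equal `avail * (1 - exp(-lambda * dt))`, slightly below
#'   the Poisson mean `avail * lambda * dt` fitted by the models.
#'   `"poisson"`: transition counts are drawn from that Poisson distribution
#'   directly (capped at the available items, a practically impossible event
#'   at realistic rates) and assigned to uniformly chosen items; this is the
#'   model-consistent mode used for simulation-based calibration of the
#'   fitting machinery.
#' @return Object of class `simulated_cohort`: a list with `panel` (a
#'   [deficit_panel()] whose covariates carry `death_time` and `censored`),
#'   `true_rates` (data frame of the generating `lambda_r`, `lambda_d` per
#'   subject-visit), `truth`, and `seed`.
#' @export
simulate_cohort <- function(truth, n_subjects, seed = 1L, survival = TRUE,
                            count_model = c("bernoulli", "poisson")) {
  count_model <- match.arg(count_model)
  stopifnot(inherits(truth, "ground_truth"), n_subjects >= 1)
  validate_ground_truth(truth)
  with_seed(seed, {
    N <- truth$n_items
    Lc <- t(chol(truth$re_corr))
    scheds <- if (is.list(truth$schedule)) truth$schedule else list(truth$schedule)
    vis_list <- list(); def_list <- list(); rate_list <- list()
    cov_rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      sched <- scheds[[(i - 1L) %% length(scheds) + 1L]]
      J <- length(sched)
      sex <- stats::rbinom(1L, 1L, truth$p_female)
      treatment <- stats::rbinom(1L, 1L, truth$p_treated)
      a0 <- stats::rnorm(1L, truth$age0_mean, truth$age0_sd)
      b <- truth$re_sd * drop(Lc %*% stats::rnorm(4L))
      state <- stats::rbinom(N, 1L, truth$init_fi)
      states <- matrix(NA_real_, J, N)
      lam_r <- lam_d <- rep(NA_real_, J)
      seg <- data.frame(age_start = numeric(0), age_end = numeric(0),
                        log_mult = numeric(0))
      for (j in seq_len(J)) {
        states[j, ] <- state
        df_j <- data.frame(t = sched[j], sex = sex, treatment = treatment,
                           f = mean(state), a0 = a0)
        X <- mouse_design_matrix(df_j, truth$standardize)
        t_std <- (sched[j] - truth$standardize$center[["t"]]) /
          truth$standardize$scale[["t"]]
        eta_r <- drop(X %*% truth$beta_r) + b[1L] + b[2L] * t_std
        eta_d <- drop(X %*% truth$beta_d) + b[3L] + b[4L] * t_std
        lam_r[j] <- softplus(eta_r)
        lam_d[j] <- softplus(eta_d)
        if (j < J) {
          dt <- sched[j + 1L] - sched[j]
          damaged <- state == 1L
          if (count_model == "bernoulli") {
            p_rep <- -expm1(-lam_r[j] * dt)
            p_dam <- -expm1(-lam_d[j] * dt)
            flip_rep <- damaged & stats::runif(N) < p_rep
            flip_dam <- !damaged & stats::runif(N) < p_dam
            state[flip_rep] <- 0L
            state[flip_dam] <- 1L
          } else {
            n_av_r <- sum(damaged); n_av_d <- N - n_av_r
            k_r <- min(stats::rpois(1L, n_av_r * lam_r[j] * dt), n_av_r)
            k_d <- min(stats::rpois(1L, n_av_d * lam_d[j] * dt), n_av_d)
            if (k_r > 0) state[sample(which(damaged), k_r)] <- 0L
            if (k_d > 0) state[sample(which(!damaged), k_d)] <- 1L
          }
          U <- mouse_surv_matrix(df_j, truth$standardize)
          seg <- rbind(seg, data.frame(
            age_start = a0 + sched[j], age_end = a0 + sched[j + 1L],
            log_mult = drop(U %*% truth$gamma) + truth$gamma_r * eta_r +
              truth$gamma_d * eta_d))
        }
      }
      if (survival && nrow(seg)) {
        sv <- simulate_survival(truth, seg, sex = sex)
      } else {
        sv <- list(death_time = a0 + sched[J], censored = 1L)
      }
      keep <- if (sv$censored == 1L) seq_len(J) else which(a0 + sched <= sv$death_time)
      if (length(keep) == 0L) keep <- 1L  # death before 2nd visit: keep baseline
      vis_list[[i]] <- data.frame(subject_id = sprintf("s%04d", i),
                                  time = sched[keep])
      def_list[[i]] <- states[keep, , drop = FALSE]
      rate_list[[i]] <- data.frame(subject_id = sprintf("s%04d", i),
                                   time = sched[keep],
                                   lambda_r = lam_r[keep], lambda_d = lam_d[keep])
      cov_rows[[i]] <- data.frame(subject_id = sprintf("s%04d", i), sex = sex,
                                  treatment = treatment, a0 = a0,
                                  death_time = sv$death_time,
                                  censored = sv$censored)
    }
    panel <- deficit_panel(do.call(rbind, vis_list), do.call(rbind, def_list),
                           do.call(rbind, cov_rows), units = "months")
    structure(list(panel = panel, true_rates = do.call(rbind, rate_list),
                   truth = truth, seed = seed),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> seed %d\n", x$seed))
  print(x$panel)
  cat(sprintf("  deaths observed: %d / %d subjects\n",
              sum(x$panel$covariates$censored == 0),
              nrow(x$panel$covariates)))
  invisible(x)
}

#' Simulate a death time for one subject
#'
#' Inverse-transform sampling on the cumulative hazard
#' `h(t) = h0(t, sex) * exp(log_mult)` where `h0` is the piecewise-constant
#' baseline of the [ground_truth()] and `log_mult` holds the per-interval
#' covariate and rate loadings (`gamma . u + gamma_r eta_r + gamma_d eta_d`,
#' constant within each observation interval). The hazard is piecewise
#' constant, so the inversion is exact. Subjects whose cumulative hazard
#' never reaches the exponential draw are right-censored at the end of the
#' last interval.
#'
#' @param truth A [ground_truth()] (supplies the baseline hazard).
#' @param segments Data frame with `age_start`, `age_end`, `log_mult`, one
#'   row per observation interval, contiguous and increasing.
#' @param sex 0/1 (1 = female, selects the baseline).
#' @param seed Optional seed; by default draws from the current RNG stream.
#' @return List with `death_time` (age) and `censored` (1 = censored at the
#'   last interval end).
#' @export
simulate_survival <- function(truth, segments, sex, seed = NULL) {
  run <- function() {
    bh <- truth$base_hazard
    base <- if (sex >= 0.5) bh$female else bh$male
    target <- stats::rexp(1L)
    H <- 0
    for (r in seq_len(nrow(segments))) {
      a <- segments$age_start[r]; bnd <- segments$age_end[r]
      if (bnd <= a) stop("segments must have positive length", call. = FALSE)
      cuts <- sort(unique(c(a, bnd, bh$breaks[bh$breaks > a & bh$breaks < bnd])))
      for (s in seq_len(length(cuts) - 1L)) {
        h <- piecewise_rate(cuts[s], bh$breaks, base) * exp(segments$log_mult[r])
        if (h < 0) stop("internal consistency error: negative hazard", call. = FALSE)
        len <- cuts[s + 1L] - cuts[s]
        if (H + h * len >= target && h > 0) {
          return(list(death_time = cuts[s] + (target - H) / h, censored = 0L))
        }
        H <- H + h * len
      }
    }
    list(death_time = segments$age_end[nrow(segments)], censored = 1L)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
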
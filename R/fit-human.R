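# Human varying-coefficient model: design construction, a synthetic human
# cohort generator for testing, and the fit function.

human_parents <- c("t", "sex", "w", "f", "a0")
human_design_cols <- c("intercept", "t", "sex", "w", "f", "a0",
                       "sex:t", "w:t", "a0:t", "sex:f", "w:f", "a0:f")

human_design_matrix <- function(df, constants) {
  s <- std_cols(df, constants)
  X <- cbind(1, s$t, s$sex, s$w, s$f, s$a0,
             s$sex * s$t, s$w * s$t, s$a0 * s$t,
             s$sex * s$f, s$w * s$f, s$a0 * s$f)
  colnames(X) <- human_design_cols
  X
}

# multipliers of the four coefficient surfaces: (1, sex, t, sex*t),
# standardized parents
human_mult_matrix <- function(df, constants) {
  s <- std_cols(df, constants)
  M <- cbind(1, s$sex, s$t, s$sex * s$t)
  colnames(M) <- c("base", "sex", "t", "sex:t")
  M
}

#' Ground truth for synthetic human cohorts
#'
#' Generating parameters for an ELSA-like human panel: 23 binary deficits
#' (activities of daily living), visits every 2 years over 9 waves, baseline
#' ages 50-89, log-transformed net household wealth, no mortality. The four
#' coefficient surfaces per process are supplied as functions of
#' `(w, a0)` (constants are recycled), so flat-surface ground truths for
#' recovery checks and wealth-dependent ones for sign checks are both easy
#' to express.
#'
#' @param beta0_r,beta0_d Length-12 coefficients on the standardized design
#'   `(1, t, sex, w, f, a0, sex:t, w:t, a0:t, sex:f, w:f, a0:f)`.
#' @param surf_r,surf_d Lists of 4 surface specifications (constant or
#'   `function(w, a0)`), multiplying `(1, sex, t, sex*t)` respectively.
#' @param re_sd,re_corr SDs (length 2) and correlation of the
#'   repair/damage random intercepts.
#' @param n_items,schedule,init_fi,age0_range,p_female Study conditions.
#' @param wealth_meanlog,wealth_sdlog Raw wealth is log-normal; the stored
#'   covariate is `log(w_raw + mean(w_raw))` as in the preprocessing rules.
#' @param standardize Standardization constants over
#'   `t, sex, w, f, a0`; defaults match the default conditions.
#' @return Object of class `ground_truth_human`.
#' @export
ground_truth_human <- function(
    beta0_r = c(-1.8, -0.15, -0.05, 0.10, -0.10, -0.10, 0, 0, 0, 0, 0, 0),
    beta0_d = c(-3.2, 0.20, 0.05, -0.10, 0.15, 0.15, 0, 0, 0, 0, 0, 0),
    surf_r = list(0, 0, 0, 0),
    surf_d = list(0, 0, 0, 0),
    re_sd = c(0.4, 0.4),
    re_corr = matrix(c(1, -0.3, -0.3, 1), 2),
    n_items = 23L,
    schedule = seq(0, 16, by = 2),
    init_fi = 0.1,
    age0_range = c(50, 89),
    p_female = 0.55,
    wealth_meanlog = 11.5,
    wealth_sdlog = 1.0,
    standardize = NULL) {
  if (is.null(standardize)) {
    w_typ <- log(2 * exp(wealth_meanlog + wealth_sdlog^2 / 2))
    standardize <- list(
      center = c(t = mean(schedule), sex = p_female, w = w_typ,
                 f = init_fi + 0.05, a0 = mean(age0_range) - 8),
      scale = c(t = stats::sd(schedule), sex = 0.5, w = 0.6, f = 0.08, a0 = 9))
  }
  structure(list(beta0_r = beta0_r, beta0_d = beta0_d, surf_r = surf_r,
                 surf_d = surf_d, re_sd = re_sd, re_corr = re_corr,
                 n_items = as.integer(n_items), schedule = schedule,
                 init_fi = init_fi, age0_range = age0_range,
                 p_female = p_female, wealth_meanlog = wealth_meanlog,
                 wealth_sdlog = wealth_sdlog, standardize = standardize),
            class = "ground_truth_human")
}

surface_value <- function(spec, w, a0) {
  if (is.function(spec)) spec(w, a0) else rep_len(spec, length(w))
}

#' Simulate an ELSA-like human cohort
#'
#' Per-item Bernoulli transitions (or model-consistent Poisson counts) with
#' rates from the human varying-coefficient model structure; no mortality
#' (all subjects complete the schedule).
#'
#' @param truth A [ground_truth_human()].
#' @param n_subjects,seed,count_model As in [simulate_cohort()].
#' @return A `simulated_cohort` (panel units are years).
#' @export
simulate_human_cohort <- function(truth, n_subjects, seed = 1L,
                                  count_model = c("bernoulli", "poisson")) {
  count_model <- match.arg(count_model)
  stopifnot(inherits(truth, "ground_truth_human"), n_subjects >= 1)
  with_seed(seed, {
    N <- truth$n_items
    Lc <- t(chol(truth$re_corr))
    sched <- truth$schedule
    J <- length(sched)
    vis <- list(); defs <- list(); rates <- list(); covs <- list()
    for (i in seq_len(n_subjects)) {
      sex <- stats::rbinom(1L, 1L, truth$p_female)
      a0 <- stats::runif(1L, truth$age0_range[1L], truth$age0_range[2L])
      w_raw <- stats::rlnorm(1L, truth$wealth_meanlog, truth$wealth_sdlog)
      w <- log(w_raw + exp(truth$wealth_meanlog + truth$wealth_sdlog^2 / 2))
      b <- truth$re_sd * drop(Lc %*% stats::rnorm(2L))
      state <- stats::rbinom(N, 1L, truth$init_fi)
      states <- matrix(NA_real_, J, N)
      lam_r <- lam_d <- rep(NA_real_, J)
      for (j in seq_len(J)) {
        states[j, ] <- state
        df_j <- data.frame(t = sched[j], sex = sex, w = w, f = mean(state), a0 = a0)
        X <- human_design_matrix(df_j, truth$standardize)
        mult <- human_mult_matrix(df_j, truth$standardize)
        sr <- vapply(truth$surf_r, surface_value, numeric(1), w = w, a0 = a0)
        sd_ <- vapply(truth$surf_d, surface_value, numeric(1), w = w, a0 = a0)
        eta_r <- drop(X %*% truth$beta0_r) + sum(mult * sr) + b[1L]
        eta_d <- drop(X %*% truth$beta0_d) + sum(mult * sd_) + b[2L]
        lam_r[j] <- softplus(eta_r)
        lam_d[j] <- softplus(eta_d)
        if (j < J) {
          dt <- sched[j + 1L] - sched[j]
          damaged <- state == 1L
          if (count_model == "bernoulli") {
            flip_r <- damaged & stats::runif(N) < -expm1(-lam_r[j] * dt)
            flip_d <- !damaged & stats::runif(N) < -expm1(-lam_d[j] * dt)
            state[flip_r] <- 0L
            state[flip_d] <- 1L
          } else {
            n_av_r <- sum(damaged); n_av_d <- N - n_av_r
            k_r <- min(stats::rpois(1L, n_av_r * lam_r[j] * dt), n_av_r)
            k_d <- min(stats::rpois(1L, n_av_d * lam_d[j] * dt), n_av_d)
            if (k_r > 0) state[sample(which(damaged), k_r)] <- 0L
            if (k_d > 0) state[sample(which(!damaged), k_d)] <- 1L
          }
        }
      }
      id <- sprintf("h%04d", i)
      vis[[i]] <- data.frame(subject_id = id, time = sched)
      defs[[i]] <- states
      rates[[i]] <- data.frame(subject_id = id, time = sched,
                               lambda_r = lam_r, lambda_d = lam_d)
      covs[[i]] <- data.frame(subject_id = id, sex = sex, a0 = a0,
                              wealth = w, wealth_raw = w_raw)
    }
    panel <- deficit_panel(do.call(rbind, vis), do.call(rbind, defs),
                           do.call(rbind, covs), units = "years")
    structure(list(panel = panel, true_rates = do.call(rbind, rates),
                   truth = truth, seed = seed),
              class = "simulated_cohort")
  })
}

#' Random-walk smoothing log-prior for a coefficient surface
#'
#' Log-density of the 2D random-walk smoothing prior on a 5 x 5 surface
#' coefficient grid: the corner cell is N(0,1); first-row/first-column cells
#' follow a one-sided walk along their only available axis; interior cells
#' follow a two-component density mixture
#' `p_w N(s[i-1,j], tau_w) + p_b0 N(s[i,j-1], tau_b0)`.
#'
#' @param s 5 x 5 coefficient grid (rows: wealth axis, columns: baseline-age
#'   axis).
#' @param tau_w,tau_b0 Positive step scales.
#' @param p_w Mixture weight of the wealth-axis step (`p_b0 = 1 - p_w`).
#' @return Log prior density (scalar).
#' @export
random_walk_logprior <- function(s, tau_w, tau_b0, p_w) {
  stopifnot(is.matrix(s), nrow(s) == 5L, ncol(s) == 5L)
  if (tau_w <= 0 || tau_b0 <= 0) stop("step scales must be positive", call. = FALSE)
  if (p_w < 0 || p_w > 1) stop("p_w must lie in [0, 1]", call. = FALSE)
  lp <- stats::dnorm(s[1L, 1L], 0, 1, log = TRUE)
  for (j in seq_len(5L)) {
    for (i in seq_len(5L)) {
      if (i == 1L && j == 1L) next
      if (j == 1L) {
        lp <- lp + stats::dnorm(s[i, 1L], s[i - 1L, 1L], tau_w, log = TRUE)
      } else if (i == 1L) {
        lp <- lp + stats::dnorm(s[1L, j], s[1L, j - 1L], tau_b0, log = TRUE)
      } else {
        mix <- p_w * stats::dnorm(s[i, j], s[i - 1L, j], tau_w) +
          (1 - p_w) * stats::dnorm(s[i, j], s[i, j - 1L], tau_b0)
        lp <- lp + log(mix)
      }
    }
  }
  lp
}

#' Fit the non-linear varying-coefficient model for human cohorts
#'
#' The human analogue of [fit_mouse_joint()]: Poisson damage/repair counts
#' with Softplus-linear rates whose intercept, sex, time and sex-time
#' coefficients vary smoothly with net household wealth and baseline age via
#' tensor-product quadratic B-spline surfaces (5 x 5 coefficients per
#' surface, knots at the minimum, terciles and maximum of each variable)
#' under 2D random-walk smoothing priors; subjects get correlated random
#' intercepts only (no subject time-slopes), and there is no survival
#' component.
#'
#' @param counts A [count_transitions()] result whose covariates include
#'   `sex`, `wealth` and `a0`.
#' @param knots_w,knots_a0 Surface knots; default [surface_knots()] on the
#'   per-subject wealth and baseline-age values.
#' @inheritParams fit_mouse_joint
#' @return A `human_spline_fit` with draws of `beta0_r[...]`,
#'   `beta0_d[...]`, surface coefficients `S_r[k;i,j]`, `S_d[k;i,j]`,
#'   `sigma[...]`, `Omega[2,1]`, `tau_*`, `p_w_*`, and random intercepts.
#' @export
fit_human_spline <- function(counts, knots_w = NULL, knots_a0 = NULL,
                             standardize = NULL, chains = 2L, iter = 1000L,
                             warmup = 1000L, seed = 1L, adapt_delta = 0.8,
                             max_treedepth = 10L,
                             convergence = c("error", "warn", "none")) {
  convergence <- match.arg(convergence)
  stopifnot(inherits(counts, "transition_counts"))
  if (is.null(counts$wealth) || is.null(counts$a0)) {
    stop("counts must carry 'wealth' and 'a0' covariates", call. = FALSE)
  }
  counts$w <- counts$wealth
  N <- attr(counts, "n_items")
  subjects <- unique(counts$subject_id)
  n <- length(subjects)
  si <- match(counts$subject_id, subjects) - 1L
  if (is.null(standardize)) standardize <- standardize_constants(counts, human_parents)

  first <- !duplicated(counts$subject_id)
  sub_cov <- counts[first, c("subject_id", "sex", "w", "a0")]
  sub_cov <- sub_cov[match(subjects, sub_cov$subject_id), ]
  if (is.null(knots_w)) knots_w <- surface_knots(sub_cov$w)
  if (is.null(knots_a0)) knots_a0 <- surface_knots(sub_cov$a0)
  Bw <- bspline_basis5(sub_cov$w, knots_w)
  Ba <- bspline_basis5(sub_cov$a0, knots_a0)
  TB <- t(vapply(seq_len(n), function(i) as.vector(outer(Bw[i, ], Ba[i, ])),
                 numeric(25L)))

  data <- list(model_flag = 2L,
               X0 = human_design_matrix(counts, standardize),
               MULT = human_mult_matrix(counts, standardize),
               TB = TB, subj = si, nr = counts$n_r, nd = counts$n_d,
               avail_r = counts$n, avail_d = N - counts$n, dt = counts$dt,
               lgam_nr = lgamma(counts$n_r + 1), lgam_nd = lgamma(counts$n_d + 1))
  pars <- list(beta0_r = c(init_link_intercept(counts, "repair"), rep(0, 11)),
               beta0_d = c(init_link_intercept(counts, "damage"), rep(0, 11)),
               S_r = matrix(0, 25, 4), S_d = matrix(0, 25, 4),
               z = matrix(0, 2, n), log_sigma = rep(log(0.3), 2),
               corr_y = 0, log_tau = rep(log(0.5), 4), p_y = rep(0, 2))
  obj <- TMB::MakeADFun(data = data, parameters = pars, DLL = "damagerepair",
                        silent = TRUE)
  res <- run_chains(obj, obj$par, warmup, iter, chains, seed, adapt_delta,
                    max_treedepth)
  un <- do.call(rbind, lapply(res, function(x) x$draws))
  chain_id <- rep(seq_len(chains), each = iter)
  layout <- par_layout(pars)
  natural <- human_natural_draws(un, layout, n)
  fixed <- c(paste0("beta0_r[", human_design_cols, "]"),
             paste0("beta0_d[", human_design_cols, "]"),
             paste0("sigma[", 1:2, "]"))
  assemble_fit("human_spline", res, natural, chain_id, fixed,
               data = data,
               extras = list(standardize = standardize, knots_w = knots_w,
                             knots_a0 = knots_a0, subjects = subjects,
                             n_items = N, counts = counts,
                             settings = list(chains = chains, iter = iter,
                                             warmup = warmup, seed = seed)),
               convergence = convergence)
}

surf_names <- function(proc) {
  grid <- expand.grid(i = 1:5, j = 1:5)
  unlist(lapply(1:4, function(k)
    sprintf("S_%s[%d;%d,%d]", proc, k, grid$i, grid$j)))
}

human_natural_draws <- function(un, layout, n) {
  ndraw <- nrow(un)
  cn <- c(paste0("beta0_r[", human_design_cols, "]"),
          paste0("beta0_d[", human_design_cols, "]"),
          surf_names("r"), surf_names("d"),
          paste0("sigma[", 1:2, "]"), "Omega[2,1]",
          "tau_w_r", "tau_b0_r", "tau_w_d", "tau_b0_d", "p_w_r", "p_w_d",
          paste0("b[", rep(seq_len(n), each = 2), ",", rep(1:2, n), "]"))
  out <- matrix(NA_real_, ndraw, length(cn), dimnames = list(NULL, cn))
  out[, 1:12] <- un[, layout$beta0_r]
  out[, 13:24] <- un[, layout$beta0_d]
  out[, 25:124] <- un[, layout$S_r]
  out[, 125:224] <- un[, layout$S_d]
  sig <- exp(un[, layout$log_sigma, drop = FALSE])
  out[, 225:226] <- sig
  rho <- tanh(un[, layout$corr_y])
  out[, 227] <- rho
  out[, 228:231] <- exp(un[, layout$log_tau])
  out[, 232:233] <- stats::plogis(un[, layout$p_y])
  b_cols <- 234:ncol(out)
  for (d in seq_len(ndraw)) {
    Lc <- matrix(c(1, rho[d], 0, sqrt(1 - rho[d]^2)), 2, 2)
    z <- matrix(un[d, layout$z], 2L, n)
    out[d, b_cols] <- as.vector(sig[d, ] * (Lc %*% z))
  }
  out
}

#' Posterior coefficient surfaces on a wealth-age grid
#'
#' Evaluates the fitted coefficient surfaces `beta_k(w, a0)` of a human
#' model on a grid, per posterior draw.
#'
#' @param fit A `human_spline_fit`.
#' @param w,a0 Grid coordinates (defaults: 25 points across each knot span).
#' @param process `"repair"` or `"damage"`.
#' @param k Surface index 1-4 (multiplying 1, sex, t, sex*t).
#' @return Data frame with `w, a0, draw, value`.
#' @export
surface_draws <- function(fit, w = NULL, a0 = NULL,
                          process = c("repair", "damage"), k = 1L) {
  process <- match.arg(process)
  stopifnot(inherits(fit, "human_spline_fit"), k %in% 1:4)
  if (is.null(w)) w <- seq(fit$knots_w[1L], fit$knots_w[4L], length.out = 25L)
  if (is.null(a0)) a0 <- seq(fit$knots_a0[1L], fit$knots_a0[4L], length.out = 25L)
  grid <- expand.grid(w = w, a0 = a0)
  Bw <- bspline_basis5(grid$w, fit$knots_w)
  Ba <- bspline_basis5(grid$a0, fit$knots_a0)
  TB <- vapply(seq_len(nrow(grid)),
               function(i) as.vector(outer(Bw[i, ], Ba[i, ])), numeric(25L))
  proc <- if (process == "repair") "r" else "d"
  cols <- sprintf("S_%s[%d;%d,%d]", proc, k,
                  rep(1:5, 5), rep(1:5, each = 5))
  vals <- fit$draws[, cols, drop = FALSE] %*% TB
  data.frame(w = rep(grid$w, each = nrow(vals)),
             a0 = rep(grid$a0, each = nrow(vals)),
             draw = rep(seq_len(nrow(vals)), nrow(grid)),
             value = as.vector(vals))
}
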
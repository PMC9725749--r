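#' Fit the joint longitudinal-survival model for mouse cohorts
#'
#' The Bayesian joint model of damage/repair dynamics and mortality. The
#' longitudinal component models per-interval repair and damage counts as
#' Poisson with means `n lambda_r dt` and `(N - n) lambda_d dt`, where the
#' rates are Softplus-linear in the standardized covariates
#' `(1, t, sex, treatment, f, a0)` and their sex/treatment/time interactions,
#' with correlated subject-specific intercepts and time-slopes for both
#' processes (4-dimensional random effect, LKJ(2)-correlated, half-Cauchy
#' SDs, non-centered). The survival component is a proportional-hazards model
#' with sex-specific M-spline baseline hazards on the age axis and log-hazard
#' loadings `gamma_r`, `gamma_d` on the link-scale (inverse-Softplus) repair
#' and damage rates; the cumulative hazard is computed by 5-point
#' Gauss-Legendre quadrature between observed visits. Priors: N(0,3) on
#' intercepts, N(0,1) on coefficients, Dirichlet(1) on the baseline-hazard
#' simplexes.
#'
#' Sampling uses the package's No-U-Turn sampler on the TMB-differentiated
#' joint posterior. The fit fails (or warns, per `convergence`) if split-Rhat
#' exceeds 1.05 on any fixed effect.
#'
#' @param counts A [count_transitions()] result whose covariates include
#'   `sex`, `treatment`, `a0`, and (unless `survival = FALSE`) `death_time`
#'   (age at death or censoring) and `censored` (1 = censored).
#' @param survival Include the survival component? With `FALSE` the model
#'   reduces to the longitudinal Poisson model.
#' @param knots Baseline-hazard knots; default [make_knots_mouse()] on the
#'   last-follow-up ages.
#' @param standardize Optional standardization constants (as stored in a
#'   [ground_truth()]); default: computed from `counts`.
#' @param chains,iter,warmup MCMC settings (per chain).
#' @param seed Integer seed; chains are offset deterministically.
#' @param adapt_delta,max_treedepth Sampler tuning.
#' @param convergence Action on split-Rhat > 1.05: `"error"`, `"warn"` or
#'   `"none"`.
#' @return A `mouse_joint_fit` object: posterior draws of all natural
#'   parameters (`beta_r[...]`, `beta_d[...]`, `sigma[...]`, `Omega[i,j]`,
#'   `gamma[...]`, `gamma_r`, `gamma_d`, `a_male[l]`, `a_female[l]`, subject
#'   random effects `b[subject,component]`), diagnostics, and the design
#'   metadata needed by the derived-quantity functions.
#' @export
fit_mouse_joint <- function(counts, survival = TRUE, knots = NULL,
                            standardize = NULL, chains = 2L, iter = 1000L,
                            warmup = 1000L, seed = 1L, adapt_delta = 0.8,
                            max_treedepth = 10L,
                            convergence = c("error", "warn", "none")) {
  convergence <- match.arg(convergence)
  stopifnot(inherits(counts, "transition_counts"))
  N <- attr(counts, "n_items")
  subjects <- unique(counts$subject_id)
  n <- length(subjects)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  si <- match(counts$subject_id, subjects) - 1L
  if (is.null(counts$treatment)) counts$treatment <- 0
  if (is.null(counts$a0)) stop("counts must carry baseline age 'a0'", call. = FALSE)
  if (is.null(standardize)) standardize <- standardize_constants(counts)

  bad_r <- counts$n == 0 & counts$n_r > 0
  bad_d <- counts$n == N & counts$n_d > 0
  if (any(bad_r) || any(bad_d)) {
    stop("count exceeds available items (invariant violation upstream)", call. = FALSE)
  }

  X <- mouse_design_matrix(counts, standardize)
  t_std <- (counts$t - standardize$center[["t"]]) / standardize$scale[["t"]]

  first <- !duplicated(counts$subject_id)
  sub_cov <- counts[first, c("subject_id", "sex", "treatment", "a0")]
  sub_cov <- sub_cov[match(subjects, sub_cov$subject_id), ]

  data <- list(model_flag = 1L, X = X, t_std = t_std, subj = si,
               nr = counts$n_r, nd = counts$n_d,
               avail_r = counts$n, avail_d = N - counts$n, dt = counts$dt,
               lgam_nr = lgamma(counts$n_r + 1), lgam_nd = lgamma(counts$n_d + 1),
               has_survival = as.integer(survival))

  if (survival) {
    if (is.null(counts$death_time) || is.null(counts$censored)) {
      stop("survival = TRUE needs 'death_time' and 'censored' covariates", call. = FALSE)
    }
    sv <- counts[first, c("subject_id", "death_time", "censored")]
    sv <- sv[match(subjects, sv$subject_id), ]
    if (is.null(knots)) knots <- make_knots_mouse(sv$death_time)
    qd <- mouse_quadrature(counts, sv, sub_cov, knots, standardize)
    data <- c(data, qd,
              list(death = as.integer(sv$censored == 0),
                   sexf = as.integer(sub_cov$sex >= 0.5)))
  } else {
    knots <- if (is.null(knots)) seq(0, 1, length.out = 17L) else knots
    # placeholder survival blocks (unused branch in the template)
    data <- c(data, list(
      death = integer(n), sexf = integer(n),
      UT = matrix(0, n, 6), XT = matrix(0, n, 10), tT_std = numeric(n),
      BT = matrix(0, n, length(knots) + 1L), UQ = matrix(0, 1, 6),
      XQ = matrix(0, 1, 10), tQ_std = 0, subjQ = 0L, wQ = 0,
      BQi = matrix(-1L, 1, 4), BQw = matrix(0, 1, 4)))
  }

  L <- length(knots) + 1L  # quadratic M-spline basis count
  pars <- list(beta_r = c(init_link_intercept(counts, "repair"), rep(0, 9)),
               beta_d = c(init_link_intercept(counts, "damage"), rep(0, 9)),
               z = matrix(0, 4, n), log_sigma = rep(log(0.3), 4),
               corr_y = rep(0, 6), gamma = rep(0, 6),
               gamma_r = 0, gamma_d = 0,
               ya_m = rep(0, L - 1L), ya_f = rep(0, L - 1L))
  obj <- TMB::MakeADFun(data = data, parameters = pars, DLL = "damagerepair",
                        silent = TRUE)
  res <- run_chains(obj, obj$par, warmup, iter, chains, seed, adapt_delta,
                    max_treedepth)
  un <- do.call(rbind, lapply(res, function(x) x$draws))
  chain_id <- rep(seq_len(chains), each = iter)

  layout <- par_layout(pars)
  natural <- mouse_natural_draws(un, layout, n, L, survival)
  fixed <- c(paste0("beta_r[", mouse_design_cols, "]"),
             paste0("beta_d[", mouse_design_cols, "]"),
             paste0("sigma[", 1:4, "]"))
  if (survival) {
    fixed <- c(fixed, paste0("gamma[", mouse_surv_cols, "]"), "gamma_r", "gamma_d")
  }
  assemble_fit("mouse_joint", res, natural, chain_id, fixed,
               data = data,
               extras = list(standardize = standardize, knots = knots,
                             subjects = subjects, n_items = N,
                             survival = survival, counts = counts,
                             settings = list(chains = chains, iter = iter,
                                             warmup = warmup, seed = seed)),
               convergence = convergence)
}

# positions of each parameter block in the flat unconstrained vector
par_layout <- function(pars) {
  lens <- vapply(pars, length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

mouse_natural_draws <- function(un, layout, n, L, survival) {
  ndraw <- nrow(un)
  cn <- c(paste0("beta_r[", mouse_design_cols, "]"),
          paste0("beta_d[", mouse_design_cols, "]"),
          paste0("sigma[", 1:4, "]"),
          paste0("Omega[", c("2,1", "3,1", "3,2", "4,1", "4,2", "4,3"), "]"),
          paste0("gamma[", mouse_surv_cols, "]"), "gamma_r", "gamma_d",
          paste0("a_male[", seq_len(L), "]"),
          paste0("a_female[", seq_len(L), "]"),
          paste0("b[", rep(seq_len(n), each = 4), ",", rep(1:4, n), "]"))
  out <- matrix(NA_real_, ndraw, length(cn), dimnames = list(NULL, cn))
  out[, 1:10] <- un[, layout$beta_r]
  out[, 11:20] <- un[, layout$beta_d]
  sig <- exp(un[, layout$log_sigma, drop = FALSE])
  out[, 21:24] <- sig
  for (d in seq_len(ndraw)) {
    Lc <- corr_chol_from_unconstrained(un[d, layout$corr_y], 4L)
    Om <- Lc %*% t(Lc)
    out[d, 25:30] <- Om[lower.tri(Om)][c(1, 2, 4, 3, 5, 6)]
    z <- matrix(un[d, layout$z], 4L, n)
    b <- sig[d, ] * (Lc %*% z)
    out[d, (31 + 6 + 2 + 2 * L):ncol(out)] <- as.vector(b)
    out[d, (39 + 2 * 0):(38 + L)] <- simplex_from_unconstrained(un[d, layout$ya_m])
    out[d, (39 + L):(38 + 2 * L)] <- simplex_from_unconstrained(un[d, layout$ya_f])
  }
  out[, 31:36] <- un[, layout$gamma]
  out[, 37] <- un[, layout$gamma_r]
  out[, 38] <- un[, layout$gamma_d]
  out
}
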
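#' Posterior damage/repair rate curves for a covariate profile
#'
#' Evaluates, per posterior draw, the repair rate, damage rate and frailty
#' index over a time grid for a fixed covariate profile (random effects at
#' zero unless a subject is named). The frailty-index trajectory is obtained
#' by integrating `df/dt = (1 - f) lambda_d - f lambda_r` (classic RK4 on
#' the grid, with the rates' dependence on `f` fed back at every stage), so
#' the rate curves and the FI curve are mutually consistent within each
#' draw.
#'
#' @param fit A `mouse_joint_fit` or `human_spline_fit`.
#' @param profile Named list: `sex`, `treatment` (mouse), `wealth` (human),
#'   `a0`, and `f0` (FI at `times[1]`). Missing entries default to the data
#'   means.
#' @param times Increasing time grid (time since baseline, panel units).
#' @param draws Optional draw indices (default: all).
#' @param subject Optional subject id whose posterior random effects are
#'   added to the linear predictors.
#' @return Object of class `rate_curve`: list with `times` and
#'   draws-by-times matrices `lambda_r`, `lambda_d`, `f`, plus the per-draw
#'   link-scale time-derivative pieces used by [rate_time_slope()].
#' @export
rate_curve <- function(fit, profile = list(), times, draws = NULL,
                       subject = NULL) {
  stopifnot(inherits(fit, "damagerepair_fit"),
            length(times) >= 2L, !is.unsorted(times, strictly = TRUE))
  lin <- curve_linpred(fit, profile, draws, subject)
  nd <- lin$n_draws
  nt <- length(times)
  f0 <- profile$f0
  if (is.null(f0)) f0 <- fit$standardize$center[["f"]]
  lambda_r <- lambda_d <- fmat <- matrix(NA_real_, nd, nt)
  f <- rep(f0, nd)
  for (j in seq_len(nt)) {
    er <- lin$eta_r(times[j], f)
    ed <- lin$eta_d(times[j], f)
    lambda_r[, j] <- softplus(er)
    lambda_d[, j] <- softplus(ed)
    fmat[, j] <- f
    if (j < nt) {
      h <- times[j + 1L] - times[j]
      fdot <- function(tt, ff) {
        (1 - ff) * softplus(lin$eta_d(tt, ff)) - ff * softplus(lin$eta_r(tt, ff))
      }
      k1 <- fdot(times[j], f)
      k2 <- fdot(times[j] + h / 2, f + h / 2 * k1)
      k3 <- fdot(times[j] + h / 2, f + h / 2 * k2)
      k4 <- fdot(times[j] + h, f + h * k3)
      f <- pmin(pmax(f + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0), 1)
    }
  }
  structure(list(times = times, lambda_r = lambda_r, lambda_d = lambda_d,
                 f = fmat, deta_dt_r = lin$deta_dt_r, deta_dt_d = lin$deta_dt_d,
                 deta_df_r = lin$deta_df_r, deta_df_d = lin$deta_df_d,
                 profile = lin$profile, units = attr(fit$counts, "units")),
            class = "rate_curve")
}

# model-specific linear predictors eta(t, f) vectorized over draws, plus the
# per-draw constants d eta / dt (holding f) and d eta / df
curve_linpred <- function(fit, profile, draws, subject) {
  dr <- fit$draws
  if (!is.null(draws)) dr <- dr[draws, , drop = FALSE]
  nd <- nrow(dr)
  cn <- fit$standardize$center; sc <- fit$standardize$scale
  pick <- function(name, default) if (!is.null(profile[[name]])) profile[[name]] else default

  if (inherits(fit, "mouse_joint_fit")) {
    sex <- pick("sex", cn[["sex"]]); trt <- pick("treatment", cn[["treatment"]])
    a0 <- pick("a0", cn[["a0"]])
    s_sex <- (sex - cn[["sex"]]) / sc[["sex"]]
    s_trt <- (trt - cn[["treatment"]]) / sc[["treatment"]]
    s_a0 <- (a0 - cn[["a0"]]) / sc[["a0"]]
    B_r <- dr[, paste0("beta_r[", mouse_design_cols, "]"), drop = FALSE]
    B_d <- dr[, paste0("beta_d[", mouse_design_cols, "]"), drop = FALSE]
    b <- matrix(0, nd, 4L)
    if (!is.null(subject)) {
      i <- match(subject, fit$subjects)
      if (is.na(i)) stop("unknown subject", call. = FALSE)
      b <- dr[, paste0("b[", i, ",", 1:4, "]"), drop = FALSE]
    }
    make_eta <- function(B, b0, b1) {
      force(B)
      function(t, f) {
        s_t <- (t - cn[["t"]]) / sc[["t"]]
        s_f <- (f - cn[["f"]]) / sc[["f"]]
        B[, 1L] + B[, 2L] * s_t + B[, 3L] * s_sex + B[, 4L] * s_trt +
          B[, 5L] * s_f + B[, 6L] * s_a0 + B[, 7L] * s_sex * s_trt +
          B[, 8L] * s_sex * s_t + B[, 9L] * s_trt * s_t +
          B[, 10L] * s_sex * s_trt * s_t + b0 + b1 * s_t
      }
    }
    ddt <- function(B, b1) {
      (B[, 2L] + B[, 8L] * s_sex + B[, 9L] * s_trt +
         B[, 10L] * s_sex * s_trt + b1) / sc[["t"]]
    }
    list(n_draws = nd,
         eta_r = make_eta(B_r, b[, 1L], b[, 2L]),
         eta_d = make_eta(B_d, b[, 3L], b[, 4L]),
         deta_dt_r = ddt(B_r, b[, 2L]), deta_dt_d = ddt(B_d, b[, 4L]),
         deta_df_r = B_r[, 5L] / sc[["f"]], deta_df_d = B_d[, 5L] / sc[["f"]],
         profile = list(sex = sex, treatment = trt, a0 = a0))
  } else if (inherits(fit, "human_spline_fit")) {
    sex <- pick("sex", cn[["sex"]]); w <- pick("wealth", cn[["w"]])
    a0 <- pick("a0", cn[["a0"]])
    s_sex <- (sex - cn[["sex"]]) / sc[["sex"]]
    s_w <- (w - cn[["w"]]) / sc[["w"]]
    s_a0 <- (a0 - cn[["a0"]]) / sc[["a0"]]
    B_r <- dr[, paste0("beta0_r[", human_design_cols, "]"), drop = FALSE]
    B_d <- dr[, paste0("beta0_d[", human_design_cols, "]"), drop = FALSE]
    wq <- pmin(pmax(w, fit$knots_w[1L]), fit$knots_w[4L])
    aq <- pmin(pmax(a0, fit$knots_a0[1L]), fit$knots_a0[4L])
    TBp <- as.vector(outer(drop(bspline_basis5(wq, fit$knots_w)),
                           drop(bspline_basis5(aq, fit$knots_a0))))
    g <- function(proc) {
      vapply(1:4, function(k) {
        cols <- sprintf("S_%s[%d;%d,%d]", proc, k, rep(1:5, 5), rep(1:5, each = 5))
        drop(dr[, cols, drop = FALSE] %*% TBp)
      }, numeric(nd))
    }
    G_r <- g("r"); G_d <- g("d")  # nd x 4
    b <- matrix(0, nd, 2L)
    if (!is.null(subject)) {
      i <- match(subject, fit$subjects)
      if (is.na(i)) stop("unknown subject", call. = FALSE)
      b <- dr[, paste0("b[", i, ",", 1:2, "]"), drop = FALSE]
    }
    make_eta <- function(B, G, b0) {
      function(t, f) {
        s_t <- (t - cn[["t"]]) / sc[["t"]]
        s_f <- (f - cn[["f"]]) / sc[["f"]]
        B[, 1L] + B[, 2L] * s_t + B[, 3L] * s_sex + B[, 4L] * s_w +
          B[, 5L] * s_f + B[, 6L] * s_a0 + B[, 7L] * s_sex * s_t +
          B[, 8L] * s_w * s_t + B[, 9L] * s_a0 * s_t +
          B[, 10L] * s_sex * s_f + B[, 11L] * s_w * s_f +
          B[, 12L] * s_a0 * s_f +
          G[, 1L] + G[, 2L] * s_sex + G[, 3L] * s_t + G[, 4L] * s_sex * s_t +
          b0
      }
    }
    ddt <- function(B, G) {
      (B[, 2L] + B[, 7L] * s_sex + B[, 8L] * s_w + B[, 9L] * s_a0 +
         G[, 3L] + G[, 4L] * s_sex) / sc[["t"]]
    }
    ddf <- function(B) {
      (B[, 5L] + B[, 10L] * s_sex + B[, 11L] * s_w + B[, 12L] * s_a0) / sc[["f"]]
    }
    list(n_draws = nd,
         eta_r = make_eta(B_r, G_r, b[, 1L]),
         eta_d = make_eta(B_d, G_d, b[, 2L]),
         deta_dt_r = ddt(B_r, G_r), deta_dt_d = ddt(B_d, G_d),
         deta_df_r = ddf(B_r), deta_df_d = ddf(B_d),
         profile = list(sex = sex, wealth = w, a0 = a0))
  } else {
    stop("rate curves are defined for mouse_joint and human_spline fits",
         call. = FALSE)
  }
}

#' Frailty-index time-derivative per posterior draw
#'
#' `df/dt = (1 - f) lambda_d - f lambda_r`, evaluated pointwise on the
#' curve's grid for every draw.
#'
#' @param curve A [rate_curve()].
#' @return Draws-by-times matrix.
#' @export
fi_derivative <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  (1 - curve$f) * curve$lambda_d - curve$f * curve$lambda_r
}

#' Time-slopes of the repair and damage rates per posterior draw
#'
#' The total time-derivative of each rate along the model trajectory,
#' including the feedback through the rising frailty index:
#' `dlambda/dt = (deta/dt + deta/df df/dt) * logistic(eta)` where `eta` is
#' the link-scale linear predictor (the Softplus derivative is the logistic
#' of `eta`).
#'
#' @param curve A [rate_curve()].
#' @return List with draws-by-times matrices `repair` and `damage`.
#' @export
rate_time_slope <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  fdot <- fi_derivative(curve)
  # recover eta from lambda: eta = softplus_inverse(lambda)
  eta_r <- softplus_inverse(pmax(curve$lambda_r, 1e-300))
  eta_d <- softplus_inverse(pmax(curve$lambda_d, 1e-300))
  list(repair = (curve$deta_dt_r + curve$deta_df_r * fdot) * softplus_deriv(eta_r),
       damage = (curve$deta_dt_d + curve$deta_df_d * fdot) * softplus_deriv(eta_d))
}

#' Decompose the frailty-index curvature into robustness and resilience terms
#'
#' The second time-derivative of the FI splits exactly into a damage
#' (robustness) term `(1 - f) dlambda_d/dt - (df/dt) lambda_d` and a repair
#' (resilience) term `-[f dlambda_r/dt + (df/dt) lambda_r]`; their sum is
#' `d2f/dt2` per draw. Also reports, per time point, the posterior
#' proportion of draws in which the damage term minus the magnitude of the
#' repair term is negative — the Bayesian analogue of a p-value for damage
#' dominating the curvature.
#'
#' @param curve A [rate_curve()].
#' @return Object of class `curvature_decomposition`: list with
#'   draws-by-times matrices `damage_term`, `repair_term`, `total`
#'   (their exact sum), `difference` (`damage_term - |repair_term|`), and a
#'   summary data frame with the per-time posterior proportion
#'   `prop_negative`.
#' @export
curvature_terms <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  sl <- rate_time_slope(curve)
  fdot <- fi_derivative(curve)
  damage_term <- (1 - curve$f) * sl$damage - fdot * curve$lambda_d
  repair_term <- -(curve$f * sl$repair + fdot * curve$lambda_r)
  diff <- damage_term - abs(repair_term)
  structure(list(
    times = curve$times,
    damage_term = damage_term, repair_term = repair_term,
    total = damage_term + repair_term, difference = diff,
    summary = data.frame(time = curve$times,
                         damage_med = apply(damage_term, 2L, stats::median),
                         repair_med = apply(repair_term, 2L, stats::median),
                         total_med = apply(damage_term + repair_term, 2L, stats::median),
                         prop_negative = colMeans(diff < 0))),
    class = "curvature_decomposition")
}

#' Posterior Spearman correlation between a rate and age
#'
#' Per posterior draw, the Spearman rank correlation between the draw's rate
#' evaluated at the supplied ages (linear interpolation on the curve grid)
#' and those ages; constant draws yield `NA`.
#'
#' @param curve A [rate_curve()].
#' @param ages Observation ages (time since baseline, curve units); >= 3
#'   values.
#' @param process `"repair"` or `"damage"`.
#' @return List with `rho` (per-draw correlations), `median` and `ci` (95%
#'   credible interval).
#' @export
posterior_spearman <- function(curve, ages, process = c("repair", "damage")) {
  process <- match.arg(process)
  stopifnot(inherits(curve, "rate_curve"), length(ages) >= 3L)
  lam <- if (process == "repair") curve$lambda_r else curve$lambda_d
  rho <- apply(lam, 1L, function(v) {
    y <- stats::approx(curve$times, v, xout = ages, rule = 2)$y
    if (stats::sd(y) == 0) return(NA_real_)
    suppressWarnings(stats::cor(y, ages, method = "spearman"))
  })
  list(rho = rho, median = stats::median(rho, na.rm = TRUE),
       ci = stats::quantile(rho, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
}

#' Mortality log hazard ratios per SD of the link-scale rates
#'
#' The joint model's mortality loadings `gamma_r`, `gamma_d` are per unit of
#' the inverse-Softplus (link-scale) rates; this rescales them to a
#' 1-standard-deviation increase, with the SDs computed over all
#' subject-intervals at the posterior median parameters (random effects
#' included).
#'
#' @param fit A `mouse_joint_fit` with a survival component.
#' @return List with per-draw `log_hr_repair`, `log_hr_damage`, the SDs
#'   used, and a summary data frame (median and 95% CI).
#' @export
hazard_ratio_per_sd <- function(fit) {
  stopifnot(inherits(fit, "mouse_joint_fit"))
  if (!isTRUE(fit$survival)) stop("fit has no survival component", call. = FALSE)
  med <- apply(fit$draws, 2L, stats::median)
  counts <- fit$counts
  X <- fit$data$X
  si <- fit$data$subj + 1L
  b_med <- matrix(med[grep("^b\\[", colnames(fit$draws))], nrow = 4L)
  eta_r <- drop(X %*% med[paste0("beta_r[", mouse_design_cols, "]")]) +
    b_med[1L, si] + b_med[2L, si] * fit$data$t_std
  eta_d <- drop(X %*% med[paste0("beta_d[", mouse_design_cols, "]")]) +
    b_med[3L, si] + b_med[4L, si] * fit$data$t_std
  sd_r <- stats::sd(eta_r); sd_d <- stats::sd(eta_d)
  if (sd_r == 0 || sd_d == 0) stop("degenerate link-scale rate SD", call. = FALSE)
  lhr_r <- fit$draws[, "gamma_r"] * sd_r
  lhr_d <- fit$draws[, "gamma_d"] * sd_d
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  list(log_hr_repair = lhr_r, log_hr_damage = lhr_d,
       sd_link_repair = sd_r, sd_link_damage = sd_d,
       summary = data.frame(process = c("repair", "damage"),
                            rbind(qs(lhr_r), qs(lhr_d))) |>
         stats::setNames(c("process", "q2.5", "q50", "q97.5")))
}
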
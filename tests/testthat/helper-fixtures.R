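# Small fixtures shared across test files; everything is generated in code.

# a hand-written 3-subject fractional panel with missing values
tiny_fractional_panel <- function() {
  visits <- data.frame(
    subject_id = rep(c("m1", "m2", "m3"), times = c(3L, 3L, 1L)),
    time = c(0, 1, 2, 0, 1.5, 3, 0))
  deficits <- rbind(
    c(0, NA, 1),   # m1 t=0
    c(NA, 0.5, 1),
    c(1, 0.75, NA),
    c(0, 0, 0),    # m2
    c(0.25, NA, 0.5),
    c(1, 1, 0.5),
    c(0.5, 0.25, 0))  # m3 single visit
  covariates <- data.frame(subject_id = c("m1", "m2", "m3"),
                           sex = c(0, 1, 0), treatment = c(0, 1, 1),
                           a0 = c(16, 17, 16.5))
  deficit_panel(visits, deficits, covariates, units = "months")
}

# a binary panel built from explicit per-item series
binary_panel <- function(series_by_subject, times = NULL, covariates = NULL,
                         units = "months") {
  vis <- list(); defs <- list()
  for (sid in names(series_by_subject)) {
    mat <- series_by_subject[[sid]]  # visits x items
    tt <- if (is.null(times)) seq_len(nrow(mat)) - 1 else times[[sid]]
    vis[[sid]] <- data.frame(subject_id = sid, time = tt)
    defs[[sid]] <- mat
  }
  if (is.null(covariates)) {
    covariates <- data.frame(subject_id = names(series_by_subject),
                             sex = 0, treatment = 0, a0 = 0)
  }
  deficit_panel(do.call(rbind, vis), do.call(rbind, defs), covariates, units)
}

# constant-rate ground truth: rates independent of every covariate
constant_rate_truth <- function(lambda_r, lambda_d, n_items = 124L,
                                schedule = 0:7, survival_off = TRUE) {
  base <- if (survival_off) list(breaks = c(20, 24), male = c(0, 0, 0),
                                 female = c(0, 0, 0))
  else list(breaks = c(20, 24), male = c(0.02, 0.07, 0.18),
            female = c(0.015, 0.05, 0.12))
  ground_truth(
    beta_r = c(softplus_inverse(max(lambda_r, 1e-12)), rep(0, 9)),
    beta_d = c(softplus_inverse(max(lambda_d, 1e-12)), rep(0, 9)),
    re_sd = rep(0, 4), gamma = rep(0, 6), gamma_r = 0, gamma_d = 0,
    base_hazard = base, n_items = n_items, schedule = schedule)
}

# interval/right-censored records simulated from a constant hazard
constant_hazard_records <- function(n, hazard, visit_times, seed) {
  damagerepair:::with_seed(seed, {
    event <- stats::rexp(n, hazard)
    t_lower <- t_upper <- t_censor <- rep(NA_real_, n)
    censored <- integer(n)
    last <- max(visit_times)
    for (i in seq_len(n)) {
      if (event[i] > last) {
        censored[i] <- 1L
        t_censor[i] <- last
      } else {
        j <- findInterval(event[i], visit_times)
        t_lower[i] <- visit_times[j]
        t_upper[i] <- visit_times[j + 1L]
      }
    }
    data.frame(subject_id = sprintf("r%04d", seq_len(n)), deficit_id = "d1",
               state = "damaged", entry = 0, t_lower = t_lower,
               t_upper = t_upper, t_censor = t_censor, censored = censored)
  })
}


# a hand-constructed posterior for testing the derived-quantity layer
# without MCMC: `draws` rows are treated as posterior draws
fake_mouse_fit <- function(beta_r_draws, beta_d_draws,
                           standardize = ground_truth()$standardize) {
  stopifnot(ncol(beta_r_draws) == 10, ncol(beta_d_draws) == 10)
  nd <- nrow(beta_r_draws)
  cols <- c(paste0("beta_r[", damagerepair:::mouse_design_cols, "]"),
            paste0("beta_d[", damagerepair:::mouse_design_cols, "]"))
  draws <- cbind(beta_r_draws, beta_d_draws)
  colnames(draws) <- cols
  structure(list(model = "mouse_joint", draws = draws,
                 chain_id = rep(1L, nd), standardize = standardize,
                 subjects = character(0), survival = FALSE),
            class = c("mouse_joint_fit", "damagerepair_fit"))
}

constant_rate_fit <- function(lambda_r, lambda_d, n_draws = 1,
                              standardize = ground_truth()$standardize) {
  br <- matrix(0, n_draws, 10); bd <- matrix(0, n_draws, 10)
  br[, 1] <- softplus_inverse(lambda_r)
  bd[, 1] <- softplus_inverse(lambda_d)
  fake_mouse_fit(br, bd, standardize)
}
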
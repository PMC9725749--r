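#' Extract interval-censored deficit-state lifetimes
#'
#' For each deficit item of each subject, every maximal run in one state
#' that *begins at an observed transition* opens a record; runs already in
#' progress at the first visit are excluded (their onset is unobserved). If
#' the exit transition is observed, the record is interval-censored between
#' the last in-state visit and the first out-of-state visit (relative to
#' entry); if the subject dies or drops out while in-state, the record is
#' right-censored at the last in-state visit. The state-entry clock starts
#' at the first visit at which the new state is observed (`entry =
#' "right"`); `entry = "midpoint"` starts it at the midpoint of the entry
#' transition's interval, for sensitivity analyses.
#'
#' @param panel A binary [deficit_panel()].
#' @param entry Entry-clock convention (see above).
#' @return Object of class `state_intervals`: data frame with columns
#'   `subject_id, deficit_id, state` (`"damaged"`/`"undamaged"`), `entry,
#'   t_lower, t_upper, t_censor, censored` plus subject covariates present
#'   (`sex`, `treatment`, `wealth`). Zero-length right-censored records are
#'   dropped.
#' @export
extract_state_intervals <- function(panel, entry = c("right", "midpoint")) {
  entry <- match.arg(entry)
  stopifnot(inherits(panel, "deficit_panel"))
  if (!is_binary_panel(panel) || anyNA(panel$deficits)) {
    stop("panel must be binary with no missing values", call. = FALSE)
  }
  rows <- panel_subject_rows(panel)
  recs <- list()
  for (sid in names(rows)) {
    idx <- rows[[sid]]
    if (length(idx) < 2L) next
    tt <- panel$visits$time[idx]
    J <- length(tt)
    for (k in seq_len(ncol(panel$deficits))) {
      v <- panel$deficits[idx, k]
      trans <- which(v[-1L] != v[-J]) + 1L  # index of first visit in new state
      for (s in seq_along(trans)) {
        j0 <- trans[s]
        t_entry <- if (entry == "right") tt[j0] else (tt[j0 - 1L] + tt[j0]) / 2
        state <- if (v[j0] == 1) "damaged" else "undamaged"
        exit <- if (s < length(trans)) trans[s + 1L] else NA_integer_
        if (!is.na(exit)) {
          rec <- data.frame(subject_id = sid,
                            deficit_id = colnames(panel$deficits)[k],
                            state = state, entry = t_entry,
                            t_lower = tt[exit - 1L] - t_entry,
                            t_upper = tt[exit] - t_entry,
                            t_censor = NA_real_, censored = 0L)
        } else {
          tc <- tt[J] - t_entry
          if (tc <= 0) next  # zero-length censored spell carries no information
          rec <- data.frame(subject_id = sid,
                            deficit_id = colnames(panel$deficits)[k],
                            state = state, entry = t_entry,
                            t_lower = NA_real_, t_upper = NA_real_,
                            t_censor = tc, censored = 1L)
        }
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(subject_id = character(0), deficit_id = character(0),
               state = character(0), entry = numeric(0), t_lower = numeric(0),
               t_upper = numeric(0), t_censor = numeric(0), censored = integer(0))
  keep <- intersect(c("sex", "treatment", "wealth"), names(panel$covariates))
  if (length(keep) && nrow(out)) {
    out <- merge(out, panel$covariates[, c("subject_id", keep)],
                 by = "subject_id", sort = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("state_intervals", "data.frame"),
            units = panel$units)
}

#' Nonparametric survival estimate for interval-censored data
#'
#' Turnbull's self-consistency (EM) estimator of the survival function from
#' a mixture of interval-censored records `(t_lower, t_upper]` and
#' right-censored records `(t_censor, Inf)`.
#'
#' @param records A `state_intervals` data frame (or any data frame with
#'   `t_lower, t_upper, t_censor, censored` columns).
#' @param tol,max_iter EM convergence controls.
#' @return List with `intervals` (Turnbull support intervals `q, p` and
#'   their probability masses `prob`) and `surv`, a right-continuous step
#'   function `S(t)` evaluated between support intervals.
#' @export
npmle_interval <- function(records, tol = 1e-8, max_iter = 5000L) {
  L <- ifelse(records$censored == 1L, records$t_censor, records$t_lower)
  R <- ifelse(records$censored == 1L, Inf, records$t_upper)
  if (any(!is.na(R) & is.finite(R) & R <= L)) {
    stop("records with t_upper <= t_lower", call. = FALSE)
  }
  # Turnbull support: [q, p] with q a left endpoint, p the smallest right
  # endpoint >= q with no other left endpoint in between
  lefts <- sort(unique(L))
  rights <- sort(unique(R))  # includes Inf when right-censored records exist
  q <- numeric(0); p <- numeric(0)
  for (ql in lefts) {
    pr <- rights[rights > ql]
    if (length(pr) == 0L) next
    pr <- pr[1L]
    if (!any(lefts > ql & lefts < pr)) { q <- c(q, ql); p <- c(p, pr) }
  }
  if (length(q) == 0L) {  # all records censored: all mass beyond the data
    sfun <- function(t) rep(1, length(t))
    return(list(intervals = data.frame(q = numeric(0), p = numeric(0),
                                       prob = numeric(0)), surv = sfun))
  }
  m <- length(q)
  # alpha[i, j] = 1 if support interval j is contained in record i's interval
  A <- outer(L, q, function(l, qq) qq >= l) &
    outer(R, p, function(r, pp) pp <= r)
  storage.mode(A) <- "double"
  prob <- rep(1 / m, m)
  for (it in seq_len(max_iter)) {
    num <- A * rep(prob, each = nrow(A))
    denom <- rowSums(num)
    if (any(denom <= 0)) stop("record incompatible with NPMLE support", call. = FALSE)
    new_prob <- colSums(num / denom) / nrow(A)
    if (max(abs(new_prob - prob)) < tol) { prob <- new_prob; break }
    prob <- new_prob
  }
  cum <- cumsum(prob)
  sfun <- function(t) {
    vapply(t, function(x) {
      done <- sum(prob[p <= x])
      1 - done
    }, numeric(1))
  }
  list(intervals = data.frame(q = q, p = p, prob = prob), surv = sfun)
}

#' Permutation generalized log-rank test for interval-censored lifetimes
#'
#' Tests equality of state-survival functions across groups. Each record
#' receives a log-rank score from the pooled Turnbull estimate
#' (`(S(L) log S(L) - S(R) log S(R)) / (S(L) - S(R))` for an
#' interval-censored record, `log S(L)` for a right-censored one); the
#' statistic is the sum over groups of squared group-sums of centered
#' scores, scaled by group size, and its null distribution is obtained by
#' permuting group labels.
#'
#' @param records Interval records (see [npmle_interval()]).
#' @param group Group label per record (>= 2 groups).
#' @param n_permutations At least 199.
#' @param seed Integer seed for the permutation draw.
#' @return List with `statistic`, `p_value`
#'   (`(1 + #permuted >= observed) / (1 + n_permutations)`), `scores`, and
#'   `n_permutations`.
#' @export
generalized_logrank <- function(records, group, n_permutations = 999L, seed = 1L) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (n_permutations < 199L) stop("use at least 199 permutations", call. = FALSE)
  stopifnot(length(group) == nrow(records))
  est <- npmle_interval(records)
  SL <- ifelse(records$censored == 1L, est$surv(records$t_censor),
               est$surv(records$t_lower))
  SR <- ifelse(records$censored == 1L, 0, est$surv(records$t_upper))
  xlogx <- function(x) ifelse(x <= 0, 0, x * log(x))
  scores <- ifelse(
    records$censored == 1L,
    ifelse(SL <= 0, 0, log(SL)),
    ifelse(SL - SR > 1e-12, (xlogx(SL) - xlogx(SR)) / (SL - SR), log(pmax(SL, 1e-12))))
  scores <- scores - mean(scores)
  stat_fun <- function(g) {
    sums <- tapply(scores, g, sum)
    ns <- tapply(rep(1, length(g)), g, sum)
    sum(sums^2 / ns)
  }
  observed <- stat_fun(group)
  with_seed(seed, {
    perm <- vapply(seq_len(n_permutations),
                   function(i) stat_fun(sample(group)), numeric(1))
    p <- (1 + sum(perm >= observed - 1e-12)) / (1 + n_permutations)
    list(statistic = observed, p_value = p, scores = scores,
         n_permutations = n_permutations)
  })
}

#' Log-likelihood of interval/right-censored records under a survival curve
#'
#' `sum log S(T)` over right-censored records plus
#' `sum log[S(T_lower) - S(T_upper)]` over interval-censored records;
#' `-Inf` if any interval has non-positive probability mass.
#'
#' @param records Interval records.
#' @param surv Vectorized survival function `S(t)`.
#' @return Scalar log-likelihood.
#' @export
interval_censored_loglik <- function(records, surv) {
  if (any(records$censored == 0L & records$t_upper <= records$t_lower)) {
    stop("records with t_upper <= t_lower", call. = FALSE)
  }
  ll <- 0
  rc <- records$censored == 1L
  if (any(rc)) ll <- ll + sum(log(surv(records$t_censor[rc])))
  if (any(!rc)) {
    mass <- surv(records$t_lower[!rc]) - surv(records$t_upper[!rc])
    if (any(mass <= 0)) return(-Inf)
    ll <- ll + sum(log(mass))
  }
  ll
}

#' Fit the Bayesian M-spline survival model to deficit-state lifetimes
#'
#' Models the hazard of leaving the current deficit state as
#' `h(t) = exp(gamma0) sum_l a_l M_l(t)` with a 32-component M-spline basis,
#' a uniform Dirichlet prior on the simplex `a` and a broad N(0,10) prior on
#' `gamma0`; the likelihood mixes interval-censored and right-censored
#' records. Typically fitted separately per state and per sex/intervention
#' group.
#'
#' @param records Interval records (see [extract_state_intervals()]).
#' @param knots Knot vector; default [make_knots_state()] on representative
#'   event times (interval midpoints; censoring times otherwise).
#' @inheritParams fit_mouse_joint
#' @return A `state_survival_fit` with draws of `gamma0` and `a[l]`, plus
#'   `knots`. Use [state_survival_curves()] for posterior survival bands.
#' @export
fit_state_survival <- function(records, knots = NULL, chains = 2L,
                               iter = 1000L, warmup = 1000L, seed = 1L,
                               adapt_delta = 0.8, max_treedepth = 10L,
                               convergence = c("error", "warn", "none")) {
  convergence <- match.arg(convergence)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (all(records$censored == 1L)) {
    warning("all records are right-censored; the exit hazard is unidentified")
  }
  rep_time <- ifelse(records$censored == 1L, records$t_censor,
                     (records$t_lower + records$t_upper) / 2)
  if (is.null(knots)) {
    knots <- make_knots_state(rep_time)
    # the state-entry clock starts at 0, so the hazard support must cover
    # the whole observable window: anchor the lower boundary knot at 0
    # (interior quantiles still summarize the event times)
    if (knots[1L] > 0) knots[1L] <- 0
  }
  L <- length(knots) + 1L  # quadratic M-spline basis count
  lo <- ifelse(records$censored == 1L, records$t_censor, records$t_lower)
  hi <- ifelse(records$censored == 1L, lo, records$t_upper)
  data <- list(model_flag = 3L, is_right = as.integer(records$censored),
               I_lo = ispline_basis(lo, knots), I_hi = ispline_basis(hi, knots))
  pars <- list(gamma0 = 0, ya = rep(0, L - 1L))
  obj <- TMB::MakeADFun(data = data, parameters = pars, DLL = "damagerepair",
                        silent = TRUE)
  res <- run_chains(obj, obj$par, warmup, iter, chains, seed, adapt_delta,
                    max_treedepth)
  un <- do.call(rbind, lapply(res, function(x) x$draws))
  chain_id <- rep(seq_len(chains), each = iter)
  natural <- matrix(NA_real_, nrow(un), 1L + L,
                    dimnames = list(NULL, c("gamma0", paste0("a[", seq_len(L), "]"))))
  natural[, 1L] <- un[, 1L]
  for (d in seq_len(nrow(un))) {
    natural[d, -1L] <- simplex_from_unconstrained(un[d, -1L])
  }
  assemble_fit("state_survival", res, natural, chain_id, "gamma0",
               data = data,
               extras = list(knots = knots, records = records,
                             settings = list(chains = chains, iter = iter,
                                             warmup = warmup, seed = seed)),
               convergence = convergence)
}

#' Posterior deficit-state survival curves
#'
#' @param fit A `state_survival_fit`.
#' @param times Evaluation times.
#' @param probs Quantiles of the posterior survival at each time.
#' @return List with `times`, `draws` (draws x times survival matrix) and
#'   `summary` (data frame of the requested quantiles).
#' @export
state_survival_curves <- function(fit, times, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(fit, "state_survival_fit"))
  I <- ispline_basis(times, fit$knots)
  a <- fit$draws[, paste0("a[", seq_len(length(fit$knots) + 1L), "]"), drop = FALSE]
  cum <- exp(fit$draws[, "gamma0"]) * (a %*% t(I))
  S <- exp(-cum)
  qs <- apply(S, 2L, stats::quantile, probs = probs)
  list(times = times, draws = S,
       summary = data.frame(time = times, t(qs), check.names = FALSE))
}
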
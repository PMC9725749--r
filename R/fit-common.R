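# Shared machinery of the three model fits: running chains of the NUTS
# sampler over a TMB objective, mapping unconstrained draws to natural
# parameters, and convergence checking.

run_chains <- function(obj, init, n_warmup, n_iter, chains, seed, adapt_delta,
                       max_treedepth, init_jitter = 0.05) {
  log_post <- function(th) {
    v <- -obj$fn(th)
    if (!is.finite(v)) -Inf else as.numeric(v)
  }
  grad <- function(th) as.numeric(-obj$gr(th))
  out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init_ch <- with_seed(seed + 1000L * ch, init + stats::rnorm(length(init), 0, init_jitter))
    out[[ch]] <- sample_nuts(log_post, grad, init_ch, n_warmup = n_warmup,
                             n_iter = n_iter, seed = seed + ch,
                             adapt_delta = adapt_delta,
                             max_treedepth = max_treedepth)
  }
  out
}

# draws: matrix (all chains stacked); chain_id: integer vector
assemble_fit <- function(model, chain_results, natural, chain_id, fixed_names,
                         data, extras, convergence = c("error", "warn", "none")) {
  convergence <- match.arg(convergence)
  diag_df <- data.frame(parameter = fixed_names,
                        mean = NA_real_, sd = NA_real_, rhat = NA_real_,
                        ess = NA_real_)
  for (r in seq_along(fixed_names)) {
    v <- natural[, fixed_names[r]]
    per_chain <- split(v, chain_id)
    diag_df$mean[r] <- mean(v)
    diag_df$sd[r] <- stats::sd(v)
    diag_df$rhat[r] <- split_rhat(per_chain)
    diag_df$ess[r] <- ess_basic(per_chain)
  }
  divergences <- sum(vapply(chain_results, function(x) x$divergences, numeric(1)))
  fit <- structure(
    c(list(model = model, draws = natural, chain_id = chain_id,
           diagnostics = diag_df, divergences = divergences,
           sampler = lapply(chain_results, function(x)
             x[c("step_size", "divergences", "treedepth")])),
      extras, list(data = data)),
    class = c(paste0(model, "_fit"), "damagerepair_fit"))
  bad <- diag_df$parameter[!is.na(diag_df$rhat) & diag_df$rhat > 1.05]
  if (length(bad)) {
    msg <- sprintf("convergence failure: split-Rhat > 1.05 for %s",
                   paste(bad, collapse = ", "))
    if (convergence == "error") stop(msg, call. = FALSE)
    if (convergence == "warn") warning(msg, call. = FALSE)
  }
  fit
}

#' @export
print.damagerepair_fit <- function(x, ...) {
  cat(sprintf("<%s> %d draws (%d chains), %d parameters, %d divergences\n",
              class(x)[1L], nrow(x$draws), length(unique(x$chain_id)),
              ncol(x$draws), x$divergences))
  cat("fixed-effect summary:\n")
  print(utils::head(summary(x), 12))
  invisible(x)
}

#' Posterior summary of a model fit
#'
#' Means, SDs, central quantiles, split-Rhat and effective sample size for
#' the model's fixed effects (all named parameters excluding subject-level
#' random effects).
#'
#' @param object A fit from [fit_mouse_joint()], [fit_human_spline()] or
#'   [fit_state_survival()].
#' @param pars Optional character vector restricting the summary.
#' @param ... Unused.
#' @return Data frame with one row per parameter.
#' @export
summary.damagerepair_fit <- function(object, pars = NULL, ...) {
  nm <- if (is.null(pars)) object$diagnostics$parameter else pars
  qs <- t(apply(object$draws[, nm, drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.5, 0.975)))
  out <- data.frame(parameter = nm,
                    mean = colMeans(object$draws[, nm, drop = FALSE]),
                    sd = apply(object$draws[, nm, drop = FALSE], 2L, stats::sd),
                    q2.5 = qs[, 1L], q50 = qs[, 2L], q97.5 = qs[, 3L],
                    row.names = NULL)
  dg <- object$diagnostics
  out$rhat <- dg$rhat[match(nm, dg$parameter)]
  out$ess <- dg$ess[match(nm, dg$parameter)]
  out
}

#' Export posterior draws as a tidy data frame
#'
#' @param x A model fit.
#' @param pars Optional parameter subset.
#' @param ... Unused.
#' @return Data frame with columns `chain, draw, parameter, value`.
#' @export
as.data.frame.damagerepair_fit <- function(x, pars = NULL, ...) {
  nm <- if (is.null(pars)) colnames(x$draws) else pars
  per_chain <- as.vector(table(x$chain_id))
  draw_idx <- unlist(lapply(per_chain, seq_len))
  data.frame(
    chain = rep(x$chain_id, length(nm)),
    draw = rep(draw_idx, length(nm)),
    parameter = rep(nm, each = nrow(x$draws)),
    value = as.vector(x$draws[, nm, drop = FALSE]))
}

# crude moment-based initial intercepts on the link scale
init_link_intercept <- function(counts, which = c("repair", "damage")) {
  which <- match.arg(which)
  N <- attr(counts, "n_items")
  obs <- if (which == "repair") {
    ifelse(counts$n > 0, counts$n_r / (counts$n * counts$dt), NA_real_)
  } else {
    ifelse(counts$n < N, counts$n_d / ((N - counts$n) * counts$dt), NA_real_)
  }
  m <- mean(obs, na.rm = TRUE)
  if (!is.finite(m)) m <- 1e-3
  softplus_inverse(max(m, 1e-3))
}
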
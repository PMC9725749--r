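#' No-U-Turn sampler over a differentiable log posterior
#'
#' A self-contained implementation of the No-U-Turn sampler (tree doubling
#' with slice termination), with dual-averaging step-size adaptation during
#' warmup and a diagonal mass matrix estimated from the second half of the
#' warmup draws. Used by all `fit_*` functions with gradients supplied by
#' automatic differentiation of the model templates.
#'
#' @param log_post Function returning the log posterior density at an
#'   unconstrained parameter vector (may return `-Inf`).
#' @param grad Function returning its gradient.
#' @param init Initial unconstrained parameter vector.
#' @param n_warmup,n_iter Warmup and retained iterations.
#' @param seed Integer seed (one chain; callers offset per chain).
#' @param adapt_delta Target acceptance statistic (default 0.8; raise towards
#'   1 to take smaller steps).
#' @param max_treedepth Maximum tree doubling depth.
#' @return List with `draws` (`n_iter` x `length(init)`), `accept_stat`,
#'   `treedepth`, `divergences` (count), `step_size`, `inv_mass`.
#' @export
sample_nuts <- function(log_post, grad, init, n_warmup = 500L, n_iter = 500L,
                        seed = 1L, adapt_delta = 0.8, max_treedepth = 10L) {
  with_seed(seed, {
    d <- length(init)
    theta <- as.numeric(init)
    lp0 <- log_post(theta)
    if (!is.finite(lp0)) stop("log posterior is not finite at the initial value", call. = FALSE)

    inv_mass <- rep(1, d)
    sqrt_inv_mass <- sqrt(inv_mass)
    eps <- find_initial_step(log_post, grad, theta, inv_mass)

    # dual averaging state
    gamma_da <- 0.05; t0 <- 10; kappa <- 0.75
    mu <- log(10 * eps)
    log_eps_bar <- log(eps)
    h_bar <- 0
    da_count <- 0L

    # Stan-style warmup schedule: step-size-only buffers around doubling
    # mass-estimation windows
    b_init <- max(round(0.15 * n_warmup), 10L)
    b_term <- max(round(0.10 * n_warmup), 10L)
    middle <- max(n_warmup - b_init - b_term, 0L)
    win_ends <- integer(0)
    if (middle >= 20L) {
      w <- max(10L, floor(middle / 7))
      pos <- b_init
      repeat {
        nxt <- pos + w
        if (nxt + 2L * w > b_init + middle) nxt <- b_init + middle
        win_ends <- c(win_ends, nxt)
        if (nxt >= b_init + middle) break
        pos <- nxt
        w <- 2L * w
      }
    }
    win_start <- b_init + 1L

    draws <- matrix(NA_real_, n_iter, d)
    accept_stat <- numeric(n_iter)
    treedepth <- integer(n_iter)
    divergences <- 0L
    mass_buf <- NULL

    total <- n_warmup + n_iter
    for (it in seq_len(total)) {
      r0 <- stats::rnorm(d) / sqrt_inv_mass
      lp <- log_post(theta)
      joint0 <- lp - 0.5 * sum(r0^2 * inv_mass)
      log_u <- joint0 - stats::rexp(1)  # slice variable, log scale

      theta_minus <- theta_plus <- theta
      r_minus <- r_plus <- r0
      g_minus <- g_plus <- grad(theta)
      theta_new <- theta
      n_valid <- 1L
      s <- TRUE
      depth <- 0L
      sum_alpha <- 0; n_alpha <- 0L
      div_this <- FALSE

      while (s && depth < max_treedepth) {
        dir <- if (stats::runif(1) < 0.5) -1 else 1
        if (dir == -1) {
          bt <- build_tree(theta_minus, r_minus, g_minus, log_u, dir, depth, eps,
                           log_post, grad, inv_mass, joint0)
          theta_minus <- bt$theta_bwd; r_minus <- bt$r_bwd; g_minus <- bt$g_bwd
        } else {
          bt <- build_tree(theta_plus, r_plus, g_plus, log_u, dir, depth, eps,
                           log_post, grad, inv_mass, joint0)
          theta_plus <- bt$theta_fwd; r_plus <- bt$r_fwd; g_plus <- bt$g_fwd
        }
        if (bt$divergent) div_this <- TRUE
        if (bt$s && bt$n_valid > 0L && stats::runif(1) < bt$n_valid / n_valid) {
          theta_new <- bt$theta_prop
        }
        n_valid <- n_valid + bt$n_valid
        sum_alpha <- sum_alpha + bt$sum_alpha
        n_alpha <- n_alpha + bt$n_alpha
        dtheta <- theta_plus - theta_minus
        s <- bt$s &&
          sum(dtheta * (inv_mass * r_minus)) >= 0 &&
          sum(dtheta * (inv_mass * r_plus)) >= 0
        depth <- depth + 1L
      }
      theta <- theta_new
      alpha_mean <- if (n_alpha > 0L) sum_alpha / n_alpha else 0

      if (it <= n_warmup) {
        # dual averaging update
        da_count <- da_count + 1L
        frac <- 1 / (da_count + t0)
        h_bar <- (1 - frac) * h_bar + frac * (adapt_delta - alpha_mean)
        log_eps <- mu - sqrt(da_count) / gamma_da * h_bar
        pow <- da_count^(-kappa)
        log_eps_bar <- pow * log_eps + (1 - pow) * log_eps_bar
        eps <- exp(log_eps)
        if (it >= win_start) mass_buf <- rbind(mass_buf, theta)
        if (length(win_ends) && it == win_ends[1L]) {
          # close the mass window: update the metric, restart dual averaging
          if (nrow(mass_buf) >= 10L) {
            v <- apply(mass_buf, 2L, stats::var)
            w <- nrow(mass_buf)
            v <- (w / (w + 5)) * v + (5 / (w + 5)) * 1e-3
            v[v < 1e-10] <- 1e-10
            inv_mass <- v
            sqrt_inv_mass <- sqrt(inv_mass)
          }
          eps <- find_initial_step(log_post, grad, theta, inv_mass,
                                   max(eps, 1e-6))
          mu <- log(10 * eps)
          log_eps_bar <- log(eps)
          h_bar <- 0
          da_count <- 0L
          mass_buf <- NULL
          win_start <- it + 1L
          win_ends <- win_ends[-1L]
        }
        if (it == n_warmup) eps <- exp(log_eps_bar)
      } else {
        k <- it - n_warmup
        draws[k, ] <- theta
        accept_stat[k] <- alpha_mean
        treedepth[k] <- depth
        if (div_this) divergences <- divergences + 1L
      }
    }
    list(draws = draws, accept_stat = accept_stat, treedepth = treedepth,
         divergences = divergences, step_size = eps, inv_mass = inv_mass)
  })
}

# one leapfrog step in position theta, momentum r, gradient g
leapfrog <- function(theta, r, g, eps, grad, inv_mass) {
  r_half <- r + 0.5 * eps * g
  theta_new <- theta + eps * inv_mass * r_half
  g_new <- grad(theta_new)
  if (any(!is.finite(g_new))) {
    return(list(theta = theta_new, r = r_half, g = g_new, ok = FALSE))
  }
  r_new <- r_half + 0.5 * eps * g_new
  list(theta = theta_new, r = r_new, g = g_new, ok = TRUE)
}

build_tree <- function(theta, r, g, log_u, dir, depth, eps, log_post, grad,
                       inv_mass, joint0) {
  if (depth == 0L) {
    lf <- leapfrog(theta, r, g, dir * eps, grad, inv_mass)
    if (!lf$ok) {
      return(list(theta_bwd = lf$theta, r_bwd = lf$r, g_bwd = lf$g,
                  theta_fwd = lf$theta, r_fwd = lf$r, g_fwd = lf$g,
                  theta_prop = theta, n_valid = 0L, s = FALSE, divergent = TRUE,
                  sum_alpha = 0, n_alpha = 1L))
    }
    lp <- log_post(lf$theta)
    joint <- if (is.finite(lp)) lp - 0.5 * sum(lf$r^2 * inv_mass) else -Inf
    n_valid <- as.integer(is.finite(joint) && log_u <= joint)
    divergent <- !is.finite(joint) || (log_u - 1000) > joint
    alpha <- if (is.finite(joint)) min(1, exp(joint - joint0)) else 0
    list(theta_bwd = lf$theta, r_bwd = lf$r, g_bwd = lf$g,
         theta_fwd = lf$theta, r_fwd = lf$r, g_fwd = lf$g,
         theta_prop = lf$theta, n_valid = n_valid, s = !divergent,
         divergent = divergent, sum_alpha = alpha, n_alpha = 1L)
  } else {
    t1 <- build_tree(theta, r, g, log_u, dir, depth - 1L, eps, log_post, grad,
                     inv_mass, joint0)
    if (!t1$s) return(t1)
    if (dir == -1) {
      t2 <- build_tree(t1$theta_bwd, t1$r_bwd, t1$g_bwd, log_u, dir, depth - 1L,
                       eps, log_post, grad, inv_mass, joint0)
      t1$theta_bwd <- t2$theta_bwd; t1$r_bwd <- t2$r_bwd; t1$g_bwd <- t2$g_bwd
    } else {
      t2 <- build_tree(t1$theta_fwd, t1$r_fwd, t1$g_fwd, log_u, dir, depth - 1L,
                       eps, log_post, grad, inv_mass, joint0)
      t1$theta_fwd <- t2$theta_fwd; t1$r_fwd <- t2$r_fwd; t1$g_fwd <- t2$g_fwd
    }
    ntot <- t1$n_valid + t2$n_valid
    if (t2$n_valid > 0L && stats::runif(1) < t2$n_valid / ntot) {
      t1$theta_prop <- t2$theta_prop
    }
    dtheta <- t1$theta_fwd - t1$theta_bwd
    t1$s <- t2$s &&
      sum(dtheta * (inv_mass * t1$r_bwd)) >= 0 &&
      sum(dtheta * (inv_mass * t1$r_fwd)) >= 0
    t1$divergent <- t1$divergent || t2$divergent
    t1$n_valid <- ntot
    t1$sum_alpha <- t1$sum_alpha + t2$sum_alpha
    t1$n_alpha <- t1$n_alpha + t2$n_alpha
    t1
  }
}

# heuristic initial step size: double/halve until the one-step acceptance
# probability crosses 0.5
find_initial_step <- function(log_post, grad, theta, inv_mass, eps = 1) {
  d <- length(theta)
  r <- stats::rnorm(d) / sqrt(inv_mass)
  lp <- log_post(theta)
  joint0 <- lp - 0.5 * sum(r^2 * inv_mass)
  g <- grad(theta)
  step_joint <- function(eps) {
    lf <- leapfrog(theta, r, g, eps, grad, inv_mass)
    if (!lf$ok) return(-Inf)
    lp1 <- log_post(lf$theta)
    if (!is.finite(lp1)) return(-Inf)
    lp1 - 0.5 * sum(lf$r^2 * inv_mass)
  }
  j <- step_joint(eps)
  while (!is.finite(j) && eps > 1e-10) {
    eps <- eps / 2
    j <- step_joint(eps)
  }
  if (eps <= 1e-10) stop("could not find a workable step size", call. = FALSE)
  a <- if (j - joint0 > log(0.5)) 1 else -1
  for (tries in 1:50) {
    eps <- eps * 2^a
    j <- step_joint(eps)
    if (!is.finite(j)) { eps <- eps / 2; break }
    if (a * (j - joint0) <= a * log(0.5)) break
  }
  eps
}

#' Convergence diagnostics for posterior draws
#'
#' `split_rhat` computes the split-chain potential scale reduction factor;
#' `ess_basic` the effective sample size from the initial monotone positive
#' sequence of autocorrelations, pooled across chains.
#'
#' @param chains List of numeric vectors (one per chain) or a single vector.
#' @return A scalar.
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  halves <- list()
  for (ch in chains) {
    m <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt((n - 1) / n + B / (n * W))
}

#' @rdname split_rhat
#' @export
ess_basic <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  n <- length(chains[[1L]])
  nch <- length(chains)
  # pooled autocorrelation (Geyer initial positive sequence) per chain
  rho_sum <- 0
  for (ch in chains) {
    ac <- stats::acf(ch, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[-1L]
    s <- 0
    for (k in seq(1L, length(ac) - 1L, by = 2L)) {
      pair <- ac[k] + ac[k + 1L]
      if (!is.finite(pair) || pair <= 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  rho <- rho_sum / nch
  max(1, nch * n / (1 + 2 * rho))
}
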
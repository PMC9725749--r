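#' Per-interval damage and repair transition counts
#'
#' Converts a binary [deficit_panel()] into one record per subject-interval:
#' the number of deficits present at the interval start `n`, the number
#' damaged (`0 -> 1`) and repaired (`1 -> 0`) across the interval, the
#' interval length, and the subject covariates. Counts satisfy the
#' conservation identity `n(t_{j+1}) = n(t_j) + n_d(t_j) - n_r(t_j)` exactly,
#' and are attributed to the left endpoint of each interval.
#'
#' @param panel A binary [deficit_panel()] (subjects need >= 2 visits;
#'   single-visit subjects contribute no intervals).
#' @return Object of class `transition_counts`: a data frame with columns
#'   `subject_id, t, dt, n, n_d, n_r, f, age` plus the subject covariates,
#'   with attributes `n_items` and `units`.
#' @export
count_transitions <- function(panel) {
  stopifnot(inherits(panel, "deficit_panel"))
  if (!is_binary_panel(panel) || anyNA(panel$deficits)) {
    stop("panel must be binary with no missing values", call. = FALSE)
  }
  N <- ncol(panel$deficits)
  rows <- panel_subject_rows(panel)
  recs <- vector("list", length(rows))
  for (s in seq_along(rows)) {
    idx <- rows[[s]]
    if (length(idx) < 2L) next
    D <- panel$deficits[idx, , drop = FALSE]
    tt <- panel$visits$time[idx]
    J <- length(idx)
    from <- D[-J, , drop = FALSE]
    to <- D[-1L, , drop = FALSE]
    n_d <- rowSums(from == 0 & to == 1)
    n_r <- rowSums(from == 1 & to == 0)
    recs[[s]] <- data.frame(
      subject_id = panel$visits$subject_id[idx[1L]],
      t = tt[-J], dt = diff(tt),
      n = rowSums(from), n_d = n_d, n_r = n_r,
      f = rowSums(from) / N)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no subject has >= 2 visits", call. = FALSE)
  out <- merge(out, panel$covariates, by = "subject_id", sort = FALSE)
  out <- out[order(match(out$subject_id, unique(panel$visits$subject_id)), out$t), ]
  rownames(out) <- NULL
  if (!is.null(out$a0)) out$age <- out$a0 + out$t
  # conservation identity is structural; verify defensively
  nxt <- out$n + out$n_d - out$n_r
  same <- c(out$subject_id[-1L] == out$subject_id[-nrow(out)], FALSE)
  later_n <- c(out$n[-1L], NA)
  stopifnot(all(nxt[same] == later_n[same]))
  structure(out, class = c("transition_counts", "data.frame"),
            n_items = N, units = panel$units)
}

#' Binned nonparametric damage and repair rate estimates
#'
#' Per age (or time) bin, the empirical repair rate is the unweighted mean
#' over intervals of `n_r / (n * dt)` (intervals with `n = 0` excluded) and
#' the damage rate the mean of `n_d / ((N - n) * dt)` (intervals with
#' `n = N` excluded), with standard error `sd / sqrt(m)`. Bins are
#' left-closed, right-open.
#'
#' @param counts A [count_transitions()] result.
#' @param bin_edges Increasing vector of bin edges.
#' @param at Values to bin on; defaults to interval-start age (`age`) when
#'   present, otherwise interval-start time `t`.
#' @return Data frame with `bin_lo, bin_hi, bin_mid, rate_type, rate, se, m`;
#'   empty bins are omitted with a warning.
#' @export
binned_rates <- function(counts, bin_edges, at = NULL) {
  stopifnot(inherits(counts, "transition_counts"), length(bin_edges) >= 2L)
  N <- attr(counts, "n_items")
  if (is.null(at)) at <- if (!is.null(counts$age)) counts$age else counts$t
  bin <- findInterval(at, bin_edges, rightmost.closed = FALSE, left.open = FALSE)
  bin[at >= bin_edges[length(bin_edges)]] <- NA  # beyond last edge
  bin[bin == 0L] <- NA
  obs_r <- ifelse(counts$n > 0, counts$n_r / (counts$n * counts$dt), NA_real_)
  obs_d <- ifelse(counts$n < N, counts$n_d / ((N - counts$n) * counts$dt), NA_real_)
  out <- list(); empty <- 0L
  for (b in seq_len(length(bin_edges) - 1L)) {
    sel <- which(!is.na(bin) & bin == b)
    for (type in c("repair", "damage")) {
      obs <- if (type == "repair") obs_r[sel] else obs_d[sel]
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0L) { empty <- empty + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        bin_lo = bin_edges[b], bin_hi = bin_edges[b + 1L],
        bin_mid = (bin_edges[b] + bin_edges[b + 1L]) / 2,
        rate_type = type, rate = mean(obs),
        se = stats::sd(obs) / sqrt(length(obs)), m = length(obs))
    }
  }
  if (empty > 0L) warning(sprintf("%d empty bin/rate combinations omitted", empty))
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Repair and damage event totals per deficit item
#'
#' One-line per-item report of how often each deficit item damaged and
#' repaired across the panel.
#'
#' @param panel A binary [deficit_panel()].
#' @return Data frame with `deficit_id, n_damage, n_repair, n_observations`.
#' @export
item_transition_table <- function(panel) {
  stopifnot(inherits(panel, "deficit_panel"))
  rows <- panel_subject_rows(panel)
  N <- ncol(panel$deficits)
  dmg <- rep_len(0L, N); rep_ <- rep_len(0L, N); nobs <- 0L
  for (idx in rows) {
    if (length(idx) < 2L) next
    D <- panel$deficits[idx, , drop = FALSE]
    from <- D[-length(idx), , drop = FALSE]
    to <- D[-1L, , drop = FALSE]
    dmg <- dmg + colSums(from == 0 & to == 1)
    rep_ <- rep_ + colSums(from == 1 & to == 0)
    nobs <- nobs + nrow(from)
  }
  data.frame(deficit_id = colnames(panel$deficits), n_damage = dmg,
             n_repair = rep_, n_observations = nobs, row.names = NULL)
}
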
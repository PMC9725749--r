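#' Last-observation-carried-forward imputation
#'
#' Fills missing deficit values forward from the last observed value; leading
#' missing values are filled backward from the first observed value. Applied
#' per subject and deficit item.
#'
#' @param panel A [deficit_panel()] (binary or fractional, `NA` = missing).
#' @return The imputed [deficit_panel()] with no missing values.
#' @export
impute_locf <- function(panel) {
  stopifnot(inherits(panel, "deficit_panel"))
  D <- panel$deficits
  rows <- panel_subject_rows(panel)
  for (sid in names(rows)) {
    idx <- rows[[sid]]
    for (k in seq_len(ncol(D))) {
      v <- D[idx, k]
      if (!anyNA(v)) next
      obs <- which(!is.na(v))
      if (length(obs) == 0L) {
        stop(sprintf("cannot impute: subject '%s', deficit '%s' has no observed values",
                     sid, colnames(D)[k]), call. = FALSE)
      }
      # backward fill of leading NAs, then forward fill
      v[seq_len(obs[1L] - 1L)] <- v[obs[1L]]
      for (j in seq_along(v)[-1L]) if (is.na(v[j])) v[j] <- v[j - 1L]
      D[idx, k] <- v
    }
  }
  panel$deficits <- D
  panel
}

#' Expand fractional deficits into ordered binary deficits
#'
#' A deficit scored on the quarter grid `{0, 0.25, 0.5, 0.75, 1}` is
#' represented by 4 ordered binary deficits with the first `4 * value` bits
#' set: `0.75` becomes `[1, 1, 1, 0]`. Applied panel-wide this turns an
#' `N`-item fractional frailty index into a `4 * N`-item binary one and
#' preserves every frailty-index value exactly.
#'
#' @param value Numeric vector on the quarter grid (tolerance 1e-9).
#' @return `encode_fractional` returns a `length(value)` x 4 0/1 matrix;
#'   `expand_fractional` returns the expanded binary [deficit_panel()].
#' @examples
#' encode_fractional(0.75)  # 1 1 1 0
#' @export
encode_fractional <- function(value) {
  q <- value * 4
  if (anyNA(value) || any(abs(q - round(q)) > 1e-9) || any(value < 0) || any(value > 1)) {
    stop("values must lie on {0, 0.25, 0.5, 0.75, 1}", call. = FALSE)
  }
  q <- as.integer(round(q))
  out <- matrix(0L, length(value), 4L)
  for (b in 1:4) out[, b] <- as.integer(q >= b)
  out
}

#' @rdname encode_fractional
#' @param panel A [deficit_panel()] with no missing values.
#' @export
expand_fractional <- function(panel) {
  stopifnot(inherits(panel, "deficit_panel"))
  if (anyNA(panel$deficits)) {
    stop("impute missing values (impute_locf) before expanding", call. = FALSE)
  }
  N <- ncol(panel$deficits)
  cols <- vector("list", N)
  for (k in seq_len(N)) {
    bits <- encode_fractional(panel$deficits[, k])
    colnames(bits) <- paste0(colnames(panel$deficits)[k], "_b", 1:4)
    cols[[k]] <- bits
  }
  panel$deficits <- do.call(cbind, cols)
  panel
}

#' Remove visits with abnormally short or long intervals
#'
#' Removes visits closer than `min_gap` or farther than `max_gap` from the
#' previous *retained* visit (the later visit of an offending pair is
#' dropped, and gaps are re-evaluated against the last retained visit). After
#' gap filtering, subjects with fewer than 2 remaining visits are dropped.
#'
#' @param panel A [deficit_panel()].
#' @param min_gap,max_gap Thresholds in panel time units; `NULL` disables.
#' @return The filtered [deficit_panel()] (possibly with fewer subjects).
#' @export
filter_visits <- function(panel, min_gap = NULL, max_gap = NULL) {
  stopifnot(inherits(panel, "deficit_panel"))
  rows <- panel_subject_rows(panel)
  keep <- integer(0)
  for (idx in rows) {
    tt <- panel$visits$time[idx]
    retained <- 1L
    last_t <- tt[1L]
    for (j in seq_along(tt)[-1L]) {
      gap <- tt[j] - last_t
      bad <- (!is.null(min_gap) && gap < min_gap) ||
        (!is.null(max_gap) && gap > max_gap)
      if (!bad) {
        retained <- c(retained, j)
        last_t <- tt[j]
      }
    }
    if (length(retained) >= 2L) keep <- c(keep, idx[retained])
  }
  if (length(keep) == 0L) {
    warning("no subjects remain after visit filtering")
  }
  dropped <- length(unique(panel$visits$subject_id)) -
    length(unique(panel$visits$subject_id[keep]))
  if (dropped > 0L) {
    message(sprintf("filter_visits: dropped %d subject(s) with < 2 remaining visits", dropped))
  }
  panel_subset_rows(panel, keep)
}

#' Cohort selection and wealth transform for human panel data
#'
#' Applies the selection rules for the human cohort: subjects are dropped if
#' their baseline age is outside `age_range`, any inter-visit gap exceeds
#' `max_gap` years, they have fewer than `min_followups` observation waves in
#' total, or their wealth assessment was imputed. Net household wealth is
#' then transformed as `w = log(w_raw + mean(w_raw))` with the mean taken
#' over the retained subjects.
#'
#' @param panel A [deficit_panel()] whose covariates include `a0`,
#'   `wealth` and (optionally) logical `wealth_imputed`.
#' @param age_range Inclusive baseline-age window (years).
#' @param max_gap Maximum allowed inter-visit gap (years).
#' @param min_followups Minimum number of observation waves per subject.
#' @return The filtered [deficit_panel()]; covariates gain the transformed
#'   `wealth` column (raw wealth kept as `wealth_raw`).
#' @export
elsa_select <- function(panel, age_range = c(50, 89), max_gap = 4, min_followups = 6L) {
  stopifnot(inherits(panel, "deficit_panel"))
  cv <- panel$covariates
  if (!all(c("a0", "wealth") %in% names(cv))) {
    stop("covariates must include 'a0' and 'wealth'", call. = FALSE)
  }
  rows <- panel_subject_rows(panel)
  ok <- vapply(names(rows), function(sid) {
    idx <- rows[[sid]]
    crow <- cv[cv$subject_id == sid, ]
    tt <- panel$visits$time[idx]
    if (length(tt) < min_followups) return(FALSE)
    if (length(tt) > 1L && any(diff(tt) > max_gap)) return(FALSE)
    if (crow$a0 < age_range[1L] || crow$a0 > age_range[2L]) return(FALSE)
    if (!is.null(cv$wealth_imputed) && isTRUE(crow$wealth_imputed)) return(FALSE)
    TRUE
  }, logical(1))
  keep_rows <- unlist(rows[ok], use.names = FALSE)
  if (length(keep_rows) == 0L) {
    warning("no subjects remain after selection")
    return(panel_subset_rows(panel, integer(0)))
  }
  out <- panel_subset_rows(panel, sort(keep_rows))
  w_raw <- out$covariates$wealth
  shifted <- w_raw + mean(w_raw)
  if (any(shifted <= 0)) {
    stop("wealth transform undefined: w_raw + mean(w_raw) <= 0 for some subject",
         call. = FALSE)
  }
  out$covariates$wealth_raw <- w_raw
  out$covariates$wealth <- log(shifted)
  out
}

#' Prune isolated single-visit transitions
#'
#' Sensitivity-analysis pruning of putative measurement errors: any
#' single-visit excursion flanked by at least 2 visits of the opposite state
#' on each side is flattened — exactly the patterns `x,x,!x,x,x` become
#' `x,x,x,x,x` (e.g. `{0,0,1,0,0}` becomes `{0,0,0,0,0}`). Excursions with
#' fewer than 2 flanking visits on either side, and excursions of length 2
#' or more, are left untouched. The operation is idempotent and never
#' increases the number of transitions.
#'
#' @param panel A binary [deficit_panel()].
#' @return The pruned [deficit_panel()].
#' @export
prune_isolated_transitions <- function(panel) {
  stopifnot(inherits(panel, "deficit_panel"))
  if (!is_binary_panel(panel)) stop("panel must be binary", call. = FALSE)
  D <- panel$deficits
  rows <- panel_subject_rows(panel)
  for (idx in rows) {
    if (length(idx) < 5L) next
    for (k in seq_len(ncol(D))) {
      v <- D[idx, k]
      J <- length(v)
      mid <- 3:(J - 2L)
      hit <- v[mid - 2L] == v[mid - 1L] & v[mid + 1L] == v[mid + 2L] &
        v[mid - 1L] == v[mid + 1L] & v[mid] != v[mid - 1L]
      if (any(hit)) {
        v[mid[hit]] <- v[mid[hit] - 1L]
        D[idx, k] <- v
      }
    }
  }
  panel$deficits <- D
  panel
}
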
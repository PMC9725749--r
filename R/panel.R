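#' Longitudinal panel of binary health deficits
#'
#' The universal input of the package: for each subject, a strictly
#' increasing grid of visit times and the observed state of `N` health
#' deficits at each visit, plus subject-level covariates. Deficit values are
#' binary (`0` undamaged, `1` damaged), or on the fractional quarter grid
#' `{0, 0.25, 0.5, 0.75, 1}` before [expand_fractional()], with `NA` marking
#' missing observations before [impute_locf()].
#'
#' @param visits Data frame with columns `subject_id` and `time` (one row per
#'   subject-visit; months for mice, years for humans). Rows must be grouped
#'   by subject with strictly increasing times.
#' @param deficits Numeric matrix with one row per row of `visits` and one
#'   column per deficit item.
#' @param covariates Data frame with one row per subject: `subject_id` plus
#'   any of `sex` (0/1), `treatment` (0/1), `a0` (baseline age), `wealth`,
#'   `wealth_imputed` (logical), `death_time` (age scale), `censored` (0
#'   death observed, 1 censored).
#' @param units Time unit of `time` (and of all rates derived from the
#'   panel): `"months"` or `"years"`.
#' @return An object of class `deficit_panel`.
#' @seealso [count_transitions()], [expand_fractional()], [fi()]
#' @export
deficit_panel <- function(visits, deficits, covariates, units = c("months", "years")) {
  units <- match.arg(units)
  visits <- as.data.frame(visits)
  covariates <- as.data.frame(covariates)
  deficits <- as.matrix(deficits)
  stopifnot(all(c("subject_id", "time") %in% names(visits)),
            "subject_id" %in% names(covariates),
            nrow(deficits) == nrow(visits))
  if (anyDuplicated(covariates$subject_id)) {
    stop("covariates must have one row per subject", call. = FALSE)
  }
  if (!all(unique(visits$subject_id) %in% covariates$subject_id)) {
    stop("every subject in visits needs a covariates row", call. = FALSE)
  }
  for (sid in unique(visits$subject_id)) {
    tt <- visits$time[visits$subject_id == sid]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop(sprintf("visit times for subject '%s' are not strictly increasing", sid),
           call. = FALSE)
    }
  }
  vals <- deficits[!is.na(deficits)]
  on_grid <- abs(vals * 4 - round(vals * 4)) < 1e-9 & vals >= 0 & vals <= 1
  if (!all(on_grid)) {
    stop("deficit values must lie on {0, 0.25, 0.5, 0.75, 1} (or be NA)", call. = FALSE)
  }
  if (is.null(colnames(deficits))) {
    colnames(deficits) <- paste0("d", seq_len(ncol(deficits)))
  }
  structure(
    list(visits = visits, deficits = deficits, covariates = covariates, units = units),
    class = "deficit_panel"
  )
}

#' @export
print.deficit_panel <- function(x, ...) {
  cat(sprintf("<deficit_panel> %d subjects, %d visits, %d items (%s)\n",
              length(unique(x$visits$subject_id)), nrow(x$visits),
              ncol(x$deficits), x$units))
  fi_rng <- range(fi(x), na.rm = TRUE)
  cat(sprintf("  FI range %.3f-%.3f; %s values missing; %s\n",
              fi_rng[1], fi_rng[2], sum(is.na(x$deficits)),
              if (is_binary_panel(x)) "binary" else "fractional"))
  invisible(x)
}

#' Frailty index per visit
#'
#' The frailty index is the fraction of deficits present, `f = n / N`,
#' computed per subject-visit row.
#'
#' @param panel A [deficit_panel()].
#' @return Numeric vector aligned with `panel$visits`.
#' @export
fi <- function(panel) {
  stopifnot(inherits(panel, "deficit_panel"))
  rowMeans(panel$deficits)
}

is_binary_panel <- function(panel) {
  v <- panel$deficits[!is.na(panel$deficits)]
  all(v %in% c(0, 1))
}

n_items <- function(panel) ncol(panel$deficits)

# split row indices of panel$visits by subject, preserving order
panel_subject_rows <- function(panel) {
  split(seq_len(nrow(panel$visits)), factor(panel$visits$subject_id,
                                            levels = unique(panel$visits$subject_id)))
}

# keep only the given visit rows (and drop subjects with no remaining rows)
panel_subset_rows <- function(panel, rows) {
  visits <- panel$visits[rows, , drop = FALSE]
  deficits <- panel$deficits[rows, , drop = FALSE]
  keep_subj <- unique(visits$subject_id)
  covariates <- panel$covariates[panel$covariates$subject_id %in% keep_subj, , drop = FALSE]
  rownames(visits) <- rownames(covariates) <- NULL
  structure(list(visits = visits, deficits = deficits, covariates = covariates,
                 units = panel$units), class = "deficit_panel")
}

#' Read and write deficit panels as delimited text
#'
#' `write_panel` writes a long-format observation table
#' (`subject_id, time, deficit_id, value`) and a subject-level covariate
#' table (including any survival columns) as two CSV files with a common
#' prefix; `read_panel` reads them back.
#'
#' @param panel A [deficit_panel()].
#' @param prefix Path prefix; files `<prefix>_observations.csv` and
#'   `<prefix>_subjects.csv` are created.
#' @param units Time unit when reading.
#' @return `read_panel` returns a [deficit_panel()]; `write_panel` returns
#'   the two file paths invisibly.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "deficit_panel"))
  long <- data.frame(
    subject_id = rep(panel$visits$subject_id, ncol(panel$deficits)),
    time = rep(panel$visits$time, ncol(panel$deficits)),
    deficit_id = rep(colnames(panel$deficits), each = nrow(panel$deficits)),
    value = as.vector(panel$deficits)
  )
  long <- long[order(match(long$subject_id, unique(panel$visits$subject_id)),
                     long$time, long$deficit_id), ]
  f_obs <- paste0(prefix, "_observations.csv")
  f_sub <- paste0(prefix, "_subjects.csv")
  utils::write.csv(long, f_obs, row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$covariates, f_sub, row.names = FALSE, quote = FALSE)
  invisible(c(observations = f_obs, subjects = f_sub))
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix, units = c("months", "years")) {
  units <- match.arg(units)
  long <- utils::read.csv(paste0(prefix, "_observations.csv"))
  covariates <- utils::read.csv(paste0(prefix, "_subjects.csv"))
  items <- sort(unique(long$deficit_id))
  key <- paste(long$subject_id, long$time, sep = "\r")
  ukey <- unique(key)
  deficits <- matrix(NA_real_, length(ukey), length(items),
                     dimnames = list(NULL, items))
  deficits[cbind(match(key, ukey), match(long$deficit_id, items))] <- long$value
  first <- !duplicated(key)
  visits <- data.frame(subject_id = long$subject_id[first], time = long$time[first])
  ord <- order(match(visits$subject_id, unique(visits$subject_id)), visits$time)
  deficit_panel(visits[ord, , drop = FALSE], deficits[ord, , drop = FALSE],
                covariates, units)
}
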
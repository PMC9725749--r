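#' Longitudinal Poisson log-likelihood of transition counts
#'
#' The joint mouse model's longitudinal component as a standalone function:
#' `lambda_r = softplus(beta_r . x + b[1] + b[2] t_std)` (damage analogous),
#' Poisson log-mass with means `n lambda_r dt` and `(N - n) lambda_d dt`,
#' summed over subject-intervals. Intervals with no available items
#' contribute 0 when their count is 0 and `-Inf` otherwise. Written
#' independently of the sampling backend; the model templates must agree
#' with it (this is checked in the test suite).
#'
#' @param counts A [count_transitions()] result.
#' @param beta_r,beta_d Length-10 coefficient vectors on the standardized
#'   mouse design.
#' @param b Optional 4-row matrix of subject random effects (columns in
#'   order of `unique(counts$subject_id)`); defaults to zero.
#' @param standardize Standardization constants; default computed from
#'   `counts`.
#' @return Scalar log-likelihood.
#' @export
longitudinal_loglik <- function(counts, beta_r, beta_d, b = NULL,
                                standardize = NULL) {
  stopifnot(inherits(counts, "transition_counts"),
            length(beta_r) == 10L, length(beta_d) == 10L)
  N <- attr(counts, "n_items")
  if (is.null(counts$treatment)) counts$treatment <- 0
  if (is.null(standardize)) standardize <- standardize_constants(counts)
  subjects <- unique(counts$subject_id)
  if (is.null(b)) b <- matrix(0, 4L, length(subjects))
  si <- match(counts$subject_id, subjects)
  X <- mouse_design_matrix(counts, standardize)
  t_std <- (counts$t - standardize$center[["t"]]) / standardize$scale[["t"]]
  eta_r <- drop(X %*% beta_r) + b[1L, si] + b[2L, si] * t_std
  eta_d <- drop(X %*% beta_d) + b[3L, si] + b[4L, si] * t_std
  term <- function(y, avail, lambda) {
    mu <- avail * lambda * counts$dt
    out <- numeric(length(y))
    pos <- mu > 0
    out[pos] <- stats::dpois(y[pos], mu[pos], log = TRUE)
    out[!pos] <- ifelse(y[!pos] == 0, 0, -Inf)
    out
  }
  sum(term(counts$n_r, counts$n, softplus(eta_r))) +
    sum(term(counts$n_d, N - counts$n, softplus(eta_d)))
}
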
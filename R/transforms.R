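# Unconstrained-parameter transforms shared between the samplers' R side and
# the TMB templates. The C++ templates implement identical maps; unit tests
# compare the two through REPORT()ed values.

# stick-breaking map: y in R^{K-1} -> simplex a in R^K
simplex_from_unconstrained <- function(y) {
  K <- length(y) + 1L
  a <- numeric(K)
  stick <- 1
  for (l in seq_len(K - 1L)) {
    z <- stats::plogis(y[l] - log(K - l))
    a[l] <- stick * z
    stick <- stick * (1 - z)
  }
  a[K] <- stick
  a
}

simplex_to_unconstrained <- function(a) {
  K <- length(a)
  stopifnot(all(a > 0), abs(sum(a) - 1) < 1e-8)
  y <- numeric(K - 1L)
  stick <- 1
  for (l in seq_len(K - 1L)) {
    z <- a[l] / stick
    y[l] <- stats::qlogis(z) + log(K - l)
    stick <- stick - a[l]
  }
  y
}

# canonical-partial-correlation map: y in R^{K(K-1)/2} -> lower Cholesky
# factor L of a correlation matrix (row-filled: (2,1), (3,1), (3,2), ...)
corr_chol_from_unconstrained <- function(y, K) {
  stopifnot(length(y) == K * (K - 1L) / 2L)
  z <- tanh(y)
  L <- diag(K)
  idx <- 0L
  for (i in 2L:K) {
    rem <- 1
    for (j in 1L:(i - 1L)) {
      idx <- idx + 1L
      L[i, j] <- z[idx] * sqrt(rem)
      rem <- rem * (1 - z[idx]^2)
    }
    L[i, i] <- sqrt(rem)
  }
  L
}

corr_chol_to_unconstrained <- function(L) {
  K <- nrow(L)
  y <- numeric(K * (K - 1L) / 2L)
  idx <- 0L
  for (i in 2L:K) {
    rem <- 1
    for (j in 1L:(i - 1L)) {
      idx <- idx + 1L
      z <- L[i, j] / sqrt(rem)
      y[idx] <- atanh(min(max(z, -1 + 1e-12), 1 - 1e-12))
      rem <- rem * (1 - z^2)
    }
  }
  y
}
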
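test_that("softplus and its inverse are exact and overflow-safe", {
  expect_equal(softplus(0), log(2), tolerance = 1e-12)
  expect_lt(abs(softplus(40) - 40), 1e-15)
  expect_equal(softplus_inverse(log(2)), 0, tolerance = 1e-12)
  y <- c(1e-8, 1e-4, 0.1, 1, 10, 50)
  expect_lt(max(abs(softplus(softplus_inverse(y)) - y) / y), 1e-10)
  x <- seq(-30, 30, length.out = 101)
  expect_lt(max(abs(softplus_inverse(softplus(x)) - x)), 1e-10)
  expect_error(softplus_inverse(-1), "positive")
  expect_error(softplus_inverse(0), "positive")
})

test_that("knot placement yields exactly 17 (mouse) and 32 (state) knots", {
  k <- make_knots_mouse(seq(0, 1, length.out = 100))
  expect_length(k, 17L)
  expect_equal(k[1], 0)
  expect_equal(k[17], 1)
  # interior quantiles of a linear grid equal the quantile levels (scaled)
  expect_equal(k[2:16], seq(0.05, 0.95, length.out = 15), tolerance = 1e-10)
  ks <- make_knots_state(seq(2, 12, length.out = 1000))
  expect_length(ks, 32L)
  expect_equal(ks[2:31], 2 + 10 * seq(0.1, 0.9, length.out = 30), tolerance = 1e-2)
  expect_error(make_knots_mouse(rep(1:10, 5)), "distinct")
  expect_error(make_knots_state(rep(1:20, 3)), "distinct")
})

test_that("M-spline basis is non-negative and integrates to one; I-splines are its integrals", {
  k <- make_knots_mouse(c(16, 26, 16 + 10 * stats::qbeta(seq(0.01, 0.99, length.out = 60), 2, 2)))
  xs <- seq(16, 26, length.out = 4001)
  M <- mspline_basis(xs, k)
  expect_equal(ncol(M), 18L)
  expect_true(all(M >= 0))
  # trapezoid oracle for the integral of each basis
  ints <- colSums((M[-1, ] + M[-nrow(M), ]) / 2 * diff(xs))
  expect_equal(unname(ints), rep(1, 18), tolerance = 1e-4)
  I <- ispline_basis(xs, k)
  expect_true(all(I >= -1e-12), all(I <= 1 + 1e-12))
  expect_true(all(apply(I, 2, function(v) all(diff(v) >= -1e-12))))
  expect_equal(unname(I[nrow(I), ]), rep(1, 18), tolerance = 1e-10)
  Inum <- apply(M, 2, function(m) cumsum(c(0, (m[-1] + m[-length(m)]) / 2 * diff(xs))))
  expect_lt(max(abs(I - Inum)), 1e-5)
})

# independent Cox-de Boor recursion for the quadratic surface basis
cox_de_boor <- function(x, tau, ord) {
  nb <- length(tau) - ord
  B <- matrix(0, length(x), length(tau) - 1L)
  for (l in seq_len(length(tau) - 1L)) {
    B[, l] <- as.numeric(x >= tau[l] & x < tau[l + 1L])
  }
  B[x == tau[length(tau)], max(which(tau < tau[length(tau)]))] <- 1
  for (k in 2:ord) {
    Bn <- matrix(0, length(x), length(tau) - k)
    for (l in seq_len(length(tau) - k)) {
      d1 <- tau[l + k - 1L] - tau[l]
      d2 <- tau[l + k] - tau[l + 1L]
      t1 <- if (d1 > 0) (x - tau[l]) / d1 * B[, l] else 0
      t2 <- if (d2 > 0) (tau[l + k] - x) / d2 * B[, l + 1L] else 0
      Bn[, l] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(nb), drop = FALSE]
}

test_that("tensor-product surface matches a brute-force Cox-de Boor oracle", {
  set.seed(42)
  kw <- surface_knots(rnorm(200, 10, 2))
  ka <- surface_knots(runif(200, 50, 90))
  s <- matrix(rnorm(25), 5, 5)
  w <- runif(40, kw[1], kw[4])
  a0 <- runif(40, ka[1], ka[4])
  tau_w <- c(rep(kw[1], 2), kw, rep(kw[4], 2))
  tau_a <- c(rep(ka[1], 2), ka, rep(ka[4], 2))
  Bw <- cox_de_boor(w, tau_w, 3L)
  Ba <- cox_de_boor(a0, tau_a, 3L)
  oracle <- vapply(seq_along(w),
                   function(i) sum(s * outer(Bw[i, ], Ba[i, ])), numeric(1))
  expect_equal(bspline_surface(w, a0, s, kw, ka), oracle, tolerance = 1e-10)
})

test_that("surface basis is a partition of unity and single-coefficient surfaces are compact", {
  set.seed(7)
  kw <- surface_knots(rnorm(100))
  x <- seq(kw[1], kw[4], length.out = 200)
  B <- bspline_basis5(x, kw)
  expect_equal(ncol(B), 5L)
  expect_true(all(B >= 0))
  expect_equal(rowSums(B), rep(1, length(x)), tolerance = 1e-12)
  # all coefficients equal -> constant surface
  s <- matrix(3.25, 5, 5)
  v <- bspline_surface(runif(20, kw[1], kw[4]), runif(20, kw[1], kw[4]), s, kw, kw)
  expect_equal(v, rep(3.25, 20), tolerance = 1e-12)
  # single nonzero coefficient -> that basis product, non-negative
  s1 <- matrix(0, 5, 5); s1[2, 3] <- 1
  v1 <- bspline_surface(x, rep(mean(kw), length(x)), s1, kw, kw)
  expect_true(all(v1 >= 0))
  expect_true(any(v1 > 0))
  expect_true(v1[1] == 0 && v1[length(v1)] == 0)  # compact support
  expect_warning(bspline_basis5(kw[4] + 1, kw), "clamp")
})

test_that("surfaces are smooth inside the span (finite-difference curvature is bounded)", {
  set.seed(11)
  kw <- surface_knots(rnorm(100))
  s <- matrix(rnorm(25), 5, 5)
  x <- seq(kw[1] + 0.05, kw[4] - 0.05, length.out = 400)
  v <- bspline_surface(x, rep(mean(kw), length(x)), s, kw, kw)
  d1 <- diff(v) / diff(x)[1]
  # quadratic splines: first derivative continuous, so successive
  # finite-difference slopes change smoothly
  expect_lt(max(abs(diff(d1))), 0.2 * max(abs(d1)) + 1e-6)
})

test_that("cumulative hazard quadrature is exact for constants and cubics", {
  expect_equal(cumulative_hazard(function(t) rep(2.5, length(t)), 0, 4), 10,
               tolerance = 1e-13)
  h <- function(t) 0.1 + 0.02 * t + 0.003 * t^2 + 4e-4 * t^3
  H <- function(t) 0.1 * t + 0.01 * t^2 + 0.001 * t^3 + 1e-4 * t^4
  expect_equal(cumulative_hazard(h, 1, 7, breaks = c(2, 3.5, 6)), H(7) - H(1),
               tolerance = 1e-12)
  expect_error(cumulative_hazard(function(t) rep(1, length(t)), 2, 1), ">=")
})
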
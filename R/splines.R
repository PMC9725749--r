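#' M-spline and I-spline basis matrices
#'
#' Non-negative spline bases for baseline hazards. An M-spline basis function
#' integrates to 1 over the knot span, so a simplex-weighted combination of
#' M-splines is a valid (unnormalized-shape) hazard; the corresponding
#' I-splines (running integrals) are monotone from 0 to 1 and give the
#' cumulative hazard in closed form.
#'
#' The basis is the standard order-3 (quadratic) M-spline construction with
#' full boundary-knot multiplicity on the supplied distinct knot locations,
#' giving `length(knots) + 1` basis functions (18 for the 17 mouse
#' baseline-hazard knots, 33 for the 32 deficit-state knots). The first and
#' last basis functions are positive at the boundary knots, so hazards need
#' not vanish at the edges of the span.
#'
#' @param x Evaluation points.
#' @param knots Increasing vector of distinct knot locations (including the
#'   two boundary knots).
#' @return A `length(x)` by `length(knots) + 1` matrix. For `ispline_basis`,
#'   values at `x` below the first knot are 0 and above the last knot are 1.
#' @examples
#' k <- make_knots_mouse(seq(16, 26, length.out = 100))
#' M <- mspline_basis(seq(16, 26, 0.1), k)
#' ncol(M)  # 18
#' @export
mspline_basis <- function(x, knots) {
  tau <- mspline_knot_seq(knots)
  ord <- 3L
  xc <- pmin(pmax(x, knots[1L]), knots[length(knots)])
  B <- splines::splineDesign(tau, xc, ord = ord, outer.ok = TRUE)
  norm <- ord / (tau[(ord + 1L):length(tau)] - tau[seq_len(ncol(B))])
  sweep(B, 2L, norm, `*`)
}

#' @rdname mspline_basis
#' @export
ispline_basis <- function(x, knots) {
  # M-splines are piecewise quadratic, so 5-point Gauss-Legendre quadrature
  # per knot segment integrates them exactly
  gl <- gauss_legendre5()
  nseg <- length(knots) - 1L
  L <- length(knots) + 1L
  seg_int <- matrix(0, nseg, L)
  for (s in seq_len(nseg)) {
    half <- (knots[s + 1L] - knots[s]) / 2
    mid <- (knots[s + 1L] + knots[s]) / 2
    Mq <- mspline_basis(mid + half * gl$nodes, knots)
    seg_int[s, ] <- half * colSums(Mq * gl$weights)
  }
  cumseg <- rbind(0, apply(seg_int, 2L, cumsum))
  out <- matrix(0, length(x), L)
  xc <- pmin(pmax(x, knots[1L]), knots[length(knots)])
  seg_of <- pmin(pmax(findInterval(xc, knots), 1L), nseg)
  for (s in unique(seg_of)) {
    sel <- which(seg_of == s)
    full <- matrix(cumseg[s, ], length(sel), L, byrow = TRUE)
    for (i in seq_along(sel)) {
      a <- knots[s]; bnd <- xc[sel[i]]
      if (bnd > a) {
        half <- (bnd - a) / 2; mid <- (bnd + a) / 2
        Mq <- mspline_basis(mid + half * gl$nodes, knots)
        full[i, ] <- full[i, ] + half * colSums(Mq * gl$weights)
      }
    }
    out[sel, ] <- full
  }
  out[x >= knots[length(knots)], ] <- 1
  out[x < knots[1L], ] <- 0
  out
}

mspline_knot_seq <- function(knots) {
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  # full boundary multiplicity (3) for the order-3 basis: length(knots) + 1
  # basis functions, positive at the boundaries
  c(rep(knots[1L], 2L), knots, rep(knots[length(knots)], 2L))
}

#' Knot-placement rules for the baseline hazards
#'
#' `make_knots_mouse` places 17 knots for the mortality baseline hazard of the
#' joint mouse model: the minimum and maximum of the last-follow-up ages plus
#' 15 uniformly spaced quantiles from 0.05 to 0.95. `make_knots_state` places
#' 32 knots for deficit-state survival: the minimum and maximum of the
#' representative event times plus 30 uniformly spaced quantiles from 0.1 to
#' 0.9.
#'
#' @param times Numeric vector of last-follow-up ages (mouse) or
#'   representative event times (state survival; interval midpoints for
#'   interval-censored records, censoring times otherwise).
#' @return Increasing numeric vector of 17 (mouse) or 32 (state) knots.
#' @export
make_knots_mouse <- function(times) {
  place_knots(times, n_quantiles = 15L, q_range = c(0.05, 0.95))
}

#' @rdname make_knots_mouse
#' @export
make_knots_state <- function(times) {
  place_knots(times, n_quantiles = 30L, q_range = c(0.1, 0.9))
}

place_knots <- function(times, n_quantiles, q_range) {
  times <- times[is.finite(times)]
  n_target <- n_quantiles + 2L
  # quantiles of the distinct times: heavily tied data (gridded visit
  # schedules) would otherwise collapse interior knots onto each other
  times_u <- sort(unique(times))
  if (length(times_u) < n_target) {
    stop(sprintf("need at least %d distinct times to place %d knots, got %d",
                 n_target, n_target, length(times_u)), call. = FALSE)
  }
  qs <- stats::quantile(times_u, probs = seq(q_range[1L], q_range[2L],
                                             length.out = n_quantiles),
                        names = FALSE)
  knots <- c(times_u[1L], qs, times_u[length(times_u)])
  if (anyDuplicated(knots)) {
    stop("knot quantiles are not distinct; supply data with more spread", call. = FALSE)
  }
  knots
}

#' Quadratic B-spline basis on tercile knots
#'
#' One axis of the tensor-product coefficient surfaces of the human model:
#' order-3 (quadratic) B-splines on distinct knots at the minimum, terciles
#' and maximum of the observed variable, full boundary multiplicity, giving
#' exactly 5 basis functions that form a partition of unity over the span.
#'
#' @param x Evaluation points; values outside the knot span are clamped with
#'   a warning.
#' @param knots 4 distinct knot locations `(min, tercile1, tercile2, max)`,
#'   e.g. from [surface_knots()].
#' @return `length(x)` by 5 basis matrix.
#' @export
bspline_basis5 <- function(x, knots) {
  if (length(knots) != 4L || is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be 4 strictly increasing values (min, terciles, max)", call. = FALSE)
  }
  if (any(x < knots[1L] - 1e-12) || any(x > knots[4L] + 1e-12)) {
    warning("evaluation points outside the knot span; clamping to the boundary")
  }
  xc <- pmin(pmax(x, knots[1L]), knots[4L])
  tau <- c(rep(knots[1L], 2L), knots, rep(knots[4L], 2L))
  splines::splineDesign(tau, xc, ord = 3L, outer.ok = TRUE)
}

#' @rdname bspline_basis5
#' @param values Observed values of the variable from which tercile knots are
#'   computed.
#' @export
surface_knots <- function(values) {
  values <- values[is.finite(values)]
  k <- c(min(values), stats::quantile(values, c(1 / 3, 2 / 3), names = FALSE), max(values))
  if (anyDuplicated(k)) stop("tercile knots are not distinct", call. = FALSE)
  k
}

#' Evaluate a tensor-product B-spline coefficient surface
#'
#' Evaluates `sum_ij s[i, j] B_i(w) B_j(a0)` with quadratic B-splines on
#' tercile knots along each axis. With all coefficients equal to a constant
#' `c` the surface is identically `c` (partition of unity).
#'
#' @param w,a0 Coordinates (recycled to a common length).
#' @param s 5 x 5 coefficient matrix; rows index the `w` basis, columns the
#'   `a0` basis.
#' @param knots_w,knots_a0 Axis knots from [surface_knots()].
#' @return Numeric vector of surface values.
#' @export
bspline_surface <- function(w, a0, s, knots_w, knots_a0) {
  stopifnot(is.matrix(s), nrow(s) == 5L, ncol(s) == 5L)
  n <- max(length(w), length(a0))
  w <- rep_len(w, n)
  a0 <- rep_len(a0, n)
  Bw <- bspline_basis5(w, knots_w)
  Ba <- bspline_basis5(a0, knots_a0)
  rowSums((Bw %*% s) * Ba)
}

# sparse row representation of a spline basis matrix: cubic bases have at
# most 4 nonzero entries per row; returns 0-based column indices (-1 = pad)
sparse_basis_rows <- function(B, width = 4L) {
  idx <- matrix(-1L, nrow(B), width)
  w <- matrix(0, nrow(B), width)
  for (r in seq_len(nrow(B))) {
    nz <- which(B[r, ] != 0)
    if (length(nz) > width) {  # numerically tiny extras: keep the largest
      nz <- nz[order(B[r, nz], decreasing = TRUE)[seq_len(width)]]
      nz <- sort(nz)
    }
    if (length(nz)) {
      idx[r, seq_along(nz)] <- nz - 1L
      w[r, seq_along(nz)] <- B[r, nz]
    }
  }
  list(idx = idx, w = w)
}

# 5-point Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre5 <- function() {
  x <- c(-0.9061798459386640, -0.5384693101056831, 0,
         0.5384693101056831, 0.9061798459386640)
  w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
         0.4786286704993665, 0.2369268850561891)
  list(nodes = x, weights = w)
}
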
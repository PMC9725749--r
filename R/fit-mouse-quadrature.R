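# Quadrature layout for the survival component of the joint mouse model:
# 5-point Gauss-Legendre nodes between consecutive observed visit ages (and
# a final segment up to the death/censoring age T_i). Covariates at a node
# use the interval-start frailty index; beyond the last visit the last
# observed FI is carried forward, so the link-scale rate trajectory is
# extrapolated linearly in t.
mouse_quadrature <- function(counts, sv, sub_cov, knots, standardize) {
  gl <- gauss_legendre5()
  N <- attr(counts, "n_items")
  kmin <- knots[1L]; kmax <- knots[length(knots)]
  eps <- 1e-4 * (kmax - kmin)
  subjects <- sv$subject_id
  rowsQ <- list(); subjQ <- integer(0); wQ <- numeric(0); ageQ <- numeric(0)
  rowsT <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    rows <- which(counts$subject_id == subjects[s])
    a0 <- sub_cov$a0[s]; sex <- sub_cov$sex[s]; trt <- sub_cov$treatment[s]
    t_vis <- c(counts$t[rows], counts$t[rows[length(rows)]] + counts$dt[rows[length(rows)]])
    f_vis <- c(counts$f[rows],
               (counts$n[rows[length(rows)]] + counts$n_d[rows[length(rows)]] -
                  counts$n_r[rows[length(rows)]]) / N)
    ages <- a0 + t_vis
    T_i <- sv$death_time[s]
    grid <- c(ages[ages < T_i - 1e-12], T_i)
    f_at <- function(age) f_vis[pmin(pmax(findInterval(age, ages), 1L), length(f_vis))]
    for (g in seq_len(length(grid) - 1L)) {
      half <- (grid[g + 1L] - grid[g]) / 2
      if (half <= 0) next
      mid <- (grid[g + 1L] + grid[g]) / 2
      node_age <- mid + half * gl$nodes
      rowsQ[[length(rowsQ) + 1L]] <- data.frame(
        t = node_age - a0, sex = sex, treatment = trt,
        f = f_at(grid[g]), a0 = a0)
      subjQ <- c(subjQ, rep(s - 1L, 5L))
      wQ <- c(wQ, half * gl$weights)
      ageQ <- c(ageQ, node_age)
    }
    rowsT[[s]] <- data.frame(t = T_i - a0, sex = sex, treatment = trt,
                             f = f_at(T_i - 1e-12), a0 = a0)
  }
  dfQ <- do.call(rbind, rowsQ)
  dfT <- do.call(rbind, rowsT)
  T_eval <- pmin(pmax(sv$death_time, kmin + eps), kmax - eps)
  sb <- sparse_basis_rows(mspline_basis(ageQ, knots))
  list(UQ = mouse_surv_matrix(dfQ, standardize),
       XQ = mouse_design_matrix(dfQ, standardize),
       tQ_std = (dfQ$t - standardize$center[["t"]]) / standardize$scale[["t"]],
       subjQ = subjQ, wQ = wQ,
       BQi = sb$idx, BQw = sb$w,
       UT = mouse_surv_matrix(dfT, standardize),
       XT = mouse_design_matrix(dfT, standardize),
       tT_std = (dfT$t - standardize$center[["t"]]) / standardize$scale[["t"]],
       BT = mspline_basis(T_eval, knots))
}
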
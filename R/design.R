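# Design construction for the mouse joint model. All parent covariates are
# standardized to mean 0, SD 1 (over the fitting data, or with supplied
# constants); interaction columns are products of standardized parents.

mouse_parents <- c("t", "sex", "treatment", "f", "a0")

mouse_design_cols <- c("intercept", "t", "sex", "treatment", "f", "a0",
                       "sex:treatment", "sex:t", "treatment:t", "sex:treatment:t")
mouse_surv_cols <- c("intercept", "sex", "treatment", "sex:treatment", "f", "a0")

#' Standardization constants for a set of covariates
#'
#' @param df Data frame containing the parent covariates.
#' @param vars Covariate names.
#' @return List with `center` and `scale` named vectors (SD 1 is substituted
#'   for degenerate zero-SD columns).
#' @keywords internal
standardize_constants <- function(df, vars = mouse_parents) {
  center <- vapply(vars, function(v) mean(df[[v]]), numeric(1))
  scale <- vapply(vars, function(v) stats::sd(df[[v]]), numeric(1))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

std_cols <- function(df, constants, vars = names(constants$center)) {
  out <- lapply(vars, function(v) (df[[v]] - constants$center[[v]]) / constants$scale[[v]])
  names(out) <- vars
  out
}

# longitudinal design matrix x_i(t); rows align with df
mouse_design_matrix <- function(df, constants) {
  s <- std_cols(df, constants)
  X <- cbind(1, s$t, s$sex, s$treatment, s$f, s$a0,
             s$sex * s$treatment, s$sex * s$t, s$treatment * s$t,
             s$sex * s$treatment * s$t)
  colnames(X) <- mouse_design_cols
  X
}

# survival covariate matrix u_i; rows align with df
mouse_surv_matrix <- function(df, constants) {
  s <- std_cols(df, constants)
  U <- cbind(1, s$sex, s$treatment, s$sex * s$treatment, s$f, s$a0)
  colnames(U) <- mouse_surv_cols
  U
}

# d(column)/dt and d(column)/df of the standardized design, for the chain
# rules of the derived quantities. `s` holds the subject's standardized
# covariate values (sex, treatment fixed over time).
mouse_design_ddt <- function(s, scale) {
  c(0, 1 / scale[["t"]], 0, 0, 0, 0, 0,
    s$sex / scale[["t"]], s$treatment / scale[["t"]],
    s$sex * s$treatment / scale[["t"]])
}

mouse_design_ddf <- function(s, scale) {
  c(0, 0, 0, 0, 1 / scale[["f"]], 0, 0, 0, 0, 0)
}
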
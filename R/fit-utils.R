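#' Nonlinear least-squares fit results
#'
#' Lightweight container shared by all fitters in the package.  Parameter
#' estimates involving equilibrium constants are reported on the log10
#' scale; asymptotic standard errors come from the linearized Jacobian at
#' the optimum.
#'
#' @param estimates named numeric vector of parameter estimates.
#' @param se named numeric vector of asymptotic standard errors (or `NA`).
#' @param residuals per-point residual vector at the optimum.
#' @param converged logical convergence flag.
#' @param extra named list of method-specific diagnostics.
#' @return object of class `suprafit_fit`.
#' @keywords internal
fit_result <- function(estimates, se, residuals, converged, extra = list()) {
  structure(c(list(estimates = estimates, se = se,
                   residuals = as.numeric(residuals),
                   rss = sum(residuals^2), converged = isTRUE(converged)),
              extra),
            class = "suprafit_fit")
}

#' @export
print.suprafit_fit <- function(x, ...) {
  cat("<suprafit_fit> ", if (x$converged) "converged" else "NOT CONVERGED",
      sprintf(", RSS = %.4g, n = %d\n", x$rss, length(x$residuals)),
      sep = "")
  tab <- data.frame(estimate = x$estimates,
                    se = if (is.null(x$se)) NA_real_ else x$se)
  print(tab)
  invisible(x)
}

#' @export
coef.suprafit_fit <- function(object, ...) object$estimates

# Levenberg-Marquardt wrapper with multistart; fn returns residual vector.
# Starts: list of named parameter vectors. Returns fit_result.
lm_multistart <- function(fn, starts, lower = NULL, upper = NULL,
                          maxit = 200) {
  best <- NULL
  for (p0 in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = fn,
        lower = if (is.null(lower)) rep(-Inf, length(p0)) else lower,
        upper = if (is.null(upper)) rep(Inf, length(p0)) else upper,
        control = minpack.lm::nls.lm.control(maxiter = maxit,
                                             ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) stop("all optimization starts failed")
  best
}

lm_se <- function(fit) {
  # asymptotic SEs from the J'J approximation held by nls.lm
  p <- length(fit$par)
  n <- length(fit$fvec)
  dof <- max(n - p, 1L)
  s2 <- fit$deviance / dof
  cv <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
  if (is.null(cv)) return(stats::setNames(rep(NA_real_, p), names(fit$par)))
  stats::setNames(sqrt(pmax(diag(cv), 0)), names(fit$par))
}

# uniform helper: draw multistart points in log10-parameter space around a
# seed using a Latin-hypercube-like stratified grid; deterministic given seed
log_multistarts <- function(center, n = 8, half_width = 3, seed = 1L) {
  k <- length(center)
  if (n <= 1) return(list(center))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pts <- lapply(seq_len(n - 1), function(i) {
    strat <- (i - 0.5) / (n - 1)           # stratified in [0, 1]
    offs <- (strat * 2 - 1) * half_width
    center + offs * stats::runif(k, 0.5, 1) * sample(c(-1, 1), k, TRUE)
  })
  c(list(center), pts)
}
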
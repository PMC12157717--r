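#' Fit a conductometric titration for ion pairing
#'
#' Joint estimation of the ion-pair association constant and (optionally)
#' one unknown molar ionic conductivity from a conductometric titration.
#' Literature molar conductivities of the remaining ions are frozen.  The
#' association constant is fitted by Levenberg-Marquardt on the log10
#' scale; at each iterate the unknown \eqn{\lambda} enters the
#' conductivity model linearly and is profiled out by linear least
#' squares.
#'
#' @param dataset a `titration_dataset` with technique
#'   `"conductometric"`: needs `schedule`, `observed$kappa`,
#'   `obs_params$lambda` (frozen values) and a `model` whose ion-pair
#'   species' formation constant is to be fitted.
#' @param pair_species name of the ion-pair species in the model whose
#'   log10 formation constant is the nonlinear free parameter; `NULL`
#'   fits no constant (pure \eqn{\lambda} fit).
#' @param unknown_lambda name of the single ionic species whose molar
#'   conductivity is unknown; `NULL` if all are frozen.
#' @return a `suprafit_fit` with `logK_IP` (when fitted) and
#'   `lambda_<species>` estimates.
#' @export
fit_conductometric <- function(dataset, pair_species = "CA",
                               unknown_lambda = NULL) {
  stopifnot(is.list(dataset), dataset$technique == "conductometric",
            !is.null(dataset$model))
  model0 <- dataset$model
  sched <- dataset$schedule
  kobs <- dataset$observed$kappa
  lam <- unlist(dataset$obs_params$lambda)
  if (!is.null(unknown_lambda)) lam <- lam[setdiff(names(lam),
                                                   unknown_lambda)]

  kappa_parts <- function(model) {
    states <- tryCatch(
      suppressWarnings(speciate_schedule(model, sched,
                                         allow_solids = FALSE)),
      error = function(e) NULL)
    if (is.null(states)) return(NULL)
    conc <- conc_matrix(states)
    known <- 1e-3 * as.numeric(conc[, names(lam), drop = FALSE] %*% lam)
    list(known = known, conc = conc)
  }

  solve_lambda <- function(parts) {
    if (is.null(parts)) return(list(lu = NA_real_, r = rep(1e3, length(kobs))))
    if (is.null(unknown_lambda)) return(list(lu = NULL, r = kobs - parts$known))
    x <- 1e-3 * parts$conc[, unknown_lambda]
    lu <- sum(x * (kobs - parts$known)) / sum(x * x)
    list(lu = lu, r = kobs - parts$known - lu * x)
  }

  if (is.null(pair_species)) {
    out <- solve_lambda(kappa_parts(model0))
    est <- stats::setNames(out$lu, paste0("lambda_", unknown_lambda))
    return(fit_result(estimates = est, se = NULL, residuals = out$r,
                      converged = TRUE,
                      extra = list(params = as.list(est),
                                   technique = "conductometric")))
  }

  jsp <- match(pair_species, model0$species$name)
  if (is.na(jsp)) stop("unknown pair species: ", pair_species)

  resfn <- function(p) {
    m <- model0
    m$species$log_beta[jsp] <- p[["logK_IP"]]
    solve_lambda(kappa_parts(m))$r
  }
  fit <- lm_multistart(resfn, lapply(c(4, 2, 6, 3, 5),
                                     function(g) c(logK_IP = g)))
  # identifiability: the objective must actually respond to the constant
  d <- sqrt(sum((resfn(fit$par + 0.2) - resfn(fit$par - 0.2))^2))
  if (d < 1e-5 * max(sqrt(sum(kobs^2)), 1e-30))
    stop("non-identifiable: conductivity curve carries no ion-pairing ",
         "signature (K_IP and lambda cannot be separated)")
  m <- model0
  m$species$log_beta[jsp] <- fit$par[["logK_IP"]]
  out <- solve_lambda(kappa_parts(m))
  est <- c(unlist(fit$par),
           if (!is.null(unknown_lambda))
             stats::setNames(out$lu, paste0("lambda_", unknown_lambda)))
  fit_result(estimates = est, se = c(lm_se(fit),
                                     if (!is.null(unknown_lambda)) NA_real_),
             residuals = out$r, converged = fit$info %in% 1:4,
             extra = list(params = c(list(K_IP = 10^fit$par[["logK_IP"]]),
                                     if (!is.null(unknown_lambda))
                                       stats::setNames(list(out$lu),
                                         paste0("lambda_", unknown_lambda))),
                          technique = "conductometric"))
}

#' Fit an ion-pairing ITC titration
#'
#' Estimates the ion-pair formation constant (log10 scale) and its
#' reaction enthalpy from a salt-mode ITC dataset.  The enthalpy enters
#' the per-injection heats linearly and is profiled out at each iterate;
#' enthalpies of any other reactions in the model are frozen at the
#' values in `obs_params`.
#'
#' @param dataset a `titration_dataset` with technique `"itc"` generated
#'   in salt mode (or any dataset with a `model` containing the pair
#'   species).
#' @param pair_species species whose formation constant is fitted.
#' @return a `suprafit_fit` with `logK_IP` and the profiled `dH`
#'   (kJ mol\eqn{^{-1}}).
#' @export
fit_itc_pairing <- function(dataset, pair_species = "CA") {
  stopifnot(is.list(dataset), dataset$technique == "itc",
            !is.null(dataset$model))
  model0 <- dataset$model
  sched <- dataset$schedule
  Qobs <- dataset$observed$Q_uJ
  jsp <- match(pair_species, model0$species$name)
  if (is.na(jsp)) stop("unknown pair species: ", pair_species)
  dH_frozen <- unlist(dataset$obs_params$enthalpies$dH %||% list())
  dH_frozen <- dH_frozen[setdiff(names(dH_frozen), pair_species)]
  scale <- sched$V0 * 1e9

  parts <- function(logK) {
    m <- model0
    m$species$log_beta[jsp] <- logK
    states <- tryCatch(
      suppressWarnings(speciate_schedule(m, sched, allow_solids = FALSE,
                                         overflow = TRUE)),
      error = function(e) NULL)
    if (is.null(states))
      return(list(r = rep(1e3, length(Qobs)), dh = NA_real_))
    conc <- conc_matrix(states)
    dC <- apply(conc, 2, diff)
    known <- intersect(names(dH_frozen), colnames(dC))
    Qk <- if (length(known))
      as.numeric(dC[, known, drop = FALSE] %*% dH_frozen[known]) * scale
    else 0
    x <- dC[, pair_species] * scale
    dh <- sum(x * (Qobs - Qk)) / sum(x * x)
    list(r = Qobs - Qk - dh * x, dh = dh)
  }

  fit <- lm_multistart(function(p) parts(p[["logK_IP"]])$r,
                       lapply(c(4, 2.5, 5.5, 3), function(g)
                         c(logK_IP = g)))
  out <- parts(fit$par[["logK_IP"]])
  fit_result(estimates = c(unlist(fit$par), dH = out$dh),
             se = c(lm_se(fit), dH = NA_real_),
             residuals = out$r, converged = fit$info %in% 1:4,
             extra = list(params = list(K_IP = 10^fit$par[["logK_IP"]],
                                        dH = out$dh),
                          technique = "itc"))
}
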
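#' Fit a common-ion solubility series (method A type)
#'
#' Least-squares estimation of the solubility product and ion-pairing
#' constant from the dependence of the total salt solubility on the added
#' common-anion concentration, using
#' [solubility_with_common_anion()] as the model.  Optimization runs in
#' log10-parameter space (the natural conditioning for constants spanning
#' many orders of magnitude).
#'
#' @param data data frame with columns `c_coion` (analytical common-anion
#'   concentration, mol dm\eqn{^{-3}}) and `s` (measured total solubility).
#'   At least three distinct `c_coion` levels including 0 are required.
#' @return a `suprafit_fit` with estimates `logKs`, `logK_IP` (log10 scale)
#'   and linear-scale copies `Ks`, `K_IP` in `$params`.
#' @export
fit_method_A <- function(data) {
  stopifnot(is.data.frame(data), all(c("c_coion", "s") %in% names(data)))
  if (length(unique(data$c_coion)) < 3 || !any(data$c_coion == 0))
    stop("non-identifiable design: need >= 3 distinct c_coion levels ",
         "including c_coion = 0")
  if (stats::sd(data$s) == 0 && length(unique(data$c_coion)) > 1 &&
      max(data$c_coion) > 0)
    stop("non-identifiable: solubility does not respond to the common ion")
  s0 <- mean(data$s[data$c_coion == 0])

  resfn <- function(p) {
    Ks <- 10^p[["logKs"]]; K <- 10^p[["logK_IP"]]
    solubility_with_common_anion(Ks, K, data$c_coion) - data$s
  }
  starts <- lapply(c(1, 4, 25, 100), function(f) {
    Ks <- (s0 / f)^2
    K <- max((s0 - sqrt(Ks)) / Ks, 1e-6)
    c(logKs = log10(Ks), logK_IP = log10(K))
  })
  fit <- lm_multistart(resfn, starts)
  est <- fit$par
  fit_result(estimates = unlist(est), se = lm_se(fit),
             residuals = fit$fvec, converged = fit$info %in% 1:4,
             extra = list(params = list(Ks = 10^est[["logKs"]],
                                        K_IP = 10^est[["logK_IP"]]),
                          method = "A"))
}

#' Fit a two-regime potentiometric precipitation titration (method B type)
#'
#' Fits pNa curves from the titration of the cation salt with the common
#' anion, where precipitation may start mid-titration.  Rows in the
#' no-solid regime follow the ion-pairing quadratic
#' ([free_cation_no_solid()], with
#' \eqn{K_{IP} = (s - \sqrt{K_s})/K_s} tied through the pure-solution
#' relation), rows past the precipitation onset follow the
#' saturation expression ([free_cation_with_solid()]).  Rows are labelled
#' by the `regime` column when present, otherwise auto-labelled with
#' [regime_test()] at the current parameter iterate.
#'
#' @param data data frame with columns `c_cation`, `c_anion`, `pNa` and
#'   optionally `regime` (`"no_solid"` / `"solid"`).
#' @param s_fixed optional fixed total solubility (mol dm\eqn{^{-3}}); when
#'   given, only \eqn{K_s} is adjustable (the protocol for titrations
#'   where the solid forms from the first addition).
#' @return a `suprafit_fit` with `logKs`, `log_s` estimates (as free),
#'   derived `K_IP` and the regime split in `$params`.
#' @export
fit_method_B <- function(data, s_fixed = NULL) {
  stopifnot(is.data.frame(data),
            all(c("c_cation", "c_anion", "pNa") %in% names(data)))
  has_label <- "regime" %in% names(data)
  cNa <- data$c_cation; cA <- data$c_anion

  # identifiability: each free parameter needs rows in its regime
  check_regimes <- function(reg) {
    if (!any(reg == "solid"))
      stop("non-identifiable: no points in the solid regime, Ks free")
    if (is.null(s_fixed) && !any(reg == "no_solid"))
      stop("non-identifiable: no points in the no-solid regime while s ",
           "(hence K_IP) is free")
  }
  if (has_label) check_regimes(data$regime)

  # smooth one-parameter subfits per regime (the two-model treatment):
  fit_Ks <- function(rows, K_IP = NULL) {
    # with s fixed, K_IP is tied to Ks through s = sqrt(Ks) + Ks K_IP and
    # no-solid rows also inform Ks; otherwise only solid rows are used
    resfn <- function(p) {
      Ks <- 10^p[["logKs"]]
      x <- free_cation_with_solid(cNa[rows], cA[rows], Ks)
      -log10(x) - data$pNa[rows]
    }
    lm_multistart(resfn, lapply(c(-8, -10, -12, -6, -14),
                                function(g) c(logKs = g)))
  }
  fit_KIP <- function(rows) {
    resfn <- function(p) {
      K <- 10^p[["logK_IP"]]
      x <- free_cation_no_solid(cNa[rows], cA[rows], K)
      -log10(x) - data$pNa[rows]
    }
    lm_multistart(resfn, lapply(c(2, 4, 6, 8), function(g) c(logK_IP = g)))
  }

  if (!is.null(s_fixed) && !has_label) {
    # one adjustable parameter; labels follow from (Ks, K_IP(Ks)) directly
    resfn <- function(p) {
      Ks <- 10^p[["logKs"]]
      K_IP <- (s_fixed - sqrt(Ks)) / Ks
      if (K_IP < 0) return(rep(1e6, nrow(data)))
      reg <- regime_test(cNa, cA, list(Ks = Ks, K_IP = K_IP))
      x <- ifelse(reg == "solid",
                  free_cation_with_solid(cNa, cA, Ks),
                  free_cation_no_solid(cNa, cA, K_IP))
      -log10(x) - data$pNa
    }
    fit <- lm_multistart(resfn, lapply(c(-8, -10, -12, -6),
                                       function(g) c(logKs = g)))
    Ks <- 10^fit$par[["logKs"]]
    K_IP <- (s_fixed - sqrt(Ks)) / Ks
    reg <- regime_test(cNa, cA, list(Ks = Ks, K_IP = K_IP))
    check_regimes(reg)
    return(fit_result(estimates = unlist(fit$par), se = lm_se(fit),
                      residuals = fit$fvec, converged = fit$info %in% 1:4,
                      extra = list(params = list(Ks = Ks, s = s_fixed,
                                                 K_IP = K_IP),
                                   regime = reg, method = "B")))
  }

  # labels given, or both parameters free.  Without labels the precipitation
  # onset is found by enumeration: points are ordered by increasing
  # anion:cation ratio (the direction of the titration), every candidate
  # onset index is tried, and the split minimizing the combined RSS of the
  # two one-parameter subfits wins.  This keeps each subproblem smooth and
  # makes the estimates independent of the row order of the input.
  if (has_label) {
    reg <- data$regime
    fK <- fit_Ks(reg == "solid")
    Ks <- 10^fK$par[["logKs"]]
    if (is.null(s_fixed)) {
      fI <- fit_KIP(reg == "no_solid")
      K_IP <- 10^fI$par[["logK_IP"]]
    } else {
      K_IP <- (s_fixed - sqrt(Ks)) / Ks
      fI <- NULL
    }
  } else {
    ord <- order(cA / pmax(cNa, 1e-300), cA)
    n <- nrow(data)
    best <- NULL
    for (k in 2:n) {          # first k-1 ordered points no-solid, rest solid
      rows_ns <- ord[seq_len(k - 1)]
      rows_s <- ord[k:n]
      cand <- tryCatch({
        fK_c <- fit_Ks(rows_s)
        fI_c <- fit_KIP(rows_ns)
        list(fK = fK_c, fI = fI_c, rss = fK_c$deviance + fI_c$deviance,
             rows_s = rows_s)
      }, error = function(e) NULL)
      if (!is.null(cand) && (is.null(best) || cand$rss < best$rss))
        best <- cand
    }
    if (is.null(best)) stop("method B fit failed at every candidate onset")
    fK <- best$fK; fI <- best$fI
    Ks <- 10^fK$par[["logKs"]]
    K_IP <- 10^fI$par[["logK_IP"]]
    reg <- rep("no_solid", n)
    reg[best$rows_s] <- "solid"
  }
  check_regimes(reg)
  s <- if (is.null(s_fixed)) solubility_pure(Ks, K_IP) else s_fixed
  resid <- ifelse(reg == "solid",
                  -log10(free_cation_with_solid(cNa, cA, Ks)),
                  -log10(free_cation_no_solid(cNa, cA, K_IP))) - data$pNa
  est <- c(logKs = log10(Ks), log_s = log10(s))
  se <- c(logKs = unname(lm_se(fK)["logKs"]),
          log_s = NA_real_)
  fit_result(estimates = est, se = se, residuals = resid,
             converged = fK$info %in% 1:4 &&
               (is.null(fI) || fI$info %in% 1:4),
             extra = list(params = list(Ks = Ks, s = s, K_IP = K_IP),
                          regime = reg, method = "B"))
}

#' Fit a dimerizing-anion solubility series (method E type)
#'
#' Like [fit_method_A()] but for a salt whose anion dimerizes; the forward
#' model is the implicit cubic of [phosphate_solubility_implicit()] with the
#' dimerization constant supplied as a fixed, independently known input.
#'
#' @inheritParams fit_method_A
#' @param K_dim_fixed fixed anion dimerization constant,
#'   mol\eqn{^{-1}} dm\eqn{^3}.
#' @export
fit_method_E <- function(data, K_dim_fixed) {
  stopifnot(is.data.frame(data), all(c("c_coion", "s") %in% names(data)),
            is.numeric(K_dim_fixed), K_dim_fixed >= 0)
  if (length(unique(data$c_coion)) < 3)
    stop("non-identifiable design: need >= 3 distinct c_coion levels")
  s0 <- data$s[which.min(data$c_coion)]

  resfn <- function(p) {
    Ks <- 10^p[["logKs"]]; K <- 10^p[["logK_IP"]]
    mod <- vapply(data$c_coion, function(cc)
      tryCatch(phosphate_solubility_implicit(Ks, K, K_dim_fixed, cc),
               error = function(e) NA_real_), 0)
    r <- mod - data$s
    r[!is.finite(r)] <- 1e3
    r
  }
  starts <- lapply(c(2, 10, 100, 1000), function(f) {
    Ks <- (s0 / f)^2
    K <- max((s0 - sqrt(Ks)) / Ks, 1e-6)
    c(logKs = log10(Ks), logK_IP = log10(K))
  })
  fit <- lm_multistart(resfn, starts)
  fit_result(estimates = unlist(fit$par), se = lm_se(fit),
             residuals = fit$fvec, converged = fit$info %in% 1:4,
             extra = list(params = list(Ks = 10^fit$par[["logKs"]],
                                        K_IP = 10^fit$par[["logK_IP"]],
                                        K_dim = K_dim_fixed),
                          method = "E"))
}

#' Fit a precipitation titration with anion dimerization (method F type)
#'
#' Single-parameter fit of \eqn{K_s} to a pNa titration of the cation salt
#' with a dimerizing anion, at fixed total solubility `s_fixed` and fixed
#' `K_dim_fixed`.  The forward model is the full speciation (solid + dimer
#' + ion pair) computed with [solve_speciation()]; the ion-pairing constant
#' is tied to \eqn{K_s} through the saturated pure solution
#' ([phosphate_free_cation_saturated()] and [kip_from_saturated()]).
#' Residuals are weighted by the local sensitivity
#' \eqn{|\partial \mathrm{pNa} / \partial \log_{10} K_s|} (normalized),
#' which concentrates the fit on the region of the curve most responsive to
#' \eqn{K_s}; weights are refreshed once after a first pass.  Unit weights
#' can be requested, reducing to ordinary least squares.
#'
#' @param data data frame with columns `c_cation`, `c_anion`, `pNa`.
#' @param s_fixed fixed total solubility of the pure salt.
#' @param K_dim_fixed fixed anion dimerization constant.
#' @param weights `"sensitivity"` (default) or `"uniform"`.
#' @return a `suprafit_fit` with `logKs` and the derived `K_IP`.
#' @export
fit_method_F <- function(data, s_fixed, K_dim_fixed,
                         weights = c("sensitivity", "uniform")) {
  stopifnot(is.data.frame(data),
            all(c("c_cation", "c_anion", "pNa") %in% names(data)),
            s_fixed > 0, K_dim_fixed > 0)
  weights <- match.arg(weights)

  pna_model <- function(logKs) {
    Ks <- 10^logKs
    n_sat <- phosphate_free_cation_saturated(Ks, K_dim_fixed)
    if (s_fixed <= n_sat) return(rep(1e6, nrow(data)))
    K_IP <- kip_from_saturated(s_fixed, n_sat, Ks)
    mod <- eq_model(
      c("Na", "A"),
      species = list(list(name = "NaA", stoich = c(Na = 1, A = 1),
                          log_beta = log10(K_IP)),
                     list(name = "A2", stoich = c(A = 2),
                          log_beta = log10(K_dim_fixed))),
      solids = list(list(name = "NaA_s", stoich = c(Na = 1, A = 1),
                         log_Ks = logKs)))
    out <- numeric(nrow(data))
    prev <- NULL
    for (i in seq_len(nrow(data))) {
      r <- tryCatch(
        suppressWarnings(solve_speciation(mod, c(Na = data$c_cation[i],
                                                 A = data$c_anion[i]),
                                          start = prev)),
        error = function(e) NULL)
      if (is.null(r) || !r$converged) return(rep(1e6, nrow(data)))
      prev <- r$free
      out[i] <- -log10(r$free[["Na"]])
    }
    out
  }

  w <- rep(1, nrow(data))
  logKs0 <- log10((s_fixed / 10)^2)
  for (pass in 1:2) {
    resfn <- function(p) sqrt(w) * (pna_model(p[["logKs"]]) - data$pNa)
    fit <- lm_multistart(resfn, lapply(c(0, -2, 2, -4),
                                       function(d) c(logKs = logKs0 + d)))
    logKs0 <- fit$par[["logKs"]]
    if (weights == "uniform" || pass == 2) break
    # sensitivity weights at the current iterate
    h <- 0.05
    dd <- abs(pna_model(logKs0 + h) - pna_model(logKs0 - h)) / (2 * h)
    if (max(dd) > 0) w <- dd / max(dd) + 1e-3
  }
  Ks <- 10^fit$par[["logKs"]]
  n_sat <- phosphate_free_cation_saturated(Ks, K_dim_fixed)
  K_IP <- kip_from_saturated(s_fixed, n_sat, Ks)
  fit_result(estimates = unlist(fit$par), se = lm_se(fit),
             residuals = fit$fvec, converged = fit$info %in% 1:4,
             extra = list(params = list(Ks = Ks, K_IP = K_IP,
                                        s = s_fixed, K_dim = K_dim_fixed),
                          weights = w, method = "F"))
}
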
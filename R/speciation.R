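#' Solve simultaneous solution equilibria, optionally with solid phases
#'
#' Computes the equilibrium composition of a solution given an equilibrium
#' model and per-component analytical (total) concentrations.  The solver
#' works in log-concentration space with damped Newton iterations and a
#' multistart strategy (all-free, all-bound and uniform 1e-7 mol dm\eqn{^{-3}}
#' initial guesses), which keeps it robust over formation constants spanning
#' ten and more orders of magnitude.  Solid phases are handled by an
#' active-set scheme: the solution-only problem is solved first, saturation
#' is checked against each solubility product, violated solids are activated
#' one at a time and the system is re-solved with the ion product pinned to
#' \eqn{K_s}; a solid whose amount turns negative is dropped again.
#'
#' The returned state satisfies, within tolerance, the mass balance
#' \eqn{\sum_j \nu_{ji} [S_j] + \sum_k \nu_{ki} n_k = T_i} for every
#' component \eqn{i} and the saturation complementarity condition for every
#' solid: either its amount is zero and its ion product does not exceed
#' \eqn{K_s}, or its amount is positive and the ion product equals
#' \eqn{K_s}.
#'
#' @param model an [eq_model()].
#' @param totals named numeric vector of analytical concentrations
#'   (mol dm\eqn{^{-3}}), one per component, all `>= 0`.
#' @param allow_solids if `FALSE`, solid phases are ignored even when the
#'   solution is supersaturated.
#' @param tol convergence tolerance on the relative mass-balance residual.
#' @param maxit Newton iteration cap per start.
#' @param start optional named vector of free concentrations used as an
#'   additional (first) initial guess, e.g. the solution of a neighbouring
#'   titration point.
#' @return an object of class `speciation`: list with `free` (named free
#'   component concentrations), `species` (named species concentrations),
#'   `solid_amounts` (named, mol dm\eqn{^{-3}} equivalent), `converged`,
#'   `residual` (max relative mass-balance residual), and `model`.
#'   Non-convergence is reported through `converged = FALSE` (with a
#'   warning), never silently.
#' @seealso [oracle_solve_1d()] for an independent brute-force check on
#'   one-unknown models, [ion_product()].
#' @export
solve_speciation <- function(model, totals, allow_solids = TRUE,
                             tol = 1e-12, maxit = 200, start = NULL) {
  stopifnot(inherits(model, "eq_model"))
  totals <- check_totals(model, totals)
  comp <- model$components

  # components with zero total: free conc 0, any species containing them 0
  zero <- totals <= 0
  sub <- reduce_model(model, keep = !zero)

  ns <- nrow(sub$model$solids)
  act <- logical(ns)
  res <- solve_newton(sub$model, totals[!zero], active = act,
                      tol = tol, maxit = maxit, start = start)
  if (allow_solids && ns > 0) {
    for (sweep in seq_len(2L * ns + 3L)) {
      changed <- FALSE
      if (res$converged) {
        # drop a negative solid first, then activate the worst violation
        if (any(act) && any(res$p[act] < 0)) {
          k <- which(act)[which.min(res$p[act])]
          act[k] <- FALSE
          changed <- TRUE
        } else {
          lip <- log_ion_products(sub$model, res$u)
          viol <- which(!act & lip > sub$model$solids$log_Ks + 1e-9)
          if (length(viol)) {
            k <- viol[which.max(lip[viol] - sub$model$solids$log_Ks[viol])]
            act[k] <- TRUE
            changed <- TRUE
          }
        }
      }
      if (!changed) break
      res <- solve_newton(sub$model, totals[!zero], active = act,
                          tol = tol, maxit = maxit,
                          start = exp(res$u))
    }
  }
  if (!res$converged)
    warning("speciation solver did not converge (residual ",
            format(res$residual, digits = 3), ")")

  free <- stats::setNames(rep(0, length(comp)), comp)
  free[!zero] <- exp(res$u)
  spc <- stats::setNames(rep(0, nrow(model$species)), model$species$name)
  spc[names(res$s)] <- res$s
  sol <- stats::setNames(rep(0, nrow(model$solids)), model$solids$name)
  if (allow_solids && ns > 0) sol[sub$model$solids$name] <- pmax(res$p, 0)

  structure(list(free = free, species = spc, solid_amounts = sol,
                 converged = res$converged, residual = res$residual,
                 totals = totals, model = model),
            class = "speciation")
}

#' @export
print.speciation <- function(x, ...) {
  cat("<speciation> ", if (x$converged) "converged" else "NOT CONVERGED",
      sprintf(" (max rel. residual %.2e)\n", x$residual), sep = "")
  cat("  free:   ", paste(sprintf("%s = %.4g", names(x$free), x$free),
                          collapse = ", "), "\n", sep = "")
  other <- setdiff(names(x$species), names(x$free))
  if (length(other))
    cat("  species:", paste(sprintf("%s = %.4g", other, x$species[other]),
                            collapse = ", "), "\n", sep = " ")
  if (length(x$solid_amounts))
    cat("  solids: ", paste(sprintf("%s = %.4g", names(x$solid_amounts),
                                    x$solid_amounts), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

check_totals <- function(model, totals) {
  comp <- model$components
  if (!is.null(names(totals))) {
    if (!all(comp %in% names(totals)))
      stop("totals missing for component(s): ",
           paste(setdiff(comp, names(totals)), collapse = ", "))
    totals <- totals[comp]
  } else if (length(totals) == length(comp)) {
    names(totals) <- comp
  } else stop("totals must be named or match the number of components")
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("analytical concentrations must be finite and >= 0")
  totals
}

# restrict a model to a subset of components, dropping species/solids that
# involve an excluded component
reduce_model <- function(model, keep) {
  if (all(keep)) return(list(model = model, keep = keep))
  Sok <- apply(model$stoich[, !keep, drop = FALSE] != 0, 1L, sum) == 0
  Bok <- if (nrow(model$solids))
    apply(model$solid_stoich[, !keep, drop = FALSE] != 0, 1L, sum) == 0
  else logical(0)
  m <- model
  m$components <- model$components[keep]
  m$species <- model$species[Sok, , drop = FALSE]
  m$stoich <- model$stoich[Sok, keep, drop = FALSE]
  m$solids <- model$solids[Bok, , drop = FALSE]
  m$solid_stoich <- model$solid_stoich[Bok, keep, drop = FALSE]
  m$charges <- model$charges[Sok]
  list(model = m, keep = keep)
}

log_ion_products <- function(model, u) {
  # natural-log free concs -> log10 ion products of every solid
  if (!nrow(model$solids)) return(numeric(0))
  as.numeric(model$solid_stoich %*% (u / log(10)))
}

# core damped-Newton solve in ln-concentration space; `active` marks solids
# whose ion product is pinned to Ks (amounts become extra unknowns)
solve_newton <- function(model, totals, active, tol = 1e-12, maxit = 200,
                         start = NULL) {
  comp <- model$components
  n <- length(comp)
  A <- model$stoich
  lnb <- model$species$log_beta * log(10)
  B <- model$solid_stoich[active, , drop = FALSE]
  lnKs <- model$solids$log_Ks[active] * log(10)
  na <- nrow(B)
  Tref <- pmax(totals, 1e-300)

  if (n == 0L)
    return(list(u = numeric(0), s = numeric(0), p = numeric(0),
                converged = TRUE, residual = 0))

  eval_state <- function(u, p) {
    s <- as.numeric(exp(lnb + A %*% u))
    F1 <- as.numeric(crossprod(A, s)) - totals
    if (na) F1 <- F1 + as.numeric(crossprod(B, p))
    r1 <- F1 / Tref
    r2 <- if (na) as.numeric(B %*% u) - lnKs else numeric(0)
    list(s = s, r = c(r1, r2))
  }

  starts <- list()
  if (!is.null(start)) {
    st <- if (!is.null(names(start))) start[comp] else start
    st <- pmax(as.numeric(st), 1e-300)
    starts <- c(starts, list(log(st)))
  }
  starts <- c(starts,
              list(log(Tref),                  # all free
                   log(pmax(Tref * 1e-8, 1e-300)),  # essentially all bound
                   rep(log(1e-7), n)))         # uniform guess

  best <- NULL
  for (u0 in starts) {
    u <- u0
    p <- rep(0, na)
    st <- eval_state(u, p)
    ok <- FALSE
    for (it in seq_len(maxit)) {
      rn <- max(abs(st$r))
      if (rn < tol) { ok <- TRUE; break }
      # Jacobian
      W <- st$s * A            # rows scaled by species conc
      J <- crossprod(A, W)     # d F1 / d u
      J <- J / Tref            # row scaling
      if (na) {
        Jup <- t(B) / Tref     # d r1 / d p  (n x na)
        Jfull <- rbind(cbind(J, Jup), cbind(B, matrix(0, na, na)))
      } else Jfull <- J
      step <- tryCatch(solve(Jfull, -st$r), error = function(e) NULL)
      if (is.null(step)) {
        step <- tryCatch(
          solve(Jfull + diag(1e-10, nrow(Jfull)), -st$r),
          error = function(e) NULL)
        if (is.null(step)) break
      }
      du <- step[seq_len(n)]
      dp <- if (na) step[n + seq_len(na)] else numeric(0)
      # cap the log step, then backtrack
      cap <- max(1, max(abs(du)) / 5)
      du <- du / cap; dp <- dp / cap
      lam <- 1
      improved <- FALSE
      for (h in 1:30) {
        cand <- eval_state(u + lam * du, p + lam * dp)
        if (max(abs(cand$r)) < rn || h == 30) {
          u <- u + lam * du; p <- p + lam * dp; st <- cand
          improved <- max(abs(cand$r)) < rn
          break
        }
        lam <- lam / 2
      }
      if (!improved && max(abs(st$r)) >= rn) break
    }
    rn <- max(abs(st$r))
    cand <- list(u = u, p = p, s = stats::setNames(st$s, model$species$name),
                 converged = ok && rn < tol, residual = rn)
    if (is.null(best) || (cand$converged && !best$converged) ||
        (cand$converged == best$converged && cand$residual < best$residual))
      best <- cand
    if (best$converged) break
  }
  # expand p over all solids of (sub)model
  pfull <- rep(0, nrow(model$solids))
  pfull[active] <- best$p
  best$p <- pfull
  best
}

#' Ion product of a solid phase in a speciation state
#'
#' The product of the free component concentrations raised to the solid's
#' stoichiometric coefficients, \eqn{\prod_i [X_i]^{\nu_i}}.  At saturation
#' this equals the solubility product \eqn{K_s}.
#'
#' @param result a [solve_speciation()] result.
#' @param solid name of a solid defined in the model.
#' @return numeric ion product (concentration units per the stoichiometry).
#' @export
ion_product <- function(result, solid) {
  stopifnot(inherits(result, "speciation"))
  model <- result$model
  k <- match(solid, model$solids$name)
  if (is.na(k)) stop("unknown solid: ", solid)
  nu <- model$solid_stoich[k, ]
  prod(result$free^nu)
}

#' Independent brute-force solver for one-unknown equilibrium models
#'
#' A deliberately simple verifier for [solve_speciation()]: applicable when
#' the model reduces to a single unknown free concentration, i.e. when at
#' most one component appears with stoichiometry greater than one and every
#' other component's mass balance is linear in its own free concentration.
#' The non-pivot components are eliminated by damped fixed-point
#' substitution and the pivot's mass balance (monotone in the pivot's free
#' concentration) is solved by log-grid bracketing and bisection.  Solid
#' phases are not supported.
#'
#' @inheritParams solve_speciation
#' @return a `speciation` object (without solids).
#' @export
oracle_solve_1d <- function(model, totals) {
  stopifnot(inherits(model, "eq_model"))
  if (nrow(model$solids) > 0)
    stop("oracle_solve_1d handles solution-only models")
  totals <- check_totals(model, totals)
  zero <- totals <= 0
  sub <- reduce_model(model, keep = !zero)$model
  comp <- sub$components
  n <- length(comp)
  A <- sub$stoich
  beta <- 10^sub$species$log_beta
  Tt <- totals[!zero]

  out_free <- stats::setNames(rep(0, length(model$components)),
                              model$components)
  spc <- stats::setNames(rep(0, nrow(model$species)), model$species$name)

  if (n > 0) {
    nonlin <- which(apply(A, 2L, max) > 1)
    if (length(nonlin) > 1)
      stop("model is not reducible to one unknown")
    pivot <- if (length(nonlin)) nonlin else 1L
    others <- setdiff(seq_len(n), pivot)

    solve_others <- function(xp) {
      x <- pmax(Tt, 1e-300)
      x[pivot] <- xp
      if (length(others)) {
        for (it in 1:2000) {
          xo <- x
          for (i in others) {
            # mass balance linear in x_i:
            #   T_i = x_i * sum_{j: A_ji = 1} beta_j prod_{l != i} x_l^A_jl
            # (the identity species contributes the bare x_i term)
            contrib <- 0
            for (j in seq_along(beta)) {
              if (A[j, i] == 1) {
                contrib <- contrib + beta[j] * prod(x[-i]^A[j, -i])
              } else if (A[j, i] > 1)
                stop("model is not reducible to one unknown")
            }
            x[i] <- Tt[i] / contrib
          }
          if (max(abs(x - xo) / pmax(x, 1e-300)) < 1e-15) break
        }
      }
      x
    }

    resid <- function(xp) {
      x <- solve_others(xp)
      s <- beta * exp(as.numeric(A %*% log(pmax(x, 1e-300))))
      sum(A[, pivot] * s) - Tt[pivot]
    }

    # resid < 0 as x_pivot -> 0 and >= 0 at x_pivot = T_pivot
    lo <- log(Tt[pivot]) - 60
    hi <- log(Tt[pivot])
    for (it in 1:160) {
      mid <- (lo + hi) / 2
      if (resid(exp(mid)) > 0) hi <- mid else lo <- mid
    }
    x <- solve_others(exp((lo + hi) / 2))
    s <- beta * exp(as.numeric(A %*% log(pmax(x, 1e-300))))
    out_free[comp] <- x
    spc[sub$species$name] <- s
  }

  resid_all <- vapply(seq_along(model$components), function(i) {
    got <- sum(model$stoich[, i] * spc)
    (got - totals[i]) / max(totals[i], 1e-300)
  }, 0)

  structure(list(free = out_free, species = spc,
                 solid_amounts = stats::setNames(
                   rep(0, nrow(model$solids)), model$solids$name),
                 converged = TRUE, residual = max(abs(resid_all), 0),
                 totals = totals, model = model),
            class = "speciation")
}

#' Per-component relative mass-balance residuals of a speciation state
#'
#' @param result a `speciation` object.
#' @return named numeric vector of `(computed - total) / total` per
#'   component (solids included).
#' @export
mass_balance_residuals <- function(result) {
  stopifnot(inherits(result, "speciation"))
  m <- result$model
  vapply(seq_along(m$components), function(i) {
    got <- sum(m$stoich[, i] * result$species)
    if (nrow(m$solids))
      got <- got + sum(m$solid_stoich[, i] * result$solid_amounts)
    (got - result$totals[i]) / max(result$totals[i], 1e-300)
  }, 0) |> stats::setNames(m$components)
}

#' Export a speciation state as a one-row data frame
#'
#' Used to build speciation tables along a titration (one row per point, one
#' column per free component / species / solid).
#'
#' @param result a `speciation` object.
#' @return a one-row data frame.
#' @export
as_speciation_row <- function(result) {
  stopifnot(inherits(result, "speciation"))
  out <- c(as.list(result$species),
           if (length(result$solid_amounts))
             as.list(stats::setNames(result$solid_amounts,
                                     paste0("solid_",
                                            names(result$solid_amounts)))),
           list(converged = result$converged))
  as.data.frame(out, check.names = FALSE)
}
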
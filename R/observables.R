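#' Titration schedules and dilution bookkeeping
#'
#' A titration schedule describes stepwise additions of a titrant solution
#' to an initial titrand solution.  Totals after the k-th addition follow
#' exact dilution bookkeeping,
#' \deqn{T_k = (V_0 c_0 + V_{add,k} c_{tit}) / (V_0 + V_{add,k}),}
#' with `V_add,k` the cumulative added volume.  Volumes are dm\eqn{^3}
#' internally; concentrations mol dm\eqn{^{-3}}.
#'
#' @param V0 initial titrand volume, dm\eqn{^3}.
#' @param c0 named vector of initial analytical concentrations per
#'   component.
#' @param c_titrant named vector of titrant analytical concentrations
#'   (components absent from the titrant may be omitted).
#' @param v_add vector of per-addition volumes, dm\eqn{^3} (not
#'   cumulative).  A point with `v = 0` (the initial state) is always
#'   prepended.
#' @return object of class `titration_schedule`.
#' @export
titration_schedule <- function(V0, c0, c_titrant, v_add) {
  stopifnot(V0 > 0, all(v_add > 0), !is.null(names(c0)))
  comps <- union(names(c0), names(c_titrant))
  c0f <- stats::setNames(rep(0, length(comps)), comps)
  ctf <- c0f
  c0f[names(c0)] <- c0
  ctf[names(c_titrant)] <- c_titrant
  structure(list(V0 = V0, c0 = c0f, c_titrant = ctf,
                 v_add = as.numeric(v_add),
                 v_cum = cumsum(as.numeric(v_add))),
            class = "titration_schedule")
}

#' @export
print.titration_schedule <- function(x, ...) {
  cat(sprintf("<titration_schedule> V0 = %.4g dm^3, %d additions (total %.4g dm^3)\n",
              x$V0, length(x$v_add), sum(x$v_add)))
  cat("  titrand:", paste(sprintf("%s = %.4g", names(x$c0), x$c0),
                          collapse = ", "), "\n")
  cat("  titrant:", paste(sprintf("%s = %.4g", names(x$c_titrant),
                                  x$c_titrant), collapse = ", "), "\n")
  invisible(x)
}

#' Total concentrations along a schedule
#'
#' @param schedule a [titration_schedule()].
#' @param overflow if `TRUE`, use the constant-volume overflow (perfusion)
#'   cell model of VP-ITC-class calorimeters: the cell volume stays `V0`,
#'   each injection displaces its own volume of averaged cell content, so
#'   totals follow \eqn{T_k = T_{k-1} e^{-dV/V_0} +
#'   c_{tit}(1 - e^{-dV/V_0})}.  Otherwise (default) volumes add.
#' @return matrix (points x components) of analytical concentrations; the
#'   first row is the initial state.
#' @export
schedule_totals <- function(schedule, overflow = FALSE) {
  stopifnot(inherits(schedule, "titration_schedule"))
  comps <- names(schedule$c0)
  npt <- length(schedule$v_add) + 1L
  out <- matrix(0, npt, length(comps), dimnames = list(NULL, comps))
  out[1L, ] <- schedule$c0
  if (!overflow) {
    for (k in seq_along(schedule$v_add)) {
      vc <- schedule$v_cum[k]
      out[k + 1L, ] <- (schedule$V0 * schedule$c0 + vc * schedule$c_titrant) /
        (schedule$V0 + vc)
    }
  } else {
    for (k in seq_along(schedule$v_add)) {
      f <- exp(-schedule$v_add[k] / schedule$V0)
      out[k + 1L, ] <- out[k, ] * f + schedule$c_titrant * (1 - f)
    }
  }
  out
}

# solve a model along a schedule with warm starts; returns list of
# speciation objects
speciate_schedule <- function(model, schedule, allow_solids = TRUE,
                              overflow = FALSE) {
  tot <- schedule_totals(schedule, overflow = overflow)
  prev <- NULL
  out <- vector("list", nrow(tot))
  for (i in seq_len(nrow(tot))) {
    r <- solve_speciation(model, tot[i, ], allow_solids = allow_solids,
                          start = prev)
    if (!r$converged)
      stop("speciation failed at titration point ", i)
    prev <- r$free
    out[[i]] <- r
  }
  out
}

#' Speciation table along a titration
#'
#' @inheritParams schedule_totals
#' @param model an [eq_model()].
#' @param allow_solids passed to [solve_speciation()].
#' @return data frame: point index, cumulative titrant volume, one column
#'   per species (and solid).
#' @export
speciation_table <- function(model, schedule, allow_solids = TRUE) {
  states <- speciate_schedule(model, schedule, allow_solids = allow_solids)
  rows <- do.call(rbind, lapply(states, as_speciation_row))
  cbind(data.frame(point = seq_along(states) - 1L,
                   v_titrant = c(0, schedule$v_cum)),
        rows)
}

#' Calibrate an ion-selective electrode
#'
#' Ordinary least-squares line of measured potential against
#' \eqn{\log_{10}} concentration of the standards.  The slope is fitted,
#' not fixed at the Nernstian 59.16 mV/decade, since real electrodes in
#' nonaqueous solvents are routinely sub-Nernstian.
#'
#' @param standards data frame with columns `c` (known concentration,
#'   mol dm\eqn{^{-3}}) and `E` (measured potential, mV); at least two
#'   distinct concentrations.
#' @return list with `E0` (intercept, mV) and `slope` (mV per decade).
#' @export
calibrate_ise <- function(standards) {
  stopifnot(is.data.frame(standards), all(c("c", "E") %in% names(standards)))
  if (length(unique(standards$c)) < 2)
    stop("need at least two distinct standard concentrations")
  fit <- stats::lm(E ~ I(log10(c)), data = standards)
  list(E0 = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]))
}

#' Simulate a potentiometric (ISE) titration
#'
#' Solves the speciation at every titration point and maps the free cation
#' concentration to electrode potential via the Nernst-type calibration
#' \eqn{E = E_0 + \mathrm{slope}\cdot\log_{10}[C^+]} and to
#' \eqn{\mathrm{pNa} = -\log_{10}[C^+]}.  The pNa series is continuous in
#' value across a precipitation onset (only its slope breaks).
#'
#' @inheritParams speciation_table
#' @param calibration list with `E0` (mV) and `slope` (mV/decade), e.g.
#'   from [calibrate_ise()].
#' @param ion component whose free concentration the electrode senses
#'   (default `"Na"`).
#' @return data frame: `point`, `v_titrant`, totals, `pNa`, `E_mV`,
#'   `regime` (`"solid"` when any solid is present).
#' @export
simulate_potentiometric <- function(schedule, model, calibration,
                                    ion = "Na", allow_solids = TRUE) {
  states <- speciate_schedule(model, schedule, allow_solids = allow_solids)
  free <- vapply(states, function(s) s$free[[ion]], 0)
  solid <- vapply(states, function(s) any(s$solid_amounts > 0), TRUE)
  tot <- schedule_totals(schedule)
  data.frame(point = seq_along(states) - 1L,
             v_titrant = c(0, schedule$v_cum),
             tot,
             pNa = -log10(free),
             E_mV = calibration$E0 + calibration$slope * log10(free),
             regime = ifelse(solid, "solid", "no_solid"),
             check.names = FALSE)
}

#' Simulate a conductometric titration
#'
#' Solution conductivity from molar ionic conductivities:
#' \eqn{\kappa = 10^{-3} \sum_i \lambda_i c_i} (S cm\eqn{^{-1}}, with
#' \eqn{\lambda} in S cm\eqn{^2} mol\eqn{^{-1}} and c in mol
#' dm\eqn{^{-3}}).  Ion pairs and other neutral species do not conduct, so
#' ion pairing lowers \eqn{\kappa} relative to a no-pairing model at the
#' same totals.  No Onsager-type concentration corrections are applied
#' (constant ionic strength assumption).
#'
#' @inheritParams speciation_table
#' @param params list with `lambda` (named molar conductivities for the
#'   conducting species) and `charged` (character vector naming every
#'   charged species in the model; each must have a `lambda` entry).
#' @return data frame with `point`, `v_titrant` and `kappa` (S
#'   cm\eqn{^{-1}}).
#' @export
simulate_conductometric <- function(schedule, model, params,
                                    allow_solids = TRUE) {
  stopifnot(is.list(params), !is.null(params$lambda))
  lam <- params$lambda
  charged <- params$charged %||% names(lam)
  missing_l <- setdiff(charged, names(lam))
  if (length(missing_l))
    stop("missing molar conductivity for charged species: ",
         paste(missing_l, collapse = ", "))
  if (any(unlist(lam) < 0)) stop("molar conductivities must be >= 0")
  unknown <- setdiff(names(lam), model$species$name)
  if (length(unknown))
    stop("conductivity given for species absent from the model: ",
         paste(unknown, collapse = ", "))
  lam <- unlist(lam)
  states <- speciate_schedule(model, schedule, allow_solids = allow_solids)
  kap <- vapply(states, function(s)
    1e-3 * sum(lam * s$species[names(lam)]), 0)
  data.frame(point = seq_along(states) - 1L,
             v_titrant = c(0, schedule$v_cum), kappa = kap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ITC injection series
#'
#' Per-injection heats from the change in moles of each complex in the
#' cell between consecutive equilibrium states,
#' \deqn{Q_k = V_0 \sum_j \Delta_r H^\circ_j\, \Delta c_j(k) + q_{dil},}
#' with totals diluted by the constant-volume overflow model of
#' VP-ITC-class instruments (see [schedule_totals()] with
#' `overflow = TRUE`) and a constant per-injection dilution-heat baseline
#' `q_dil`.  Enthalpies apply to the formation reactions of non-component
#' species (components carry zero).  By construction
#' \eqn{\sum_k (Q_k - q_{dil})} equals the enthalpy-content difference
#' between final and initial cell states.
#'
#' @inheritParams speciation_table
#' @param enthalpies list with `dH` (named vector, kJ mol\eqn{^{-1}}, per
#'   formation reaction / species), optional `q_dil_uJ` (baseline, µJ,
#'   default 0).
#' @return data frame with `point` (1..n injections), `v_titrant`, `Q_uJ`
#'   (heat per injection, µJ) and `Q_kJ_per_mol` (per mole of injectant).
#' @export
simulate_itc <- function(schedule, model, enthalpies, allow_solids = TRUE) {
  stopifnot(is.list(enthalpies), !is.null(enthalpies$dH))
  dH <- enthalpies$dH                       # kJ / mol
  q_dil <- enthalpies$q_dil_uJ %||% 0
  states <- speciate_schedule(model, schedule, allow_solids = allow_solids,
                              overflow = TRUE)
  conc <- conc_matrix(states)
  keep <- intersect(colnames(conc), names(dH))
  # enthalpy content of the cell, J: (mol dm^-3 . kJ mol^-1) . dm^3 . 1e3
  H <- if (length(keep))
    as.numeric(conc[, keep, drop = FALSE] %*% unlist(dH[keep])) *
      schedule$V0 * 1e3
  else rep(0, nrow(conc))
  Q_J <- diff(H) + q_dil * 1e-6
  mol_inj <- schedule$c_titrant[which.max(schedule$c_titrant)] *
    schedule$v_add
  data.frame(point = seq_along(schedule$v_add),
             v_titrant = schedule$v_cum,
             Q_uJ = Q_J * 1e6,
             Q_kJ_per_mol = ifelse(mol_inj > 0, Q_J * 1e-3 / mol_inj, NA))
}

#' Simulate a multiwavelength UV titration
#'
#' Beer-Lambert additivity: \eqn{A(\lambda) = l \sum_i
#' \varepsilon_i(\lambda) c_i}.  Isosbestic points emerge automatically for
#' two-state systems whose molar absorptivity curves cross.
#'
#' @inheritParams speciation_table
#' @param spectra list with `wavelength` (grid, nm), `epsilon` (matrix
#'   wavelength x species, mol\eqn{^{-1}} dm\eqn{^3} cm\eqn{^{-1}}), `path`
#'   (cm, default 1).
#' @return list with `wavelength`, `absorbance` (points x wavelengths
#'   matrix) and `v_titrant`.
#' @export
simulate_uv <- function(schedule, model, spectra, allow_solids = TRUE) {
  stopifnot(is.list(spectra), !is.null(spectra$epsilon))
  eps <- spectra$epsilon
  if (any(eps < 0)) stop("molar absorptivities must be >= 0")
  l <- spectra$path %||% 1
  states <- speciate_schedule(model, schedule, allow_solids = allow_solids)
  conc <- conc_matrix(states)
  absent <- setdiff(colnames(eps), colnames(conc))
  if (length(absent)) stop("spectra given for unknown species: ",
                           paste(absent, collapse = ", "))
  A <- l * conc[, colnames(eps), drop = FALSE] %*% t(eps)
  list(wavelength = spectra$wavelength,
       absorbance = A,
       v_titrant = c(0, schedule$v_cum))
}

#' Simulate a fast-exchange NMR titration
#'
#' Population-weighted average chemical shift over the fast-exchanging
#' species that contain the observed nucleus pool:
#' \deqn{\delta_{obs} = \sum_i f_i \delta_i, \qquad
#'       f_i = \nu_{i,pool} c_i / \sum_i \nu_{i,pool} c_i,}
#' restricted to species in the fast pool.  Species behind slow equilibria
#' are excluded from the average (experimentally they give separate
#' signals) and are returned as separate tracks with populations.  The
#' titrand-approximation mode of practice — treating the cation-host
#' complex CH\eqn{^+} as the sole initial host species — is obtained
#' simply by building the model with CH\eqn{^+} as a component.
#'
#' @inheritParams speciation_table
#' @param shifts list with `delta` (named shifts, ppm, per species in the
#'   fast pool), optional `slow` (character vector of species to exclude).
#' @param pool component defining the observed nucleus pool (e.g. the
#'   host).
#' @return data frame with `point`, `v_titrant`, `delta_obs` and, for each
#'   slow species, a `pop_<name>` population column.
#' @export
simulate_nmr_fast <- function(schedule, model, shifts, pool,
                              allow_solids = TRUE) {
  stopifnot(is.list(shifts), !is.null(shifts$delta))
  delta <- unlist(shifts$delta)
  slow <- shifts$slow %||% character(0)
  ip <- match(pool, model$components)
  if (is.na(ip)) stop("unknown pool component: ", pool)
  carriers <- model$species$name[model$stoich[, ip] != 0]
  fast <- setdiff(carriers, slow)
  miss <- setdiff(fast, names(delta))
  if (length(miss))
    stop("missing chemical shift for fast species: ",
         paste(miss, collapse = ", "))
  states <- speciate_schedule(model, schedule, allow_solids = allow_solids)
  nu <- stats::setNames(model$stoich[, ip], model$species$name)
  rows <- lapply(states, function(s) {
    wf <- nu[fast] * s$species[fast]
    if (sum(wf) <= 0) stop("no nucleus pool present in the fast species")
    f <- wf / sum(wf)
    d <- sum(f * delta[fast])
    pops <- if (length(slow)) {
      tot <- sum(nu[carriers] * s$species[carriers])
      stats::setNames(nu[slow] * s$species[slow] / tot, paste0("pop_", slow))
    } else NULL
    c(delta_obs = d, pops)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(point = seq_along(states) - 1L,
                   v_titrant = c(0, schedule$v_cum)), out)
}

# points x species concentration matrix from a list of speciation states
conc_matrix <- function(states) {
  nm <- names(states[[1]]$species)
  m <- matrix(unlist(lapply(states, `[[`, "species")),
              nrow = length(states), byrow = TRUE)
  colnames(m) <- nm
  m
}
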
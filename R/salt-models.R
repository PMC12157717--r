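#' Closed-form salt solubility, ion-pairing and precipitation models
#'
#' These functions implement the algebra of a sparingly soluble 1:1 salt CA
#' in a nonaqueous solvent, where three coupled processes operate: the
#' dissolution equilibrium with solubility product
#' \eqn{K_s = [C^+][A^-]} at saturation, free-ion pairing
#' \eqn{K_{IP} = [CA]/([C^+][A^-])}, and (for dihydrogen phosphate type
#' anions) anion dimerization \eqn{K_{dim} = [A_2^{2-}]/[A^-]^2}.  The
#' generic speciation solver ([solve_speciation()]) is the single source of
#' truth these closed forms are verified against.
#'
#' @name salt_models
NULL

#' Total solubility of the pure salt
#'
#' In a saturated solution of the pure salt (no common ion added) the total
#' solubility is \eqn{s = \sqrt{K_s} + K_s K_{IP}}: the free-cation term
#' plus the (saturation-constant) ion-pair concentration.
#'
#' @param Ks solubility product, mol\eqn{^2} dm\eqn{^{-6}} (> 0).
#' @param K_IP ion-pair association constant, mol\eqn{^{-1}} dm\eqn{^3}
#'   (>= 0).
#' @return total solubility, mol dm\eqn{^{-3}}.
#' @export
solubility_pure <- function(Ks, K_IP) {
  stopifnot(is.numeric(Ks), is.numeric(K_IP))
  if (any(Ks <= 0)) stop("Ks must be positive")
  if (any(K_IP < 0)) stop("K_IP must be >= 0")
  sqrt(Ks) + Ks * K_IP
}

#' Total solubility with an added common anion
#'
#' Total solubility of the salt in a solution containing the common anion at
#' analytical concentration `c_coion` (e.g. NaCl in the presence of TEACl):
#' \eqn{s = 0.5\,(2 K_s K_{IP} - c + \sqrt{c^2 + 4 K_s})}.  At `c_coion = 0`
#' this reduces exactly to [solubility_pure()]; as `c_coion` grows the ionic
#' contribution falls towards the ion-pair floor \eqn{K_s K_{IP}}.
#'
#' @inheritParams solubility_pure
#' @param c_coion analytical common-anion concentration, mol dm\eqn{^{-3}}.
#' @export
solubility_with_common_anion <- function(Ks, K_IP, c_coion) {
  if (any(Ks <= 0)) stop("Ks must be positive")
  if (any(K_IP < 0) || any(c_coion < 0)) stop("K_IP and c_coion must be >= 0")
  0.5 * (2 * Ks * K_IP - c_coion + sqrt(c_coion^2 + 4 * Ks))
}

#' Free cation concentration before the precipitation onset
#'
#' Solves the no-solid mass balances
#' \eqn{c_C = [C^+] + [CA]}, \eqn{c_A = [A^-] + [CA]} with
#' \eqn{[CA] = K_{IP}[C^+][A^-]} for the free cation.  With
#' \eqn{\Delta = c_C - c_A} the quadratic
#' \eqn{K_{IP} x^2 + (1 - K_{IP}\Delta)x - c_C = 0} gives the physical root.
#' The \eqn{K_{IP} \to 0} limit (free = total) is taken analytically when
#' \eqn{K_{IP}(c_C + c_A)} is negligible, avoiding catastrophic
#' cancellation.
#'
#' @param c_cation,c_anion analytical concentrations, mol dm\eqn{^{-3}}.
#' @param K_IP ion-pair association constant (>= 0).
#' @return free cation concentration, mol dm\eqn{^{-3}}.
#' @export
free_cation_no_solid <- function(c_cation, c_anion, K_IP) {
  if (any(K_IP < 0)) stop("K_IP must be >= 0")
  if (any(c_cation < 0) || any(c_anion < 0)) stop("totals must be >= 0")
  lim <- K_IP * (c_cation + c_anion) < 1e-10
  d <- c_cation - c_anion
  b <- 1 - K_IP * d
  # stable quadratic root: x = 2 c_C / (b + sqrt(b^2 + 4 K_IP c_C))
  x <- 2 * c_cation / (b + sqrt(b^2 + 4 * K_IP * c_cation))
  ifelse(lim, c_cation, x)
}

#' Free cation concentration with the solid salt present
#'
#' With the precipitate present, the mass balances collapse to
#' \eqn{c_C - c_A = [C^+] - [A^-]} and the saturation condition
#' \eqn{[C^+][A^-] = K_s} gives
#' \eqn{[C^+] = 0.5(\Delta + \sqrt{\Delta^2 + 4 K_s})},
#' \eqn{\Delta = c_C - c_A}.
#'
#' @inheritParams free_cation_no_solid
#' @param Ks solubility product (> 0).
#' @export
free_cation_with_solid <- function(c_cation, c_anion, Ks) {
  if (any(Ks <= 0)) stop("Ks must be positive")
  d <- c_cation - c_anion
  0.5 * (d + sqrt(d^2 + 4 * Ks))
}

#' Decide whether the solid phase is present at given totals
#'
#' Computes the hypothetical no-solid state via [free_cation_no_solid()] and
#' declares the solid present iff its ion product strictly exceeds
#' \eqn{K_s} (equivalently iff the hypothetical ion-pair concentration
#' exceeds \eqn{K_s K_{IP}}); exact equality classifies as `"no_solid"`.
#'
#' @inheritParams free_cation_no_solid
#' @param params list or vector with elements `Ks`, `K_IP`.
#' @return `"no_solid"` or `"solid"`.
#' @export
regime_test <- function(c_cation, c_anion, params) {
  Ks <- params[["Ks"]]; K_IP <- params[["K_IP"]]
  x <- free_cation_no_solid(c_cation, c_anion, K_IP)
  y <- x - (c_cation - c_anion)
  ifelse(x * y > Ks, "solid", "no_solid")
}

#' Solubility of a dimerizing-anion salt with added common anion
#'
#' For a salt whose anion dimerizes (2 A\eqn{^-} \eqn{\rightleftharpoons}
#' A\eqn{_2^{2-}}), the total solubility s in the presence of the common
#' anion at analytical concentration `c` satisfies the cubic
#' \deqn{s^3 + s^2 (c - 3b) + s\,(3b^2 - 2bc - K_s) +
#'       (c b^2 - b^3 + K_s b - 2 K_{dim} K_s^2) = 0, \quad b = K_s K_{IP},}
#' obtained by eliminating the free concentrations from the saturation
#' condition and the cation/anion mass balances
#' (s = \eqn{[A^-] + 2[A_2^{2-}] + [CA] - c}).  The physical root is found
#' by bracketing on a log grid and must imply an all-positive speciation
#' (in particular \eqn{s > K_s K_{IP}} so that the free-cation term is
#' positive).  At `K_dim = 0`, `c = 0` the result equals
#' [solubility_pure()].
#'
#' @inheritParams solubility_pure
#' @param K_dim anion dimerization constant, mol\eqn{^{-1}} dm\eqn{^3}
#'   (>= 0).
#' @param c_coion analytical common-anion (e.g. TBA salt) concentration.
#' @export
phosphate_solubility_implicit <- function(Ks, K_IP, K_dim, c_coion) {
  if (Ks <= 0 || K_IP < 0 || K_dim < 0 || c_coion < 0)
    stop("invalid parameters")
  b <- Ks * K_IP
  # substituting u = s - b (the free-cation concentration) gives the
  # numerically well-conditioned equivalent cubic
  #   u^3 + c u^2 - Ks u - 2 K_dim Ks^2 = 0
  # (the cubic in s itself suffers severe cancellation when the ion-pair
  # term dominates the solubility)
  poly_u <- function(u) u^3 + c_coion * u^2 - Ks * u - 2 * K_dim * Ks^2
  grid <- 10^seq(-17, 0.5, length.out = 526)
  v <- vapply(grid, poly_u, 0)
  sgn <- sign(v)
  idx <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & v[-1] != v[-length(v)])
  if (!length(idx))
    stop("no positive root consistent with the mass balance")
  lo <- grid[idx[1]]; hi <- grid[idx[1] + 1]
  u <- stats::uniroot(poly_u, c(lo, hi),
                      tol = .Machine$double.eps^0.95)$root
  # one Newton polish for full double accuracy
  du <- poly_u(u) / (3 * u^2 + 2 * c_coion * u - Ks)
  if (is.finite(du) && abs(du) < 0.5 * u) u <- u - du
  b + u
}

#' Free cation concentration in the saturated pure dimerizing-anion salt
#'
#' For the pure saturated salt with anion dimerization, the free cation
#' concentration n satisfies the degree-six polynomial
#' \deqn{64 K_{dim}^2 n^6 - 256 K_s^2 K_{dim}^3 n^3
#'       - 64 K_s^2 K_{dim}^2 n^2 + 256 K_s^4 K_{dim}^4 = 0,}
#' which is algebraically equivalent (for the physical branch) to the cubic
#' \eqn{n^3 - K_s n - 2 K_{dim} K_s^2 = 0} expressing
#' \eqn{n = [A^-] + 2[A_2^{2-}]} with \eqn{[A^-] = K_s/n}.  The root is
#' bracketed numerically; as \eqn{K_{dim} \to 0} it tends to
#' \eqn{\sqrt{K_s}}.
#'
#' @inheritParams phosphate_solubility_implicit
#' @return free cation concentration at saturation, mol dm\eqn{^{-3}}.
#' @export
phosphate_free_cation_saturated <- function(Ks, K_dim) {
  if (Ks <= 0 || K_dim <= 0) stop("Ks and K_dim must be positive")
  f <- function(n)
    64 * K_dim^2 * n^6 - 256 * Ks^2 * K_dim^3 * n^3 -
      64 * Ks^2 * K_dim^2 * n^2 + 256 * Ks^4 * K_dim^4
  # all sign-change roots on a log grid over [1e-16, 1] ...
  grid <- 10^seq(-16, 0, length.out = 801)
  v <- vapply(grid, f, 0)
  idx <- which(sign(v[-1]) * sign(v[-length(v)]) <= 0 & v[-1] != v[-length(v)])
  if (!length(idx)) stop("root bracketing failed")
  roots <- vapply(idx, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]),
                   tol = .Machine$double.eps^0.9)$root, 0)
  # ... filtered by the physical mass balance n = Ks/n + 2 K_dim Ks^2 / n^2
  # (the sextic acquires spurious roots when squared during its derivation)
  mb <- abs(roots - Ks / roots - 2 * K_dim * Ks^2 / roots^2) / roots
  roots <- roots[mb < 1e-4]
  if (!length(roots)) stop("no root consistent with the mass balance")
  min(roots)
}

#' Ion-pairing constant from the saturated-solution composition
#'
#' At saturation the ion-pair concentration is \eqn{s - [C^+]_{sat}} and its
#' constituents' product is \eqn{K_s}, so
#' \eqn{K_{IP} = (s - [C^+]_{sat}) / K_s}.
#'
#' @param s total solubility, mol dm\eqn{^{-3}}.
#' @param free_cation_sat free cation concentration at saturation.
#' @param Ks solubility product.
#' @export
kip_from_saturated <- function(s, free_cation_sat, Ks) {
  if (Ks <= 0) stop("Ks must be positive")
  if (free_cation_sat < 0) stop("free cation concentration must be >= 0")
  if (s < free_cation_sat)
    stop("s < free cation at saturation would imply a negative ion-pair ",
         "concentration")
  (s - free_cation_sat) / Ks
}

#' Total solubility from a flame-AES reading
#'
#' Converts a flame atomic-emission reading on the worked-up residue of a
#' saturated-solution aliquot back to the solubility in the original
#' solvent.  The aliquot (volume `aliquot_volume_mL`) is evaporated, the
#' residue dissolved in `diluent_mass_g` of water, and the solution diluted
#' `dilution_factor`-fold into the calibration range; `ppm_measured` is the
#' analyte mass fraction (mg analyte per kg of final solution, diluent mass
#' taken as the solution mass).
#'
#' @param ppm_measured instrument reading, mg kg\eqn{^{-1}} (>= 0).
#' @param dilution_factor fold dilution applied before measurement.
#' @param diluent_mass_g mass of water used to take up the residue, g.
#' @param aliquot_volume_mL volume of saturated solution evaporated, mL.
#' @param molar_mass molar mass of the analyte element/species, g
#'   mol\eqn{^{-1}}.
#' @return solubility, mol dm\eqn{^{-3}}.
#' @export
aes_solubility <- function(ppm_measured, dilution_factor, diluent_mass_g,
                           aliquot_volume_mL, molar_mass) {
  if (ppm_measured < 0) stop("ppm must be >= 0")
  if (dilution_factor <= 0 || diluent_mass_g <= 0 ||
      aliquot_volume_mL <= 0 || molar_mass <= 0)
    stop("all inputs must be positive")
  mg <- ppm_measured * dilution_factor * 1e-3 * diluent_mass_g # mg analyte
  mol <- mg * 1e-3 / molar_mass
  mol / (aliquot_volume_mL * 1e-3)                             # mol dm^-3
}

#' Solubility product from total solubility and the pairing constant
#'
#' Inverts the pure-saturated-solution relation
#' \eqn{s = \sqrt{K_s} + K_s K_{IP}} for \eqn{K_s}: with
#' \eqn{x = \sqrt{K_s}}, the positive root of
#' \eqn{K_{IP} x^2 + x - s = 0} gives
#' \eqn{K_s = x^2}.
#'
#' @param s total solubility, mol dm\eqn{^{-3}} (> 0).
#' @param K_IP ion-pair association constant (>= 0).
#' @return solubility product, mol\eqn{^2} dm\eqn{^{-6}}.
#' @export
ks_from_solubility <- function(s, K_IP) {
  if (s <= 0) stop("s must be positive")
  if (K_IP < 0) stop("K_IP must be >= 0")
  if (K_IP == 0) return(s^2)
  x <- (-1 + sqrt(1 + 4 * K_IP * s)) / (2 * K_IP)
  x^2
}
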
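#' Noise specification for synthetic datasets
#'
#' Gaussian noise levels per technique, with the RNG seed recorded so any
#' dataset can be regenerated bit-identically.  Defaults reflect typical
#' instrument precisions: 0.01 pNa units, 0.2\% relative conductivity,
#' 1 µJ per ITC injection, 0.002 absorbance units, 0.002 ppm chemical
#' shift, 1\% relative solubility.
#'
#' @param pNa,kappa_rel,itc_uJ,absorbance,delta_ppm,solubility_rel sigma
#'   per technique (see above; `*_rel` are relative).
#' @param seed integer RNG seed.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(pNa = 0.01, kappa_rel = 0.002, itc_uJ = 1,
                       absorbance = 0.002, delta_ppm = 0.002,
                       solubility_rel = 0.01, seed = 1L) {
  sig <- list(pNa = pNa, kappa_rel = kappa_rel, itc_uJ = itc_uJ,
              absorbance = absorbance, delta_ppm = delta_ppm,
              solubility_rel = solubility_rel)
  if (any(unlist(sig) < 0)) stop("noise sigmas must be >= 0")
  structure(c(sig, list(seed = as.integer(seed))), class = "noise_spec")
}

#' Zero-noise specification
#' @export
#' @rdname noise_spec
no_noise <- function() noise_spec(0, 0, 0, 0, 0, 0, seed = 0L)

# host-system constant bundle from a preset
preset_system <- function(preset) {
  list(logK_CH = preset$logK_CH, logK_HA = preset$logK_HA,
       logK_ternary = preset$logK_ternary, K_IP = preset$K_IP,
       K_dim = preset$K_dim)
}

# salt model (cation + anion + pair + optional dimer + solid)
salt_model <- function(preset, solid = TRUE, extra_components = NULL) {
  sp <- list(list(name = "CA", stoich = c(C = 1, A = 1),
                  log_beta = log10(preset$K_IP)))
  if (preset$K_dim > 0)
    sp <- c(sp, list(list(name = "A2", stoich = c(A = 2),
                          log_beta = log10(preset$K_dim))))
  so <- if (solid)
    list(list(name = "CA_s", stoich = c(C = 1, A = 1),
              log_Ks = log10(preset$Ks)))
  eq_model(c("C", "A", extra_components), species = sp, solids = so)
}

# reference UV spectra of the host species: hyperchromic series (each
# complexation step raises the band, as observed for aryl hosts whose
# titrations show hyperchromic shifts), with small band shifts
default_uv_spectra <- function(wavelength = seq(250, 300, by = 2)) {
  band <- function(a, mu, w) a * exp(-((wavelength - mu) / w)^2)
  eps <- cbind(H = band(8000, 270, 15),
               CH = band(9200, 269, 15),
               HA = band(8800, 271, 15),
               CHA = band(11000, 268, 15))
  list(wavelength = wavelength, epsilon = eps, path = 1)
}

default_nmr_shifts <- function() {
  # urea NH region; ternary complex strongly downfield
  list(delta = list(H = 6.5, CH = 7.0, HA = 7.8, CHA = 8.5),
       slow = character(0))
}

#' Generate a synthetic experiment with known ground truth
#'
#' Runs the appropriate forward model for the requested technique under a
#' scenario preset and adds seeded Gaussian noise.  With zero noise the
#' output reproduces the forward model exactly.  The returned dataset
#' carries everything a fitter needs (`schedule`, `observed`,
#' `obs_params`, the generating `model` where relevant) plus the full
#' ground truth and generator settings in `truth` / `meta`, so any
#' dataset can be regenerated bit-identically from its metadata.
#'
#' Techniques and their default designs (all config-overridable through
#' `schedule` / technique options):
#' \describe{
#'   \item{`"solubility"`}{saturated-solution series vs. common-ion
#'     concentration (methods A / E input); observed `s` at `c_levels`.}
#'   \item{`"potentiometric"`}{constant-ionic-strength pNa titration of
#'     the cation salt with the common anion crossing the precipitation
#'     onset (methods B / F input).}
#'   \item{`"conductometric"`}{ion-pairing titration with spectator
#'     electrolyte ions (method C input).}
#'   \item{`"itc"`}{injection-heat series; `mode = "salt"` reproduces the
#'     ion-pairing design (method D), `mode = "host"` the ternary-complex
#'     titration of the cation-preloaded host.}
#'   \item{`"uv"`}{multiwavelength absorbance titration of the
#'     equimolar host + cation titrand with the anion (full-model
#'     generated).}
#'   \item{`"nmr_fast"`}{fast-exchange shift series for the successive
#'     anion binding to the preformed cation-host complex.}
#' }
#'
#' @param technique one of the names above.
#' @param preset a [scenario_preset()] (or its name).
#' @param schedule optional [titration_schedule()] overriding the default
#'   design.
#' @param noise a [noise_spec()]; default [no_noise()].
#' @param mode for `"itc"`: `"salt"` or `"host"`.
#' @param c_levels for `"solubility"`: common-ion analytical
#'   concentrations.
#' @return object of class `titration_dataset`.
#' @export
generate <- function(technique = c("solubility", "potentiometric",
                                   "conductometric", "itc", "uv",
                                   "nmr_fast"),
                     preset = "NaCl", schedule = NULL, noise = no_noise(),
                     mode = c("salt", "host"),
                     c_levels = c(0, 1e-4, 2e-4, 3e-4, 6e-4, 1e-3)) {
  technique <- match.arg(technique)
  mode <- match.arg(mode)
  if (is.character(preset)) preset <- scenario_preset(preset, quiet = TRUE)
  stopifnot(inherits(noise, "noise_spec"))
  set.seed(noise$seed)
  sys <- preset_system(preset)

  meta <- list(technique = technique, preset = preset$name,
               noise = unclass(noise), package = "suprafit",
               version = as.character(utils::packageVersion("suprafit")))

  ds <- switch(technique,
    solubility = {
      s <- if (preset$K_dim > 0)
        vapply(c_levels, function(cc) phosphate_solubility_implicit(
          preset$Ks, preset$K_IP, preset$K_dim, cc), 0)
      else solubility_with_common_anion(preset$Ks, preset$K_IP, c_levels)
      sobs <- s * (1 + stats::rnorm(length(s), 0, noise$solubility_rel))
      list(observed = data.frame(c_coion = c_levels, s = sobs),
           obs_params = list(), schedule = NULL, model = NULL)
    },
    potentiometric = {
      sch <- schedule %||% titration_schedule(
        V0 = 25e-3, c0 = c(C = 1e-4, A = 0),
        c_titrant = c(C = 0, A = 1e-2),
        v_add = c(rep(5e-6, 10), rep(2.5e-5, 20)))
      model <- salt_model(preset)
      calib <- list(E0 = 0, slope = 59.2)
      sim <- simulate_potentiometric(sch, model, calib, ion = "C")
      sim$pNa <- sim$pNa + stats::rnorm(nrow(sim), 0, noise$pNa)
      sim$E_mV <- calib$E0 - calib$slope * sim$pNa
      list(observed = sim, obs_params = list(calibration = calib),
           schedule = sch, model = model)
    },
    conductometric = {
      sch <- schedule %||% titration_schedule(
        V0 = 20e-3, c0 = c(C = 1e-4, P = 1e-4, T = 0, A = 0),
        c_titrant = c(C = 0, P = 0, T = 1e-3, A = 1e-3),
        v_add = rep(2.4e-4, 15))
      model <- salt_model(preset, solid = FALSE,
                          extra_components = c("P", "T"))
      lam <- list(C = 76.9, P = 103.7, T = 61.4, A = 58)
      par <- list(lambda = lam, charged = c("C", "P", "T", "A"))
      sim <- simulate_conductometric(sch, model, par)
      sim$kappa <- sim$kappa *
        (1 + stats::rnorm(nrow(sim), 0, noise$kappa_rel))
      list(observed = sim, obs_params = par, schedule = sch, model = model)
    },
    itc = {
      if (mode == "salt") {
        sch <- schedule %||% titration_schedule(
          V0 = 1.43e-3, c0 = c(C = 2e-4, A = 0),
          c_titrant = c(C = 0, A = 3e-3), v_add = rep(1e-5, 20))
        model <- salt_model(preset, solid = FALSE)
        enth <- list(dH = list(CA = preset$dH$CA))
        if (preset$K_dim > 0) enth$dH$A2 <- -5
        sim <- simulate_itc(sch, model, enth)
      } else {
        sch <- schedule %||% titration_schedule(
          V0 = 1.43e-3, c0 = c(H = 2e-4, C = 2e-4, A = 0),
          c_titrant = c(H = 0, C = 0, A = 3.8e-3), v_add = rep(1e-5, 20))
        model <- ladder_model("M3", sys)
        enth <- list(dH = list(CH = preset$dH$CH, HA = preset$dH$HA,
                               CHA = preset$dH$CH + preset$dH$CHA,
                               CA = preset$dH$CA))
        sim <- simulate_itc(sch, model, enth)
      }
      sim$Q_uJ <- sim$Q_uJ + stats::rnorm(nrow(sim), 0, noise$itc_uJ)
      # frozen enthalpies exclude the reaction under study
      frozen <- enth
      frozen$dH[[if (mode == "salt") "CA" else "CHA"]] <- NULL
      list(observed = sim, obs_params = list(enthalpies = frozen),
           schedule = sch, model = model)
    },
    uv = {
      # titrant strengths follow the published designs: ~5 mM for the
      # chloride system, 0.1 M for hydrogen sulfate (weaker binding needs
      # higher equivalents to reach saturation)
      sch <- schedule %||% switch(preset$name,
        NaHSO4 = titration_schedule(
          V0 = 2.2e-3, c0 = c(H = 2e-4, C = 2e-4, A = 0),
          c_titrant = c(H = 0, C = 0, A = 0.1), v_add = rep(5e-6, 20)),
        titration_schedule(
          V0 = 2.2e-3, c0 = c(H = 2e-4, C = 2e-4, A = 0),
          c_titrant = c(H = 0, C = 0, A = 5e-3), v_add = rep(1.5e-5, 20)))
      model <- ladder_model("M3", sys)
      spectra <- default_uv_spectra()
      sim <- simulate_uv(sch, model, spectra)
      A <- sim$absorbance +
        stats::rnorm(length(sim$absorbance), 0, noise$absorbance)
      frozen <- spectra
      frozen$epsilon <- frozen$epsilon[, c("H", "CH", "HA"), drop = FALSE]
      list(observed = list(absorbance = A, wavelength = spectra$wavelength,
                           v_titrant = sim$v_titrant),
           obs_params = list(spectra = frozen),
           schedule = sch, model = model)
    },
    nmr_fast = {
      sch <- schedule %||% switch(preset$name,
        NaHSO4 = titration_schedule(
          V0 = 5e-4, c0 = c(H = 4e-4, C = 4e-4, A = 0),
          c_titrant = c(H = 0, C = 0, A = 0.37), v_add = rep(2e-6, 12)),
        titration_schedule(
          V0 = 5e-4, c0 = c(H = 2e-4, C = 2e-4, A = 0),
          c_titrant = c(H = 0, C = 0, A = 7e-3), v_add = rep(1e-5, 12)))
      shifts <- default_nmr_shifts()
      # generated under the titrand approximation actually used for these
      # systems: all host preformed as CH+, successive binding fast
      m1 <- ladder_model("M1", sys)
      sch1 <- map_schedule_m1(sch)
      sim <- simulate_nmr_fast(sch1, m1, shifts, pool = "CH")
      sim$delta_obs <- sim$delta_obs +
        stats::rnorm(nrow(sim), 0, noise$delta_ppm)
      frozen <- list(delta = shifts$delta[c("H", "CH", "HA")],
                     slow = shifts$slow)
      list(observed = sim, obs_params = list(shifts = frozen),
           schedule = sch, model = m1)
    })

  structure(c(ds, list(technique = technique, truth = c(sys,
                       list(Ks = preset$Ks, K_IP = preset$K_IP,
                            K_dim = preset$K_dim, s = preset$s,
                            dH = preset$dH)),
                       meta = meta)),
            class = "titration_dataset")
}

#' @export
print.titration_dataset <- function(x, ...) {
  n <- if (is.data.frame(x$observed)) nrow(x$observed)
       else nrow(x$observed$absorbance)
  cat(sprintf("<titration_dataset> technique = %s, preset = %s, %d points\n",
              x$technique, x$meta$preset, n))
  cat(sprintf("  noise seed = %d\n", x$meta$noise$seed))
  invisible(x)
}

#' Write / read a synthetic dataset as CSV + JSON sidecar
#'
#' `write_dataset` stores the observed table as CSV (spectra as a wide
#' matrix with a wavelength header) and all generator metadata, ground
#' truth and schedule information as a JSON sidecar
#' (`<prefix>_meta.json`), sufficient to regenerate the dataset
#' bit-identically.  `read_dataset` restores the pair.
#'
#' @param dataset a `titration_dataset`.
#' @param prefix output path prefix.
#' @return `write_dataset`: invisibly the two file paths;
#'   `read_dataset`: the restored dataset.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "titration_dataset"))
  csv <- paste0(prefix, ".csv")
  if (dataset$technique == "uv") {
    tab <- as.data.frame(dataset$observed$absorbance)
    names(tab) <- paste0("A_", dataset$observed$wavelength)
    tab <- cbind(point = seq_len(nrow(tab)) - 1L,
                 v_titrant = dataset$observed$v_titrant, tab)
  } else tab <- dataset$observed
  utils::write.csv(tab, csv, row.names = FALSE)
  meta <- paste0(prefix, "_meta.json")
  op <- dataset$obs_params
  if (!is.null(op$spectra$epsilon))  # keep species names through JSON
    op$spectra$epsilon <- as.data.frame(op$spectra$epsilon)
  sch <- if (!is.null(dataset$schedule)) {
    s <- unclass(dataset$schedule)
    s$c0 <- as.list(s$c0)                 # keep component names in JSON
    s$c_titrant <- as.list(s$c_titrant)
    s
  }
  side <- list(technique = dataset$technique, meta = dataset$meta,
               truth = dataset$truth, schedule = sch,
               obs_params = op)
  jsonlite::write_json(side, meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  tab <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  side <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  sched <- if (!is.null(side$schedule))
    titration_schedule(side$schedule$V0,
                       unlist(side$schedule$c0),
                       unlist(side$schedule$c_titrant),
                       side$schedule$v_add)
  if (!is.null(side$obs_params$spectra$epsilon))
    side$obs_params$spectra$epsilon <-
      as.matrix(side$obs_params$spectra$epsilon)
  observed <- if (side$technique == "uv") {
    wl <- as.numeric(sub("^A_", "", grep("^A_", names(tab), value = TRUE)))
    list(absorbance = as.matrix(tab[, grep("^A_", names(tab))]),
         wavelength = wl, v_titrant = tab$v_titrant)
  } else tab
  structure(list(observed = observed, schedule = sched,
                 obs_params = side$obs_params,
                 technique = side$technique,
                 truth = side$truth, meta = side$meta,
                 model = NULL),
            class = "titration_dataset")
}

#' Adapt a potentiometric dataset to the method B/F fitter schema
#'
#' @param dataset a `titration_dataset` with technique
#'   `"potentiometric"`.
#' @return data frame with columns `c_cation`, `c_anion`, `pNa`.
#' @export
potentiometric_fit_data <- function(dataset) {
  stopifnot(dataset$technique == "potentiometric")
  obs <- dataset$observed
  data.frame(c_cation = obs$C, c_anion = obs$A, pNa = obs$pNa)
}
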
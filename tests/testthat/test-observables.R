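sched_demo <- function() {
  titration_schedule(V0 = 2e-3, c0 = c(M = 1e-3, L = 0),
                     c_titrant = c(M = 0, L = 5e-3),
                     v_add = rep(5e-5, 10))
}

test_that("schedule totals agree with an independent mole ledger", {
  sch <- sched_demo()
  tot <- schedule_totals(sch)
  moles_M <- sch$V0 * 1e-3
  for (k in 0:10) {
    v <- if (k == 0) 0 else sch$v_cum[k]
    expect_equal(unname(tot[k + 1, "M"]), moles_M / (sch$V0 + v))
    expect_equal(unname(tot[k + 1, "L"]), 5e-3 * v / (sch$V0 + v))
  }
  # overflow model conserves nothing but tends to the titrant composition
  tov <- schedule_totals(sch, overflow = TRUE)
  expect_true(all(diff(tov[, "L"]) > 0))
  expect_lt(tov[11, "M"], tot[11, "M"])
})

test_that("potentiometric forward model applies the Nernst-type calibration", {
  m <- eq_model("Na")
  sch <- titration_schedule(V0 = 1e-3, c0 = c(Na = 1e-3),
                            c_titrant = c(Na = 1e-3), v_add = 1e-9)
  sim <- simulate_potentiometric(sch, m, list(E0 = 0, slope = 59.2),
                                 ion = "Na")
  expect_equal(sim$pNa[1], 3)
  expect_equal(sim$E_mV[1], -177.6, tolerance = 1e-10)
})

test_that("precipitation onset appears at the first solid-positive point", {
  preset <- scenario_preset("NaCl", quiet = TRUE)
  ds <- generate("potentiometric", preset)
  obs <- ds$observed
  onset <- which(obs$regime == "solid")[1]
  reg <- regime_test(obs$C, obs$A, list(Ks = preset$Ks,
                                        K_IP = preset$K_IP))
  expect_equal(onset, which(reg == "solid")[1])
  # pNa is continuous in value across the onset (no jump)
  expect_lt(abs(obs$pNa[onset] - obs$pNa[onset - 1]), 0.2)
})

test_that("dilution bookkeeping is path independent at matching volumes", {
  m <- model_1to1(5)
  s1 <- titration_schedule(V0 = 2e-3, c0 = c(M = 1e-3, L = 0),
                           c_titrant = c(M = 0, L = 5e-3),
                           v_add = rep(4e-5, 8))
  s2 <- titration_schedule(V0 = 2e-3, c0 = c(M = 1e-3, L = 0),
                           c_titrant = c(M = 0, L = 5e-3),
                           v_add = rep(2e-5, 16))
  cal <- list(E0 = 10, slope = -59)
  p1 <- simulate_potentiometric(s1, m, cal, ion = "M")
  p2 <- simulate_potentiometric(s2, m, cal, ion = "M")
  # identical totals at the shared cumulative volumes -> identical pNa
  expect_equal(p1$pNa, p2$pNa[c(1, seq(3, 17, 2))], tolerance = 1e-10)
})

test_that("ISE calibration is an OLS line in log10 concentration", {
  std <- data.frame(c = c(1e-4, 1e-2), E = c(-236.8, -118.4))
  cal <- calibrate_ise(std)
  expect_equal(cal$slope, 59.2, tolerance = 1e-9)
  expect_equal(cal$E0, 0, tolerance = 1e-9)
  set.seed(3)
  cs <- 10^seq(-5, -2, length.out = 12)
  noisy <- data.frame(c = cs, E = 5 + 57 * log10(cs) + rnorm(12, 0, 0.5))
  cal2 <- calibrate_ise(noisy)
  expect_equal(cal2$slope, 57, tolerance = 0.05)
  cal3 <- calibrate_ise(noisy[sample(12), ])
  expect_equal(cal3$slope, cal2$slope)
  expect_error(calibrate_ise(data.frame(c = c(1e-3, 1e-3),
                                        E = c(1, 2))), "distinct")
})

test_that("conductivity sums molar conductivities of charged species only", {
  m <- eq_model("X")
  sch <- titration_schedule(V0 = 1e-3, c0 = c(X = 1e-3),
                            c_titrant = c(X = 1e-3), v_add = 1e-9)
  k <- simulate_conductometric(sch, m, list(lambda = list(X = 50),
                                            charged = "X"))
  expect_equal(k$kappa[1], 5e-5)
  expect_error(simulate_conductometric(sch, m,
                                       list(lambda = list(),
                                            charged = "X")),
               "missing molar conductivity")
})

test_that("ion pairing bends and lowers the conductometric curve", {
  preset0 <- scenario_preset("NaHSO4", overrides = list(K_IP = 1e-6),
                             quiet = TRUE)
  preset <- scenario_preset("NaHSO4", quiet = TRUE)
  d0 <- generate("conductometric", preset0)
  d1 <- generate("conductometric", preset)
  # no pairing: kappa exactly linear in the delivered titrant moles after
  # dilution correction
  V <- d0$schedule$V0 + c(0, d0$schedule$v_cum)
  kcorr <- d0$observed$kappa * V
  vt <- c(0, d0$schedule$v_cum)
  fitlm <- stats::lm(kcorr ~ vt)
  expect_lt(max(abs(stats::residuals(fitlm))) / max(kcorr), 1e-9)
  # pairing lowers kappa pointwise and bends the volume-corrected curve
  # below the chord of its endpoints (negative curvature)
  expect_true(all(d1$observed$kappa <= d0$observed$kappa + 1e-15))
  k1corr <- d1$observed$kappa * V
  chord <- k1corr[1] + (k1corr[16] - k1corr[1]) * (vt - vt[1]) /
    (vt[16] - vt[1])
  expect_lt(min(k1corr - chord), -1e-10)
  expect_lt(max(k1corr - chord), 1e-12)
})

test_that("ITC heats integrate to the enthalpy content difference", {
  m <- model_1to1(8)
  sch <- titration_schedule(V0 = 1.43e-3, c0 = c(M = 1e-4, L = 0),
                            c_titrant = c(M = 0, L = 2e-3),
                            v_add = rep(1e-5, 15))
  # zero enthalpies give zero heats
  q0 <- simulate_itc(sch, m, list(dH = list(ML = 0)))
  expect_equal(q0$Q_uJ, rep(0, 15))
  # strong binding: plateau then drop after the equivalence point
  q <- simulate_itc(sch, m, list(dH = list(ML = -40)))
  states <- suprafit:::speciate_schedule(m, sch, overflow = TRUE)
  H <- vapply(states, function(s) s$species[["ML"]], 0) *
    sch$V0 * (-40) * 1e9
  expect_equal(sum(q$Q_uJ), H[16] - H[1], tolerance = 1e-9 * abs(H[16]))
  # pre-equivalence plateau: each heat ~ dH x moles injected
  mol_per_inj <- 2e-3 * 1e-5                       # ~2e-8 mol
  q_plateau <- -40e3 * mol_per_inj * 1e6           # J -> uJ
  expect_equal(q$Q_uJ[1], q_plateau, tolerance = 0.02 * abs(q_plateau))
  expect_lt(stats::sd(q$Q_uJ[1:5]) / abs(q$Q_uJ[1]), 0.02)
  expect_lt(abs(q$Q_uJ[15]), 0.05 * abs(q$Q_uJ[1]))
  # total heat ~ (dilution-corrected) titrand moles x dH once saturated
  mol_M_final <- 1e-4 * exp(-sum(sch$v_add) / 1.43e-3) * 1.43e-3
  expect_equal(sum(q$Q_uJ) * 1e-6, mol_M_final * (-40) * 1e3,
               tolerance = 0.01)
})

test_that("Beer-Lambert additivity and isosbestic behavior emerge", {
  # single species: absorbance linear in concentration
  m <- eq_model("X")
  sch <- titration_schedule(V0 = 1e-3, c0 = c(X = 1e-4),
                            c_titrant = c(X = 2e-4), v_add = rep(5e-5, 6))
  wl <- seq(250, 300, 10)
  eps <- cbind(X = rep(1000, length(wl)))
  uv <- simulate_uv(sch, m, list(wavelength = wl, epsilon = eps, path = 1))
  tot <- schedule_totals(sch)
  expect_equal(unname(uv$absorbance[, 1]), unname(1000 * tot[, "X"]))
  # two-state system with crossing spectra: isosbestic point is invariant
  m2 <- model_1to1(4)
  sch2 <- titration_schedule(V0 = 1e-3, c0 = c(M = 2e-4, L = 0),
                             c_titrant = c(M = 0, L = 5e-3),
                             v_add = rep(2e-5, 10))
  wl7 <- seq(250, 300, length.out = 7)
  epsM <- seq(2000, 500, length.out = 7)
  epsML <- seq(500, 2000, length.out = 7)
  # L does not absorb; M and ML cross exactly at the middle wavelength
  uv2 <- simulate_uv(sch2, m2,
                     list(wavelength = wl7,
                          epsilon = cbind(M = epsM, ML = epsML), path = 1))
  # dilution-corrected absorbance at the crossing wavelength is constant
  cross <- 4
  V <- 1e-3 + c(0, sch2$v_cum)
  acorr <- uv2$absorbance[, cross] * V / 1e-3
  expect_lt(max(abs(acorr - acorr[1])) / acorr[1], 1e-9)
  # a third species' spectrum can be reconstructed by linear algebra
  eps3 <- default_uv_spectra()
  ds <- generate("uv", "NaCl")
  conc <- t(vapply(suprafit:::speciate_schedule(
    ds$model, ds$schedule, allow_solids = FALSE),
    function(s) s$species, numeric(nrow(ds$model$species))))
  known <- c("H", "CH", "HA")
  R <- ds$observed$absorbance -
    conc[, known] %*% t(eps3$epsilon[, known])
  eCHA <- qr.solve(conc[, "CHA", drop = FALSE], R)
  expect_equal(as.numeric(eCHA), unname(eps3$epsilon[, "CHA"]),
               tolerance = 1e-6)
})

test_that("fast-exchange shifts average over the fast pool only", {
  m <- eq_model("X")
  sch <- titration_schedule(V0 = 1e-3, c0 = c(X = 1e-4),
                            c_titrant = c(X = 1e-4), v_add = 1e-9)
  s1 <- simulate_nmr_fast(sch, m, list(delta = list(X = 7.77)), pool = "X")
  expect_equal(s1$delta_obs, rep(7.77, 2))
  # 50/50 mixture of two fast species averages their shifts
  m2 <- eq_model(c("P", "Q"),
                 species = list(list(name = "PQ", stoich = c(P = 1, Q = 1),
                                     log_beta = 12)))
  sch2 <- titration_schedule(V0 = 1e-3, c0 = c(P = 2e-4, Q = 1e-4),
                             c_titrant = c(P = 0, Q = 0), v_add = 1e-9)
  s2 <- simulate_nmr_fast(sch2, m2, list(delta = list(P = 7, PQ = 9)),
                          pool = "P")
  expect_equal(s2$delta_obs, rep(8, 2), tolerance = 1e-4)
  # observed shift stays inside the convex hull of the fast-pool shifts
  ds <- generate("nmr_fast", "NaCl")
  expect_true(all(ds$observed$delta_obs >= 7 - 1e-9 &
                    ds$observed$delta_obs <= 8.5 + 1e-9))
  # slow species are excluded from the average and reported as tracks
  m3 <- eq_model(c("H", "C"),
                 species = list(list(name = "CH", stoich = c(H = 1, C = 1),
                                     log_beta = 6)))
  sch3 <- titration_schedule(V0 = 1e-3, c0 = c(H = 2e-4, C = 1e-4),
                             c_titrant = c(H = 0, C = 0), v_add = 1e-9)
  s3 <- simulate_nmr_fast(sch3, m3,
                          list(delta = list(H = 6.5), slow = "CH"),
                          pool = "H")
  expect_equal(s3$delta_obs, rep(6.5, 2), tolerance = 1e-6)
  expect_true(all(s3$pop_CH > 0 & s3$pop_CH < 1))
})
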
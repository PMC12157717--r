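test_that("pure-salt solubility combines the ionic and ion-pair terms", {
  expect_equal(solubility_pure(1e-8, 0), 1e-4)
  expect_equal(solubility_pure(2e-9, 7.7e3),
               sqrt(2e-9) + 2e-9 * 7.7e3)   # ~6.01e-5
  # cross-check against the saturated state of the generic solver
  m <- model_nacl(Ks = 2e-9, K_IP = 7.7e3)
  r <- solve_speciation(m, c(Na = 5e-4, Cl = 5e-4))
  s_solver <- r$free[["Na"]] + r$species[["NaCl"]]
  expect_equal(solubility_pure(2e-9, 7.7e3), unname(s_solver),
               tolerance = 1e-8)
  expect_error(solubility_pure(-1, 0), "positive")
})

test_that("common-anion suppression follows the quadratic closed form", {
  expect_equal(solubility_with_common_anion(2e-9, 7.7e3, 0),
               solubility_pure(2e-9, 7.7e3))
  s <- solubility_with_common_anion(2e-9, 7.7e3, 1e-3)
  expect_equal(s, 0.5 * (2 * 2e-9 * 7.7e3 - 1e-3 + sqrt(1e-6 + 8e-9)),
               tolerance = 1e-12)
  # total solubility from the solver at the same common-ion level agrees
  m <- model_nacl(Ks = 2e-9, K_IP = 7.7e3)
  r <- solve_speciation(m, c(Na = 5e-4, Cl = 5e-4 + 1e-3))
  s_solver <- r$free[["Na"]] + r$species[["NaCl"]]
  expect_equal(s, unname(s_solver), tolerance = 1e-7)
  # ionic part decays monotonically to the ion-pair floor
  cs <- c(0, 1e-4, 1e-3, 1e-2, 1e-1)
  ss <- solubility_with_common_anion(2e-9, 7.7e3, cs)
  expect_true(all(diff(ss) < 0))
  expect_gt(ss[length(ss)], 2e-9 * 7.7e3)
})

test_that("no-solid free cation solves the pairing mass balances", {
  expect_equal(free_cation_no_solid(1e-3, 5e-4, 0), 1e-3)
  x <- free_cation_no_solid(1e-3, 1e-3, 1e4)   # 1e4 x^2 + x = 1e-3
  expect_equal(x, (-1 + sqrt(1 + 4 * 1e4 * 1e-3)) / (2 * 1e4),
               tolerance = 1e-12)
  # asymmetric case against the generic solver
  m <- eq_model(c("Na", "Cl"),
                species = list(list(name = "NaCl",
                                    stoich = c(Na = 1, Cl = 1),
                                    log_beta = 4)))
  r <- solve_speciation(m, c(Na = 1e-3, Cl = 1e-4))
  expect_equal(free_cation_no_solid(1e-3, 1e-4, 1e4),
               unname(r$free[["Na"]]), tolerance = 1e-8)
})

test_that("saturated free cation follows the solid-regime expression", {
  expect_equal(free_cation_with_solid(1e-4, 1e-4, 2e-9), sqrt(2e-9))
  expect_equal(free_cation_with_solid(2e-4, 1e-4, 2e-9),
               0.5 * (1e-4 + sqrt(1e-8 + 8e-9)), tolerance = 1e-12)
  expect_equal(free_cation_with_solid(2e-4, 1e-4, 1e-30), 1e-4,
               tolerance = 1e-6)
})

test_that("regime test matches the strict saturation inequality", {
  p <- list(Ks = 2e-9, K_IP = 1e4)
  expect_equal(regime_test(1e-6, 1e-6, p), "no_solid")
  expect_equal(regime_test(1e-3, 1e-3, p), "solid")
  # boundary: totals tuned so the hypothetical product equals Ks exactly
  x <- sqrt(2e-9)
  tot <- x + 1e4 * x^2                  # symmetric totals giving product Ks
  expect_equal(regime_test(tot, tot, p), "no_solid")
})

test_that("dimerizing-anion solubility cubic reduces and matches the solver", {
  expect_equal(phosphate_solubility_implicit(2e-14, 1e9, 0, 0),
               solubility_pure(2e-14, 1e9), tolerance = 1e-10)
  s0 <- phosphate_solubility_implicit(2e-14, 1e9, 1e2, 0)
  # oracle: saturated speciation with ion pair + dimer + solid
  m <- eq_model(c("Na", "A"),
    species = list(list(name = "NaA", stoich = c(Na = 1, A = 1),
                        log_beta = 9),
                   list(name = "A2", stoich = c(A = 2), log_beta = 2)),
    solids = list(list(name = "NaA_s", stoich = c(Na = 1, A = 1),
                       log_Ks = log10(2e-14))))
  r <- solve_speciation(m, c(Na = 1e-3, A = 1e-3))
  s_solver <- r$free[["A"]] + 2 * r$species[["A2"]] + r$species[["NaA"]]
  expect_equal(s0, unname(s_solver), tolerance = 1e-6)
  # common-ion suppression direction
  s1 <- phosphate_solubility_implicit(2e-14, 1e9, 1e2, 5e-4)
  expect_lt(s1, s0)
})

test_that("saturated free cation of the dimerizing salt obeys its polynomial", {
  n <- phosphate_free_cation_saturated(2e-14, 1e2)
  # independent cross-check: the equivalent cubic mass balance
  expect_equal(n^3 - 2e-14 * n - 2 * 1e2 * (2e-14)^2, 0,
               tolerance = 1e-25)
  # K_dim -> 0 limit tends to sqrt(Ks)
  expect_equal(phosphate_free_cation_saturated(2e-14, 1e-6), sqrt(2e-14),
               tolerance = 1e-3 * sqrt(2e-14))
  # scaling: 100x Ks scales the root by 10 when Kdim sqrt(Ks) << 1
  n2 <- phosphate_free_cation_saturated(2e-12, 1e2)
  expect_equal(n2 / n, 10, tolerance = 1e-3)
  # agreement with the saturated generic speciation
  m <- eq_model(c("Na", "A"),
    species = list(list(name = "A2", stoich = c(A = 2), log_beta = 2)),
    solids = list(list(name = "NaA_s", stoich = c(Na = 1, A = 1),
                       log_Ks = log10(2e-14))))
  r <- solve_speciation(m, c(Na = 1e-3, A = 1e-3))
  expect_equal(n, unname(r$free[["Na"]]), tolerance = 1e-6)
})

test_that("K_IP from the saturated composition inverts the pure relation", {
  expect_equal(kip_from_saturated(1e-4, 1e-4, 1e-8), 0)
  for (K in c(10, 1e3, 1e6)) {
    Ks <- 4e-9
    expect_equal(kip_from_saturated(solubility_pure(Ks, K), sqrt(Ks), Ks),
                 K, tolerance = 1e-9)
  }
  expect_error(kip_from_saturated(1e-5, 2e-5, 1e-8), "negative ion-pair")
})

test_that("flame-AES arithmetic recovers the solubility chain", {
  s <- aes_solubility(1.6, 10, 5.00, 3.00, 22.99)
  expect_equal(s, 1.16e-3, tolerance = 2e-3)
  expect_equal(aes_solubility(0, 10, 5, 3, 22.99), 0)
  expect_equal(aes_solubility(1.6, 10, 5, 6, 22.99), s / 2)
})

test_that("closed forms track the generic solver over random draws", {
  set.seed(11)
  for (i in 1:60) {
    Ks <- 10^runif(1, -14, -8)
    K <- 10^runif(1, 3, 9)
    cNa <- 10^runif(1, -5, -2.5)
    cCl <- 10^runif(1, -5, -2.5)
    m <- eq_model(c("Na", "Cl"),
                  species = list(list(name = "NaCl",
                                      stoich = c(Na = 1, Cl = 1),
                                      log_beta = log10(K))))
    r <- solve_speciation(m, c(Na = cNa, Cl = cCl))
    expect_lt(abs(free_cation_no_solid(cNa, cCl, K) - r$free[["Na"]]) /
                r$free[["Na"]], 1e-6)
  }
})

test_that("ion-pairing / solubility-product compensation follows Eq.-(6) algebra", {
  Ks <- 2e-9; K <- 7.7e3
  s_ref <- solubility_pure(Ks, K)
  s_new <- solubility_pure(Ks * 1e-5, K * 1e6)
  pred <- sqrt(Ks * 1e-5) + (Ks * 1e-5) * (K * 1e6)
  expect_equal(s_new, pred, tolerance = 1e-12)
  expect_equal(s_new / s_ref, pred / s_ref, tolerance = 1e-12)
})

test_that("method A recovers its generating parameters", {
  cc <- c(0, 1e-4, 3e-4, 6e-4, 1e-3)
  d <- data.frame(c_coion = cc,
                  s = solubility_with_common_anion(2e-9, 7.7e3, cc))
  f <- fit_method_A(d)
  expect_lt(abs(f$params$Ks - 2e-9) / 2e-9, 1e-3)
  expect_lt(abs(f$params$K_IP - 7.7e3) / 7.7e3, 1e-3)
  # seeded 1% noise keeps estimates within 20%
  set.seed(42)
  dn <- d; dn$s <- dn$s * (1 + rnorm(nrow(d), 0, 0.01))
  fn <- fit_method_A(dn)
  expect_lt(abs(fn$params$Ks - 2e-9) / 2e-9, 0.2)
  expect_lt(abs(fn$params$K_IP - 7.7e3) / 7.7e3, 0.2)
  # degenerate designs are flagged
  expect_error(fit_method_A(data.frame(c_coion = c(0, 0, 0),
                                       s = rep(6e-5, 3))),
               "non-identifiable")
})

test_that("method B recovers s, Ks, K_IP from a two-regime titration", {
  Ks <- 2e-9; K <- 7.7e3; s <- solubility_pure(Ks, K)
  cNa <- rep(1e-4, 20); cCl <- seq(1e-5, 4e-4, length.out = 20)
  reg <- regime_test(cNa, cCl, list(Ks = Ks, K_IP = K))
  pna <- ifelse(reg == "solid",
                -log10(free_cation_with_solid(cNa, cCl, Ks)),
                -log10(free_cation_no_solid(cNa, cCl, K)))
  d <- data.frame(c_cation = cNa, c_anion = cCl, pNa = pna)
  f <- fit_method_B(d)
  expect_lt(abs(f$params$Ks - Ks) / Ks, 5e-3)
  expect_lt(abs(f$params$s - s) / s, 5e-3)
  expect_lt(abs(f$params$K_IP - K) / K, 5e-3)
  # row order does not matter
  set.seed(9)
  f2 <- fit_method_B(d[sample(nrow(d)), ])
  expect_equal(f2$params$Ks, f$params$Ks, tolerance = 1e-10)
  # high-concentration protocol: solid from the first addition, s fixed
  cNa2 <- rep(5e-4, 15); cCl2 <- seq(5e-5, 8e-4, length.out = 15)
  pna2 <- -log10(free_cation_with_solid(cNa2, cCl2, Ks))
  f3 <- fit_method_B(data.frame(c_cation = cNa2, c_anion = cCl2,
                                pNa = pna2), s_fixed = s)
  expect_lt(abs(f3$params$Ks - Ks) / Ks, 5e-3)
  # labelled data with an empty regime and the matching parameter free
  d$regime <- "no_solid"
  expect_error(fit_method_B(d), "non-identifiable")
})

test_that("method E recovers Ks and K_IP at fixed K_dim", {
  cc <- c(0, 1e-4, 3e-4, 6e-4, 1e-3)
  Ks <- 2e-14; KIP <- 1.4e8
  s <- vapply(cc, function(x)
    phosphate_solubility_implicit(Ks, KIP, 1e2, x), 0)
  f <- fit_method_E(data.frame(c_coion = cc, s = s), 1e2)
  expect_lt(abs(f$params$Ks - Ks) / Ks, 5e-3)
  expect_lt(abs(f$params$K_IP - KIP) / KIP, 5e-3)
  set.seed(5)
  sn <- s * (1 + rnorm(length(s), 0, 0.01))
  fn <- fit_method_E(data.frame(c_coion = cc, s = sn), 1e2)
  expect_lt(abs(log10(fn$params$Ks) - log10(Ks)) / 13.7, 0.2)
  expect_error(fit_method_E(data.frame(c_coion = c(0, 0), s = c(1, 1)),
                            1e2), "non-identifiable")
})

test_that("method F recovers Ks and round-trips K_IP via the saturated state", {
  Ks <- 2e-14; Kdim <- 1e2
  nsat <- phosphate_free_cation_saturated(Ks, Kdim)
  s <- nsat + 1e9 * Ks
  KIP <- kip_from_saturated(s, nsat, Ks)
  m <- eq_model(c("Na", "A"),
    species = list(list(name = "NaA", stoich = c(Na = 1, A = 1),
                        log_beta = log10(KIP)),
                   list(name = "A2", stoich = c(A = 2),
                        log_beta = log10(Kdim))),
    solids = list(list(name = "NaA_s", stoich = c(Na = 1, A = 1),
                       log_Ks = log10(Ks))))
  cNa <- rep(1e-4, 15); cA <- seq(2e-5, 5e-4, length.out = 15)
  pna <- vapply(seq_along(cA), function(i)
    -log10(solve_speciation(m, c(Na = cNa[i], A = cA[i]))$free[["Na"]]), 0)
  d <- data.frame(c_cation = cNa, c_anion = cA, pNa = pna)
  f <- fit_method_F(d, s_fixed = s, K_dim_fixed = Kdim)
  expect_lt(abs(f$params$Ks - Ks) / Ks, 0.01)
  expect_lt(abs(f$params$K_IP - KIP) / KIP, 0.02)
  # uniform weights reduce to ordinary least squares and still recover
  fu <- fit_method_F(d, s_fixed = s, K_dim_fixed = Kdim,
                     weights = "uniform")
  expect_lt(abs(fu$params$Ks - Ks) / Ks, 0.01)
})
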
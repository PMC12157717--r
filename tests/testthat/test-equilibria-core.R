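test_that("free-component-only models return the totals unchanged", {
  m <- eq_model(c("X", "Y"))
  r <- solve_speciation(m, c(X = 1e-3, Y = 2e-3))
  expect_true(r$converged)
  expect_equal(unname(r$free), c(1e-3, 2e-3))
  expect_equal(unname(oracle_solve_1d(m, c(X = 1e-3, Y = 2e-3))$free),
               c(1e-3, 2e-3))
})

test_that("1:1 binding matches the quadratic closed form", {
  m <- model_1to1(6)
  r <- solve_speciation(m, c(M = 1e-4, L = 1e-4))
  x <- free_1to1_equal(1e6, 1e-4)       # 9.512492e-06
  expect_equal(unname(r$free[["M"]]), x, tolerance = 1e-8)
  expect_equal(unname(r$free[["L"]]), x, tolerance = 1e-8)
  expect_equal(unname(r$species[["ML"]]), 1e6 * x^2, tolerance = 1e-8)
  # frozen values from the quadratic oracle
  expect_equal(unname(r$free[["M"]]), 9.512492e-6, tolerance = 1e-6)
  expect_equal(unname(r$species[["ML"]]), 9.048751e-5, tolerance = 1e-6)
})

test_that("a supersaturated 1:1 salt precipitates to free = sqrt(Ks)", {
  m <- model_nacl(Ks = 2e-9)
  r <- solve_speciation(m, c(Na = 1e-4, Cl = 1e-4), allow_solids = TRUE)
  expect_equal(unname(r$free[["Na"]]), sqrt(2e-9), tolerance = 1e-9)
  expect_equal(unname(r$free[["Cl"]]), sqrt(2e-9), tolerance = 1e-9)
  expect_gt(r$solid_amounts[["NaCl_s"]], 0)
  # with solids disallowed the ions stay in solution even if supersaturated
  r2 <- solve_speciation(m, c(Na = 1e-4, Cl = 1e-4), allow_solids = FALSE)
  expect_equal(unname(r2$free[["Na"]]), 1e-4)
  expect_gt(ion_product(r2, "NaCl_s"), 2e-9)
})

test_that("ion products multiply free concentrations per stoichiometry", {
  m <- model_nacl(Ks = 2e-9)
  r <- solve_speciation(m, c(Na = 1e-4, Cl = 1e-4))
  expect_equal(ion_product(r, "NaCl_s"), 2e-9, tolerance = 1e-9)
  r$free[] <- c(1e-5, 1e-5)
  expect_equal(ion_product(r, "NaCl_s"), 1e-10)
  r$free[] <- c(2e-5, 5e-6)
  expect_equal(ion_product(r, "NaCl_s"), 1e-10)
  expect_error(ion_product(r, "bogus"), "unknown solid")
})

test_that("anion dimerization solves the stated monomer quadratic", {
  # 2 K x^2 + x = total
  m <- model_dimer(1e2)
  r <- solve_speciation(m, c(A = 1e-2))
  x <- (-1 + sqrt(1 + 8 * 1e2 * 1e-2)) / (4 * 1e2)   # 5.0e-3
  expect_equal(unname(r$free[["A"]]), x, tolerance = 1e-9)
  expect_equal(unname(oracle_solve_1d(m, c(A = 1e-2))$free[["A"]]), x,
               tolerance = 1e-9)
})

test_that("invalid totals and malformed models are rejected", {
  m <- model_1to1()
  expect_error(solve_speciation(m, c(M = -1e-4, L = 1e-4)), ">= 0")
  expect_error(solve_speciation(m, c(M = 1e-4)), "missing")
  expect_error(eq_model(c("A", "A")), "unique")
  expect_error(eq_model("A", species = list(list(name = "B",
                                                 stoich = c(A = 0.5),
                                                 log_beta = 1))),
               "integers")
  expect_error(eq_model("A", species = list(list(name = "B",
                                                 stoich = c(A = 1),
                                                 log_beta = Inf))),
               "finite")
})

test_that("oracle rejects models it cannot reduce and solids", {
  m2 <- eq_model(c("A", "B"),
                 species = list(list(name = "A2B2",
                                     stoich = c(A = 2, B = 2),
                                     log_beta = 8)))
  expect_error(oracle_solve_1d(m2, c(A = 1e-3, B = 1e-3)),
               "not reducible")
  expect_error(oracle_solve_1d(model_nacl(), c(Na = 1e-4, Cl = 1e-4)),
               "solution-only")
})

test_that("solver and oracle agree over random one-unknown models", {
  cases <- random_one_unknown(150)
  for (cs in cases) {
    a <- solve_speciation(cs$model, cs$totals)
    b <- oracle_solve_1d(cs$model, cs$totals)
    expect_true(a$converged)
    expect_lt(max(abs(a$free - b$free) / pmax(b$free, 1e-300)), 1e-6)
  }
})

test_that("mass balance closes to 1e-10 relative for converged states", {
  cases <- random_one_unknown(40, seed = 77)
  for (cs in cases) {
    r <- solve_speciation(cs$model, cs$totals)
    expect_lt(max(abs(mass_balance_residuals(r))), 1e-10)
  }
  # with a solid phase present
  r <- solve_speciation(model_nacl(Ks = 2e-9, K_IP = 7.7e3),
                        c(Na = 5e-4, Cl = 3e-4))
  expect_lt(max(abs(mass_balance_residuals(r))), 1e-10)
})

test_that("saturation complementarity holds for every solid", {
  m <- model_nacl(Ks = 2e-9, K_IP = 7.7e3)
  for (tot in list(c(Na = 1e-6, Cl = 1e-6), c(Na = 1e-4, Cl = 1e-4),
                   c(Na = 5e-4, Cl = 1e-3))) {
    r <- solve_speciation(m, tot)
    ip <- ion_product(r, "NaCl_s")
    amt <- r$solid_amounts[["NaCl_s"]]
    if (amt > 0) expect_equal(ip, 2e-9, tolerance = 1e-6)
    else expect_lte(ip, 2e-9 * (1 + 1e-9))
    expect_lt(abs(amt * (2e-9 - ip)), 1e-20)
  }
})

test_that("free concentration is monotone in its own total", {
  m <- eq_model(c("M", "L"),
                species = list(list(name = "ML", stoich = c(M = 1, L = 1),
                                    log_beta = 5),
                               list(name = "ML2", stoich = c(M = 1, L = 2),
                                    log_beta = 9)))
  totsM <- 10^seq(-5, -3, length.out = 9)
  free <- vapply(totsM, function(tm)
    solve_speciation(m, c(M = tm, L = 5e-4))$free[["M"]], 0)
  expect_true(all(diff(free) > 0))
})

test_that("model definition files round-trip through YAML", {
  m <- eq_model(c("Na", "Cl"),
                species = list(list(name = "NaCl", stoich = c(Na = 1, Cl = 1),
                                    log_beta = 3.886)),
                solids = list(list(name = "NaCl_s",
                                   stoich = c(Na = 1, Cl = 1),
                                   log_Ks = -8.7)),
                charges = c(Na = 1, Cl = -1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_eq_model(m, path)
  m2 <- read_eq_model(path)
  expect_equal(m2$components, m$components)
  expect_equal(m2$species, m$species)
  expect_equal(m2$solids, m$solids)
  expect_equal(unname(m2$stoich), unname(m$stoich))
})
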
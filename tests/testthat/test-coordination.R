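# minimal hand-built frames for boundary checks
atom_row <- function(role, group, x, y, z, bonded_to = NA_integer_)
  data.frame(role = role, group = group, x = x, y = y, z = z,
             bonded_to = bonded_to)

test_that("cation coordination counts split by oxygen role", {
  f <- generate_frames(list(Na = c(6, 4, 2)))[[1]]
  expect_equal(unname(na_coordination(f)), c(6, 4, 2))
  f2 <- generate_frames(list(Na = c(0, 0, 0)))[[1]]
  expect_equal(unname(na_coordination(f2)), c(0, 0, 0))
  expect_error(na_coordination(generate_frames(list(Cl = c(2, 2, 0)))[[1]]),
               "no Na")
})

test_that("distance cutoffs are strict at the boundary", {
  # O at exactly 3.0 A from Na is excluded; at 2.999 it counts
  base <- rbind(atom_row("Na", "ion", 0, 0, 0),
                atom_row("C", "s", 4.2, 1, 0),
                atom_row("O_ether", "s", 3.0, 0, 0, bonded_to = 2L))
  f <- labeled_frame(base)
  expect_equal(unname(na_coordination(f)), c(0, 0, 0))
  base$x[3] <- 2.999
  expect_equal(unname(na_coordination(labeled_frame(base))), c(1, 1, 0))
  # N-H...Cl with a 85 degree approach angle is rejected
  n <- atom_row("N_urea", "urea1", 0, 1.0, 0)
  h <- atom_row("H_ureaNH", "urea1", 0, 0, 0, bonded_to = 1L)
  cl <- atom_row("Cl", "ion", 2.0 * cos(85 * pi / 180),
                 -2.0 * sin(85 * pi / 180) * 0 + 2.0 * 0,
                 0)
  # place Cl so that angle(N-H-Cl) = 85 deg at d = 2.0
  ang <- 85 * pi / 180
  cl$x <- 2.0 * sin(ang); cl$y <- 2.0 * cos(ang)
  f2 <- labeled_frame(rbind(n, h, cl))
  expect_equal(unname(cl_coordination(f2)), c(0, 0, 0))
  cl$x <- 2.0 * sin(130 * pi / 180); cl$y <- -2.0 * cos(50 * pi / 180)
  f3 <- labeled_frame(rbind(n, h, cl))
  expect_equal(unname(cl_coordination(f3)), c(1, 1, 0))
  # H...O at exactly 3.2 A is excluded (donor angle ~136 deg kept valid
  # by tilting the N-H bond instead of the O position)
  n2 <- atom_row("N_urea", "urea1", 0.7, 0.714, 0)
  h2 <- atom_row("H_ureaNH", "urea1", 0, 0, 0, bonded_to = 1L)
  o <- atom_row("O_amide", "amide1", 0, -3.2, 0)
  f4 <- labeled_frame(rbind(n2, h2, o))
  expect_equal(unname(hb_detect(f4)), c(0, 0, 0))
  o$y <- -3.19
  expect_equal(unname(hb_detect(labeled_frame(rbind(n2, h2, o)))),
               c(1, 1, 0))
})

test_that("anion coordination splits by urea moiety", {
  expect_equal(unname(cl_coordination(
    generate_frames(list(Cl = c(4, 2, 2)))[[1]])), c(4, 2, 2))
  expect_equal(unname(cl_coordination(
    generate_frames(list(Cl = c(2, 2, 0)))[[1]])), c(2, 2, 0))
})

test_that("hydrogen-bond matrices count amide and urea acceptors", {
  expect_equal(unname(hb_detect(
    generate_frames(list(HB = c(2, 2, 0)))[[1]])), c(2, 2, 0))
  expect_equal(unname(hb_detect(
    generate_frames(list(HB = c(3, 2, 1)))[[1]])), c(3, 2, 1))
  expect_equal(unname(hb_detect(
    generate_frames(list(Cl = c(4, 2, 2)))[[1]])), c(0, 0, 0))
})

test_that("solvent inclusion classifies by the included end", {
  for (sv in c("methyl_in", "nitrile_in", "none")) {
    f <- generate_frames(list(Na = c(6, 4, 2), solvent = sv))[[1]]
    expect_equal(solvent_inclusion(f), sv)
  }
  f <- generate_frames(list(Na = c(6, 4, 2)))[[1]]
  f$atoms <- f$atoms[f$atoms$role != "scaffold_ref", ]
  expect_error(solvent_inclusion(f), "missing")
})

test_that("classification is invariant under rigid-body motion", {
  f <- generate_frames(list(Na = c(6, 4, 2), Cl = c(2, 2, 0),
                            solvent = "methyl_in"))[[1]]
  key0 <- coordination_state(f)$key
  fv0 <- feature_vector(f)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(f$atoms[, c("x", "y", "z")]) %*% R
  f2 <- f
  f2$atoms$x <- xyz[, 1] + 5; f2$atoms$y <- xyz[, 2] - 3
  f2$atoms$z <- xyz[, 3] + 11
  expect_equal(coordination_state(f2)$key, key0)
  expect_equal(feature_vector(f2), fv0, tolerance = 1e-10)
})

test_that("feature vectors ignore the input row order", {
  f <- generate_frames(list(Na = c(6, 4, 2), Cl = c(2, 2, 0)))[[1]]
  fv0 <- feature_vector(f)
  set.seed(8)
  perm <- sample(nrow(f$atoms))
  a <- f$atoms[perm, ]
  a$bonded_to <- match(f$atoms$bonded_to[perm], perm)
  f2 <- labeled_frame(a)
  expect_equal(coordination_state(f2)$key, coordination_state(f)$key)
  expect_equal(unname(feature_vector(f2)), unname(fv0), tolerance = 1e-12)
})

test_that("cluster populations are frame fractions with member representatives", {
  ens <- c(generate_frames(list(Cl = c(4, 2, 2)), n_frames = 97,
                           jitter = 0.05, seed = 2),
           generate_frames(list(Cl = c(2, 2, 0)), n_frames = 3,
                           jitter = 0.05, seed = 3))
  rep <- cluster_frames(ens)
  expect_equal(sum(rep$population_pct), 100, tolerance = 0.1)
  expect_equal(rep$population_pct[1], 97, tolerance = 0.01)
  expect_equal(rep$population_pct[2], 3, tolerance = 0.01)
  # representative belongs to its own cluster
  states <- attr(rep, "states")
  for (i in seq_len(nrow(rep)))
    expect_equal(states[[rep$representative[i]]]$key, rep$signature[i])
  # a single frame forms one full cluster represented by itself
  one <- cluster_frames(ens[1])
  expect_equal(one$population_pct, 100)
  expect_equal(one$representative, 1L)
  expect_error(cluster_frames(list()), "no frames")
})

test_that("jittered ensembles keep their signature at safe margins", {
  fr <- generate_frames(list(Na = c(6, 4, 2)), n_frames = 100,
                        jitter = 0.2, seed = 4)
  keys <- vapply(fr, function(f) coordination_state(f)$key, "")
  expect_gte(mean(keys == "Na(6,4,2)|HB(0,0,0)|none"), 0.95)
})

test_that("unrealizable signatures are refused", {
  expect_error(generate_frames(list(Cl = c(5, 3, 2))), "unrealizable")
  expect_error(generate_frames(list(Na = c(7, 5, 2))), "unrealizable")
  expect_error(generate_frames(list(Cl = c(4, 2, 2), HB = c(2, 2, 0))),
               "unrealizable")
})

test_that("frames round-trip through XYZ and PDB with a role map", {
  dir <- withr::local_tempdir()
  fr <- generate_frames(list(Na = c(6, 4, 2), Cl = c(2, 2, 0)),
                        n_frames = 3, jitter = 0.1, seed = 6)
  xyz <- file.path(dir, "frames.xyz")
  rmp <- file.path(dir, "roles.yaml")
  write_frames_xyz(fr, xyz, rmp)
  back <- read_frames_xyz(xyz, rmp)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$atoms$x, fr[[k]]$atoms$x, tolerance = 1e-5)
    expect_equal(coordination_state(back[[k]])$key,
                 coordination_state(fr[[k]])$key)
  }
  # a minimal multi-model PDB with the same labels reads identically
  rm <- yaml::read_yaml(rmp)$atoms
  labs <- vapply(rm, `[[`, "", "label")
  pdb <- file.path(dir, "frames.pdb")
  con <- file(pdb, "w")
  for (k in 1:2) {
    writeLines(sprintf("MODEL %8d", k), con)
    a <- fr[[k]]$atoms
    writeLines(sprintf(
      "ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(a)), labs, a$x, a$y, a$z), con)
    writeLines("ENDMDL", con)
  }
  close(con)
  pback <- read_frames_pdb(pdb, rmp)
  expect_length(pback, 2)
  expect_equal(coordination_state(pback[[1]])$key,
               coordination_state(fr[[1]])$key)
  # coordination report export writes signatures, clusters, representatives
  rep <- export_coordination_report(fr, file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out_signatures.csv")))
  expect_true(file.exists(file.path(dir, "out_clusters.json")))
  expect_true(file.exists(file.path(dir, "out_representatives.xyz")))
})
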
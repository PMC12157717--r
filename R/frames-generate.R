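#' Generate labelled coordinate frames with prescribed coordination
#'
#' Builds synthetic host-ion structure frames whose classified
#' coordination signatures equal the requested ones at zero jitter, for
#' testing the classification pipeline end-to-end without any trajectory
#' input.  The generator places a schematic host (four ether oxygens, two
#' amide oxygens, two urea moieties with two N-H groups each, two urea
#' oxygens, four cavity reference atoms) and positions the ions, hydrogen
#' bond contacts and an optional included solvent molecule so that every
#' requested contact sits well inside its criterion (distance margins
#' \eqn{\ge 0.7 \AA}, angle margins \eqn{\ge 40°}) and every
#' non-contact sits well outside.  The zero-jitter frame is verified
#' against the classifier and generation fails loudly for unrealizable
#' signatures (e.g. more coordinating N-H groups than a urea owns).
#'
#' @param pattern list with entries `Na` (`c(total, ether, amide)` or
#'   `NULL`), `Cl` (`c(total, urea1, urea2)` or `NULL`), `HB`
#'   (`c(total, amide, urea)`, default zeros) and `solvent` (`"none"`,
#'   `"methyl_in"` or `"nitrile_in"`).
#' @param n_frames number of frames.
#' @param jitter Gaussian displacement added to every coordinate,
#'   \eqn{\AA}.
#' @param seed RNG seed for the jitter.
#' @return list of [labeled_frame()] objects.
#' @export
generate_frames <- function(pattern, n_frames = 1, jitter = 0, seed = 1L) {
  pat <- list(Na = pattern$Na, Cl = pattern$Cl,
              HB = pattern$HB %||% c(0, 0, 0),
              solvent = pattern$solvent %||% "none")
  if (!is.null(pat$Na)) {
    if (length(pat$Na) != 3 || pat$Na[2] > 4 || pat$Na[3] > 2 ||
        pat$Na[1] != pat$Na[2] + pat$Na[3] || any(pat$Na < 0))
      stop("unrealizable Na signature (total must equal ether + amide, ",
           "<= 4 ether and <= 2 amide oxygens exist)")
  }
  if (!is.null(pat$Cl)) {
    if (length(pat$Cl) != 3 || pat$Cl[2] > 2 || pat$Cl[3] > 2 ||
        pat$Cl[1] != pat$Cl[2] + pat$Cl[3] || any(pat$Cl < 0))
      stop("unrealizable Cl signature (each urea owns two N-H groups)")
  }
  if (pat$HB[1] != pat$HB[2] + pat$HB[3] || any(pat$HB < 0))
    stop("unrealizable HB signature")
  n_cl <- if (is.null(pat$Cl)) 0 else pat$Cl[1]
  if (n_cl + pat$HB[1] > 4)
    stop("unrealizable: ", n_cl + pat$HB[1],
         " N-H contacts requested but only 4 N-H groups exist")

  base <- build_frame(pat)
  st <- coordination_state(base)
  same <- function(got, want) is.null(want) || all(unname(got) == want)
  ok <- same(st$HB, pat$HB) && same(st$Na, pat$Na) && same(st$Cl, pat$Cl) &&
    st$solvent == pat$solvent
  if (!ok)
    stop("internal generator check failed: built frame classifies as ",
         st$key)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_frames), function(k) {
    a <- base$atoms
    if (jitter > 0) {
      a$x <- a$x + stats::rnorm(nrow(a), 0, jitter)
      a$y <- a$y + stats::rnorm(nrow(a), 0, jitter)
      a$z <- a$z + stats::rnorm(nrow(a), 0, jitter)
    }
    labeled_frame(a, time = k - 1)
  })
}

# deterministic geometry for one signature
build_frame <- function(pat) {
  rows <- list()
  add <- function(role, group, p, bonded_to = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      role = role, group = group, x = p[1], y = p[2], z = p[3],
      bonded_to = bonded_to)
    length(rows)
  }
  unit <- function(v) v / sqrt(sum(v^2))
  perp <- function(v) {
    w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    unit(w - sum(w * unit(v)) * unit(v))
  }

  na_pos <- c(0, 0, 0)
  cl_pos <- c(0, 0, 7)

  # --- cation site: 4 ether + 2 amide oxygens, each with a bonded carbon
  eth_dir <- lapply(c(45, 135, 225, 315) * pi / 180, function(th)
    unit(c(cos(th), sin(th), -0.7)))
  am_dir <- list(unit(c(1, 0, -0.35)), unit(c(-1, 0, -0.35)))
  n_eth <- if (is.null(pat$Na)) 0 else pat$Na[2]
  n_am <- if (is.null(pat$Na)) 0 else pat$Na[3]
  o_amide_idx <- integer(2); o_amide_coord <- logical(2)
  for (k in 1:4) {
    d <- if (k <= n_eth) 2.1 else 4.2
    o <- na_pos + d * unlist(eth_dir[[k]])
    # carbon placed off the O-Na line (angle C-O-Na ~ 57 deg)
    cdir <- unit(unit(na_pos - o) + 1.5 * perp(na_pos - o))
    ic <- add("C", "scaffold", o + 1.4 * cdir)
    add("O_ether", "scaffold", o, bonded_to = ic)
  }
  for (k in 1:2) {
    d <- if (k <= n_am) 2.1 else 4.2
    o <- na_pos + d * unlist(am_dir[[k]])
    cdir <- unit(unit(na_pos - o) + 1.5 * perp(na_pos - o))
    ic <- add("C", paste0("amide", k), o + 1.4 * cdir)
    o_amide_idx[k] <- add("O_amide", paste0("amide", k), o, bonded_to = ic)
    o_amide_coord[k] <- k <= n_am
  }
  if (!is.null(pat$Na)) add("Na", "ion", na_pos)

  # --- anion site: N-H slots, Cl-coordinating ones aimed at the anion
  nh_dirs <- list(unit(c(0.55, 0.35, -0.76)), unit(c(-0.55, 0.35, -0.76)),
                  unit(c(0.55, -0.35, -0.76)), unit(c(-0.55, -0.35, -0.76)))
  slot_urea <- c(1, 1, 2, 2)
  n_cl_u <- if (is.null(pat$Cl)) c(0, 0) else pat$Cl[2:3]
  used <- logical(4)
  place_nh_at_cl <- function(slot) {
    f <- unlist(nh_dirs[[slot]])
    h <- cl_pos + 2.0 * f
    w <- unit(cl_pos - h)
    g <- cos(160 * pi / 180) * w + sin(160 * pi / 180) * perp(w)
    n <- h + 1.0 * g
    inn <- add("N_urea", paste0("urea", slot_urea[slot]), n)
    add("H_ureaNH", paste0("urea", slot_urea[slot]), h, bonded_to = inn)
  }
  for (u in 1:2) {
    slots <- which(slot_urea == u)
    if (n_cl_u[u] > 0)
      for (s in slots[seq_len(n_cl_u[u])]) { place_nh_at_cl(s); used[s] <- TRUE }
  }

  # --- intramolecular hydrogen bonds on the remaining N-H slots
  hb_targets <- c(rep("amide", pat$HB[2]), rep("urea", pat$HB[3]))
  free_slots <- which(!used)
  urea_o_groups <- integer(0)
  hb_k <- 0
  for (tgt in hb_targets) {
    hb_k <- hb_k + 1
    s <- free_slots[hb_k]
    if (tgt == "amide") {
      # prefer an amide oxygen not engaged at the cation site
      kfree <- which(!o_amide_coord)
      k <- if (length(kfree)) kfree[1] else 1L
      orow <- rows[[o_amide_idx[k]]]
      o <- c(orow$x, orow$y, orow$z)
      away <- if (o_amide_coord[k]) unit(o - na_pos) else unit(c(0, 1, 0.3))
    } else {
      # urea oxygens are placed on demand, far from everything else
      o <- c(16 + 5 * hb_k, 0, 2)
      cdir <- unit(c(0, 0, -1))
      ic <- add("C", paste0("urea", slot_urea[s]), o + 1.4 * cdir)
      add("O_urea", paste0("urea", slot_urea[s]), o, bonded_to = ic)
      urea_o_groups <- c(urea_o_groups, slot_urea[s])
      away <- unit(c(0, 1, 0.2))
    }
    # rotate successive donors around the acceptor to keep them apart
    rot <- (hb_k - 1) * 0.9
    t1 <- perp(away)
    away2 <- unit(cos(rot) * away + sin(rot) * t1)
    h <- o + 2.1 * away2
    w <- unit(o - h)
    g <- cos(155 * pi / 180) * w + sin(155 * pi / 180) * perp(w)
    n <- h + 1.0 * g
    inn <- add("N_urea", paste0("urea", slot_urea[s]), n)
    add("H_ureaNH", paste0("urea", slot_urea[s]), h, bonded_to = inn)
    used[s] <- TRUE
  }

  # unused N-H slots parked far from the anion and all oxygens
  for (s in which(!used)) {
    n <- c(-14 - 3 * s, 8, 6)
    inn <- add("N_urea", paste0("urea", slot_urea[s]), n)
    add("H_ureaNH", paste0("urea", slot_urea[s]), n + c(0, 0, 1),
        bonded_to = inn)
  }

  # default (spare) urea oxygens so the role set is complete
  for (u in setdiff(1:2, urea_o_groups)) {
    o <- c(10, (-1)^u * 9, 11)
    ic <- add("C", paste0("urea", u), o + c(0, 0, 1.4))
    add("O_urea", paste0("urea", u), o, bonded_to = ic)
  }

  if (!is.null(pat$Cl)) add("Cl", "ion", cl_pos)

  # cavity reference atoms and the solvent molecule
  for (th in c(0, 90, 180, 270) * pi / 180)
    add("scaffold_ref", "scaffold", c(3 * cos(th), 3 * sin(th), 1.5))
  # the wide-rim direction is the mean N position; compute after building
  df <- do.call(rbind, rows)
  c0 <- c(0, 0, 1.5)
  irim <- which(df$role == "N_urea")
  c1 <- colMeans(df[irim, c("x", "y", "z")])
  ax <- unit(as.numeric(c1) - c0)
  L <- sqrt(sum((as.numeric(c1) - c0)^2))
  if (pat$solvent == "methyl_in") {
    add("solvent_C_methyl", "solvent1", c0 + 0.35 * L * ax)
    add("solvent_N", "solvent1", c0 + 0.35 * L * ax + 1.5 * ax)
  } else if (pat$solvent == "nitrile_in") {
    add("solvent_N", "solvent1", c0 + 0.35 * L * ax)
    add("solvent_C_methyl", "solvent1", c0 + 0.35 * L * ax + 1.5 * ax)
  } else {
    add("solvent_C_methyl", "solvent1", c(25, 25, 0))
    add("solvent_N", "solvent1", c(25, 25, 1.5))
  }

  labeled_frame(do.call(rbind, rows), time = 0)
}
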
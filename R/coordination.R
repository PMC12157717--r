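#' Labelled 3-D structure frames
#'
#' A labelled frame is a data frame of atom positions (\eqn{\AA}) with the
#' role annotations needed by the coordination criteria: columns `x`,
#' `y`, `z`, `role`, `group` and `bonded_to` (integer row index of the
#' covalently bonded partner: every urea N-H hydrogen points to its
#' nitrogen, every carbonyl/ether oxygen to its carbon — donor/acceptor
#' vectors are taken from labelled bonds, never inferred from distances).
#'
#' Recognized roles: `Na`, `Cl`, `O_ether`, `O_amide`, `O_urea`,
#' `N_urea`, `H_ureaNH`, `C` (generic bonded carbon), `scaffold_ref`
#' (cavity reference atoms), `solvent_C_methyl`, `solvent_N`.  Groups
#' distinguish e.g. `urea1` from `urea2` and solvent molecules.
#'
#' @param atoms data frame with the columns above.
#' @param time optional frame time stamp.
#' @return object of class `labeled_frame`.
#' @export
labeled_frame <- function(atoms, time = NA_real_) {
  need <- c("x", "y", "z", "role", "group", "bonded_to")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  h <- which(atoms$role == "H_ureaNH")
  bad <- h[is.na(atoms$bonded_to[h]) |
             atoms$role[atoms$bonded_to[h]] != "N_urea"]
  if (length(bad))
    stop("every H_ureaNH must be bonded to a labelled N_urea (rows ",
         paste(bad, collapse = ", "), ")")
  structure(list(atoms = atoms, time = time), class = "labeled_frame")
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat(sprintf("<labeled_frame> %d atoms (t = %s)\n", nrow(x$atoms),
              format(x$time)))
  print(table(x$atoms$role))
  invisible(x)
}

vec3 <- function(atoms, i) as.numeric(atoms[i, c("x", "y", "z")])
dist3 <- function(a, b) sqrt(sum((a - b)^2))
angle3 <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cth, -1), 1)) * 180 / pi
}

#' Cation coordination matrix of a frame
#'
#' Counts the oxygen atoms coordinating the cation under the criteria
#' d(O-Na\eqn{^+}) < 3 \eqn{\AA} (strict) and 0° < \eqn{\angle}(C-O-Na\eqn{^+})
#' < 180° (strict; the angle window is implemented literally and is
#' vacuous except for exactly collinear geometries).  Returned as the
#' matrix (total, ether, amide); urea oxygens count towards the total
#' only.
#'
#' @param frame a [labeled_frame()].
#' @return named integer vector `c(total, ether, amide)`.
#' @export
na_coordination <- function(frame) {
  a <- frame$atoms
  ina <- which(a$role == "Na")
  if (!length(ina)) stop("frame contains no Na")
  na <- vec3(a, ina[1])
  os <- which(a$role %in% c("O_ether", "O_amide", "O_urea"))
  hit <- vapply(os, function(i) {
    o <- vec3(a, i)
    if (dist3(o, na) >= 3.0) return(FALSE)
    ic <- a$bonded_to[i]
    if (is.na(ic)) return(FALSE)
    ang <- angle3(vec3(a, ic), o, na)
    ang > 0 && ang < 180
  }, TRUE)
  roles <- a$role[os][hit]
  c(total = sum(hit), ether = sum(roles == "O_ether"),
    amide = sum(roles == "O_amide"))
}

#' Anion coordination matrix of a frame
#'
#' Counts the urea N-H groups coordinating the anion under
#' d(H-Cl\eqn{^-}) < 2.9 \eqn{\AA} and 90° < \eqn{\angle}(N-H-Cl\eqn{^-})
#' < 180° (both strict), split by urea moiety: (total, from urea 1, from
#' urea 2).
#'
#' @inheritParams na_coordination
#' @return named integer vector `c(total, urea1, urea2)`.
#' @export
cl_coordination <- function(frame) {
  a <- frame$atoms
  icl <- which(a$role == "Cl")
  if (!length(icl)) stop("frame contains no Cl")
  cl <- vec3(a, icl[1])
  hs <- which(a$role == "H_ureaNH")
  hit <- vapply(hs, function(i) {
    h <- vec3(a, i)
    if (dist3(h, cl) >= 2.9) return(FALSE)
    ang <- angle3(vec3(a, a$bonded_to[i]), h, cl)
    ang > 90 && ang < 180
  }, TRUE)
  grp <- a$group[hs][hit]
  c(total = sum(hit), urea1 = sum(grp == "urea1"),
    urea2 = sum(grp == "urea2"))
}

#' Intramolecular hydrogen-bond matrix of a frame
#'
#' Counts urea N-H donors bonded to host oxygens under
#' d(H-O) < 3.2 \eqn{\AA} and 90° < \eqn{\angle}(N-H-O) < 180° (both
#' strict), as (total, to amide-O, to urea-O).
#'
#' @inheritParams na_coordination
#' @return named integer vector `c(total, amide, urea)`.
#' @export
hb_detect <- function(frame) {
  a <- frame$atoms
  hs <- which(a$role == "H_ureaNH")
  os <- which(a$role %in% c("O_amide", "O_urea"))
  n_am <- 0L; n_ur <- 0L
  for (i in hs) {
    h <- vec3(a, i)
    nn <- vec3(a, a$bonded_to[i])
    for (j in os) {
      o <- vec3(a, j)
      if (dist3(h, o) >= 3.2) next
      ang <- angle3(nn, h, o)
      if (ang > 90 && ang < 180) {
        if (a$role[j] == "O_amide") n_am <- n_am + 1L else n_ur <- n_ur + 1L
      }
    }
  }
  c(total = n_am + n_ur, amide = n_am, urea = n_ur)
}

#' Default cavity specification
#'
#' The basket cavity is a cylinder of radius `radius` about the axis from
#' the centroid of the scaffold reference atoms towards the centroid of
#' the wide-rim atoms; an atom is inside if it lies within the cylinder
#' between the two rim planes.
#'
#' @param ref_role role of the scaffold reference atoms (cavity floor).
#' @param rim_role role whose centroid defines the wide-rim plane.
#' @param radius cylinder radius, \eqn{\AA}.
#' @export
basket_spec <- function(ref_role = "scaffold_ref", rim_role = "N_urea",
                        radius = 2.5) {
  list(ref_role = ref_role, rim_role = rim_role, radius = radius)
}

#' Solvent-inclusion class of a frame
#'
#' Classifies each frame as `"none"`, `"methyl_in"` or `"nitrile_in"`
#' depending on which end of an acetonitrile molecule (the methyl carbon
#' or the nitrile nitrogen) lies inside the cavity cylinder of
#' [basket_spec()].  When both ends of a molecule are inside, the deeper
#' one (closer to the cavity floor) decides.
#'
#' @inheritParams na_coordination
#' @param spec a [basket_spec()].
#' @return character class.
#' @export
solvent_inclusion <- function(frame, spec = basket_spec()) {
  a <- frame$atoms
  iref <- which(a$role == spec$ref_role)
  irim <- which(a$role == spec$rim_role)
  if (!length(iref) || !length(irim))
    stop("basket reference atoms (", spec$ref_role, " / ", spec$rim_role,
         ") missing from frame")
  c0 <- colMeans(a[iref, c("x", "y", "z")])
  c1 <- colMeans(a[irim, c("x", "y", "z")])
  ax <- as.numeric(c1 - c0); L <- sqrt(sum(ax^2)); ax <- ax / L
  inside <- function(p) {
    t <- sum((p - c0) * ax)
    if (t < 0 || t > L) return(c(FALSE, Inf))
    rad <- sqrt(max(sum((p - c0)^2) - t^2, 0))
    c(rad < spec$radius, t)
  }
  for (g in unique(a$group[a$role %in% c("solvent_C_methyl", "solvent_N")])) {
    im <- which(a$role == "solvent_C_methyl" & a$group == g)
    inn <- which(a$role == "solvent_N" & a$group == g)
    mi <- if (length(im)) inside(vec3(a, im[1])) else c(FALSE, Inf)
    ni <- if (length(inn)) inside(vec3(a, inn[1])) else c(FALSE, Inf)
    if (mi[1] && (!ni[1] || mi[2] <= ni[2])) return("methyl_in")
    if (ni[1]) return("nitrile_in")
  }
  "none"
}

#' Internal-coordinate feature vector of a frame
#'
#' The coordination feature vector used for representative-structure
#' selection: (1) distances between the amide oxygens and the N-H
#' hydrogens of both ureas and between the urea oxygens and those N-H
#' hydrogens; (2) distances between Cl\eqn{^-} and the N-H hydrogens
#' (when Cl is present); (3) distances between Na\eqn{^+} and the ether,
#' amide and urea oxygens (when Na is present); plus, for every distance,
#' the corresponding angle (\eqn{\angle}N-H-O, \eqn{\angle}N-H-Cl,
#' \eqn{\angle}C-O-Na).  Atoms are ordered canonically (by role, group,
#' then distance to the host centroid), so the vector is invariant under
#' permutation of the input rows and under rigid-body motion (internal
#' coordinates only).
#'
#' @inheritParams na_coordination
#' @return named numeric vector; length depends only on which ions are
#'   present (the system type).
#' @export
feature_vector <- function(frame) {
  a <- frame$atoms
  host <- a$role %in% c("O_ether", "O_amide", "O_urea", "N_urea",
                        "H_ureaNH", "scaffold_ref")
  ctr <- colMeans(a[host, c("x", "y", "z")])
  pick <- function(role) {
    i <- which(a$role == role)
    key <- vapply(i, function(j) dist3(vec3(a, j), ctr), 0)
    i[order(a$group[i], key)]
  }
  o_am <- pick("O_amide"); o_ur <- pick("O_urea"); o_et <- pick("O_ether")
  hs <- pick("H_ureaNH")
  out <- c()
  dpair <- function(i, j) dist3(vec3(a, i), vec3(a, j))
  for (j in c(o_am, o_ur)) for (i in hs) {
    nm <- paste0("d_", a$role[j], a$group[j], "_", a$group[i])
    out <- c(out, stats::setNames(dpair(i, j), nm),
             stats::setNames(angle3(vec3(a, a$bonded_to[i]), vec3(a, i),
                                    vec3(a, j)), paste0("ang_", nm)))
  }
  icl <- which(a$role == "Cl")
  if (length(icl)) {
    cl <- vec3(a, icl[1])
    for (i in hs) {
      nm <- paste0("d_Cl_", a$group[i], "_",
                   which(hs == i))
      out <- c(out, stats::setNames(dist3(vec3(a, i), cl), nm),
               stats::setNames(angle3(vec3(a, a$bonded_to[i]), vec3(a, i),
                                      cl), paste0("ang_", nm)))
    }
  }
  ina <- which(a$role == "Na")
  if (length(ina)) {
    na <- vec3(a, ina[1])
    for (j in c(o_et, o_am, o_ur)) {
      nm <- paste0("d_Na_", a$role[j], "_", which(c(o_et, o_am, o_ur) == j))
      ang <- if (!is.na(a$bonded_to[j]))
        angle3(vec3(a, a$bonded_to[j]), vec3(a, j), na) else NA_real_
      out <- c(out, stats::setNames(dist3(vec3(a, j), na), nm),
               stats::setNames(ang, paste0("ang_", nm)))
    }
  }
  out
}

#' Full coordination signature of a frame
#'
#' @inheritParams solvent_inclusion
#' @return list with elements `Na`, `Cl`, `HB` (integer matrices or
#'   `NULL` when the ion is absent), `solvent` and a canonical `key`
#'   string.
#' @export
coordination_state <- function(frame, spec = basket_spec()) {
  a <- frame$atoms
  na <- if (any(a$role == "Na")) na_coordination(frame)
  cl <- if (any(a$role == "Cl")) cl_coordination(frame)
  hb <- hb_detect(frame)
  sv <- solvent_inclusion(frame, spec)
  fmt <- function(lbl, v) if (is.null(v)) NULL
    else sprintf("%s(%d,%d,%d)", lbl, v[1], v[2], v[3])
  key <- paste(c(fmt("Na", na), fmt("Cl", cl), fmt("HB", hb), sv),
               collapse = "|")
  list(Na = na, Cl = cl, HB = hb, solvent = sv, key = key)
}

#' Cluster frames by coordination signature with PCA representatives
#'
#' Frames are grouped by their discrete coordination signature
#' ([coordination_state()]); cluster populations are the corresponding
#' fractions of frames (percent of simulation time for equally spaced
#' frames).  Within each system type (frames sharing the same feature
#' layout), a principal component analysis of the feature vectors of the
#' whole ensemble defines a low-dimensional shape space, and the
#' representative of each cluster is the member frame closest (Euclidean)
#' to the cluster centroid in the space of the first three principal
#' components.
#'
#' @param frames list of [labeled_frame()] objects.
#' @param spec a [basket_spec()].
#' @return data frame (one row per cluster, sorted by decreasing
#'   population): `signature`, `n`, `population_pct`,
#'   `representative` (frame index).  The per-frame signatures are
#'   attached as attribute `"states"`.
#' @export
cluster_frames <- function(frames, spec = basket_spec()) {
  if (!length(frames)) stop("no frames given")
  states <- lapply(frames, coordination_state, spec = spec)
  keys <- vapply(states, `[[`, "", "key")
  feats <- lapply(frames, feature_vector)
  layout <- vapply(feats, function(f) paste(names(f), collapse = ";"), "")

  # PC1-3 scores per system type
  scores <- matrix(NA_real_, length(frames), 3)
  for (ly in unique(layout)) {
    idx <- which(layout == ly)
    X <- do.call(rbind, feats[idx])
    if (length(idx) < 2) { scores[idx, ] <- 0; next }
    keep <- apply(X, 2, function(v) stats::sd(v) > 1e-12)
    npc <- min(3, sum(keep), length(idx) - 1)
    if (npc >= 1 && sum(keep) >= 1) {
      pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE,
                          scale. = FALSE)
      sc <- pc$x[, seq_len(min(npc, ncol(pc$x))), drop = FALSE]
      scores[idx, seq_len(ncol(sc))] <- sc
      scores[idx, setdiff(1:3, seq_len(ncol(sc)))] <- 0
    } else scores[idx, ] <- 0
  }

  tab <- sort(table(keys), decreasing = TRUE)
  rows <- lapply(names(tab), function(k) {
    idx <- which(keys == k)
    ctr <- colMeans(scores[idx, , drop = FALSE])
    d2 <- rowSums((scores[idx, , drop = FALSE] -
                     matrix(ctr, length(idx), 3, byrow = TRUE))^2)
    data.frame(signature = k, n = length(idx),
               population_pct = 100 * length(idx) / length(frames),
               representative = idx[which.min(d2)])
  })
  out <- do.call(rbind, rows)
  attr(out, "states") <- states
  out
}
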
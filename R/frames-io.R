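#' Read and write labelled frames (XYZ + role map)
#'
#' Frames travel as standard multi-frame XYZ (atom label, x, y, z; one
#' block per frame, constant atom order) with a YAML sidecar mapping atom
#' labels to roles, group ids and bonded partners.  PDB input is accepted
#' too: atom names are looked up in the same role map (`MODEL` blocks
#' delimit frames).
#'
#' @param frames list of [labeled_frame()] (same atom layout in each).
#' @param path XYZ file path.
#' @param rolemap_path YAML role-map path.
#' @return `write_frames_xyz` invisibly returns its paths;
#'   `read_frames_xyz` / `read_frames_pdb` a list of `labeled_frame`s.
#' @export
write_frames_xyz <- function(frames, path, rolemap_path) {
  stopifnot(length(frames) >= 1)
  a0 <- frames[[1]]$atoms
  labels <- sprintf("%s%d", gsub("[^A-Za-z]", "", substr(a0$role, 1, 2)),
                    seq_len(nrow(a0)))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    a <- f$atoms
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("t=%s", format(f$time)), con)
    writeLines(sprintf("%-8s %12.6f %12.6f %12.6f", labels, a$x, a$y, a$z),
               con)
  }
  rm <- lapply(seq_len(nrow(a0)), function(i)
    c(list(label = labels[i], role = a0$role[i], group = a0$group[i]),
      if (!is.na(a0$bonded_to[i])) list(bonded_to = labels[a0$bonded_to[i]])))
  yaml::write_yaml(list(atoms = rm), rolemap_path)
  invisible(c(path, rolemap_path))
}

read_role_map <- function(rolemap_path) {
  rm <- yaml::read_yaml(rolemap_path)$atoms
  if (is.null(rm)) stop("role map ", rolemap_path, ": missing 'atoms' block")
  lab <- vapply(rm, function(e) as.character(e$label), "")
  data.frame(label = lab,
             role = vapply(rm, function(e) as.character(e$role), ""),
             group = vapply(rm, function(e) as.character(e$group %||% ""), ""),
             bonded_label = vapply(rm, function(e)
               as.character(e$bonded_to %||% NA_character_), ""),
             stringsAsFactors = FALSE)
}

assemble_frames <- function(coords, labels, rolemap, times) {
  m <- match(labels, rolemap$label)
  if (anyNA(m))
    stop("atoms not in role map: ",
         paste(unique(labels[is.na(m)]), collapse = ", "))
  bonded <- match(rolemap$bonded_label[m], labels)
  lapply(seq_along(coords), function(k) {
    labeled_frame(data.frame(role = rolemap$role[m],
                             group = rolemap$group[m],
                             x = coords[[k]][, 1], y = coords[[k]][, 2],
                             z = coords[[k]][, 3],
                             bonded_to = bonded), time = times[k])
  })
}

#' @rdname write_frames_xyz
#' @export
read_frames_xyz <- function(path, rolemap_path) {
  lines <- readLines(path)
  rolemap <- read_role_map(rolemap_path)
  coords <- list(); times <- numeric(0); labels <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, ": expected atom count")
    cm <- lines[i + 1L]
    tm <- suppressWarnings(as.numeric(sub("^t=", "", trimws(cm))))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    lab <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(labels)) labels <- lab
    else if (!identical(labels, lab))
      stop("atom order changes between frames")
    coords[[length(coords) + 1L]] <- xyz
    times <- c(times, if (is.na(tm)) length(coords) - 1 else tm)
    i <- i + 2L + n
  }
  assemble_frames(coords, labels, rolemap, times)
}

#' @rdname write_frames_xyz
#' @export
read_frames_pdb <- function(path, rolemap_path) {
  lines <- readLines(path)
  rolemap <- read_role_map(rolemap_path)
  coords <- list(); labels <- NULL
  cur <- NULL; curlab <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur)) {
      coords[[length(coords) + 1L]] <<- do.call(rbind, cur)
      if (is.null(labels)) labels <<- curlab
      else if (!identical(labels, curlab))
        stop("atom order changes between models")
    }
    cur <<- list(); curlab <<- character(0)
  }
  cur <- list(); curlab <- character(0)
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") flush()
    else if (substr(tag, 1, 4) %in% c("ATOM", "HETA")) {
      curlab <- c(curlab, trimws(substr(ln, 13, 16)))
      cur[[length(cur) + 1L]] <- as.numeric(c(substr(ln, 31, 38),
                                              substr(ln, 39, 46),
                                              substr(ln, 47, 54)))
    }
  }
  flush()
  assemble_frames(coords, labels, rolemap, seq_along(coords) - 1)
}

#' Per-frame signature table and cluster report export
#'
#' Writes the per-frame coordination signatures as CSV and the cluster
#' report as JSON; optionally writes the representative frames back as
#' XYZ.
#'
#' @param frames list of [labeled_frame()].
#' @param prefix output path prefix.
#' @param spec a [basket_spec()].
#' @return invisibly, the cluster report data frame.
#' @export
export_coordination_report <- function(frames, prefix,
                                       spec = basket_spec()) {
  rep <- cluster_frames(frames, spec)
  states <- attr(rep, "states")
  per_frame <- data.frame(
    frame = seq_along(frames) - 1L,
    signature = vapply(states, `[[`, "", "key"),
    solvent = vapply(states, `[[`, "", "solvent"))
  utils::write.csv(per_frame, paste0(prefix, "_signatures.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep, paste0(prefix, "_clusters.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  reps <- frames[rep$representative]
  write_frames_xyz(reps, paste0(prefix, "_representatives.xyz"),
                   paste0(prefix, "_rolemap.yaml"))
  invisible(rep)
}
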
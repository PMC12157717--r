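#' Define a solution-equilibrium model
#'
#' An `eq_model` collects everything needed to compute the composition of a
#' solution at equilibrium: the independent components, the soluble species
#' formed from them (each with a cumulative formation constant
#' \eqn{\beta = [\mathrm{species}] / \prod_i [\mathrm{comp}_i]^{\nu_i}} on the
#' log10 scale), and optional solid phases, each with a solubility product
#' \eqn{K_s = \prod_i [\mathrm{comp}_i]^{\nu_i}} at saturation (log10 scale).
#'
#' Every free component is itself carried as a species with identity
#' stoichiometry and `log_beta = 0`; the constructor adds these rows
#' automatically when they are not supplied.  Concentrations are
#' mol dm\eqn{^{-3}} throughout; activity coefficients are taken as unity
#' (constant ionic strength assumption).
#'
#' @param components character vector of unique component names.
#' @param species `NULL`, or a data frame with columns `name`, `log_beta` and
#'   one integer column per component (the stoichiometric coefficients).
#'   Alternatively a list of `list(name=, stoich=, log_beta=)` entries, where
#'   `stoich` is a named or positional integer vector over the components.
#' @param solids like `species` but with a `log_Ks` column / field, describing
#'   solid phases that may precipitate.
#' @param charges optional named integer vector of species charges, used by
#'   conductivity forward models to decide which species conduct.
#' @return an object of class `eq_model` with elements `components`,
#'   `species` (data frame `name`, `log_beta`), `stoich` (species x component
#'   integer matrix), `solids` (data frame `name`, `log_Ks`), `solid_stoich`
#'   (solid x component matrix) and `charges`.
#' @examples
#' # 1:1 complexation M + L <-> ML with log K = 6
#' m <- eq_model(c("M", "L"),
#'               species = list(list(name = "ML", stoich = c(M = 1, L = 1),
#'                                   log_beta = 6)))
#' @export
eq_model <- function(components, species = NULL, solids = NULL,
                     charges = NULL) {
  stopifnot(is.character(components), length(components) >= 1L)
  if (anyDuplicated(components))
    stop("component names must be unique")
  n <- length(components)

  parse_block <- function(x, kconst) {
    if (is.null(x))
      return(list(tab = data.frame(name = character()),
                  S = matrix(0L, 0L, n, dimnames = list(NULL, components)),
                  k = numeric()))
    if (is.data.frame(x)) {
      stopifnot(all(c("name", kconst) %in% names(x)),
                all(components %in% names(x)))
      S <- as.matrix(x[, components, drop = FALSE])
      nm <- as.character(x$name)
      k <- as.numeric(x[[kconst]])
    } else {
      nm <- vapply(x, function(e) as.character(e$name), "")
      k <- vapply(x, function(e) as.numeric(e[[kconst]]), 0)
      S <- t(vapply(x, function(e) {
        s <- e$stoich
        if (!is.null(names(s))) {
          out <- stats::setNames(numeric(n), components)
          if (!all(names(s) %in% components))
            stop("unknown component in stoichiometry: ",
                 paste(setdiff(names(s), components), collapse = ", "))
          out[names(s)] <- s
          out
        } else {
          if (length(s) != n) stop("stoichiometry length mismatch")
          as.numeric(s)
        }
      }, numeric(n)))
      colnames(S) <- components
    }
    if (any(S != round(S))) stop("stoichiometric coefficients must be integers")
    if (nrow(S) > 0 && any(rowSums(abs(S)) == 0))
      stop("every species/solid needs at least one nonzero coefficient")
    if (any(!is.finite(k)))
      stop("all log_beta / log_Ks must be finite")
    list(tab = data.frame(name = nm, stringsAsFactors = FALSE),
         S = S, k = k)
  }

  sp <- parse_block(species, "log_beta")
  so <- parse_block(solids, "log_Ks")

  # prepend the free components as identity species
  idS <- diag(n)
  colnames(idS) <- components
  have <- apply(sp$S, 1L, function(r) sum(r != 0) == 1L && any(r == 1)) &
    sp$k == 0
  # keep user species as-is; add any component not present as identity/beta 0
  keep <- rep(TRUE, n)
  S <- rbind(idS[keep, , drop = FALSE], sp$S)
  nm <- c(components[keep], sp$tab$name)
  lb <- c(rep(0, sum(keep)), sp$k)
  if (anyDuplicated(nm))
    stop("species names must be unique and must not repeat component names")
  if (nrow(so$S) > 0 && anyDuplicated(c(nm, so$tab$name)))
    stop("solid names must be unique")

  chg <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  if (!is.null(charges)) {
    bad <- setdiff(names(charges), nm)
    if (length(bad)) stop("charges given for unknown species: ",
                          paste(bad, collapse = ", "))
    chg[names(charges)] <- as.integer(charges)
  }

  structure(list(
    components = components,
    species = data.frame(name = nm, log_beta = lb, stringsAsFactors = FALSE),
    stoich = S,
    solids = data.frame(name = so$tab$name, log_Ks = so$k,
                        stringsAsFactors = FALSE),
    solid_stoich = so$S,
    charges = chg
  ), class = "eq_model")
}

#' @export
print.eq_model <- function(x, ...) {
  cat("<eq_model> ", length(x$components), " components: ",
      paste(x$components, collapse = ", "), "\n", sep = "")
  cat("  species:\n")
  for (j in seq_len(nrow(x$species))) {
    st <- x$stoich[j, ]
    lab <- paste(sprintf("%+d %s", st[st != 0], x$components[st != 0]),
                 collapse = " ")
    cat(sprintf("    %-12s log_beta = %-8.4g [%s]\n",
                x$species$name[j], x$species$log_beta[j], lab))
  }
  if (nrow(x$solids))
    for (k in seq_len(nrow(x$solids)))
      cat(sprintf("    solid %-6s log_Ks = %.4g\n",
                  x$solids$name[k], x$solids$log_Ks[k]))
  invisible(x)
}

#' Read / write an equilibrium model definition file
#'
#' The on-disk format is YAML with three blocks: `components` (list of
#' names), `species` and `solids` (each a list of records with `name`,
#' `stoich` (mapping component -> integer) and `log_beta` / `log_Ks`).
#'
#' @param path file path.
#' @return `read_eq_model` returns an [eq_model()]; `write_eq_model`
#'   (invisibly) its `path` argument.
#' @export
read_eq_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components))
    stop("model file ", path, ": missing 'components' block")
  as_entries <- function(block, kconst) {
    if (is.null(block)) return(NULL)
    lapply(block, function(e) {
      if (is.null(e$name) || is.null(e$stoich) || is.null(e[[kconst]]))
        stop("model file ", path, ": each entry needs name, stoich, ", kconst)
      list(name = e$name, stoich = unlist(e$stoich), log_beta = e[[kconst]])
    })
  }
  sp <- as_entries(cfg$species, "log_beta")
  so <- as_entries(cfg$solids, "log_Ks")
  if (!is.null(so))
    so <- lapply(so, function(e) list(name = e$name, stoich = e$stoich,
                                      log_Ks = e$log_beta))
  chg <- if (!is.null(cfg$charges)) unlist(cfg$charges) else NULL
  eq_model(unlist(cfg$components), species = sp, solids = so, charges = chg)
}

#' @rdname read_eq_model
#' @param model an [eq_model()].
#' @export
write_eq_model <- function(model, path) {
  stopifnot(inherits(model, "eq_model"))
  ncomp <- length(model$components)
  non_id <- which(!vapply(seq_len(nrow(model$stoich)), function(j) {
    r <- model$stoich[j, ]
    sum(r != 0) == 1L && any(r == 1) && model$species$log_beta[j] == 0
  }, TRUE))
  cfg <- list(
    components = as.list(model$components),
    species = lapply(non_id, function(j)
      list(name = model$species$name[j],
           stoich = as.list(stats::setNames(as.integer(model$stoich[j, ]),
                                            model$components)),
           log_beta = model$species$log_beta[j])),
    solids = lapply(seq_len(nrow(model$solids)), function(k)
      list(name = model$solids$name[k],
           stoich = as.list(stats::setNames(
             as.integer(model$solid_stoich[k, ]), model$components)),
           log_Ks = model$solids$log_Ks[k]))
  )
  ch <- model$charges[!is.na(model$charges)]
  if (length(ch)) cfg$charges <- as.list(ch)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
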
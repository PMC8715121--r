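#' Declarative kinetic schemes
#'
#' A kinetic scheme is an ordered set of enzyme states connected by
#' unimolecular or bimolecular (ligand-consuming) transitions.  Each
#' transition direction is labelled with the name of a rate constant held in
#' a [parameter_set()]; a direction that references a ligand is bimolecular
#' and its rate constant carries units of \code{/uM/s}, otherwise \code{/s}.
#' An absent reverse label makes the step irreversible.
#'
#' @param name scheme identifier.
#' @param states character vector of unique state names, in pathway order.
#' @param ligands character vector of ligand (free-species) names.
#' @param transitions a data.frame (or list of lists coerced to one) with
#'   columns \code{from}, \code{to}, \code{kf}, and optionally \code{kr},
#'   \code{ligand_f}, \code{ligand_r}.  \code{kf}/\code{kr} name parameters;
#'   \code{ligand_f} is the ligand consumed in the forward direction (and
#'   released in the reverse direction), \code{ligand_r} the converse.
#' @return an object of class \code{kinetic_scheme}.
#' @seealso [parameter_set()], [paper_fixture()], [rate_matrix()]
#' @examples
#' sc <- kinetic_scheme("two_state", c("A", "B"),
#'                      transitions = data.frame(from = "A", to = "B",
#'                                               kf = "kon", kr = "koff"))
#' @export
kinetic_scheme <- function(name, states, ligands = character(), transitions) {
  stopifnot(is.character(states), length(states) >= 1L)
  if (anyDuplicated(states)) stop("state names must be unique")
  if (length(intersect(states, ligands)))
    stop("ligand names must be distinct from state names")
  tr <- as.data.frame(transitions, stringsAsFactors = FALSE)
  for (col in c("kr", "ligand_f", "ligand_r"))
    if (is.null(tr[[col]])) tr[[col]] <- rep(NA_character_, nrow(tr))
  tr <- tr[, c("from", "to", "kf", "kr", "ligand_f", "ligand_r")]
  bad <- setdiff(c(tr$from, tr$to), states)
  if (length(bad)) stop("transition endpoint not a declared state: ",
                        paste(bad, collapse = ", "))
  badl <- setdiff(stats::na.omit(c(tr$ligand_f, tr$ligand_r)), ligands)
  if (length(badl)) stop("transition references undeclared ligand: ",
                         paste(badl, collapse = ", "))
  structure(list(name = name, states = states, ligands = ligands,
                 transitions = tr),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", length(x$states), " states, ",
      nrow(x$transitions), " transitions\n", sep = "")
  tr <- x$transitions
  for (i in seq_len(nrow(tr))) {
    lf <- if (!is.na(tr$ligand_f[i])) paste0(" + ", tr$ligand_f[i]) else ""
    arrow <- if (is.na(tr$kr[i])) " -> " else " <-> "
    cat("  ", tr$from[i], lf, arrow, tr$to[i],
        "   [", tr$kf[i],
        if (!is.na(tr$kr[i])) paste0("/", tr$kr[i]) else "", "]\n", sep = "")
  }
  invisible(x)
}

#' Rate-constant sets
#'
#' Holds named, strictly positive rate constants with units, lock flags,
#' optional box bounds, and optional linkage-group labels (parameters in one
#' group are constrained equal during global fitting).  Units are
#' normalized internally to micromolar and seconds: \code{/s} for
#' unimolecular and \code{/uM/s} for bimolecular constants.  \code{/mM/s}
#' and \code{/nM/s} are accepted on input and converted.
#'
#' @param ... named parameter entries.  Each may be a bare positive number
#'   (units \code{/s}) or a list with elements \code{value}, \code{units},
#'   \code{locked}, \code{lower}, \code{upper}, \code{link_group}.
#' @return an object of class \code{parameter_set}: a data.frame with one
#'   row per parameter.
#' @examples
#' ps <- parameter_set(kon = list(value = 10, units = "/uM/s", locked = TRUE),
#'                     koff = 15000)
#' @export
parameter_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) &&
      is.null(entries[[1L]]$value) && !is.null(names(entries[[1L]])))
    entries <- entries[[1L]]
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("all parameters must be named")
  if (anyDuplicated(names(entries))) stop("duplicate parameter name")
  one <- function(e) {
    if (!is.list(e)) e <- list(value = e)
    units <- e$units %||% "/s"
    conv <- c("/s" = 1, "/uM/s" = 1, "/mM/s" = 1e-3, "/nM/s" = 1e3)
    if (!units %in% names(conv)) stop("unknown units: ", units)
    val <- e$value * conv[[units]]
    if (!is.finite(val) || val <= 0) stop("parameter values must be strictly positive")
    data.frame(value = val,
               units = if (units == "/s") "/s" else "/uM/s",
               locked = isTRUE(e$locked),
               lower = e$lower %||% NA_real_,
               upper = e$upper %||% NA_real_,
               link_group = e$link_group %||% NA_character_,
               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, lapply(entries, one))
  df <- cbind(name = names(entries), df)
  rownames(df) <- df$name
  class(df) <- c("parameter_set", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.parameter_set <- function(x, ...) {
  cat("Parameter set (", nrow(x), " rate constants)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Extract parameter values
#' @param params a [parameter_set()].
#' @param names optional character vector selecting parameters.
#' @return named numeric vector of values (uM, s units).
#' @export
param_values <- function(params, names = NULL) {
  v <- stats::setNames(params$value, params$name)
  if (!is.null(names)) {
    miss <- setdiff(names, params$name)
    if (length(miss)) stop("missing parameter: ", paste(miss, collapse = ", "))
    v <- v[names]
  }
  v
}

#' Replace parameter values
#' @param params a [parameter_set()].
#' @param values named numeric vector of replacement values (uM, s units).
#' @return the updated parameter set.
#' @export
set_param_values <- function(params, values) {
  miss <- setdiff(names(values), params$name)
  if (length(miss)) stop("missing parameter: ", paste(miss, collapse = ", "))
  if (any(values <= 0)) stop("parameter values must be strictly positive")
  params[names(values), "value"] <- unname(values)
  params
}

## Check that a parameter set covers a scheme and that units match each
## transition's molecularity.
check_scheme_params <- function(scheme, params) {
  tr <- scheme$transitions
  need <- stats::na.omit(c(tr$kf, tr$kr))
  miss <- setdiff(need, params$name)
  if (length(miss))
    stop("missing parameter: ", paste(unique(miss), collapse = ", "))
  for (i in seq_len(nrow(tr))) {
    uf <- params[tr$kf[i], "units"]
    want_f <- if (is.na(tr$ligand_f[i])) "/s" else "/uM/s"
    if (uf != want_f)
      stop("parameter ", tr$kf[i], " has units ", uf, " but transition ",
           tr$from[i], "->", tr$to[i], " requires ", want_f)
    if (!is.na(tr$kr[i])) {
      ur <- params[tr$kr[i], "units"]
      want_r <- if (is.na(tr$ligand_r[i])) "/s" else "/uM/s"
      if (ur != want_r)
        stop("parameter ", tr$kr[i], " has units ", ur, " but transition ",
             tr$to[i], "->", tr$from[i], " requires ", want_r)
    }
  }
  invisible(TRUE)
}

#' Pseudo-first-order rate matrix
#'
#' Builds the matrix \eqn{M} of the linear system \eqn{dx/dt = Mx} over the
#' scheme's states, with bimolecular steps folded in at fixed ligand
#' concentrations (pseudo-first-order approximation, valid when free ligand
#' is in large excess over the enzyme pool).  Column sums are zero, which
#' expresses conservation of the enzyme pool.
#'
#' @param scheme a [kinetic_scheme()].
#' @param params a [parameter_set()] covering the scheme.
#' @param ligand_concs named numeric vector of ligand concentrations (uM).
#' @return numeric matrix with dimnames equal to the scheme states.
#' @export
rate_matrix <- function(scheme, params, ligand_concs = NULL) {
  check_scheme_params(scheme, params)
  lc <- ligand_conc_vector(scheme, ligand_concs)
  n <- length(scheme$states)
  M <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  v <- param_values(params)
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    kf <- v[[tr$kf[i]]] * (if (is.na(tr$ligand_f[i])) 1 else lc[[tr$ligand_f[i]]])
    M[tr$to[i], tr$from[i]] <- M[tr$to[i], tr$from[i]] + kf
    M[tr$from[i], tr$from[i]] <- M[tr$from[i], tr$from[i]] - kf
    if (!is.na(tr$kr[i])) {
      kr <- v[[tr$kr[i]]] * (if (is.na(tr$ligand_r[i])) 1 else lc[[tr$ligand_r[i]]])
      M[tr$from[i], tr$to[i]] <- M[tr$from[i], tr$to[i]] + kr
      M[tr$to[i], tr$to[i]] <- M[tr$to[i], tr$to[i]] - kr
    }
  }
  M
}

ligand_conc_vector <- function(scheme, ligand_concs) {
  lc <- stats::setNames(rep(0, length(scheme$ligands)), scheme$ligands)
  if (length(ligand_concs)) {
    bad <- setdiff(names(ligand_concs), scheme$ligands)
    if (length(bad)) stop("unknown ligand: ", paste(bad, collapse = ", "))
    if (any(ligand_concs < 0)) stop("ligand concentrations must be non-negative")
    lc[names(ligand_concs)] <- ligand_concs
  }
  lc
}

#' Mass-action derivative operator
#'
#' Returns the time-derivative function of the scheme's mass-action rate
#' equations.  In \code{"pseudo"} mode ligands are held at fixed
#' concentrations and the system is linear in the state vector; in
#' \code{"explicit"} mode ligands are tracked species appended after the
#' states and bimolecular steps are second order.
#'
#' @inheritParams rate_matrix
#' @param mode \code{"pseudo"} or \code{"explicit"}.
#' @return a function taking a named (or scheme-ordered) concentration
#'   vector and returning its derivative (uM/s).  In explicit mode the
#'   vector covers \code{c(states, ligands)}.
#' @export
build_rate_equations <- function(scheme, params, ligand_concs = NULL,
                                 mode = c("pseudo", "explicit")) {
  mode <- match.arg(mode)
  if (mode == "pseudo") {
    M <- rate_matrix(scheme, params, ligand_concs)
    return(function(x) drop(M %*% as.numeric(x[scheme$states])))
  }
  check_scheme_params(scheme, params)
  v <- param_values(params)
  tr <- scheme$transitions
  species <- c(scheme$states, scheme$ligands)
  function(x) {
    x <- as.numeric(x[species])
    names(x) <- species
    dx <- stats::setNames(numeric(length(species)), species)
    for (i in seq_len(nrow(tr))) {
      f <- v[[tr$kf[i]]] * x[[tr$from[i]]] *
        (if (is.na(tr$ligand_f[i])) 1 else x[[tr$ligand_f[i]]])
      r <- if (is.na(tr$kr[i])) 0 else
        v[[tr$kr[i]]] * x[[tr$to[i]]] *
          (if (is.na(tr$ligand_r[i])) 1 else x[[tr$ligand_r[i]]])
      net <- f - r
      dx[[tr$from[i]]] <- dx[[tr$from[i]]] - net
      dx[[tr$to[i]]] <- dx[[tr$to[i]]] + net
      if (!is.na(tr$ligand_f[i]))
        dx[[tr$ligand_f[i]]] <- dx[[tr$ligand_f[i]]] - net
      if (!is.na(tr$ligand_r[i]))
        dx[[tr$ligand_r[i]]] <- dx[[tr$ligand_r[i]]] + net
    }
    dx
  }
}

#' Ligand stoichiometry of each state
#'
#' Number of molecules of each ligand carried by each state (bound or
#' incorporated), determined by walking the transition graph from the first
#' state of each connected pool.  Used for conservation accounting in
#' explicit-ligand mode.
#'
#' @param scheme a [kinetic_scheme()].
#' @return integer matrix states x ligands.
#' @export
ligand_stoichiometry <- function(scheme) {
  states <- scheme$states
  ligs <- scheme$ligands
  st <- matrix(NA_integer_, length(states), length(ligs),
               dimnames = list(states, ligs))
  if (length(ligs) == 0L) { st[] <- integer(0); return(st) }
  tr <- scheme$transitions
  lig_delta <- function(i) {  # ligand gain crossing transition i forward
    d <- stats::setNames(integer(length(ligs)), ligs)
    if (!is.na(tr$ligand_f[i])) d[[tr$ligand_f[i]]] <- d[[tr$ligand_f[i]]] + 1L
    if (!is.na(tr$ligand_r[i])) d[[tr$ligand_r[i]]] <- d[[tr$ligand_r[i]]] - 1L
    d
  }
  for (root in states) {
    if (!anyNA(st[root, ])) next
    st[root, ] <- 0L
    queue <- root
    while (length(queue)) {
      s <- queue[[1L]]; queue <- queue[-1L]
      for (i in seq_len(nrow(tr))) {
        if (tr$from[i] == s) { nb <- tr$to[i];   cand <- st[s, ] + lig_delta(i) }
        else if (tr$to[i] == s) { nb <- tr$from[i]; cand <- st[s, ] - lig_delta(i) }
        else next
        if (anyNA(st[nb, ])) {
          st[nb, ] <- cand
          queue <- c(queue, nb)
        } else if (any(st[nb, ] != cand)) {
          stop("inconsistent ligand stoichiometry at state ", nb)
        }
      }
    }
  }
  st
}

#' Conserved totals
#'
#' One total per connected conserved pool of states (the enzyme-DNA pool for
#' a connected scheme) and, in explicit-ligand mode, one total per ligand
#' counting free plus state-bound/incorporated molecules.
#'
#' @param scheme a [kinetic_scheme()].
#' @param init named concentration vector (uM) over states and, in explicit
#'   mode, ligands.  Missing entries are zero.
#' @param mode \code{"pseudo"} (state pools only) or \code{"explicit"}.
#' @return named numeric vector of totals (uM).
#' @export
conservation_totals <- function(scheme, init, mode = c("pseudo", "explicit")) {
  mode <- match.arg(mode)
  if (any(init < 0)) stop("initial concentrations must be non-negative")
  x <- stats::setNames(rep(0, length(scheme$states) + length(scheme$ligands)),
                       c(scheme$states, scheme$ligands))
  bad <- setdiff(names(init), names(x))
  if (length(bad)) stop("unknown species in init: ", paste(bad, collapse = ", "))
  x[names(init)] <- init
  comp <- state_pools(scheme)
  totals <- vapply(comp, function(states) sum(x[states]), numeric(1))
  names(totals) <- paste0("pool.", vapply(comp, `[[`, "", 1L))
  if (mode == "explicit" && length(scheme$ligands)) {
    st <- ligand_stoichiometry(scheme)
    lig <- vapply(scheme$ligands, function(L)
      x[[L]] + sum(st[, L] * x[scheme$states]), numeric(1))
    totals <- c(totals, lig)
  }
  totals
}

## Connected components of the state graph (ligands ignored).
state_pools <- function(scheme) {
  states <- scheme$states
  parent <- stats::setNames(seq_along(states), states)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    a <- find(match(tr$from[i], states)); b <- find(match(tr$to[i], states))
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(seq_along(states), find, numeric(1))
  lapply(unique(roots), function(r) states[roots == r])
}
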
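#' Integrate a kinetic scheme into a time course
#'
#' Numerically integrates the mass-action rate equations of a scheme.  In
#' pseudo-first-order mode the system is linear and by default solved
#' exactly through the matrix exponential (eigendecomposition with a
#' scaling-and-squaring fallback); \code{method = "lsoda"} forces stiff ODE
#' integration with the analytic Jacobian, which is also used for
#' explicit-ligand (second-order) systems.  Rate constants in these
#' mechanisms span about eight orders of magnitude, hence the tight default
#' tolerances.
#'
#' @inheritParams rate_matrix
#' @param init named initial concentrations (uM) over states (and ligands
#'   in explicit mode; ligands missing from \code{init} are taken from
#'   \code{ligand_concs}).
#' @param times numeric vector of output times (s), starting at 0,
#'   strictly increasing.
#' @param mode \code{"pseudo"} (ligands fixed) or \code{"explicit"}
#'   (ligands tracked as species).
#' @param method \code{"auto"} (matrix exponential when linear, else
#'   lsoda), \code{"expm"}, or \code{"lsoda"}.
#' @param rtol,atol integrator tolerances (relative; absolute, uM).
#' @return a \code{time_course}: data.frame with column \code{time} and one
#'   column per species, plus attributes \code{scheme}, \code{ligand_concs}
#'   and \code{mode}.
#' @examples
#' fx <- paper_fixture("fig3_binding")
#' tc <- integrate_scheme(fx$scheme, fx$params, c(ED = 0.2),
#'                        ligand_concs = c(dTTP = 3000),
#'                        times = seq(0, 0.05, length.out = 51))
#' @export
integrate_scheme <- function(scheme, params, init, ligand_concs = NULL,
                             times, mode = c("pseudo", "explicit"),
                             method = c("auto", "expm", "lsoda"),
                             rtol = 1e-8, atol = 1e-12) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (times[1] != 0) stop("times must start at 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  species <- if (mode == "pseudo") scheme$states else
    c(scheme$states, scheme$ligands)
  x0 <- stats::setNames(rep(0, length(species)), species)
  bad <- setdiff(names(init), species)
  if (length(bad)) stop("unknown species in init: ", paste(bad, collapse = ", "))
  x0[names(init)] <- init
  if (mode == "explicit" && length(ligand_concs)) {
    fill <- setdiff(intersect(names(ligand_concs), scheme$ligands), names(init))
    x0[fill] <- ligand_concs[fill]
  }
  if (any(x0 < 0)) stop("initial concentrations must be non-negative")

  if (mode == "pseudo" && method != "lsoda") {
    M <- rate_matrix(scheme, params, ligand_concs)
    out <- linear_trajectory(M, x0, times)
  } else {
    if (mode == "pseudo") {
      M <- rate_matrix(scheme, params, ligand_concs)
      func <- function(t, x, p) list(drop(M %*% x))
      jac <- function(t, x, p) M
      sol <- try(deSolve::lsoda(x0, times, func, parms = NULL, jacfunc = jac,
                                jactype = "fullusr", rtol = rtol, atol = atol),
                 silent = TRUE)
    } else {
      deriv <- build_rate_equations(scheme, params, mode = "explicit")
      func <- function(t, x, p) list(deriv(x))
      sol <- try(deSolve::lsoda(x0, times, func, parms = NULL,
                                rtol = rtol, atol = atol), silent = TRUE)
    }
    if (inherits(sol, "try-error") || nrow(sol) < length(times))
      stop("integrator failure for scheme '", scheme$name, "' (params: ",
           paste(sprintf("%s=%g", params$name, params$value), collapse = ", "),
           ")")
    out <- as.matrix(sol[, species, drop = FALSE])
  }
  if (min(out) < -1e-9)
    warning("negative concentrations beyond tolerance: min = ", min(out))
  out[out < 0] <- 0
  tc <- data.frame(time = times, out, check.names = FALSE)
  attr(tc, "scheme") <- scheme$name
  attr(tc, "ligand_concs") <- ligand_concs
  attr(tc, "ligands") <- scheme$ligands
  attr(tc, "mode") <- mode
  class(tc) <- c("time_course", "data.frame")
  tc
}

## Trajectory of dx/dt = M x via eigendecomposition; falls back to
## scaling-and-squaring when the eigenbasis is ill-conditioned.
linear_trajectory <- function(M, x0, times) {
  n <- length(x0)
  out <- matrix(0, length(times), n, dimnames = list(NULL, names(x0)))
  ev <- eigen(M)
  c0 <- tryCatch(solve(ev$vectors, x0), error = function(e) NULL)
  ok <- !is.null(c0) &&
    max(abs(ev$vectors %*% c0 - x0)) <= 1e-9 * max(1, max(abs(x0)))
  if (ok) {
    for (i in seq_along(times))
      out[i, ] <- Re(ev$vectors %*% (exp(ev$values * times[i]) * c0))
  } else {
    for (i in seq_along(times))
      out[i, ] <- drop(mat_exp(M * times[i]) %*% x0)
  }
  out
}

## Matrix exponential by scaling and squaring with a Taylor/Pade-free
## series; adequate for the small (<=12 state) systems used here.
mat_exp <- function(A) {
  n <- nrow(A)
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(n) + As
  term <- As
  for (k in 2:30) {
    term <- term %*% As / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Fluorescence observable specification
#'
#' Defines how state concentrations project onto a fluorescence signal:
#' \code{signal = A1 * sum(b_state * conc)} attenuated by the inner-filter
#' factor [inner_filter_factor()] at the prevailing absorbing-ligand
#' concentration.  Per-state factors default to 1.
#'
#' @param A1 baseline scaling factor (arbitrary units, > 0).
#' @param state_factors named numeric vector of per-state fluorescence
#'   factors (dimensionless); omitted states get 1.
#' @param q inner-filter attenuation coefficient per uM (pathlength/2 times
#'   extinction coefficient); 0 disables attenuation.
#' @param per_trace_multipliers optional named numeric vector of per-trace
#'   scaling factors.
#' @return an object of class \code{observable_spec}.
#' @export
observable_spec <- function(A1 = 1, state_factors = numeric(), q = 0,
                            per_trace_multipliers = NULL) {
  if (!is.finite(A1) || A1 <= 0) stop("A1 must be positive")
  if (!is.finite(q) || q < 0) stop("q must be non-negative")
  if (length(state_factors) && !all(is.finite(state_factors)))
    stop("state factors must be finite")
  structure(list(A1 = A1, state_factors = state_factors, q = q,
                 per_trace_multipliers = per_trace_multipliers),
            class = "observable_spec")
}

#' Inner-filter attenuation factor
#'
#' Beer-Lambert correction factor \eqn{(1 - 10^{-qL}) / (\ln(10) qL)} for
#' attenuation of fluorescence excitation by an absorbing ligand at
#' concentration L; continuous with value 1 at \eqn{qL = 0} and strictly
#' decreasing.
#'
#' @param qL product of the attenuation coefficient (per uM) and the
#'   ligand concentration (uM); non-negative.
#' @return attenuation factor in (0, 1].
#' @export
inner_filter_factor <- function(qL) {
  if (any(qL < 0)) stop("qL must be non-negative")
  ifelse(qL == 0, 1, -expm1(-log(10) * qL) / (log(10) * qL))
}

#' Project a time course onto a fluorescence signal
#'
#' @param tc a \code{time_course} from [integrate_scheme()].
#' @param obs an [observable_spec()].
#' @param ligand_conc attenuating ligand concentration (uM) for the
#'   inner-filter factor.
#' @param trace_id optional trace identifier selecting a per-trace
#'   multiplier from \code{obs}.
#' @return numeric signal vector, one value per time point.
#' @export
project_observable <- function(tc, obs, ligand_conc = 0, trace_id = NULL) {
  stopifnot(inherits(obs, "observable_spec"))
  states <- setdiff(colnames(tc), c("time", attr(tc, "ligands")))
  b <- stats::setNames(rep(1, length(states)), states)
  b[intersect(names(obs$state_factors), states)] <-
    obs$state_factors[intersect(names(obs$state_factors), states)]
  sig <- as.matrix(tc[, states, drop = FALSE]) %*% b * obs$A1
  sig <- drop(sig) * inner_filter_factor(obs$q * ligand_conc)
  if (!is.null(trace_id) && !is.null(obs$per_trace_multipliers) &&
      trace_id %in% names(obs$per_trace_multipliers))
    sig <- sig * obs$per_trace_multipliers[[trace_id]]
  sig
}

## Tree-structured equilibrium solve in explicit-ligand mode.  Each state's
## equilibrium concentration is written as (path product of step equilibrium
## constants) x (root concentration) x (free ligand ^ stoichiometry); the
## free-ligand level is found by root-finding on its conservation equation.
## Requires every step reversible and a single ligand.
equilibrium_state <- function(scheme, params, totals) {
  tr <- scheme$transitions
  if (anyNA(tr$kr))
    stop("equilibrium solve requires all steps reversible")
  if (length(scheme$ligands) != 1L)
    stop("equilibrium solve supports exactly one ligand")
  lig <- scheme$ligands
  v <- param_values(params)
  st <- ligand_stoichiometry(scheme)
  ## path coefficients relative to each pool root
  coef <- stats::setNames(rep(NA_real_, length(scheme$states)), scheme$states)
  pools <- state_pools(scheme)
  for (pool in pools) {
    coef[pool[1L]] <- 1
    queue <- pool[1L]
    while (length(queue)) {
      s <- queue[[1L]]; queue <- queue[-1L]
      for (i in seq_len(nrow(tr))) {
        K <- v[[tr$kf[i]]] / v[[tr$kr[i]]]
        if (tr$from[i] == s && is.na(coef[tr$to[i]])) {
          coef[tr$to[i]] <- coef[s] * K
          queue <- c(queue, tr$to[i])
        } else if (tr$to[i] == s && is.na(coef[tr$from[i]])) {
          coef[tr$from[i]] <- coef[s] / K
          queue <- c(queue, tr$from[i])
        }
      }
    }
  }
  pool_totals <- vapply(pools, function(p)
    sum(totals[p], na.rm = TRUE), numeric(1))
  lig_total <- if (lig %in% names(totals)) totals[[lig]] else 0
  state_concs_at <- function(free) {
    x <- numeric(0)
    for (j in seq_along(pools)) {
      p <- pools[[j]]
      w <- coef[p] * free^st[p, lig]
      x <- c(x, w / sum(w) * pool_totals[j])
    }
    x[scheme$states]
  }
  g <- function(free) {
    x <- state_concs_at(free)
    free + sum(st[, lig] * x) - lig_total
  }
  if (lig_total <= 0) {
    free <- 0
  } else if (g(lig_total) <= 0) {
    free <- lig_total
  } else {
    free <- stats::uniroot(g, c(0, lig_total), tol = 1e-14 * max(1, lig_total))$root
  }
  c(state_concs_at(free), stats::setNames(free, lig))
}

#' Stepwise equilibrium titration
#'
#' Simulates titrating a ligand stock into a cuvette in small volume steps
#' with full re-equilibration after each addition (the stepping is slow
#' compared with all binding relaxations).  Dilution of the cell contents
#' is applied cumulatively; after all additions the dilution factor is
#' V0 / (V0 + sum of added volumes).
#'
#' @inheritParams rate_matrix
#' @param cell_init named initial concentrations (uM) in the cell.
#' @param cell_volume initial cell volume (uL).
#' @param titrant ligand name being titrated.
#' @param step_volumes numeric vector of addition volumes (uL).
#' @param titrant_stock stock concentration of the titrant (uM).
#' @return data.frame with one row per titration point (including the
#'   zero-addition start): total titrant concentration, dilution factor,
#'   equilibrium concentrations of all states and the free titrant.
#' @export
simulate_titration <- function(scheme, params, cell_init, cell_volume,
                               titrant, step_volumes, titrant_stock) {
  if (!titrant %in% scheme$ligands) stop("unknown titrant: ", titrant)
  check_scheme_params(scheme, params)
  species <- c(scheme$states, scheme$ligands)
  tot <- stats::setNames(rep(0, length(species)), species)
  tot[names(cell_init)] <- cell_init
  ## per-species conserved totals (states summed into pools inside solver)
  st <- ligand_stoichiometry(scheme)
  totals <- c(tot[scheme$states],
              stats::setNames(tot[[titrant]] +
                                sum(st[, titrant] * tot[scheme$states]),
                              titrant))
  V <- cell_volume
  rows <- list()
  eq <- equilibrium_state(scheme, params, totals)
  rows[[1L]] <- c(titrant_total = unname(totals[[titrant]]),
                  dilution = 1, eq)
  for (j in seq_along(step_volumes)) {
    dV <- step_volumes[j]
    Vnew <- V + dV
    totals <- totals * V / Vnew
    totals[[titrant]] <- totals[[titrant]] + titrant_stock * dV / Vnew
    V <- Vnew
    eq <- equilibrium_state(scheme, params, totals)
    rows[[j + 1L]] <- c(titrant_total = unname(totals[[titrant]]),
                        dilution = cell_volume / V, eq)
  }
  as.data.frame(do.call(rbind, rows))
}

#' Ligand-trap dissociation experiment
#'
#' Simulates mixing a pre-equilibrated labelled complex with a large excess
#' of unlabelled trap: from t = 0 re-association of the released ligand to
#' the labelled complex is abolished (association rate set to zero) and the
#' decay of the bound complex is followed.  The trap itself is not modelled
#' explicitly because in vast excess it makes rebinding negligible.
#'
#' @inheritParams rate_matrix
#' @param init named pre-mix concentrations (uM; states and free ligand).
#'   The mixture is first brought to equilibrium.
#' @param trapped_ligand ligand whose re-association is abolished.
#' @param times output times (s), starting at 0.
#' @return a \code{time_course} over states and ligands (explicit mode),
#'   with attribute \code{bound} giving the total ligand-bound state
#'   concentration at each time.
#' @export
simulate_trap <- function(scheme, params, init, trapped_ligand, times) {
  if (!trapped_ligand %in% scheme$ligands)
    stop("unknown ligand: ", trapped_ligand)
  check_scheme_params(scheme, params)
  st <- ligand_stoichiometry(scheme)
  totals <- c(stats::setNames(rep(0, length(scheme$states)), scheme$states),
              stats::setNames(0, trapped_ligand))
  known <- intersect(names(init), names(totals))
  totals[known] <- totals[known] + init[known]
  free0 <- if (trapped_ligand %in% names(init)) init[[trapped_ligand]] else 0
  totals[[trapped_ligand]] <- free0 +
    sum(st[, trapped_ligand] * totals[scheme$states], na.rm = TRUE)
  x0 <- equilibrium_state(scheme, params, totals)
  ## abolish association of the trapped ligand
  tr <- scheme$transitions
  p2 <- params
  zero_rate <- 1e-300  # parameters must stay positive; effectively zero
  for (i in seq_len(nrow(tr))) {
    if (!is.na(tr$ligand_f[i]) && tr$ligand_f[i] == trapped_ligand)
      p2[tr$kf[i], "value"] <- zero_rate
    if (!is.na(tr$ligand_r[i]) && tr$ligand_r[i] == trapped_ligand &&
        !is.na(tr$kr[i]))
      p2[tr$kr[i], "value"] <- zero_rate
  }
  tc <- integrate_scheme(scheme, p2, x0, times = times, mode = "explicit",
                         method = "lsoda")
  bound_states <- scheme$states[st[, trapped_ligand] > 0]
  attr(tc, "bound") <- rowSums(tc[, bound_states, drop = FALSE])
  tc
}

#' Flux partitioning between branches of a mechanism
#'
#' Integrates the instantaneous flux through each branch's designated
#' product-forming transitions over the reaction and reports the fraction
#' of total product routed through each branch.  Fluxes are net (forward
#' minus reverse) by default; \code{kind = "oneway"} integrates the forward
#' flux only.
#'
#' @inheritParams integrate_scheme
#' @param branches named list mapping each branch to the forward-rate
#'   parameter names of its product-forming transitions (disjoint across
#'   branches).
#' @param t_end end time (s); must capture at least 99 percent of product
#'   formation (checked by comparing with integration to 2 t_end).
#' @param kind \code{"net"} or \code{"oneway"}.
#' @return named numeric vector of branch fractions (summing to 1), with
#'   attribute \code{flux} giving the absolute integrated fluxes (uM).
#' @export
flux_partition <- function(scheme, params, init, ligand_concs, branches,
                           t_end, kind = c("net", "oneway")) {
  kind <- match.arg(kind)
  check_scheme_params(scheme, params)
  tr <- scheme$transitions
  all_named <- unlist(branches)
  if (anyDuplicated(all_named))
    stop("branches must designate disjoint transitions")
  miss <- setdiff(all_named, tr$kf)
  if (length(miss)) stop("unknown transition parameter: ",
                         paste(miss, collapse = ", "))
  M <- rate_matrix(scheme, params, ligand_concs)
  v <- param_values(params)
  lc <- ligand_conc_vector(scheme, ligand_concs)
  nb <- length(branches)
  n <- length(scheme$states)
  ## augmented linear system: running integrals of branch fluxes
  B <- matrix(0, nb, n, dimnames = list(names(branches), scheme$states))
  for (b in seq_len(nb)) {
    for (kf_name in branches[[b]]) {
      i <- which(tr$kf == kf_name)
      keff <- v[[kf_name]] * (if (is.na(tr$ligand_f[i])) 1 else lc[[tr$ligand_f[i]]])
      B[b, tr$from[i]] <- B[b, tr$from[i]] + keff
      if (kind == "net" && !is.na(tr$kr[i])) {
        kr <- v[[tr$kr[i]]] * (if (is.na(tr$ligand_r[i])) 1 else lc[[tr$ligand_r[i]]])
        B[b, tr$to[i]] <- B[b, tr$to[i]] - kr
      }
    }
  }
  Maug <- rbind(cbind(M, matrix(0, n, nb)),
                cbind(B, matrix(0, nb, nb)))
  x0 <- stats::setNames(rep(0, n + nb),
                        c(scheme$states, names(branches)))
  x0[names(init)] <- init
  run <- function(tend) {
    xT <- linear_trajectory(Maug, x0, c(0, tend))[2L, ]
    xT[names(branches)]
  }
  flux <- run(t_end)
  flux2 <- run(2 * t_end)
  if (sum(flux2) > 0 && sum(flux) < 0.99 * sum(flux2))
    stop("t_end captures less than 99% of product formation")
  if (sum(flux) <= 0)
    stop("no product formed by t_end; branch fractions undefined")
  frac <- flux / sum(flux)
  attr(frac, "flux") <- flux
  frac
}
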
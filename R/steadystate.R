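#' King-Altman steady-state reduction
#'
#' Reduces a single-substrate catalytic mechanism to its steady-state
#' parameters kcat, Km and kcat/Km.  The absorbing product state is
#' recycled to the free-enzyme state (product release treated as
#' irreversible), the steady-state distribution is solved from the rate
#' matrix at a set of substrate concentrations, and the exact hyperbolic
#' dependence v(S) = kcat S / (Km + S) is recovered from three
#' concentrations and cross-validated at twelve more spanning six decades
#' (to one part in 1e6) — the numerical equivalent of the spanning-tree
#' reduction, robust for any mechanism whose velocity is hyperbolic in
#' substrate.
#'
#' @param scheme a [kinetic_scheme()] describing one catalytic cycle
#'   (at most 8 states); all bimolecular steps must use \code{substrate}.
#' @param params a [parameter_set()].
#' @param substrate ligand acting as the substrate.
#' @return an object of class \code{steady_state_summary}: \code{kcat}
#'   (/s), \code{Km} (uM), \code{kcat_over_Km} (/uM/s) and
#'   \code{kcat_over_Km_M} (/M/s), plus the stepwise equilibrium constants
#'   \code{K} of the reversible steps.
#' @examples
#' fx <- paper_fixture("fig7_misincorporation", variant = "two_step")
#' king_altman(fx$scheme, fx$params, "dTTP")
#' @export
king_altman <- function(scheme, params, substrate = scheme$ligands[1]) {
  check_scheme_params(scheme, params)
  if (length(scheme$states) > 8)
    stop("unsupported topology: more than 8 states")
  if (!substrate %in% scheme$ligands)
    stop("unknown substrate ligand: ", substrate)
  if (length(scheme$ligands) != 1L)
    stop("unsupported topology: multi-substrate scheme")
  ## terminal (absorbing) states recycle to the first state
  tr <- scheme$transitions
  out_deg <- vapply(scheme$states, function(s)
    sum(tr$from == s) + sum(tr$to == s & !is.na(tr$kr)), numeric(1))
  terminals <- scheme$states[out_deg == 0]
  if (!length(terminals))
    stop("unsupported topology: no absorbing product state")
  root <- scheme$states[1L]
  cycle_states <- setdiff(scheme$states, terminals)
  chem <- which(tr$to %in% terminals)   # product-forming transitions

  velocity <- function(S) {
    M <- rate_matrix(scheme, params, stats::setNames(S, substrate))
    M <- M[cycle_states, cycle_states, drop = FALSE]
    ## recycle product-forming flux back to the root state
    v <- param_values(params)
    for (i in chem) {
      keff <- v[[tr$kf[i]]] *
        (if (is.na(tr$ligand_f[i])) 1 else S)
      M[root, tr$from[i]] <- M[root, tr$from[i]] + keff
    }
    ## steady state: M x = 0, sum(x) = 1
    A <- rbind(M[-1L, , drop = FALSE], rep(1, ncol(M)))
    x <- solve(A, c(rep(0, nrow(M) - 1L), 1))
    names(x) <- cycle_states
    sum(vapply(chem, function(i) {
      keff <- v[[tr$kf[i]]] * (if (is.na(tr$ligand_f[i])) 1 else S)
      keff * x[[tr$from[i]]]
    }, numeric(1)))
  }

  ## recover the hyperbola v = kcat S/(Km + S): locate the half-saturation
  ## concentration by a wide log scan, then solve exactly from three
  ## points around it
  Sw <- 10^seq(-4, 9, by = 0.5)
  vw <- vapply(Sw, velocity, numeric(1))
  vmax <- max(vw)
  ihalf <- which(vw >= vmax / 2)[1L]
  Km0 <- if (ihalf > 1L)
    exp(stats::approx(vw[(ihalf - 1L):ihalf], log(Sw[(ihalf - 1L):ihalf]),
                      xout = vmax / 2)$y)
  else Sw[1L]
  S3 <- Km0 * c(0.3, 1, 3)
  v3 <- vapply(S3, velocity, numeric(1))
  ## solve in nondimensional variables for conditioning
  s <- S3 / Km0; w <- v3 / vmax
  A <- cbind(s, -w)
  ab <- solve(crossprod(A), crossprod(A, s * w))
  kcat <- ab[1L] * vmax; Km <- ab[2L] * Km0
  Sval <- Km * 10^seq(-3, 3, length.out = 12)
  vval <- vapply(Sval, velocity, numeric(1))
  vhyp <- kcat * Sval / (Km + Sval)
  if (max(abs(vval - vhyp) / pmax(vval, 1e-300)) > 1e-6)
    stop("unsupported topology: steady-state velocity is not hyperbolic ",
         "in the substrate")
  Ks <- step_equilibrium_constants(scheme, params)
  structure(list(kcat = kcat, Km = Km, kcat_over_Km = kcat / Km,
                 kcat_over_Km_M = kcat / Km * 1e6, K = Ks,
                 scheme = scheme$name, substrate = substrate),
            class = "steady_state_summary")
}

step_equilibrium_constants <- function(scheme, params) {
  tr <- scheme$transitions
  v <- param_values(params)
  rev_idx <- which(!is.na(tr$kr))
  stats::setNames(
    vapply(rev_idx, function(i) v[[tr$kf[i]]] / v[[tr$kr[i]]], numeric(1)),
    paste0("K.", tr$from[rev_idx], ".", tr$to[rev_idx]))
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat("Steady-state parameters (", x$scheme, ", substrate ", x$substrate,
      ")\n", sep = "")
  cat(sprintf("  kcat      = %.4g /s\n", x$kcat))
  cat(sprintf("  Km        = %.4g uM\n", x$Km))
  cat(sprintf("  kcat/Km   = %.4g /uM/s  (%.4g /M/s)\n",
              x$kcat_over_Km, x$kcat_over_Km_M))
  if (length(x$K)) {
    cat("  step equilibrium constants:\n")
    for (i in seq_along(x$K))
      cat(sprintf("    %s = %.4g\n", names(x$K)[i], x$K[i]))
  }
  invisible(x)
}

#' Rapid-equilibrium approximations for the three-step mechanism
#'
#' For the mechanism E + S (K1) ES (K2) FS -(k3)-> product with the
#' conformational step equilibrating rapidly relative to chemistry
#' (k-2 >> k3), the steady-state parameters reduce to
#' kcat = K2 k3 / (K2 + 1), Km = 1 / (K1 (K2 + 1)), and
#' kcat/Km = K1 K2 k3.  kcat is attenuated by the fraction of bound
#' nucleotide in the catalytically poised state, and Km equals the net
#' dissociation constant.  A regime flag reports whether the
#' rapid-equilibrium premise holds (k-2 >= 100 k3).
#'
#' @param k1 on-rate (/uM/s).
#' @param km1 off-rate (/s).
#' @param k2,km2 forward/reverse conformational rates (/s).
#' @param k3 chemistry rate (/s).
#' @return list with \code{kcat} (/s), \code{Km} (uM),
#'   \code{kcat_over_Km} (/uM/s), \code{K1} (/uM), \code{K2}, and
#'   \code{rapid_equilibrium} (logical regime flag).
#' @examples
#' rapid_equilibrium_approx(100, 930000, 170, 340, 1.6)
#' @export
rapid_equilibrium_approx <- function(k1, km1, k2, km2, k3) {
  K1 <- k1 / km1
  K2 <- k2 / km2
  list(kcat = K2 * k3 / (K2 + 1),
       Km = 1 / (K1 * (K2 + 1)),
       kcat_over_Km = K1 * K2 * k3,
       K1 = K1, K2 = K2,
       rapid_equilibrium = km2 >= 100 * k3)
}

#' Ground-state dissociation constant implied by Km
#'
#' Inverts the rapid-equilibrium relation Km = 1/(K1 (K2 + 1)) to recover
#' the ground-state nucleotide dissociation constant 1/K1 from a measured
#' Km and the internal equilibrium constant K2.
#'
#' @param Km Michaelis constant (uM).
#' @param K2 conformational equilibrium constant (dimensionless).
#' @return 1/K1 in uM.
#' @examples
#' ground_state_Kd_from_Km(6200, 0.5)  # 9300 uM
#' @export
ground_state_Kd_from_Km <- function(Km, K2) Km * (K2 + 1)

#' Discrimination index
#'
#' Ratio of specificity constants for correct over mismatched nucleotide
#' incorporation at the same template position: the expected number of
#' correct incorporations per error.
#'
#' @param correct,mismatch kcat/Km values in the same units, positive.
#' @return D (dimensionless); \code{Inf} if the mismatch value is zero.
#' @export
discrimination_index <- function(correct, mismatch) {
  if (correct <= 0 || mismatch < 0) stop("kcat/Km values must be positive")
  if (mismatch == 0) return(Inf)
  correct / mismatch
}

#' Discrimination table across all template/dNTP combinations
#'
#' Computes the discrimination index for every mismatch row of a
#' specificity-constant table by dividing the correct incorporation's
#' kcat/Km for the same template.
#'
#' @param table data.frame like [table2_kinetics()]: columns
#'   \code{template}, \code{dntp}, \code{kcat_over_km}, \code{is_correct}.
#' @return the table with a computed \code{D} column (exactly 1 for
#'   correct rows).
#' @export
discrimination_table <- function(table = table2_kinetics()) {
  correct <- table[table$is_correct, c("template", "kcat_over_km")]
  ref <- stats::setNames(correct$kcat_over_km, correct$template)
  table$D <- mapply(discrimination_index,
                    ref[table$template], table$kcat_over_km)
  table
}

#' Summary statistics of discrimination indices
#'
#' @param table output of [discrimination_table()] (or any data.frame with
#'   \code{D} and \code{is_correct} columns).
#' @return list with \code{median}, \code{min}, \code{max}, \code{mean}
#'   over the mismatch rows.  The median uses the midpoint of the two
#'   central order statistics for even counts.
#' @export
discrimination_summary <- function(table = discrimination_table()) {
  d <- table$D[!table$is_correct]
  if (!length(d)) stop("no mismatch rows in table")
  list(median = stats::median(d), min = min(d), max = max(d),
       mean = mean(d), n = length(d))
}

## thermodynamic constants
.R_KCAL <- 1.9872e-3        # kcal/mol/K
.KB <- 1.380649e-23         # J/K
.H <- 6.62607015e-34        # J s

#' Transition-state-theory free-energy profile
#'
#' Converts a mechanism's rate constants into a free-energy profile:
#' each step's barrier sits \eqn{\Delta G^\ddagger = -RT \ln(k h /
#' (\kappa k_B T))} above its reactant state (bimolecular steps use the
#' pseudo-first-order rate at the reference ligand concentration), and
#' state levels accumulate \eqn{-RT \ln K} per reversible step (with the
#' ligand-concentration factor for binding steps).  The reference (zero)
#' level is the first state plus free ligand.  A branch ends at the first
#' irreversible step: its barrier is defined, but the following state's
#' level is not thermodynamically determined by the rate constants and is
#' reported \code{NA}.
#'
#' @param scheme a [kinetic_scheme()].
#' @param params a [parameter_set()].
#' @param ligand_concs named reference ligand concentrations (uM), e.g. a
#'   physiological nucleotide level.
#' @param temperature Kelvin (default 293).
#' @param kappa transmission coefficient (default 0.01; rescaling kappa
#'   shifts every barrier by the same constant and cannot change which
#'   barrier is highest).
#' @return an object of class \code{free_energy_profile}: a data.frame of
#'   alternating state and barrier levels (kcal/mol) per branch, plus the
#'   settings.
#' @examples
#' fx <- paper_fixture("fig7_misincorporation", variant = "two_step")
#' pr <- free_energy_profile(fx$scheme, fx$params, c(dTTP = 175))
#' highest_barrier(pr)
#' @export
free_energy_profile <- function(scheme, params, ligand_concs,
                                temperature = 293, kappa = 0.01) {
  check_scheme_params(scheme, params)
  if (any(param_values(params) <= 0)) stop("rates must be positive")
  RT <- .R_KCAL * temperature
  k_ref <- kappa * .KB * temperature / .H   # reference frequency, /s
  lc <- ligand_conc_vector(scheme, ligand_concs)
  v <- param_values(params)
  tr <- scheme$transitions
  rows <- list()
  add <- function(kind, label, level, step = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, label = label,
                                             level = level, step = step)
  walk <- function(state, level, visited) {
    idx <- which(tr$from == state)
    first <- TRUE
    for (i in idx) {
      if (tr$to[i] %in% visited) next
      keff <- v[[tr$kf[i]]] *
        (if (is.na(tr$ligand_f[i])) 1 else lc[[tr$ligand_f[i]]])
      if (keff <= 0) next      # zero-concentration branch not populated
      barrier <- level - RT * log(keff / k_ref)
      step_id <- paste0(tr$from[i], ".", tr$to[i])
      add("barrier", paste0("TS.", step_id), barrier, step_id)
      if (is.na(tr$kr[i])) {
        add("state", tr$to[i], NA_real_)   # level undefined past an
        next                               # irreversible step
      }
      kr <- v[[tr$kr[i]]] *
        (if (is.na(tr$ligand_r[i])) 1 else lc[[tr$ligand_r[i]]])
      lev2 <- barrier + RT * log(kr / k_ref)
      add("state", tr$to[i], lev2)
      walk(tr$to[i], lev2, c(visited, tr$to[i]))
    }
  }
  root <- scheme$states[1L]
  add("state", root, 0)
  walk(root, 0, root)
  profile <- do.call(rbind, rows)
  structure(list(profile = profile, temperature = temperature,
                 kappa = kappa, ligand_concs = ligand_concs,
                 scheme = scheme$name),
            class = "free_energy_profile")
}

#' Highest barrier of a free-energy profile
#'
#' The step whose transition state lies highest above the reference
#' (starting-material) level — the step through which the specificity
#' constant is determined, since kcat/Km reflects all steps up to and
#' including the highest barrier.  Ties (within 1e-9 kcal/mol) resolve to
#' the earlier step with a \code{tie} flag.
#'
#' @param profile a [free_energy_profile()].
#' @return the step identifier (\code{"from.to"}), with attributes
#'   \code{level} (kcal/mol) and \code{tie}.
#' @export
highest_barrier <- function(profile) {
  b <- profile$profile[profile$profile$kind == "barrier", ]
  if (!nrow(b)) stop("profile has no barriers")
  top <- max(b$level)
  at <- which(b$level > top - 1e-9)
  structure(b$step[at[1L]], level = top, tie = length(at) > 1L)
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("Free-energy profile (", x$scheme, "): T = ", x$temperature,
      " K, kappa = ", x$kappa, "\n", sep = "")
  cat("  reference ligand:",
      paste(sprintf("%s = %g uM", names(x$ligand_concs), x$ligand_concs),
            collapse = ", "), "\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  p <- x$profile[!is.na(x$profile$level), ]
  pos <- seq_len(nrow(p))
  graphics::plot(pos, p$level, type = "n", xaxt = "n",
                 xlab = "reaction coordinate", ylab = "free energy (kcal/mol)",
                 ...)
  graphics::axis(1, at = pos, labels = p$label, las = 2, cex.axis = 0.6)
  for (i in seq_len(nrow(p) - 1L))
    graphics::segments(pos[i], p$level[i], pos[i + 1L], p$level[i + 1L])
  graphics::points(pos, p$level,
                   pch = ifelse(p$kind == "state", 15, 17),
                   col = ifelse(p$kind == "state", "black", "firebrick"))
  invisible(x)
}
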
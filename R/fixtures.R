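#' Built-in polymerase mechanisms with published rate constants
#'
#' Returns one of the package's built-in kinetic mechanisms for nucleotide
#' misincorporation and mismatch extension by exonuclease-deficient T7 DNA
#' polymerase, together with the published best-fit rate constants.
#' Equilibrium-constant-only parameters are expanded using the standard
#' locking convention: the bimolecular on-rate is locked at 10 /uM/s and
#' the off-rate is on-rate times the dissociation constant.
#'
#' Available fixtures:
#' \describe{
#'   \item{\code{fig1_minimal}}{Minimal misincorporation model
#'     \code{ED + N -(kalpha)-> XDN -(kbeta)-> EP}, both steps irreversible,
#'     where \code{kalpha} is kcat/Km and \code{kbeta} is kcat.  Default
#'     constants are the A:dCTP misincorporation screen values.}
#'   \item{\code{fig2_sequential}}{Sequential T:dTTP misincorporation (27 to
#'     28 nt) followed by mismatch extension (28 to 29 nt), each a
#'     rapid-equilibrium binding step plus an irreversible incorporation.}
#'   \item{\code{fig3_binding}}{Two-step dTTP binding to the
#'     dideoxy-terminated mismatch-extension complex: ground-state binding
#'     then isomerization to a closed state (no chemistry).}
#'   \item{\code{fig5_extension}}{Branched mismatch-extension mechanism:
#'     binding, two conformational steps, chemistry and PPi release, plus a
#'     nucleotide-activated branch in which a second dTTP binds the FDT
#'     state (forming GDTp) and chemistry proceeds from GDTp.}
#'   \item{\code{fig7_misincorporation}}{T:dTTP misincorporation.
#'     \code{variant = "one_step"}: single-step binding then combined
#'     chemistry/PPi release. \code{variant = "two_step"}: diffusion-limited
#'     ground-state binding, conformational change, then chemistry.
#'     \code{variant = "full"}: one-step misincorporation followed by the
#'     complete mismatch-extension mechanism with extension constants
#'     locked.}
#' }
#'
#' @param name fixture identifier (see above).
#' @param variant for \code{fig7_misincorporation}: \code{"one_step"}
#'   (default), \code{"two_step"}, or \code{"full"}.
#' @return a list of class \code{paper_fixture} with elements
#'   \code{scheme}, \code{params} and \code{provenance}.
#' @examples
#' fx <- paper_fixture("fig3_binding")
#' param_values(fx$params)
#' @export
paper_fixture <- function(name, variant = c("one_step", "two_step", "full")) {
  catalog <- c("fig1_minimal", "fig2_sequential", "fig3_binding",
               "fig5_extension", "fig7_misincorporation")
  if (!name %in% catalog)
    stop("unknown fixture '", name, "'; valid names: ",
         paste(catalog, collapse = ", "))
  variant <- match.arg(variant)
  fx <- switch(name,
    fig1_minimal = fixture_fig1(),
    fig2_sequential = fixture_fig2(),
    fig3_binding = fixture_fig3(),
    fig5_extension = fixture_fig5(),
    fig7_misincorporation = fixture_fig7(variant))
  class(fx) <- "paper_fixture"
  fx
}

#' @export
print.paper_fixture <- function(x, ...) {
  cat("Fixture:", x$provenance, "\n")
  print(x$scheme)
  print(x$params)
  invisible(x)
}

LOCKED_ON_RATE <- 10  # /uM/s; convention for expanding dissociation constants

fixture_fig1 <- function() {
  scheme <- kinetic_scheme(
    "fig1_minimal",
    states = c("ED", "XDN", "EP"),
    ligands = "dNTP",
    transitions = data.frame(
      from = c("ED", "XDN"), to = c("XDN", "EP"),
      kf = c("kalpha", "kbeta"), kr = NA_character_,
      ligand_f = c("dNTP", NA), ligand_r = NA_character_))
  params <- parameter_set(
    kalpha = list(value = 143e-6, units = "/uM/s"),   # 143 /M/s
    kbeta = list(value = 1.2))
  list(scheme = scheme, params = params,
       provenance = "minimal misincorporation screen model (A:dCTP defaults)")
}

fixture_fig2 <- function() {
  scheme <- kinetic_scheme(
    "fig2_sequential",
    states = c("ED27", "ED27T", "ED28", "ED28T", "ED29"),
    ligands = "dTTP",
    transitions = data.frame(
      from = c("ED27", "ED27T", "ED28", "ED28T"),
      to = c("ED27T", "ED28", "ED28T", "ED29"),
      kf = c("kA1", "kA2", "kB1", "kB2"),
      kr = c("kmA1", NA, "kmB1", NA),
      ligand_f = c("dTTP", NA, "dTTP", NA),
      ligand_r = NA_character_))
  params <- parameter_set(
    kA1 = list(value = LOCKED_ON_RATE, units = "/uM/s", locked = TRUE),
    kmA1 = 7700 * LOCKED_ON_RATE,   # 1/K'A1 = 7.7 mM
    kA2 = 0.68,
    kB1 = list(value = LOCKED_ON_RATE, units = "/uM/s", locked = TRUE),
    kmB1 = 460 * LOCKED_ON_RATE,    # 1/K'B1 = 460 uM
    kB2 = 0.20)
  list(scheme = scheme, params = params,
       provenance = "sequential misincorporation + mismatch extension (quench)")
}

fixture_fig3 <- function() {
  scheme <- kinetic_scheme(
    "fig3_binding",
    states = c("ED", "EDT", "FDT"),
    ligands = "dTTP",
    transitions = data.frame(
      from = c("ED", "EDT"), to = c("EDT", "FDT"),
      kf = c("kB1", "kB2"), kr = c("kmB1", "kmB2"),
      ligand_f = c("dTTP", NA), ligand_r = NA_character_))
  params <- parameter_set(
    kB1 = list(value = LOCKED_ON_RATE, units = "/uM/s", locked = TRUE),
    kmB1 = 1500 * LOCKED_ON_RATE,   # 1/KB1 = 1.5 mM
    kB2 = 310,
    kmB2 = 6.8)
  list(scheme = scheme, params = params,
       provenance = "two-step dTTP binding to dideoxy mismatch-extension complex")
}

fixture_fig5 <- function() {
  scheme <- kinetic_scheme(
    "fig5_extension",
    states = c("ED", "EDT", "FDT", "GDT", "FPPPi", "EP",
               "GDTp", "FPPPip", "EPp"),
    ligands = "dTTP",
    transitions = data.frame(
      from = c("ED", "EDT", "FDT", "GDT", "FPPPi", "FDT", "GDTp", "FPPPip"),
      to = c("EDT", "FDT", "GDT", "FPPPi", "EP", "GDTp", "FPPPip", "EPp"),
      kf = c("k4", "k5", "k6", "k7", "k8", "k9", "k10", "k11"),
      kr = c("km4", "km5", "km6", NA, NA, "km9", NA, NA),
      ligand_f = c("dTTP", NA, NA, NA, NA, "dTTP", NA, NA),
      ligand_r = NA_character_))
  params <- parameter_set(
    k4 = list(value = LOCKED_ON_RATE, units = "/uM/s", locked = TRUE),
    km4 = 2600 * LOCKED_ON_RATE,    # 1/K4 = 2.6 mM
    k5 = 500, km5 = 140,
    k6 = 45, km6 = 6.6,
    k7 = 0.102, k8 = 0.22,
    k9 = list(value = 0.007, units = "/uM/s"), km9 = 14,
    k10 = 0.90, k11 = 0.12)
  list(scheme = scheme, params = params,
       provenance = "branched mismatch-extension mechanism (global fit)")
}

fixture_fig7 <- function(variant) {
  if (variant == "one_step") {
    scheme <- kinetic_scheme(
      "fig7_one_step",
      states = c("ED", "FDT", "EP"),
      ligands = "dTTP",
      transitions = data.frame(
        from = c("ED", "FDT"), to = c("FDT", "EP"),
        kf = c("k12", "k3"), kr = c("km12", NA),
        ligand_f = c("dTTP", NA), ligand_r = NA_character_))
    params <- parameter_set(
      k12 = list(value = 0.055, units = "/uM/s"),
      km12 = 340,
      k3 = 0.53)
    return(list(scheme = scheme, params = params,
                provenance = "T:dTTP misincorporation, one-step binding"))
  }
  if (variant == "two_step") {
    scheme <- kinetic_scheme(
      "fig7_two_step",
      states = c("ED", "EDT", "FDT", "EP"),
      ligands = "dTTP",
      transitions = data.frame(
        from = c("ED", "EDT", "FDT"), to = c("EDT", "FDT", "EP"),
        kf = c("k1", "k2", "k3"), kr = c("km1", "km2", NA),
        ligand_f = c("dTTP", NA, NA), ligand_r = NA_character_))
    params <- parameter_set(
      k1 = list(value = 100, units = "/uM/s", locked = TRUE),
      km1 = list(value = 930000, locked = TRUE),  # 1/K1 = 9.3 mM
      k2 = 170,
      km2 = list(value = 340, locked = TRUE),
      k3 = 1.6)
    return(list(scheme = scheme, params = params,
                provenance = "T:dTTP misincorporation, estimated two-step binding"))
  }
  ## full: one-step misincorporation followed by mismatch extension, with
  ## extension constants locked at their globally fitted values.
  ext <- fixture_fig5()
  ext$params$locked <- TRUE
  scheme <- kinetic_scheme(
    "fig7_full",
    states = c("ED27", "FD27T", ext$scheme$states),
    ligands = "dTTP",
    transitions = rbind(
      data.frame(from = c("ED27", "FD27T"), to = c("FD27T", "ED"),
                 kf = c("k12", "k3"), kr = c("km12", NA),
                 ligand_f = c("dTTP", NA), ligand_r = NA_character_),
      ext$scheme$transitions))
  params <- parameter_set(c(
    list(k12 = list(value = 0.055, units = "/uM/s"),
         km12 = 340,
         k3 = 0.53),
    lapply(split(ext$params, ext$params$name)[ext$params$name], function(r)
      list(value = r$value, units = r$units, locked = TRUE))))
  list(scheme = scheme, params = params,
       provenance = "misincorporation + locked mismatch extension (stopped-flow)")
}

#' Specificity constants for all templating base / dNTP combinations
#'
#' The measured specificity constants (kcat/Km) for the four correct
#' incorporations and all twelve possible misincorporations by
#' exonuclease-deficient T7 DNA polymerase, with standard errors and the
#' published discrimination indices.  These printed values are inputs to
#' the discrimination analysis; lower-bound-only kcat and Km entries from
#' the screen are not included.
#'
#' @return data.frame with columns \code{template}, \code{dntp},
#'   \code{kcat_over_km} (/M/s), \code{se} (/M/s), \code{is_correct}, and
#'   \code{discrimination_printed}.
#' @export
table2_kinetics <- function() {
  df <- data.frame(
    template = rep(c("A", "C", "G", "T"), each = 4),
    dntp = rep(c("dATP", "dCTP", "dGTP", "dTTP"), 4),
    kcat_over_km = c(147, 143, 10, 1.65e7,
                     190, 1.4, 1.37e7, 31,
                     295, 2.63e7, 61, 195,
                     1.56e7, 43, 265, 130),
    se = c(20, 15, 1, 0.28e7,
           25, 0.2, 0.24e7, 4,
           40, 0.36e7, 8, 20,
           0.26e7, 5, 40, 25),
    stringsAsFactors = FALSE)
  df$is_correct <- with(df, (template == "A" & dntp == "dTTP") |
                            (template == "C" & dntp == "dGTP") |
                            (template == "G" & dntp == "dCTP") |
                            (template == "T" & dntp == "dATP"))
  df$discrimination_printed <- c(112200, 115400, 1650000, 1,
                                 72100, 9800000, 1, 442000,
                                 89200, 1, 431000, 135000,
                                 1, 363000, 59000, 120000)
  df
}

#' Reference correct-incorporation mechanism (reconstructed)
#'
#' Two-step binding then chemistry for correct nucleotide incorporation,
#' assembled from the printed conformational-change and chemistry rate
#' constants (k2 = 6500 /s, k-2 = 1.7 /s, k3 = 300 /s).  The ground-state
#' binding step is a synthetic reconstruction: its equilibrium constant is
#' back-calculated from the measured specificity constant for T:dATP
#' (1.56e7 /M/s) via kcat/Km = K1 k2, with the on-rate set to a
#' diffusion-limited 100 /uM/s.  Free-energy barrier comparisons between
#' the conformational-change and chemistry steps do not depend on that
#' reconstructed step.
#'
#' @return a list with elements \code{scheme} and \code{params}.
#' @export
correct_reference_scheme <- function() {
  k2 <- 6500; km2 <- 1.7; k3 <- 300
  kcat_km_uM <- 1.56e7 * 1e-6            # /uM/s
  K1 <- kcat_km_uM / k2                  # /uM
  k1 <- 100
  scheme <- kinetic_scheme(
    "correct_reference",
    states = c("ED", "EDN", "FDN", "EP"),
    ligands = "dNTP",
    transitions = data.frame(
      from = c("ED", "EDN", "FDN"), to = c("EDN", "FDN", "EP"),
      kf = c("k1", "k2", "k3"), kr = c("km1", "km2", NA),
      ligand_f = c("dNTP", NA, NA), ligand_r = NA_character_))
  params <- parameter_set(
    k1 = list(value = k1, units = "/uM/s", locked = TRUE),
    km1 = list(value = k1 / K1, locked = TRUE),
    k2 = k2, km2 = km2, k3 = k3)
  list(scheme = scheme, params = params)
}
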
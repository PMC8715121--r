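#' Noise model for synthetic datasets
#'
#' @param kind \code{"gaussian-relative"} (standard deviation is
#'   \code{sigma} times the absolute model value) or
#'   \code{"gaussian-absolute"} (standard deviation \code{sigma} in signal
#'   units; for generators that scale noise to the dynamic range,
#'   \code{sigma} is the fraction of the range).
#' @param sigma non-negative noise magnitude.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(kind = c("gaussian-relative", "gaussian-absolute"),
                        sigma = 0.03, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

## Evaluate expr with the global RNG temporarily seeded; restores state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

add_noise <- function(x, noise, scale_abs = 1) {
  if (noise$sigma == 0) return(x)
  sd <- switch(noise$kind,
               "gaussian-relative" = noise$sigma * abs(x),
               "gaussian-absolute" = noise$sigma * scale_abs)
  x + stats::rnorm(length(as.numeric(x)), sd = sd)
}

#' Configuration for the synthetic-data generators
#'
#' Collects a fixture name and the experiment design handed to the
#' generators.  Every field has a fixture-appropriate default emulating
#' the corresponding instrument experiment; see the individual generators.
#'
#' @param fixture fixture name for [paper_fixture()].
#' @param variant fixture variant (\code{fig7_misincorporation} only).
#' @param conc_series ligand concentration series (uM).
#' @param times sampling time grid (s).
#' @param init named initial state concentrations (uM).
#' @param observable an [observable_spec()].
#' @param noise a [noise_model()].
#' @param seed convenience override for the noise model's seed.
#' @param ... further fields stored as-is (e.g. \code{start} for the
#'   quench generator).
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(fixture, variant = "one_step",
                             conc_series = NULL, times = NULL, init = NULL,
                             observable = NULL, noise = NULL, seed = NULL,
                             ...) {
  if (is.null(noise)) noise <- noise_model(seed = seed %||% 1L)
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  if (!is.null(conc_series) && (!length(conc_series) || any(conc_series <= 0)))
    stop("concentration series must be non-empty and positive")
  structure(list(fixture = fixture, variant = variant,
                 conc_series = conc_series, times = times, init = init,
                 observable = observable, noise = noise, ...),
            class = "generator_config")
}

## Integrate allowing a first observation later than t = 0 (dead time).
integrate_from_zero <- function(scheme, params, init, ligand_concs, times) {
  prepend <- times[1] > 0
  tt <- if (prepend) c(0, times) else times
  tc <- integrate_scheme(scheme, params, init, ligand_concs, tt)
  if (prepend) tc[-1L, , drop = FALSE] else tc
}

#' Synthetic chemical-quench dataset
#'
#' Emulates single-turnover quench experiments on the sequential
#' misincorporation/mismatch-extension mechanism: enzyme in excess over 75
#' nM DNA mixed with a series of dTTP concentrations, products pooled by
#' primer length.  \code{config$start = "ED27"} gives the full
#' misincorporation-plus-extension reaction (27/28/29-nt pools, 0.1-4 mM
#' dTTP); \code{"ED28"} gives mismatch extension from a preformed mismatch
#' (28/29-nt pools, 0.05-3 mM dTTP).  Before noise every trace conserves
#' the DNA total.
#'
#' @param config a [generator_config()]; defaults emulate the quench
#'   design with 3 percent relative Gaussian noise.
#' @return an [experiment_spec()] of kind \code{"quench"} with noisy data
#'   attached; attribute \code{truth} carries the generating parameters.
#' @export
generate_quench_dataset <- function(config = generator_config("fig2_sequential")) {
  fixture <- config$fixture %||% "fig2_sequential"
  fx <- paper_fixture(fixture)
  is_branched <- fixture == "fig5_extension"
  start <- config$start %||% (if (is_branched) "ED" else "ED28")
  dna <- config$dna_total %||% 0.075
  concs <- config$conc_series %||%
    (if (start == "ED27") c(100, 250, 500, 1000, 2000, 4000)
     else c(50, 100, 250, 500, 1000, 2000, 3000))
  times <- config$times %||% seq(0, 60, length.out = 25)
  pools <- if (is_branched)
    list(n28 = c("ED", "EDT", "FDT", "GDT", "GDTp"),
         n29 = c("FPPPi", "EP", "FPPPip", "EPp"))
  else if (start == "ED27")
    list(n27 = c("ED27", "ED27T"), n28 = c("ED28", "ED28T"), n29 = "ED29")
  else
    list(n28 = c("ED28", "ED28T"), n29 = "ED29")
  init <- config$init %||% stats::setNames(dna, start)
  traces <- with_seed(config$noise$seed, lapply(concs, function(cc) {
    tc <- integrate_from_zero(fx$scheme, fx$params, init,
                              c(dTTP = cc), times)
    clean <- sapply(names(pools), function(p)
      rowSums(tc[, pools[[p]], drop = FALSE]))
    stopifnot(max(abs(rowSums(clean) - sum(init))) < 1e-6 * sum(init))
    list(trace_id = paste0("T", cc), ligand_conc = c(dTTP = cc),
         init = init, times = times,
         data = add_noise(clean, config$noise))
  }))
  out <- experiment_spec("quench", fx$scheme, traces, pools = pools)
  attr(out, "truth") <- param_values(fx$params)
  attr(out, "config") <- config
  out
}

#' Synthetic stopped-flow fluorescence dataset
#'
#' Emulates stopped-flow coumarin-fluorescence traces over a nucleotide
#' concentration series, sampled on a log grid from the 1.3 ms instrument
#' dead time.  State fluorescence factors follow the observed signal
#' directions: closed extension states brighter than ground (signal rises
#' on binding), the mismatch-recognition closed state dimmer (signal dips
#' during misincorporation, then recovers as extension proceeds).  Traces
#' include inner-filter attenuation growing with nucleotide concentration.
#' Noise is 1 percent of each trace's dynamic range.
#'
#' @param config a [generator_config()]; \code{fixture} may be
#'   \code{"fig3_binding"} (binding-only, dideoxy primer) or
#'   \code{"fig7_misincorporation"} with \code{variant = "full"}.
#' @return an [experiment_spec()] of kind \code{"stopped_flow"}.
#' @export
generate_stopped_flow_dataset <- function(config = generator_config("fig3_binding")) {
  fixture <- config$fixture %||% "fig3_binding"
  fx <- paper_fixture(fixture, variant = config$variant %||% "full")
  is_binding <- fixture == "fig3_binding"
  concs <- config$conc_series %||%
    (if (is_binding) c(50, 100, 250, 500, 1000, 2000, 3000)
     else c(500, 1000, 2000, 4000))
  times <- config$times %||%
    (1.3e-3 * exp(seq(0, log((if (is_binding) 0.2 else 100) / 1.3e-3),
                      length.out = if (is_binding) 80 else 120)))
  init <- config$init %||%
    (if (is_binding) c(ED = 0.2) else c(ED27 = 0.1))
  obs <- config$observable %||% default_fluorescence_observable(fixture)
  traces <- with_seed(config$noise$seed, lapply(concs, function(cc) {
    tc <- integrate_from_zero(fx$scheme, fx$params, init,
                              c(dTTP = cc), times)
    sig <- project_observable(tc, obs, ligand_conc = cc)
    list(trace_id = paste0("T", cc), ligand_conc = c(dTTP = cc),
         init = init, times = times,
         data = add_noise(sig, config$noise, scale_abs = diff(range(sig))))
  }))
  out <- experiment_spec("stopped_flow", fx$scheme, traces, observable = obs)
  attr(out, "truth") <- param_values(fx$params)
  attr(out, "config") <- config
  out
}

## Default per-state fluorescence factors (sign-correct, magnitudes
## arbitrary) and an inner-filter coefficient attenuating the 3 mM trace
## by about 20 percent.
default_fluorescence_observable <- function(fixture) {
  factors <- switch(fixture,
    fig3_binding = c(FDT = 1.3),
    fig5_extension = c(FDT = 1.3, GDT = 1.3, GDTp = 1.3),
    fig7_misincorporation = c(FD27T = 0.8, FDT = 1.3, GDT = 1.3, GDTp = 1.3),
    numeric())
  observable_spec(A1 = 5, state_factors = factors, q = 6.7e-5)
}

#' Synthetic equilibrium-titration dataset
#'
#' Emulates titrating nucleotide stock into a cuvette of preformed
#' enzyme-DNA complex in small steps with stirring: stepwise equilibrium
#' re-solves, cumulative dilution of the cell contents, and inner-filter
#' attenuation of the raw signal.  Both the uncorrected (attenuated) and
#' corrected signals are emitted; at zero noise the Beer-Lambert correction
#' applied to the uncorrected signal reproduces the corrected one exactly.
#' Noise is 0.5 percent of the signal range.
#'
#' @param config a [generator_config()]; defaults emulate titrating 7.5 mM
#'   dTTP stock (41 steps of 0.5 uL into 280 uL) into 100 nM complex.
#' @return an [experiment_spec()] of kind \code{"titration"} whose single
#'   trace carries the titration design, \code{data} (corrected signal)
#'   and \code{data_uncorrected}.
#' @export
generate_titration_dataset <- function(config = generator_config("fig3_binding",
                                                                 noise = noise_model("gaussian-absolute", 0.005, 1))) {
  fx <- paper_fixture(config$fixture %||% "fig3_binding")
  init <- config$init %||% c(ED = 0.1)
  cell_volume <- config$cell_volume %||% 280
  step_volumes <- config$step_volumes %||% rep(0.5, 41)
  stock <- config$titrant_stock %||% 7500
  obs <- config$observable %||% default_fluorescence_observable(config$fixture %||% "fig3_binding")
  tt <- simulate_titration(fx$scheme, fx$params, init, cell_volume,
                           "dTTP", step_volumes, stock)
  states <- fx$scheme$states
  b <- stats::setNames(rep(1, length(states)), states)
  b[intersect(names(obs$state_factors), states)] <-
    obs$state_factors[intersect(names(obs$state_factors), states)]
  corrected <- drop(as.matrix(tt[, states]) %*% b) * obs$A1
  iff <- inner_filter_factor(obs$q * tt$titrant_total)
  uncorrected <- corrected * iff
  noisy_unc <- with_seed(config$noise$seed,
                         add_noise(uncorrected, config$noise,
                                   scale_abs = diff(range(uncorrected))))
  trace <- list(trace_id = "titration1", init = init,
                cell_volume = cell_volume, step_volumes = step_volumes,
                titrant = "dTTP", titrant_stock = stock,
                titrant_total = tt$titrant_total,
                dilution = tt$dilution,
                data = noisy_unc / iff,
                data_uncorrected = noisy_unc)
  out <- experiment_spec("titration", fx$scheme, list(trace), observable = obs)
  attr(out, "truth") <- param_values(fx$params)
  attr(out, "config") <- config
  out
}

#' Synthetic nucleotide-trap dissociation dataset
#'
#' Emulates the dissociation-rate experiment: a pre-equilibrated labelled
#' polymerase-DNA(dideoxy)-dTTP complex (1 uM complex, 5 uM dTTP) is mixed
#' with a vast excess of unlabelled trap so released nucleotide cannot
#' rebind, and the fluorescence decay of the bound complex is recorded.
#' With the published binding constants the zero-noise decay fits a single
#' exponential at about 6.6 per second.
#'
#' @param config a [generator_config()].
#' @return an [experiment_spec()] of kind \code{"trap"}.
#' @export
generate_trap_dataset <- function(config = generator_config("fig3_binding",
                                                            noise = noise_model("gaussian-absolute", 0.01, 1))) {
  fx <- paper_fixture(config$fixture %||% "fig3_binding")
  init <- config$init %||% c(ED = 1, dTTP = 5)
  times <- config$times %||% seq(0, 1.2, length.out = 150)
  obs <- config$observable %||% default_fluorescence_observable(config$fixture %||% "fig3_binding")
  tc <- simulate_trap(fx$scheme, fx$params, init, "dTTP", times)
  sig <- project_observable(tc, obs)
  trace <- list(trace_id = "trap1", init = init, trapped_ligand = "dTTP",
                times = times,
                data = with_seed(config$noise$seed,
                                 add_noise(sig, config$noise,
                                           scale_abs = diff(range(sig)))))
  out <- experiment_spec("trap", fx$scheme, list(trace), observable = obs)
  attr(out, "truth") <- param_values(fx$params)
  attr(out, "config") <- config
  out
}
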
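#' Describe one experiment for global fitting
#'
#' Bundles an experiment's design (scheme, per-trace initial conditions,
#' ligand series, sampling times), its observable, and its data, in the
#' shape consumed by [fit_problem()] and [kinfit()].
#'
#' @param kind one of \code{"quench"} (species concentrations observed),
#'   \code{"stopped_flow"} (fluorescence signal), \code{"trap"}
#'   (fluorescence decay after abolishing ligand re-association), or
#'   \code{"titration"} (equilibrium signal versus total titrant).
#' @param scheme a [kinetic_scheme()].
#' @param traces list of traces.  Each trace is a list with
#'   \code{trace_id}, \code{ligand_conc} (named, uM), \code{init} (named
#'   state concentrations, uM), \code{times} (s), and \code{data} (a matrix
#'   with one column per observed pool for quench; a numeric signal vector
#'   otherwise).  Titration traces carry the titration design
#'   (\code{cell_volume}, \code{step_volumes}, \code{titrant},
#'   \code{titrant_stock}) instead of \code{times}.
#' @param observable an [observable_spec()] (fluorescence kinds).
#' @param pools named list mapping observed quench pools (e.g. primer
#'   lengths) to the states summed into them.
#' @param sigma data standard deviation used in the chi-square weighting;
#'   scalar or per-trace vector.  Defaults: 2 percent of the DNA total for
#'   quench, 1 percent of each trace's dynamic range for stopped-flow and
#'   trap, 0.5 percent of range for titrations.
#' @param scaling per-trace multiplier handling for stopped-flow data:
#'   \code{"none"}, \code{"analytic"} (profiled in closed form), or
#'   \code{"fit"} (one floated nuisance multiplier per trace).
#' @return an object of class \code{experiment_spec}.
#' @export
experiment_spec <- function(kind = c("quench", "stopped_flow", "titration", "trap"),
                            scheme, traces, observable = NULL, pools = NULL,
                            sigma = NULL,
                            scaling = c("none", "analytic", "fit")) {
  kind <- match.arg(kind)
  scaling <- match.arg(scaling)
  if (kind %in% c("stopped_flow", "titration", "trap") && is.null(observable))
    stop("observable_spec required for ", kind, " experiments")
  if (kind == "quench" && is.null(pools))
    stop("pools required for quench experiments")
  if (scaling != "none" && kind != "stopped_flow")
    stop("per-trace scaling applies to stopped_flow experiments")
  for (tr in traces) {
    if (is.null(tr$trace_id)) stop("every trace needs a trace_id")
    if (!is.null(tr$times) && any(diff(tr$times) <= 0))
      stop("trace times must be strictly increasing")
  }
  structure(list(kind = kind, scheme = scheme, traces = traces,
                 observable = observable, pools = pools, sigma = sigma,
                 scaling = scaling),
            class = "experiment_spec")
}

#' Assemble a global fitting problem
#'
#' Combines experiments sharing a parameter set into one weighted
#' least-squares problem.  Locked parameters are held fixed; link groups
#' constrain parameters to a common value (the group's first member is
#' fitted, the rest follow), as used to tie ground-state binding and
#' conformational steps between dideoxy-binding and extension experiments.
#'
#' @param experiments list of [experiment_spec()] objects.
#' @param params shared [parameter_set()].
#' @param float character vector of parameters allowed to vary; defaults
#'   to every unlocked parameter referenced by the schemes.
#' @param links list of character vectors, each a group of parameter names
#'   constrained equal; groups declared via the parameter set's
#'   \code{link_group} column are added automatically.
#' @return an object of class \code{fit_problem}.
#' @export
fit_problem <- function(experiments, params, float = NULL, links = NULL) {
  if (inherits(experiments, "experiment_spec")) experiments <- list(experiments)
  used <- unique(unlist(lapply(experiments, function(e)
    stats::na.omit(c(e$scheme$transitions$kf, e$scheme$transitions$kr)))))
  for (e in experiments) check_scheme_params(e$scheme, params)
  if (is.null(float))
    float <- setdiff(intersect(params$name[!params$locked], used), NULL)
  locked_in_float <- intersect(float, params$name[params$locked])
  if (length(locked_in_float))
    stop("locked parameters cannot float: ",
         paste(locked_in_float, collapse = ", "))
  ## merge explicit links with link_group column
  grp <- split(params$name, params$link_group)
  links <- c(links, unname(grp[lengths(grp) > 1]))
  for (g in links) {
    if (length(unique(params[g, "units"])) != 1L)
      stop("link group mixes units: ", paste(g, collapse = ", "))
  }
  slaves <- unlist(lapply(links, `[`, -1L))
  free <- setdiff(float, slaves)
  ## scale parameters from per-trace "fit" mode
  problem <- structure(list(experiments = experiments, params = params,
                            float = float, links = links, free = free),
                       class = "fit_problem")
  problem$sigma <- lapply(experiments, default_sigmas)
  problem
}

default_sigmas <- function(e) {
  vapply(seq_along(e$traces), function(i) {
    tr <- e$traces[[i]]
    s <- if (!is.null(e$sigma)) rep_len(e$sigma, length(e$traces))[i] else NA
    if (!is.na(s)) return(s)
    if (e$kind == "quench") {
      0.02 * sum(tr$init)
    } else {
      rng <- diff(range(tr$data))
      frac <- if (e$kind == "titration") 0.005 else 0.01
      frac * if (rng > 0) rng else max(abs(tr$data), 1)
    }
  }, numeric(1))
}

#' Enable per-trace scaling multipliers
#'
#' Appends one multiplicative nuisance factor per trace of a stopped-flow
#' experiment, mirroring concentration-series scaling used to absorb
#' trace-to-trace instrument drift and inner-filter attenuation.  In
#' \code{"analytic"} mode the profile-optimal multiplier (a least-squares
#' ratio) is substituted in closed form at every objective evaluation; in
#' \code{"fit"} mode multipliers are floated as ordinary parameters.
#'
#' @param problem a [fit_problem()].
#' @param experiment index of the experiment within the problem.
#' @param mode \code{"analytic"} or \code{"fit"}.
#' @return the augmented problem.
#' @export
apply_per_trace_scaling <- function(problem, experiment,
                                    mode = c("analytic", "fit")) {
  mode <- match.arg(mode)
  e <- problem$experiments[[experiment]]
  if (e$kind != "stopped_flow")
    stop("per-trace scaling applies to stopped_flow experiments")
  e$scaling <- mode
  problem$experiments[[experiment]] <- e
  if (mode == "fit") {
    nm <- paste0("scale.", experiment, ".",
                 vapply(e$traces, `[[`, "", "trace_id"))
    add <- parameter_set(stats::setNames(
      lapply(nm, function(x) list(value = 1)), nm))
    problem$params <- rbind(problem$params, add)
    class(problem$params) <- c("parameter_set", "data.frame")
    problem$float <- c(problem$float, nm)
    problem$free <- c(problem$free, nm)
  }
  problem
}

## Full parameter vector from free values (propagating link groups).
expand_free <- function(problem, free_values) {
  p <- set_param_values(problem$params, free_values)
  for (g in problem$links)
    p[g[-1L], "value"] <- p[g[1L], "value"]
  p
}

## Model predictions for one experiment under a parameter set.  Returns a
## list, one element per trace, shaped like the trace data.
simulate_experiment <- function(e, params, problem = NULL, exp_index = NULL) {
  lapply(seq_along(e$traces), function(i) {
    tr <- e$traces[[i]]
    if (e$kind == "titration") {
      tt <- simulate_titration(e$scheme, params, tr$init, tr$cell_volume,
                               tr$titrant, tr$step_volumes, tr$titrant_stock)
      states <- e$scheme$states
      b <- stats::setNames(rep(1, length(states)), states)
      sf <- e$observable$state_factors
      b[intersect(names(sf), states)] <- sf[intersect(names(sf), states)]
      sig <- as.matrix(tt[, states, drop = FALSE]) %*% b * e$observable$A1
      drop(sig) * inner_filter_factor(e$observable$q * tt$titrant_total)
    } else if (e$kind == "trap") {
      tc <- simulate_trap(e$scheme, params, tr$init, tr$trapped_ligand,
                          tr$times)
      project_observable(tc, e$observable,
                         ligand_conc = sum(tr$ligand_conc %||% 0))
    } else {
      tc <- integrate_from_zero(e$scheme, params, tr$init,
                                ligand_concs = tr$ligand_conc,
                                times = tr$times)
      if (e$kind == "quench") {
        sapply(names(e$pools), function(p)
          rowSums(tc[, e$pools[[p]], drop = FALSE]))
      } else {
        m <- 1
        if (!is.null(params) && identical(e$scaling, "fit") &&
            !is.null(exp_index)) {
          nm <- paste0("scale.", exp_index, ".", tr$trace_id)
          if (nm %in% rownames(params)) m <- params[nm, "value"]
        }
        m * project_observable(tc, e$observable,
                               ligand_conc = sum(tr$ligand_conc),
                               trace_id = tr$trace_id)
      }
    }
  })
}

## Weighted residual vector across all experiments.
problem_residuals <- function(problem, params) {
  res <- list()
  for (j in seq_along(problem$experiments)) {
    e <- problem$experiments[[j]]
    model <- tryCatch(simulate_experiment(e, params, problem, j),
                      error = function(err) NULL)
    if (is.null(model)) return(NULL)
    for (i in seq_along(e$traces)) {
      dat <- e$traces[[i]]$data
      mod <- model[[i]]
      if (identical(e$scaling, "analytic")) {
        denom <- sum(mod^2)
        m <- if (denom > 0) sum(mod * dat) / denom else 1
        mod <- m * mod
      }
      res[[length(res) + 1L]] <-
        (as.numeric(mod) - as.numeric(dat)) / problem$sigma[[j]][i]
    }
  }
  unlist(res)
}

#' Global chi-square objective
#'
#' Sum over all data points of squared, sigma-weighted residuals between
#' the simulated model and the data.
#'
#' @param problem a [fit_problem()].
#' @param params optional [parameter_set()] or named vector of values
#'   overriding the problem's parameters.
#' @return the chi-square value (\code{Inf}, with a warning, if the model
#'   cannot be simulated at these parameters).
#' @export
chi_square <- function(problem, params = NULL) {
  p <- problem$params
  if (inherits(params, "parameter_set")) p <- params
  else if (!is.null(params)) p <- set_param_values(p, params)
  r <- problem_residuals(problem, p)
  if (is.null(r)) {
    warning("simulation failed; chi-square is Inf")
    return(Inf)
  }
  sum(r^2)
}

#' Fit kinetic mechanisms to data by simulation
#'
#' The package's central estimator: fits the floated rate constants of a
#' [fit_problem()] to all of its experiments simultaneously by
#' Levenberg-Marquardt minimization of the sigma-weighted chi-square,
#' simulating every experiment at each iterate.  Parameters are optimized
#' in log space (they are positive and span several orders of magnitude),
#' with any declared bounds applied as box constraints.  The fit is
#' deterministic given the data, starting values, and seed.
#'
#' @param problem a [fit_problem()].
#' @param start named numeric vector of starting values for (a subset of)
#'   the free parameters; defaults to the problem's parameter values.
#' @param seed integer seed used only for multi-start perturbations.
#' @param multistart number of starts; starts beyond the first perturb the
#'   log-parameters randomly and the best final fit is kept.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return an object of class \code{kinfit} with components
#'   \code{estimates}, \code{se}, \code{chi2}, \code{params} (full updated
#'   parameter set), \code{converged}, \code{iterations}, and the problem.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{deviance}, \code{simulate}, \code{plot},
#'   \code{confint} (via [contour_scan()]).
#' @examples
#' \donttest{
#' cfg <- generator_config("fig3_binding", seed = 1)
#' ex <- generate_stopped_flow_dataset(cfg)
#' pr <- fit_problem(list(ex), paper_fixture("fig3_binding")$params)
#' fit <- kinfit(pr)
#' summary(fit)
#' }
#' @export
kinfit <- function(problem, start = NULL, seed = NULL, multistart = 1,
                   control = minpack.lm::nls.lm.control(maxiter = 200)) {
  free <- problem$free
  if (!length(free)) {
    chi2 <- chi_square(problem)
    return(structure(list(problem = problem, params = problem$params,
                          estimates = numeric(0), se = numeric(0),
                          chi2 = chi2, converged = TRUE, iterations = 0L,
                          free = character(0), log = data.frame()),
                     class = "kinfit"))
  }
  p0 <- param_values(problem$params, free)
  if (!is.null(start)) {
    bad <- setdiff(names(start), free)
    if (length(bad)) stop("start values for non-free parameters: ",
                          paste(bad, collapse = ", "))
    p0[names(start)] <- start
  }
  lo <- stats::setNames(problem$params[free, "lower"], free)
  hi <- stats::setNames(problem$params[free, "upper"], free)
  lo[is.na(lo)] <- 1e-12; hi[is.na(hi)] <- 1e12
  if (any(p0 < lo | p0 > hi)) stop("start violates parameter bounds")

  run_one <- function(theta0) {
    fn <- function(theta) {
      r <- problem_residuals(problem, expand_free(problem, exp(theta)))
      if (is.null(r)) rep(1e6, 1L) else r
    }
    minpack.lm::nls.lm(theta0, lower = log(lo), upper = log(hi), fn = fn,
                       control = control)
  }
  starts <- list(log(p0))
  if (multistart > 1) {
    rng <- rng_stream(seed %||% 0)
    for (k in seq_len(multistart - 1L))
      starts[[k + 1L]] <- log(p0) + rng$norm(length(p0)) * log(3)
  }
  fits <- lapply(starts, run_one)
  best <- which.min(vapply(fits, `[[`, numeric(1), "deviance"))
  fit <- fits[[best]]
  est <- stats::setNames(exp(fit$par), free)
  pfull <- expand_free(problem, est)
  chi2 <- chi_square(problem, pfull)
  npts <- length(problem_residuals(problem, pfull))
  se <- tryCatch({
    cov <- solve(fit$hessian) * max(chi2 / max(1, npts - length(free)), 1e-300)
    est * sqrt(pmax(diag(cov), 0))  # delta method from log scale
  }, error = function(e) rep(NA_real_, length(free)))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("fit did not converge: ", fit$message)
  structure(list(problem = problem, params = pfull,
                 estimates = est, se = stats::setNames(se, free),
                 chi2 = chi2, n_points = npts, converged = converged,
                 iterations = fit$niter, free = free,
                 log = data.frame(iteration = seq_along(fit$rsstrace),
                                  chi2 = fit$rsstrace),
                 start = p0, seed = seed),
            class = "kinfit")
}

## Small deterministic normal stream independent of the global RNG.
rng_stream <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  list(norm = function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(env$state)
    env$state <- env$state + 1L
    stats::rnorm(n)
  })
}

#' @export
print.kinfit <- function(x, ...) {
  cat("Global fit by simulation:", length(x$free), "floated parameters,",
      x$n_points %||% NA, "data points\n")
  cat("chi-square:", format(x$chi2, digits = 6),
      if (!x$converged) " (NOT CONVERGED)" else "", "\n")
  if (length(x$estimates)) {
    df <- data.frame(estimate = signif(x$estimates, 4),
                     std.error = signif(x$se, 3))
    print(df)
  }
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  x <- object
  per_exp <- vapply(seq_along(x$problem$experiments), function(j) {
    sub <- x$problem
    sub$experiments <- x$problem$experiments[j]
    sub$sigma <- x$problem$sigma[j]
    chi_square(sub, x$params)
  }, numeric(1))
  out <- list(fit = x, per_experiment_chi2 = per_exp,
              kinds = vapply(x$problem$experiments, `[[`, "", "kind"))
  class(out) <- "summary.kinfit"
  out
}

#' @export
print.summary.kinfit <- function(x, ...) {
  print(x$fit)
  cat("\nper-experiment chi-square:\n")
  print(data.frame(kind = x$kinds, chi2 = signif(x$per_experiment_chi2, 5)))
  invisible(x)
}

#' @export
coef.kinfit <- function(object, all = FALSE, ...) {
  if (all) param_values(object$params) else object$estimates
}

#' @export
deviance.kinfit <- function(object, ...) object$chi2

#' @export
predict.kinfit <- function(object, experiment = NULL, ...) {
  idx <- experiment %||% seq_along(object$problem$experiments)
  out <- lapply(idx, function(j)
    simulate_experiment(object$problem$experiments[[j]], object$params,
                        object$problem, j))
  if (length(idx) == 1L) out[[1L]] else out
}

#' @export
residuals.kinfit <- function(object, ...) {
  problem_residuals(object$problem, object$params)
}

#' @export
simulate.kinfit <- function(object, nsim = 1, seed = NULL, ...) {
  rng <- rng_stream(seed %||% 0)
  lapply(seq_len(nsim), function(k) {
    lapply(seq_along(object$problem$experiments), function(j) {
      e <- object$problem$experiments[[j]]
      model <- simulate_experiment(e, object$params, object$problem, j)
      lapply(seq_along(model), function(i) {
        m <- model[[i]]
        m + rng$norm(length(as.numeric(m))) * object$problem$sigma[[j]][i]
      })
    })
  })
}

#' @export
plot.kinfit <- function(x, experiment = 1, ...) {
  e <- x$problem$experiments[[experiment]]
  model <- predict(x, experiment)
  is_quench <- e$kind == "quench"
  xs <- lapply(e$traces, function(tr)
    if (e$kind == "titration") cumsum(c(0, tr$step_volumes)) else tr$times)
  ylim <- range(unlist(lapply(e$traces, function(tr) as.numeric(tr$data))))
  xlim <- range(unlist(xs))
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = if (e$kind == "titration") "added volume (uL)" else "time (s)",
                 ylab = if (is_quench) "concentration (uM)" else "signal",
                 main = paste("experiment", experiment, "-", e$kind), ...)
  for (i in seq_along(e$traces)) {
    dat <- e$traces[[i]]$data
    if (is_quench) {
      for (k in seq_len(ncol(dat))) {
        graphics::points(xs[[i]], dat[, k], col = k, pch = 16, cex = 0.5)
        graphics::lines(xs[[i]], model[[i]][, k], col = k)
      }
    } else {
      graphics::points(xs[[i]], as.numeric(dat), col = i, pch = 16, cex = 0.4)
      graphics::lines(xs[[i]], as.numeric(model[[i]]), col = i)
    }
  }
  invisible(x)
}
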
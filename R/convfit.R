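#' Fit a sum of exponentials
#'
#' Fits \code{y = A0 + sum_i A_i (1 - exp(-b_i t))} with 1 to 4 phases by
#' Levenberg-Marquardt, seeded deterministically by exponential peeling on
#' log residuals so that repeated fits of the same data give identical
#' results.  Amplitudes are unconstrained in sign; rates are positive and
#' reported in descending order.
#'
#' @param times,values numeric vectors (times increasing, seconds).
#' @param n_phases number of exponential phases (1-4).
#' @return an object of class \code{exp_fit}: offset \code{A0},
#'   \code{amplitudes}, \code{rates} (descending, /s), standard errors,
#'   \code{residual_norm}, \code{n_phases}, and \code{flags} (may contain
#'   \code{"unconstrained_rate"} for constant data or
#'   \code{"near_degenerate_rates"} when two rates are within a factor of
#'   1.5).
#' @examples
#' t <- seq(0, 30, length.out = 40)
#' f <- fit_exponentials(t, 0.2 + 0.8 * (1 - exp(-0.194 * t)), 1)
#' f$rates
#' @export
fit_exponentials <- function(times, values, n_phases = 1) {
  stopifnot(n_phases %in% 1:4)
  if (any(diff(times) <= 0)) stop("times must be increasing")
  if (length(times) < 2 * n_phases + 1)
    stop("need at least ", 2 * n_phases + 1, " points for ", n_phases, " phases")
  if (stats::sd(values) < 1e-12 * max(1, abs(mean(values)))) {
    return(structure(list(A0 = mean(values),
                          amplitudes = rep(0, n_phases),
                          rates = rep(NA_real_, n_phases),
                          se = NULL, residual_norm = 0, n_phases = n_phases,
                          flags = "unconstrained_rate",
                          fitted = rep(mean(values), length(times)),
                          times = times, values = values),
                     class = "exp_fit"))
  }
  guess <- peel_exponentials(times, values, n_phases)
  model <- function(p) {
    A0 <- p[1L]
    A <- p[1L + seq_len(n_phases)]
    b <- exp(p[1L + n_phases + seq_len(n_phases)])
    A0 + colSums(A * (1 - exp(-b %o% times)))
  }
  p0 <- c(guess$A0, guess$A, log(guess$b))
  fit <- minpack.lm::nls.lm(p0, fn = function(p) values - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  A0 <- p[1L]; A <- p[1L + seq_len(n_phases)]
  b <- exp(p[1L + n_phases + seq_len(n_phases)])
  o <- order(b, decreasing = TRUE)
  A <- A[o]; b <- b[o]
  se <- tryCatch({
    cov <- solve(fit$hessian) * 2 *
      fit$deviance / max(1, length(times) - length(p))
    sqrt(pmax(diag(cov), 0))
  }, error = function(e) rep(NA_real_, length(p)))
  flags <- character()
  if (n_phases > 1 && any(b[-n_phases] / b[-1L] < 1.5))
    flags <- c(flags, "near_degenerate_rates")
  if (fit$info %in% c(0, 9)) flags <- c(flags, "not_converged")
  structure(list(A0 = unname(A0), amplitudes = unname(A), rates = unname(b),
                 se = se,
                 residual_norm = sqrt(fit$deviance), n_phases = n_phases,
                 flags = flags, fitted = model(p),
                 times = times, values = values),
            class = "exp_fit")
}

## Deterministic initial guesses by sequential peeling: estimate the
## slowest phase from a log-linear regression on the approach to plateau,
## subtract, repeat on the residual at early times.
peel_exponentials <- function(times, values, n_phases) {
  yinf <- mean(values[times >= stats::quantile(times, 0.8)])
  y0 <- values[1L]
  A0 <- y0
  span <- max(times[times > 0])
  tmin <- min(times[times > 0])
  ## log-spaced rate ladder between the resolvable extremes
  b <- exp(seq(log(1 / span), log(1 / tmin), length.out = max(n_phases, 2)))
  b <- sort(b[seq_len(n_phases)], decreasing = TRUE)
  ## refine slowest rate from the tail decay when signal is monotone
  resid <- yinf - values
  pos <- which(resid > 0.02 * max(abs(resid)) & times > 0)
  if (length(pos) >= 3) {
    co <- stats::coef(stats::lm(log(resid[pos]) ~ times[pos]))
    if (is.finite(co[2L]) && co[2L] < 0) b[n_phases] <- -co[2L]
  }
  A <- rep((yinf - y0) / n_phases, n_phases)
  list(A0 = A0, A = A, b = pmax(b, 1e-12))
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(x$n_phases, "-exponential fit: A0 = ", signif(x$A0, 4), "\n", sep = "")
  for (i in seq_len(x$n_phases))
    cat(sprintf("  phase %d: amplitude %.5g, rate %.5g /s\n",
                i, x$amplitudes[i], x$rates[i]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a hyperbola to rate-versus-concentration data
#'
#' Fits \code{y = A0 + A1 S / (Kd + S)}, the standard description of an
#' observed rate saturating with substrate concentration.  Seeds come from
#' a double-reciprocal regression, making the fit deterministic.  When the
#' data show no appreciable curvature (fitted Kd far beyond the sampled
#' range) the apparent Kd and maximum rate are individually undefined but
#' their ratio, the initial slope, remains well determined; the fit is then
#' flagged \code{"lower_bound_only"}.
#'
#' @param concs substrate concentrations (uM), at least 3 distinct.
#' @param kobs observed rates (/s).
#' @return an object of class \code{hyperbola_fit} with fields \code{A0},
#'   \code{A1}, \code{Kd_app} (uM), \code{initial_slope} (= A1/Kd,
#'   /uM/s), standard errors, \code{residual_norm} and \code{flags}.
#' @examples
#' S <- c(40, 150, 400, 1000, 2000, 3000)
#' fit_hyperbola(S, 5.8 + 332 * S / (1560 + S))
#' @export
fit_hyperbola <- function(concs, kobs) {
  if (length(unique(concs)) < 3)
    stop("need at least 3 distinct concentrations")
  A0g <- min(kobs)
  yr <- kobs - A0g
  pos <- yr > 0 & concs > 0
  if (sum(pos) >= 2) {
    ## 1/y = (Kd/A1)(1/S) + 1/A1
    co <- stats::coef(stats::lm(I(1 / yr[pos]) ~ I(1 / concs[pos])))
    A1g <- 1 / max(co[1L], 1e-12)
    Kdg <- max(co[2L] * A1g, 1e-9)
  } else {
    A1g <- max(kobs) - A0g
    Kdg <- stats::median(concs)
  }
  model <- function(p) p[1L] + p[2L] * concs / (exp(p[3L]) + concs)
  fit <- minpack.lm::nls.lm(c(A0g, A1g, log(Kdg)),
                            fn = function(p) kobs - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  Kd <- exp(p[3L])
  se <- tryCatch({
    cov <- solve(fit$hessian) * 2 *
      fit$deviance / max(1, length(kobs) - 3)
    s <- sqrt(pmax(diag(cov), 0)); s[3L] <- s[3L] * Kd; s
  }, error = function(e) rep(NA_real_, 3))
  flags <- character()
  if (Kd > 10 * max(concs)) flags <- c(flags, "lower_bound_only")
  structure(list(A0 = p[1L], A1 = p[2L], Kd_app = Kd,
                 initial_slope = p[2L] / Kd,
                 se = stats::setNames(se, c("A0", "A1", "Kd_app")),
                 residual_norm = sqrt(fit$deviance),
                 flags = flags, fitted = model(p),
                 concs = concs, kobs = kobs),
            class = "hyperbola_fit")
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic fit: A0 = %.4g /s, A1 = %.4g /s, Kd_app = %.4g uM\n",
              x$A0, x$A1, x$Kd_app))
  cat(sprintf("  initial slope A1/Kd = %.4g /uM/s\n", x$initial_slope))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Observed rates across a concentration series
#'
#' Fits each trace of a concentration series with an n-exponential function
#' and tabulates the phase rates by concentration, phases aligned by
#' descending rate.  Per-trace fit failures yield NA rows rather than
#' aborting the table.
#'
#' @param dataset list of traces, each a list with elements \code{conc}
#'   (uM), \code{times} and \code{values}.
#' @param n_phases number of phases; scalar or per-trace vector.
#' @return data.frame with column \code{conc} and one \code{rate<i>}
#'   column per phase (NA where a fit failed).
#' @export
rate_vs_concentration <- function(dataset, n_phases = 1) {
  if (!length(dataset))
    return(data.frame(conc = numeric()))
  np <- rep_len(n_phases, length(dataset))
  kmax <- max(np)
  rows <- lapply(seq_along(dataset), function(i) {
    tr <- dataset[[i]]
    rates <- rep(NA_real_, kmax)
    f <- tryCatch(fit_exponentials(tr$times, tr$values, np[i]),
                  error = function(e) {
                    warning("trace ", i, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) rates[seq_len(np[i])] <- f$rates
    c(conc = tr$conc, stats::setNames(rates, paste0("rate", seq_len(kmax))))
  })
  as.data.frame(do.call(rbind, rows))
}
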
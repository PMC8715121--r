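#' Chi-square ratio threshold from the F distribution
#'
#' Confidence-contour threshold for the ratio r = chi2_min / chi2(theta):
#' a parameter value is inside the confidence region when r exceeds
#' \deqn{[1 + p F_{1-\alpha}(p, n-p)/(n-p)]^{-1}} where p is the number of
#' floated parameters and n the number of data points (the standard
#' extra-sum-of-squares relation).  The threshold approaches 1 as n grows:
#' with many data points even small relative increases in chi-square are
#' significant.
#'
#' @param p number of floated parameters (>= 1).
#' @param n number of data points (> p).
#' @param alpha confidence level in (0, 1), default 0.95.
#' @return threshold ratio in (0, 1).
#' @examples
#' f_threshold(10, 500)   # about 0.964
#' @export
f_threshold <- function(p, n, alpha = 0.95) {
  if (p < 1) stop("p must be >= 1")
  if (n <= p) stop("need more data points than parameters (n > p)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  1 / (1 + p * stats::qf(alpha, p, n - p) / (n - p))
}

#' Confidence-contour scan for one parameter
#'
#' Profiles the chi-square ratio r(theta) = chi2_min / chi2(theta) over a
#' grid of values of one floated parameter: at each grid point the
#' parameter is fixed and all remaining floated parameters are
#' re-optimized (warm-started from the neighbouring solution).  The ratio
#' is compared with the F-distribution threshold to locate confidence
#' bounds; a side whose ratio never falls below the threshold is reported
#' open-ended, as happens for rate constants bounded only from below by
#' the data.
#'
#' @param fit a [kinfit()] result.
#' @param parameter name of a floated parameter.
#' @param grid numeric grid of parameter values; defaults to 21 log-spaced
#'   points per decade spanning 1.5 decades either side of the optimum.
#' @param alpha confidence level.
#' @param control optimizer control for the re-fits.
#' @return an object of class \code{contour_result}: \code{grid},
#'   \code{ratio}, \code{threshold}, \code{lower}/\code{upper} bounds with
#'   open-ended flags, and the scanned parameter name.
#' @export
contour_scan <- function(fit, parameter, grid = NULL, alpha = 0.95,
                         control = minpack.lm::nls.lm.control(maxiter = 100)) {
  problem <- fit$problem
  if (!parameter %in% fit$free)
    stop("parameter must be floated in the fit: ", parameter)
  best <- fit$estimates[[parameter]]
  if (is.null(grid)) {
    span <- 1.5
    grid <- best * 10^seq(-span, span, by = 1 / 21)
  }
  if (min(grid) > best || max(grid) < best)
    stop("grid must span the best-fit value")
  others <- setdiff(fit$free, parameter)
  sub <- problem
  sub$float <- setdiff(problem$float, parameter)
  sub$free <- others
  ratio <- rep(NA_real_, length(grid))
  ## scan outward from the grid point nearest the optimum, warm-starting
  ## each refit from its inner neighbour's solution
  i0 <- which.min(abs(log(grid / best)))
  eval_point <- function(i, start_vals) {
    sub$params <- set_param_values(problem$params,
                                   stats::setNames(grid[i], parameter))
    sub$params[parameter, "locked"] <- TRUE
    tryCatch({
      if (length(others)) {
        f <- suppressWarnings(kinfit(sub, start = start_vals,
                                     control = control))
        list(chi2 = f$chi2, est = f$estimates)
      } else {
        list(chi2 = chi_square(sub), est = start_vals)
      }
    }, error = function(e) NULL)
  }
  for (side in list(seq(i0, length(grid)), rev(seq_len(i0 - 1L)))) {
    current <- fit$estimates[others]
    for (i in side) {
      res <- eval_point(i, current)
      if (is.null(res)) next  # flagged point; scan continues
      current <- res$est
      ratio[i] <- fit$chi2 / res$chi2
    }
  }
  if (any(ratio > 1 + 1e-6, na.rm = TRUE))
    warning("a constrained refit improved on the reported optimum; ",
            "the original fit may not have fully converged")
  ratio <- pmin(ratio, 1)
  thr <- f_threshold(length(fit$free), fit$n_points, alpha)
  out <- structure(list(parameter = parameter, grid = grid, ratio = ratio,
                        threshold = thr, best = best, alpha = alpha),
                   class = "contour_result")
  bounds <- interval_from_contour(out)
  out$lower <- bounds$lower
  out$upper <- bounds$upper
  out
}

#' Confidence interval from a contour scan
#'
#' Locates where the chi-square ratio crosses the threshold on each side
#' of the optimum by monotone (log-linear) interpolation.  A side with no
#' crossing is open-ended.
#'
#' @param contour a \code{contour_result} from [contour_scan()].
#' @return list with \code{lower} and \code{upper}, each either a numeric
#'   bound or \code{NA} with attribute \code{open = TRUE}.
#' @export
interval_from_contour <- function(contour) {
  g <- contour$grid; r <- contour$ratio; thr <- contour$threshold
  ok <- !is.na(r)
  g <- g[ok]; r <- r[ok]
  if (!length(r) || max(r) < thr)
    stop("no grid point reaches the threshold; contour inconsistent with fit")
  imax <- which.max(r)
  left <- seq_len(imax - 1L)
  lower <- if (!length(left) || all(r[left] >= thr)) structure(NA_real_, open = TRUE)
  else {
    j <- max(which(r[left] < thr))
    k <- j + 1L
    w <- (thr - r[k]) / (r[j] - r[k])
    exp(log(g[k]) + w * (log(g[j]) - log(g[k])))
  }
  right <- seq(imax + 1L, length.out = max(0L, length(r) - imax))
  upper <- if (!length(right) || all(r[right] >= thr)) structure(NA_real_, open = TRUE)
  else {
    j <- right[min(which(r[right] < thr))]
    k <- j - 1L
    w <- (thr - r[k]) / (r[j] - r[k])
    exp(log(g[k]) + w * (log(g[j]) - log(g[k])))
  }
  list(lower = lower, upper = upper)
}

#' @export
print.contour_result <- function(x, ...) {
  fmt <- function(b) if (isTRUE(attr(b, "open"))) "open" else signif(b, 4)
  cat("Confidence contour for ", x$parameter, " (threshold ",
      signif(x$threshold, 4), ", ", 100 * x$alpha, "%)\n", sep = "")
  cat("  best fit:", signif(x$best, 5),
      "  interval: [", fmt(x$lower), ",", fmt(x$upper), "]\n")
  invisible(x)
}

#' @export
plot.contour_result <- function(x, ...) {
  graphics::plot(x$grid, x$ratio, log = "x", type = "b", pch = 16, cex = 0.6,
                 xlab = x$parameter, ylab = "chi2_min / chi2",
                 ylim = c(min(x$ratio, na.rm = TRUE), 1), ...)
  graphics::abline(h = x$threshold, lty = 2, col = "gray40")
  graphics::abline(v = x$best, lty = 3)
  invisible(x)
}

#' @export
confint.kinfit <- function(object, parm = NULL, level = 0.95, ...) {
  parm <- parm %||% object$free
  out <- t(vapply(parm, function(p) {
    sc <- contour_scan(object, p, alpha = level, ...)
    c(lower = as.numeric(sc$lower), upper = as.numeric(sc$upper))
  }, numeric(2)))
  out
}
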
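#' Coefficient of overlap between two activity patterns
#'
#' The Delta-1 estimator: the circular (trapezoidal) integral of the
#' pointwise minimum of the two von Mises kernel density estimates,
#' evaluated on a shared grid. Ranges from 0 (no overlap) to 1
#' (identical activity patterns); symmetric in its arguments and
#' invariant under a common rotation of both samples.
#'
#' @param x1,x2 event times of the two species, sun-time radians.
#' @param adjust bandwidth adjustment factor (0.8, the small-sample
#'   convention for Delta-1).
#' @param m grid size.
#' @return the overlap estimate in `[0, 1]`.
#' @export
overlap_delta1 <- function(x1, x2, adjust = 0.8, m = 128L) {
  f1 <- vm_kernel_density(x1, adjust = adjust, m = m)
  f2 <- vm_kernel_density(x2, adjust = adjust, m = m)
  min(mean(pmin(f1$values, f2$values)) * 2 * pi, 1)
}

#' @rdname overlap_delta1
#' @details `overlap_delta4()` is the large-sample variant preferred
#'   when both samples exceed roughly 75 events: it averages
#'   `min(1, f2/f1)` over the first sample and `min(1, f1/f2)` over the
#'   second, with densities evaluated at the observed points
#'   (conventional `adjust = 1`).
#' @export
overlap_delta4 <- function(x1, x2, adjust = 1, m = 128L) {
  f1 <- vm_kernel_density(x1, adjust = adjust, m = m)
  f2 <- vm_kernel_density(x2, adjust = adjust, m = m)
  d11 <- vm_kde_eval(f1$x, f1$x, f1$kappa)
  d21 <- vm_kde_eval(f1$x, f2$x, f2$kappa)
  d22 <- vm_kde_eval(f2$x, f2$x, f2$kappa)
  d12 <- vm_kde_eval(f2$x, f1$x, f1$kappa)
  (mean(pmin(1, d21 / d11)) + mean(pmin(1, d12 / d22))) / 2
}

#' Smoothed-bootstrap confidence interval for the overlap coefficient
#'
#' Resamples each species from its fitted kernel density (a data point
#' drawn uniformly plus von Mises kernel noise), recomputes Delta-1 for
#' every replicate pair, and returns the percentile interval. Seeded and
#' fully reproducible.
#'
#' The default interval is the centred percentile: the bootstrap draws
#' are recentred on the point estimate before taking quantiles, because
#' the mean of smoothed-bootstrap replicates is systematically offset
#' from the estimate (the kernel noise inflates replicate overlap) and
#' the raw percentile interval under-covers noticeably. The raw
#' percentile construction remains available via `type`.
#'
#' @inheritParams overlap_delta1
#' @param reps bootstrap replicates (the survey convention is 10,000).
#' @param level confidence level.
#' @param type interval construction: `"centered"` (recentred
#'   percentile, default) or `"percentile"` (raw quantiles).
#' @param seed RNG seed.
#' @return an `overlap_result`: `delta1`, `ci_low`, `ci_high`, `reps`,
#'   `n1`, `n2`, `level`, plus the bootstrap draws as attribute
#'   `"boot"`.
#' @export
bootstrap_ci <- function(x1, x2, reps = 10000L, level = 0.95,
                         adjust = 0.8, m = 128L,
                         type = c("centered", "percentile"), seed = 1L) {
  type <- match.arg(type)
  if (reps < 100) stop("use at least 100 bootstrap replicates")
  f1 <- vm_kernel_density(x1, adjust = adjust, m = m)
  f2 <- vm_kernel_density(x2, adjust = adjust, m = m)
  est <- min(mean(pmin(f1$values, f2$values)) * 2 * pi, 1)
  n1 <- length(x1); n2 <- length(x2)
  set.seed(seed)
  draw <- function(f, n) {
    idx <- sample.int(f$n, n, replace = TRUE)
    (f$x[idx] + rvonmises(n, 0, f$kappa)) %% (2 * pi)
  }
  boot <- vapply(seq_len(reps), function(r)
    overlap_delta1(draw(f1, n1), draw(f2, n2), adjust = adjust, m = m),
    numeric(1))
  base <- if (type == "centered") boot - mean(boot) + est else boot
  qs <- stats::quantile(base, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(delta1 = est, ci_low = max(qs[1], 0),
                 ci_high = min(qs[2], 1), reps = reps, n1 = n1, n2 = n2,
                 level = level, type = type, seed = seed),
            class = "overlap_result", boot = boot)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> Delta-1 = %.3f, %d%% CI [%.3f, %.3f] (%d bootstrap reps; n = %d, %d)\n",
    x$delta1, round(100 * x$level), x$ci_low, x$ci_high, x$reps, x$n1, x$n2))
  invisible(x)
}

#' Plot two activity densities with their overlap shaded
#'
#' @param x1,x2 event times (sun-time radians).
#' @param labels species labels for the legend.
#' @param adjust,m as in [overlap_delta1()].
#' @param ... passed to [plot()].
#' @return the overlap estimate, invisibly.
#' @export
plot_overlap <- function(x1, x2, labels = c("species 1", "species 2"),
                         adjust = 0.8, m = 128L, ...) {
  f1 <- vm_kernel_density(x1, adjust = adjust, m = m)
  f2 <- vm_kernel_density(x2, adjust = adjust, m = m)
  d1 <- min(mean(pmin(f1$values, f2$values)) * 2 * pi, 1)
  g <- c(f1$grid, 2 * pi)
  lo <- pmin(f1$values, f2$values); lo <- c(lo, lo[1])
  ylim <- c(0, max(f1$values, f2$values) * 1.1)
  plot(f1, main = sprintf("Overlap %s - %s (Delta-1 = %.2f)",
                          labels[1], labels[2], d1), ylim = ylim, ...)
  plot(f2, add = TRUE, lty = 2)
  graphics::polygon(c(g, rev(g)), c(lo, rep(0, length(g))),
                    col = grDevices::adjustcolor("grey", 0.6), border = NA)
  graphics::legend("topright", legend = labels, lty = c(1, 2), bty = "n")
  invisible(d1)
}
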
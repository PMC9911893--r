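#' Ks frequency histogram
#'
#' Density histogram of Ks values on a fixed range; densities integrate to
#' 1 over the range.
#' @param values Ks values, all inside \code{range}.
#' @param n_bins Number of bins (default 200).
#' @param range Two-element (lo, hi).
#' @return List with \code{bin_edges} (length \code{n_bins + 1}),
#'   \code{mids} and \code{density}.
#' @export
ks_histogram <- function(values, n_bins = 200, range = c(0.05, 1.5)) {
  if (length(values) == 0) stop("empty Ks sample", call. = FALSE)
  if (any(values < range[1] | values > range[2]))
    stop("values outside the histogram range", call. = FALSE)
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  h <- graphics::hist(values, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(bin_edges = edges, mids = h$mids, density = h$density)
}

#' Split a Ks sample at the inter-peak trough
#'
#' @param values Ks values (already filtered to the analysis window).
#' @param trough Split point; values strictly below go to the young subset,
#'   values at or above to the old subset.
#' @return List with \code{young} and \code{old} numeric vectors.
#' @export
split_at_trough <- function(values, trough = 0.6) {
  list(young = values[values < trough], old = values[values >= trough])
}

# sum of squared errors of a Gaussian curve against binned densities
.gauss_sse <- function(par, mids, dens) {
  m <- par[1]; s <- exp(par[2]); a <- exp(par[3])
  sum((a * exp(-(mids - m)^2 / (2 * s^2)) - dens)^2)
}

#' Fit a Gaussian to one Ks subset
#'
#' Builds the subset's own \code{n_bins}-bin density and fits a
#' three-parameter Gaussian curve (location, scale, amplitude) by least
#' squares, with the location initialized at the subset median
#' (median-anchored, \code{mode = "median"}) and the scale at half the
#' interquartile range. The fitted location is the reported WGD peak.
#'
#' @param subset Ks values of one component (at least \code{min_n}).
#' @param mode Initialization mode; only \code{"median"} is implemented.
#' @param n_bins Bins for the subset density (default 200).
#' @param min_n Minimum subset size (default 50).
#' @param weight Fraction of the full sample in this subset (carried into
#'   the result; default 1).
#' @return List with \code{peak}, \code{sd}, \code{weight} and \code{sse}.
#' @export
fit_component <- function(subset, mode = "median", n_bins = 200,
                          min_n = 50, weight = 1) {
  mode <- match.arg(mode, "median")
  if (length(subset) < min_n)
    stop(sprintf(
      "subset of %d values is below the minimum of %d; lower n_bins or pool data",
      length(subset), min_n), call. = FALSE)
  h <- ks_histogram(subset, n_bins = n_bins, range = range(subset))
  m0 <- stats::median(subset)
  s0 <- max(stats::IQR(subset) / 2, diff(range(subset)) / n_bins)
  a0 <- max(h$density)
  fit <- stats::optim(c(m0, log(s0), log(a0)), .gauss_sse,
                      mids = h$mids, dens = h$density,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(peak = fit$par[1], sd = exp(fit$par[2]), weight = weight,
       sse = fit$value)
}

#' Locate WGD peaks by trough-splitting and per-component Gaussian fits
#'
#' Splits the Ks sample at the trough, fits one Gaussian per subset
#' (\code{\link{fit_component}}), and reports components sorted by
#' ascending peak. With \code{trough = "auto"} the split point is the
#' minimum of a smoothed density between the two largest modes (opt-in;
#' the fixed trough reproduces the standard procedure).
#'
#' @param values Ks values filtered to \code{range}.
#' @param trough Fixed split point (default 0.6) or \code{"auto"}.
#' @param n_bins Bins per subset density.
#' @param range Analysis window (exclusive bounds already applied).
#' @param min_n Minimum subset size passed to \code{\link{fit_component}}.
#' @return A \code{mixture_fit}: \code{components} data frame (peak, sd,
#'   weight), \code{trough}, \code{n_bins}, \code{range}, \code{n}.
#' @export
fit_wgd_peaks <- function(values, trough = 0.6, n_bins = 200,
                          range = c(0.05, 1.5), min_n = 50) {
  if (identical(trough, "auto")) trough <- find_trough(values, range = range)
  parts <- split_at_trough(values, trough)
  comps <- lapply(c("young", "old"), function(k) {
    v <- parts[[k]]
    if (length(v) == 0)
      stop(sprintf("the %s subset is empty; is there a single WGD?", k),
           call. = FALSE)
    fit_component(v, n_bins = n_bins, min_n = min_n,
                  weight = length(v) / length(values))
  })
  comps <- comps[order(vapply(comps, `[[`, numeric(1), "peak"))]
  structure(list(
    components = data.frame(
      peak = vapply(comps, `[[`, numeric(1), "peak"),
      sd = vapply(comps, `[[`, numeric(1), "sd"),
      weight = vapply(comps, `[[`, numeric(1), "weight")),
    trough = trough, n_bins = n_bins, range = range, n = length(values)),
    class = "mixture_fit")
}

#' Automatic trough location between the two largest density modes
#'
#' Minimum of a kernel-smoothed density between the two most prominent
#' local maxima; opt-in alternative to the fixed trough.
#' @param values Ks values.
#' @param range Analysis window.
#' @export
find_trough <- function(values, range = c(0.05, 1.5)) {
  d <- stats::density(values, from = range[1], to = range[2], n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) < 2)
    stop("fewer than two density modes; cannot locate a trough", call. = FALSE)
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  seg <- top2[1]:top2[2]
  d$x[seg[which.min(y[seg])]]
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Ks mixture fit (n = %d, trough = %.3g)\n", x$n, x$trough))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  component %d: peak = %.4f, sd = %.4f, weight = %.3f\n",
                i, x$components$peak[i], x$components$sd[i],
                x$components$weight[i]))
  invisible(x)
}
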
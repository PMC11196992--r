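## Distribution analysis of the stalling index: histogram, kernel-density
## bimodality, and the valley between the two modes that serves as the
## pause cutoff.

#' Histogram of stalling-index values
#'
#' Fixed-width, left-closed bins (`[edge, edge + bin_width)`; the last bin
#' also includes its right edge) covering the range of the finite values.
#' Counts conserve the number of finite values.
#'
#' @param si Numeric vector of stalling indices; non-finite values are
#'   dropped.
#' @param bin_width Bin width in log2 units (default 0.2).
#' @return List with `breaks` (bin edges), `counts` and `mids`.
#' @export
si_histogram <- function(si, bin_width = 0.2) {
  x <- si[is.finite(si)]
  if (length(x) == 0L) stop("no finite stalling-index values", call. = FALSE)
  .assert_scalar_number(bin_width, "bin_width")
  if (bin_width <= 0) stop("'bin_width' must be > 0", call. = FALSE)
  lo <- floor(min(x) / bin_width) * bin_width
  n_bins <- max(1L, floor((max(x) - lo) / bin_width + 1e-9) + 1L)
  breaks <- lo + bin_width * seq.int(0L, n_bins)
  h <- graphics::hist(x, breaks = breaks, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Valley between the two modes of the stalling-index distribution
#'
#' Estimates the density of the finite stalling-index values with a
#' Gaussian kernel on a fixed grid spanning the data range, identifies the
#' two highest-density local maxima, and returns the grid point of minimum
#' density strictly between them — the pause cutoff.  When the density has
#' no two modes (or no interior minimum separates them) the result is an
#' explicit no-cutoff answer, never a fabricated number.
#'
#' Local maxima whose density is below `min_mode_frac` of the global
#' maximum are not counted as modes, so negligible sampling wiggles in a
#' tail cannot masquerade as a second mode.  Ties between equal-density
#' interior minima resolve to the leftmost grid point (the conservative
#' side: fewer genes called paused at equal evidence).
#'
#' @param si Numeric vector of stalling indices; non-finite values are
#'   dropped before analysis.
#' @param bandwidth Kernel bandwidth; `NULL` (default) uses Silverman's
#'   rule of thumb ([stats::bw.nrd0()]).  The recovered cutoff depends on
#'   it, which is why it is exposed.
#' @param n_grid Number of density grid points (default 512).
#' @param min_mode_frac Minimum density of a countable mode, as a fraction
#'   of the global density maximum (default 0.05).
#' @return List with `cutoff` (`NA` when no cutoff exists), `modes`
#'   (locations of the two retained modes, or all retained modes when < 2),
#'   `bandwidth`, `n` (number of finite values used) and `status`
#'   (`"ok"` or `"no_cutoff"`).
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, -1), rnorm(500, 5))
#' find_pause_cutoff(x)$cutoff
find_pause_cutoff <- function(si, bandwidth = NULL, n_grid = 512L,
                              min_mode_frac = 0.05) {
  x <- si[is.finite(si)]
  if (length(x) < 2L)
    stop("need at least 2 finite stalling-index values", call. = FALSE)
  bw <- bandwidth %||% bw.nrd0(x)
  d <- density(x, bw = bw, n = n_grid, from = min(x), to = max(x))
  y <- d$y
  n <- length(y)
  interior <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] &
                    y[-c(1L, n)] >= y[-c(1L, 2L)]) + 1L
  maxima <- interior
  if (y[1] > y[2]) maxima <- c(1L, maxima)
  if (y[n] > y[n - 1L]) maxima <- c(maxima, n)
  maxima <- maxima[y[maxima] >= min_mode_frac * max(y)]
  no_cutoff <- list(cutoff = NA_real_, modes = d$x[maxima], bandwidth = bw,
                    n = length(x), status = "no_cutoff")
  if (length(maxima) < 2L) return(no_cutoff)
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  if (top2[2] - top2[1] < 2L) return(no_cutoff)
  between <- (top2[1] + 1L):(top2[2] - 1L)
  j <- between[which.min(y[between])]
  list(cutoff = d$x[j], modes = d$x[top2], bandwidth = bw,
       n = length(x), status = "ok")
}

#' Count values at or above a threshold
#'
#' `|{si >= threshold}|` over the finite values; the tally of genes called
#' paused at a given cutoff.
#'
#' @param si Numeric vector of stalling indices.
#' @param threshold Finite threshold.
#' @return Integer count.
#' @export
count_above <- function(si, threshold) {
  .assert_scalar_number(threshold, "threshold")
  sum(si[is.finite(si)] >= threshold)
}
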
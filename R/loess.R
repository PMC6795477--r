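#' Tricube local linear smoothing with a fixed bandwidth in bp
#'
#' The smoothers in this package are local LINEAR regressions with tricube
#' weights over a centered window of fixed genomic width (not a
#' fraction-of-data span): at an evaluation point `x0`, points within
#' `window_bp / 2` receive weight `(1 - (d / h)^3)^3` with `h = window_bp / 2`,
#' a weighted straight line is fitted, and its value at `x0` is returned.
#' Missing values are excluded from each local fit; where fewer than 3 points
#' contribute the output is `NA`. Exactly linear input is reproduced exactly
#' at interior points.
#'
#' @param x Numeric predictor positions (bp), sorted increasing.
#' @param y Numeric responses, `NA` allowed.
#' @param xout Evaluation positions (bp).
#' @param window_bp Full window width in bp.
#' @return Numeric vector of fitted values at `xout`.
#' @export
loess_fit_points <- function(x, y, xout, window_bp) {
  h <- window_bp / 2
  ok <- !is.na(y) & !is.na(x)
  x <- x[ok]; y <- y[ok]
  out <- rep(NA_real_, length(xout))
  if (length(x) == 0) return(out)
  # windowed lookup on sorted x
  lo <- findInterval(xout - h, x) + 1
  hi <- findInterval(xout + h, x)
  for (i in seq_along(xout)) {
    if (hi[i] < lo[i]) next
    xi <- x[lo[i]:hi[i]]; yi <- y[lo[i]:hi[i]]
    d <- abs(xi - xout[i])
    inw <- d < h
    if (sum(inw) < 3) next
    xi <- xi[inw] - xout[i]; yi <- yi[inw]
    w <- (1 - (d[inw] / h)^3)^3
    sw <- sum(w); swx <- sum(w * xi); swy <- sum(w * yi)
    swxx <- sum(w * xi^2); swxy <- sum(w * xi * yi)
    den <- sw * swxx - swx^2
    out[i] <- if (den <= .Machine$double.eps * sw * swxx * 4 || swxx == 0)
      swy / sw                                  # degenerate: weighted mean
    else (swxx * swy - swx * swxy) / den        # intercept at xout[i]
  }
  out
}

#' LOESS-smooth a binned track in place
#'
#' Smooths a marker-frequency (or any binned) track with the fixed-bandwidth
#' tricube local linear smoother, evaluated at every grid point of the input
#' track. The replication profiles use a 50 kb window on 1 kb bins.
#'
#' @param track A [binned_track].
#' @param window_bp Full smoothing window in bp; must be at least 3 steps.
#' @return A [binned_track] on the same grid.
#' @export
loess_smooth <- function(track, window_bp = 50000) {
  stopifnot(inherits(track, "binned_track"))
  if (window_bp < 3 * track$step)
    stop("window_bp must be >= 3 x step")
  pos <- track_positions(track)
  binned_track(track$chrom, track$start, track$step,
               loess_fit_points(pos, track$values, pos, window_bp))
}

#' Smooth probe values onto a regular fine grid
#'
#' Applies the same smoothing contract as [loess_smooth] but from irregular
#' probe positions onto a regular grid, producing the smoothed ssDNA profile
#' at 0.25 kb intervals. The default 6 kb window is widened to 9 kb for the
#' noisier overexpression samples.
#'
#' @param track A [probe_track].
#' @param window_bp Full smoothing window in bp (6000 default, 9000 for
#'   overexpression samples).
#' @param grid_step Output grid spacing in bp (250 default).
#' @return A [binned_track] starting at the first grid point at or below the
#'   first probe.
#' @export
smooth_to_grid <- function(track, window_bp = 6000, grid_step = 250) {
  stopifnot(inherits(track, "probe_track"))
  if (length(track$positions) == 0) {
    warning(sprintf("empty chromosome %s: empty smoothed output", track$chrom))
    return(binned_track(track$chrom, grid_step, grid_step, NA_real_))
  }
  g0 <- max(grid_step, floor(min(track$positions) / grid_step) * grid_step)
  g1 <- ceiling(max(track$positions) / grid_step) * grid_step
  grid <- seq(g0, g1, by = grid_step)
  binned_track(track$chrom, g0, grid_step,
               loess_fit_points(track$positions, track$values, grid,
                                window_bp))
}
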
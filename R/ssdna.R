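#' Per-probe S/G1 ssDNA ratio
#'
#' Forms the ratio of ssDNA labeled in S phase relative to G1 at each probe.
#' Probes whose G1 value is zero or missing are dropped; the count is reported
#' via a message and attribute `n_dropped`.
#'
#' @param s_probes,g1_probes [probe_track]s on identical probe positions.
#' @return A [probe_track] of ratios.
#' @export
form_ratio <- function(s_probes, g1_probes) {
  stopifnot(inherits(s_probes, "probe_track"),
            inherits(g1_probes, "probe_track"))
  if (!identical(s_probes$chrom, g1_probes$chrom) ||
      length(s_probes$positions) != length(g1_probes$positions) ||
      any(s_probes$positions != g1_probes$positions))
    stop("S and G1 probe positions do not match")
  bad <- is.na(g1_probes$values) | g1_probes$values == 0 |
    is.na(s_probes$values)
  if (any(bad))
    message(sprintf("form_ratio: %d probe(s) dropped (G1 zero or missing)",
                    sum(bad)))
  out <- probe_track(s_probes$chrom, s_probes$positions[!bad],
                     s_probes$values[!bad] / g1_probes$values[!bad])
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Remove genome-wide ssDNA outliers
#'
#' Discards probe values more than 8 standard deviations above or more than 2
#' standard deviations below the genome-wide mean. Mean and sample SD are
#' computed once over all chromosomes before any removal; the asymmetric
#' bounds reflect that hybridization artifacts spike high while the
#' informative dynamic range sits just above baseline.
#'
#' @param tracks A [probe_track] or named list of them (the whole genome).
#' @return The filtered track(s), same structure as the input, with attribute
#'   `n_removed`.
#' @export
filter_outliers <- function(tracks) {
  single <- inherits(tracks, "probe_track")
  tl <- if (single) list(tracks) else tracks
  all_v <- unlist(lapply(tl, `[[`, "values"))
  if (length(all_v) < 2) stop("need at least 2 probe values genome-wide")
  m <- mean(all_v, na.rm = TRUE)
  s <- stats::sd(all_v, na.rm = TRUE)
  upper <- m + 8 * s; lower <- m - 2 * s
  removed <- 0L
  out <- lapply(tl, function(t) {
    bad <- t$values > upper | t$values < lower
    bad[is.na(bad)] <- TRUE
    removed <<- removed + sum(bad)
    probe_track(t$chrom, t$positions[!bad], t$values[!bad])
  })
  if (removed > 0)
    message(sprintf("filter_outliers: %d probe(s) removed", removed))
  res <- if (single) out[[1]] else stats::setNames(out, names(tl))
  attr(res, "n_removed") <- removed
  res
}

#' Rescale smoothed ssDNA values onto the [1, 2] range
#'
#' Applies the affine transform
#' `rescaled = (v - baseline) / (max - baseline) + 1`,
#' where `baseline` is the mode of the distribution of all smoothed values
#' genome-wide (estimated as the argmax of a Gaussian kernel density with
#' Silverman's rule-of-thumb bandwidth) and `max` is the genome-wide maximum.
#' The baseline maps to 1, the maximum to 2, and ordering is preserved, so
#' peak heights become comparable across samples.
#'
#' @param tracks A [binned_track] or named list of them (the whole genome's
#'   smoothed profile).
#' @return The rescaled track(s), with attributes `baseline` and `max`.
#' @export
rescale_track <- function(tracks) {
  single <- inherits(tracks, "binned_track")
  tl <- if (single) list(tracks) else tracks
  all_v <- unlist(lapply(tl, `[[`, "values"))
  all_v <- all_v[!is.na(all_v)]
  if (length(all_v) < 2) stop("need at least 2 smoothed values to rescale")
  if (max(all_v) <= min(all_v))
    stop("flat genome: maximum does not exceed the modal baseline")
  dens <- stats::density(all_v, bw = "nrd0")
  baseline <- dens$x[which.max(dens$y)]
  vmax <- max(all_v)
  if (vmax <= baseline)
    stop("flat genome: maximum does not exceed the modal baseline")
  out <- lapply(tl, function(t)
    binned_track(t$chrom, t$start, t$step,
                 (t$values - baseline) / (vmax - baseline) + 1))
  res <- if (single) out[[1]] else stats::setNames(out, names(tl))
  attr(res, "baseline") <- baseline
  attr(res, "max") <- vmax
  res
}

raw_local_maxima <- function(track) {
  v <- track$values
  n <- length(v)
  if (n < 3) return(integer(0))
  d <- diff(v)
  i <- 2:(n - 1)
  ok <- !is.na(d[i - 1]) & !is.na(d[i]) & d[i - 1] > 0 & d[i] < 0
  i[ok]
}

#' Call origin peaks from a smoothed ssDNA profile
#'
#' Raw peaks are all interior grid points where the slope of the smoothed
#' profile changes from positive to negative — including the small maxima in
#' the baseline noise. Significant peaks are those in the top `top_fraction`
#' of raw peak heights (threshold = the `1 - top_fraction` quantile). A
#' significant peak sitting on the shoulder of a taller significant peak less
#' than `merge_distance` away is merged into it (the taller one is kept; on a
#' height tie the leftmost wins).
#'
#' @param tracks A smoothed [binned_track] or named list of them.
#' @param top_fraction Fraction of raw peaks called significant (0.05).
#' @param merge_distance Minimum separation of significant peaks in bp (5000).
#' @param sample Sample label recorded in the result.
#' @return An object of class `peak_set`: a list with `sample`, `peaks` (a
#'   `data.frame` with chrom, position, height, significant, merged_into),
#'   `threshold` and `n_raw`.
#' @export
call_peaks <- function(tracks, top_fraction = 0.05, merge_distance = 5000,
                       sample = "sample") {
  single <- inherits(tracks, "binned_track")
  tl <- if (single) list(tracks) else tracks
  rows <- list()
  for (t in tl) {
    if (length(t$values) < 3) {
      warning(sprintf("fewer than 3 grid points on %s: skipped", t$chrom))
      next
    }
    idx <- raw_local_maxima(t)
    if (length(idx) == 0) next
    pos <- track_positions(t)[idx]
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = t$chrom, position = pos, height = t$values[idx])
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), position = numeric(), height = numeric())
  n_raw <- nrow(peaks)
  if (n_raw > 0) {
    threshold <- stats::quantile(peaks$height, 1 - top_fraction, names = FALSE)
    peaks$significant <- peaks$height >= threshold
    peaks$merged_into <- NA_integer_
    # shoulder rule: among significant peaks, keep the taller of any pair
    # closer than merge_distance; tallest first, leftmost on ties
    sig <- which(peaks$significant)
    ord <- sig[order(-peaks$height[sig], peaks$position[sig])]
    kept <- integer(0)
    for (i in ord) {
      near <- kept[peaks$chrom[kept] == peaks$chrom[i] &
                     abs(peaks$position[kept] - peaks$position[i]) <
                       merge_distance]
      if (length(near) > 0) {
        peaks$significant[i] <- FALSE
        peaks$merged_into[i] <- near[1]
      } else kept <- c(kept, i)
    }
  } else threshold <- NA_real_
  peaks <- peaks[order(peaks$chrom, peaks$position), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(sample = sample, peaks = peaks, threshold = threshold,
                 n_raw = n_raw),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf(
    "<peak_set> %s: %d raw local maxima, %d significant (threshold %.4g)\n",
    x$sample, x$n_raw, sum(x$peaks$significant), x$threshold))
  invisible(x)
}

#' Significant peak positions of a peak set
#' @param pset A `peak_set`.
#' @return `data.frame` with chrom, position, height of significant peaks.
#' @export
significant_peaks <- function(pset) {
  p <- pset$peaks[pset$peaks$significant, c("chrom", "position", "height")]
  rownames(p) <- NULL
  p
}

#' Area under a rescaled ssDNA peak window
#'
#' Sums the rescaled values in a window centered on an origin: 41 grid points
#' for the default 10 kb window at 0.25 kb step, 65 for the 16 kb variant used
#' with the broader overexpression peaks. Missing grid points contribute the
#' baseline value 1.0 (their count is available as attribute `n_filled`).
#'
#' @param track A rescaled [binned_track] (or named list; the origin's
#'   chromosome is then selected).
#' @param origin_position Window center in bp.
#' @param half_width Half window width in bp (5000 default; 8000 for the
#'   overexpression samples).
#' @param chrom Chromosome of the origin (required when `track` is a list).
#' @return The window area (a single number) with attribute `n_filled`.
#' @export
peak_area <- function(track, origin_position, half_width = 5000,
                      chrom = NULL) {
  if (!inherits(track, "binned_track")) {
    if (is.null(chrom)) stop("chrom is required when track is a list")
    if (!chrom %in% names(track))
      stop(sprintf("origin chromosome '%s' not in track set", chrom))
    track <- track[[chrom]]
  } else if (!is.null(chrom) && !identical(chrom, track$chrom)) {
    stop(sprintf("origin is on '%s' but track is on '%s'", chrom,
                 track$chrom))
  }
  w <- extract_window(track, origin_position, half_width)
  n_fill <- sum(is.na(w))
  w[is.na(w)] <- 1.0
  structure(sum(w), n_filled = n_fill)
}

#' Peak areas for a table of origins
#'
#' @param tracks Named list of rescaled [binned_track].
#' @param origins `data.frame` with columns `chrom`, `position` and
#'   optionally `id` (generated when absent).
#' @param half_width Half window width in bp.
#' @return `data.frame` with `id`, `chrom`, `position`, `area`.
#' @export
peak_areas <- function(tracks, origins, half_width = 5000) {
  if (is.null(origins$id))
    origins$id <- sprintf("peak%03d", seq_len(nrow(origins)))
  areas <- vapply(seq_len(nrow(origins)), function(i)
    as.numeric(peak_area(tracks, origins$position[i],
                         half_width = half_width,
                         chrom = origins$chrom[i])), 0)
  data.frame(id = origins$id, chrom = origins$chrom,
             position = origins$position, area = areas,
             stringsAsFactors = FALSE)
}

#' Full ssDNA processing pipeline for one sample
#'
#' Runs ratio probes through outlier filtering, smoothing onto the 0.25 kb
#' grid, and rescaling; optionally calls peaks.
#'
#' @param ratio_tracks Named list of [probe_track] of S/G1 ratios.
#' @param window_bp LOESS window (6000; use 9000 for overexpression samples).
#' @param grid_step Output grid (250 bp).
#' @param sample Sample label.
#' @return List with `filtered` (probe tracks), `smoothed` and `rescaled`
#'   (binned tracks) and `peaks` (a `peak_set`).
#' @export
process_ssdna <- function(ratio_tracks, window_bp = 6000, grid_step = 250,
                          sample = "sample") {
  filtered <- filter_outliers(ratio_tracks)
  smoothed <- stats::setNames(
    lapply(filtered, smooth_to_grid, window_bp = window_bp,
           grid_step = grid_step),
    names(filtered))
  rescaled <- rescale_track(smoothed)
  pk <- call_peaks(smoothed, sample = sample)
  list(filtered = filtered, smoothed = smoothed, rescaled = rescaled,
       peaks = pk)
}
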
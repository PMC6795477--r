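#' Genomic signal on a regular grid
#'
#' A `binned_track` stores one chromosome's signal at a fixed step: marker
#' frequency at 1 kb bins, or smoothed ssDNA on the 0.25 kb grid. Coordinates
#' are 1-based; the value in slot `i` belongs to the grid point
#' `start + (i - 1) * step`. Missing values are explicit `NA`s, never dropped,
#' so downstream summaries can choose their own policy.
#'
#' @param chrom Chromosome name.
#' @param start 1-based position of the first grid point (bp).
#' @param step Grid spacing in bp (> 0).
#' @param values Numeric vector of signal values; `NA` marks missing bins.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(chrom, start, step, values) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(step) == 1L)
  if (step <= 0) stop("step must be > 0")
  if (length(values) < 1L) stop("a binned_track needs at least one value")
  structure(
    list(chrom = as.character(chrom), start = as.numeric(start),
         step = as.numeric(step), values = as.numeric(values)),
    class = "binned_track"
  )
}

#' Grid-point coordinates of a binned track
#' @param track A `binned_track`.
#' @return Numeric vector of 1-based bp positions, strictly increasing.
#' @export
track_positions <- function(track) {
  track$start + (seq_along(track$values) - 1) * track$step
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s: %d bins, step %g bp, start %g, %d missing\n",
              x$chrom, length(x$values), x$step, x$start, sum(is.na(x$values))))
  invisible(x)
}

#' Genomic signal at irregular probe positions
#'
#' A `probe_track` carries per-probe values (raw ssDNA S/G1 ratios) at strictly
#' increasing bp positions on one chromosome.
#'
#' @param chrom Chromosome name.
#' @param positions Strictly increasing 1-based bp positions.
#' @param values One numeric value per position.
#' @return An object of class `probe_track`.
#' @export
probe_track <- function(chrom, positions, values) {
  if (length(positions) != length(values))
    stop("positions and values must have equal length")
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("probe positions must be strictly increasing")
  structure(
    list(chrom = as.character(chrom), positions = as.numeric(positions),
         values = as.numeric(values)),
    class = "probe_track"
  )
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("<probe_track> %s: %d probes spanning %g-%g bp\n",
              x$chrom, length(x$positions),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Extract a centered window of values from a binned track
#'
#' Returns the grid values from `center - half_width` to `center + half_width`
#' inclusive of both endpoints, so a 10 kb window on a 0.25 kb grid yields 41
#' values and a 16 kb window yields 65. The center is snapped to the nearest
#' grid point; grid points falling outside the track extent are returned as
#' `NA`, so the output length depends only on `half_width` and `step`.
#'
#' @param track A `binned_track`.
#' @param center Window center in bp (snapped to the nearest grid point).
#' @param half_width Half window width in bp.
#' @param chrom Optional chromosome name to check `center` against.
#' @return Numeric vector of `2 * half_width / step + 1` values (with `NA`
#'   padding outside the track).
#' @export
extract_window <- function(track, center, half_width, chrom = NULL) {
  stopifnot(inherits(track, "binned_track"))
  if (!is.null(chrom) && !identical(as.character(chrom), track$chrom))
    stop(sprintf("center is on '%s' but track is on '%s'", chrom, track$chrom))
  n_side <- round(half_width / track$step)
  c_idx <- round((center - track$start) / track$step) + 1
  idx <- (c_idx - n_side):(c_idx + n_side)
  out <- rep(NA_real_, length(idx))
  ok <- idx >= 1 & idx <= length(track$values)
  out[ok] <- track$values[idx[ok]]
  out
}

## ---- GRanges bridges and standard-format IO -------------------------------

#' Convert a binned track to GRanges
#'
#' Each bin becomes a `step`-wide interval; internal 1-based grid points map to
#' 1-based closed GRanges intervals. Missing bins are dropped.
#'
#' @param track A `binned_track`.
#' @return A [GenomicRanges::GRanges] with a `score` column.
#' @export
track_to_granges <- function(track) {
  pos <- track_positions(track)
  keep <- !is.na(track$values)
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = pos[keep], width = track$step),
    score = track$values[keep]
  )
}

granges_to_tracks <- function(gr, step = NULL) {
  out <- list()
  for (chr in as.character(unique(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    st <- GenomicRanges::start(g)
    o <- order(st)
    g <- g[o]; st <- st[o]
    wd <- GenomicRanges::width(g)
    this_step <- if (is.null(step)) wd[1] else step
    if (length(st) > 1 && any(diff(st) < this_step))
      stop(sprintf("overlapping intervals on %s", chr))
    idx <- round((st - st[1]) / this_step) + 1
    vals <- rep(NA_real_, max(idx))
    vals[idx] <- S4Vectors::mcols(g)$score
    out[[chr]] <- binned_track(chr, st[1], this_step, vals)
  }
  out
}

#' Write binned tracks to bedGraph
#'
#' Internal 1-based inclusive coordinates are converted to bedGraph's 0-based
#' half-open intervals (bin at 1..1000 becomes `chrom 0 1000 value`). Missing
#' bins are omitted and restored as `NA` on read.
#'
#' @param tracks A `binned_track` or list of them (one per chromosome).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "binned_track")) tracks <- list(tracks)
  grl <- lapply(tracks, track_to_granges)
  gr <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into binned tracks
#'
#' @param path bedGraph file path.
#' @param step Grid step in bp; inferred from the first interval width when
#'   `NULL`.
#' @return Named list of `binned_track`, one per chromosome.
#' @export
read_bedgraph <- function(path, step = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  granges_to_tracks(gr, step = step)
}

#' Write a binned track as fixed-step wiggle
#'
#' @param track A `binned_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                     track$chrom, as.integer(track$start),
                     as.integer(track$step), as.integer(track$step)), con)
  v <- track$values
  v[is.na(v)] <- 0  # wiggle has no missing marker; bedGraph is the lossless format
  writeLines(format(v, trim = TRUE, scientific = FALSE, digits = 15), con)
  invisible(path)
}

#' Read a tab-delimited probe table
#'
#' Ingests the (chrom, position, value) layout used for per-probe ssDNA data.
#' A header line is detected and skipped; probes are sorted by position and
#' duplicated positions are averaged with a warning.
#'
#' @param path File path of a 3+ column tab- or whitespace-delimited table.
#' @return Named list of `probe_track`, one per chromosome.
#' @export
read_probe_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[\t ]+")[[1]][2])))
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop(sprintf("expected >= 3 columns in '%s'", path))
  names(df)[1:3] <- c("chrom", "position", "value")
  if (!is.numeric(df$position) || !is.numeric(df$value))
    stop(sprintf("malformed probe table '%s': non-numeric position or value",
                 path))
  out <- list()
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    if (anyDuplicated(d$position)) {
      warning(sprintf("%d duplicated probe position(s) on %s averaged",
                      sum(duplicated(d$position)), chr))
      agg <- stats::aggregate(value ~ position, data = d, FUN = mean)
      d <- agg[order(agg$position), ]
    }
    out[[as.character(chr)]] <- probe_track(chr, d$position, d$value)
  }
  out
}

#' Write probe tracks as a tab-delimited table
#'
#' @param tracks A `probe_track` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(tracks, path) {
  if (inherits(tracks, "probe_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(t)
    data.frame(chrom = t$chrom, position = t$positions, value = t$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
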
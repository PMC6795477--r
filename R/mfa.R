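#' Per-sample table of binned read depths
#'
#' @param tracks Named list of [binned_track] of raw counts at a common step
#'   (1 kb for the sequencing pipeline), one per chromosome.
#' @param label Sample label.
#' @return An object of class `depth_table`.
#' @export
depth_table <- function(tracks, label = "sample") {
  stopifnot(length(tracks) > 0, all(vapply(tracks, inherits, TRUE,
                                           "binned_track")))
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, `[[`, "", "chrom")
  total <- sum(unlist(lapply(tracks, function(t) sum(t$values, na.rm = TRUE))))
  structure(list(tracks = tracks, label = label, total_reads = total),
            class = "depth_table")
}

#' Read a per-bin count table
#'
#' Ingests the tab-delimited (chrom, bin_start, count) layout produced by
#' binning aligned reads into fixed windows.
#'
#' @param path File path.
#' @param step Bin width in bp.
#' @param label Sample label.
#' @return A [depth_table].
#' @export
read_depth_table <- function(path, step = 1000, label = basename(path)) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[\t ]+")[[1]][2])))
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "bin_start", "count")
  tracks <- list()
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, ]
    d <- d[order(d$bin_start), ]
    idx <- round((d$bin_start - d$bin_start[1]) / step) + 1
    vals <- rep(NA_real_, max(idx))
    vals[idx] <- d$count
    tracks[[as.character(chr)]] <- binned_track(chr, d$bin_start[1], step,
                                                vals)
  }
  depth_table(tracks, label)
}

# bins of `track` lying inside any excluded region for this genome:
# whole chromosomes named in special_labels, plus tandem-array intervals
excluded_bins <- function(track, genome) {
  if (track$chrom %in% genome$special_labels)
    return(rep(TRUE, length(track$values)))
  excl <- rep(FALSE, length(track$values))
  if (!is.null(genome$arrays)) {
    a <- genome$arrays[genome$arrays$chrom == track$chrom, , drop = FALSE]
    if (nrow(a) > 0) {
      p1 <- track_positions(track)
      p2 <- p1 + track$step - 1
      for (i in seq_len(nrow(a)))
        excl <- excl | (p1 <= a$end[i] & p2 >= a$start[i])
    }
  }
  excl
}

#' Normalize read depth to the genome-wide average
#'
#' Divides every bin by the mean count over non-excluded bins, so the mean of
#' non-excluded output bins is 1. Excluded territory — the rDNA locus, the
#' 2-micron plasmid and the mitochondrial DNA, identified through the genome's
#' `special_labels` and tandem-array descriptors — still receives reported
#' values but does not influence the average.
#'
#' @param depth A [depth_table].
#' @param genome A [genome_map].
#' @return Named list of normalized [binned_track].
#' @export
normalize_depth <- function(depth, genome) {
  stopifnot(inherits(depth, "depth_table"))
  incl <- unlist(lapply(depth$tracks, function(t)
    t$values[!excluded_bins(t, genome)]))
  incl <- incl[!is.na(incl)]
  if (length(incl) == 0) stop("all bins excluded: cannot normalize")
  m <- mean(incl)
  lapply(depth$tracks, function(t)
    binned_track(t$chrom, t$start, t$step, t$values / m))
}

#' Per-bin marker frequency (S over G1)
#'
#' Divides each normalized S-sample bin by the matching normalized G1 bin.
#' Bins where the G1 value is 0 or missing become `NA`; the number of bins
#' masked this way is reported as attribute `n_masked` and via a message.
#'
#' @param s_norm,g1_norm Named lists of normalized [binned_track] on matching
#'   grids (from [normalize_depth]).
#' @return Named list of marker-frequency [binned_track].
#' @export
marker_frequency <- function(s_norm, g1_norm) {
  if (!setequal(names(s_norm), names(g1_norm)))
    stop("S and G1 samples cover different chromosomes")
  masked <- 0L
  out <- lapply(names(s_norm), function(chr) {
    s <- s_norm[[chr]]; g <- g1_norm[[chr]]
    if (s$start != g$start || s$step != g$step ||
        length(s$values) != length(g$values))
      stop(sprintf("grid mismatch on %s", chr))
    bad <- is.na(g$values) | g$values == 0
    masked <<- masked + sum(bad & !is.na(s$values))
    v <- ifelse(bad, NA_real_, s$values / g$values)
    binned_track(chr, s$start, s$step, v)
  })
  out <- stats::setNames(out, names(s_norm))
  if (masked > 0)
    message(sprintf("marker_frequency: %d bin(s) masked (G1 zero or missing)",
                    masked))
  attr(out, "n_masked") <- masked
  out
}

#' Mask poorly-mapped regions out of tracks
#'
#' Sets to `NA` every bin overlapping any mask interval, before smoothing.
#'
#' @param tracks Named list of [binned_track].
#' @param masks A `region_mask` table (see [region_mask], [read_bed_masks]).
#' @return The masked list of tracks.
#' @export
apply_masks <- function(tracks, masks) {
  if (is.null(masks) || nrow(masks) == 0) return(tracks)
  out <- lapply(tracks, function(t) {
    m <- masks[masks$chrom == t$chrom, , drop = FALSE]
    if (nrow(m) == 0) return(t)
    p1 <- track_positions(t)
    p2 <- p1 + t$step - 1
    v <- t$values
    for (i in seq_len(nrow(m)))
      v[p1 <= m$end[i] & p2 >= m$start[i]] <- NA_real_
    binned_track(t$chrom, t$start, t$step, v)
  })
  stats::setNames(out, names(tracks))
}

#' Whole-genome marker-frequency pipeline
#'
#' Convenience wrapper running the full sequencing-side pipeline:
#' depth normalization of S and G1 samples, the S/G1 ratio, region masking,
#' and 50 kb LOESS smoothing.
#'
#' @param s_depth,g1_depth [depth_table]s for the S (or asynchronous) and G1
#'   samples.
#' @param genome A [genome_map].
#' @param masks Optional `region_mask` table.
#' @param window_bp LOESS window in bp (50000 default).
#' @return List with elements `raw` (marker frequency) and `smoothed`, each a
#'   named list of [binned_track].
#' @export
mfa_profile <- function(s_depth, g1_depth, genome, masks = NULL,
                        window_bp = 50000) {
  s_norm <- normalize_depth(s_depth, genome)
  g1_norm <- normalize_depth(g1_depth, genome)
  mf <- marker_frequency(s_norm, g1_norm)
  mf <- apply_masks(mf, masks)
  sm <- stats::setNames(lapply(mf, loess_smooth, window_bp = window_bp),
                        names(mf))
  list(raw = mf, smoothed = sm)
}
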
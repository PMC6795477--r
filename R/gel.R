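#' CHEF-gel well fraction
#'
#' Fraction of a lane's hybridization signal retained in the well, a readout
#' of branched (still-replicating) chromosomes that cannot enter the gel. The
#' background measured in a section above the well is subtracted from the
#' well signal and from the lane signal independently; the corrected well
#' signal is then divided by the corrected total:
#' `fraction = (well - bg) / ((well - bg) + (lane - bg))`.
#' Negative corrected signals are clipped at 0 with a warning; a zero
#' corrected total yields `NA` with a warning. The fraction is invariant to a
#' common rescaling of all three signals.
#'
#' @param well,lane,background Non-negative signal intensities (vectorized).
#' @return Fractions in `[0, 1]` (`NA` where undefined).
#' @export
chef_well_fraction <- function(well, lane, background) {
  if (any(c(well, lane, background) < 0, na.rm = TRUE))
    stop("signals must be >= 0")
  w <- well - background
  l <- lane - background
  if (any(w < 0 | l < 0, na.rm = TRUE)) {
    warning("negative background-corrected signal(s) clipped at 0")
    w <- pmax(w, 0); l <- pmax(l, 0)
  }
  tot <- w + l
  out <- ifelse(tot > 0, w / tot, NA_real_)
  if (any(is.na(out) & !is.na(tot)))
    warning("zero corrected total signal: fraction undefined")
  out
}

#' 2D-gel bubble to 1N ratio
#'
#' Ratio of bubble-arc signal (replication initiation within the fragment) to
#' the 1N spot (unreplicated linear fragments). When reference signals are
#' supplied, also returns the ratio relative to the reference condition —
#' the "percent of uninduced initiation" form of report.
#'
#' @param bubble,one_n Signal intensities for the sample (`one_n > 0`).
#' @param ref_bubble,ref_one_n Optional reference-condition signals.
#' @return A list with `ratio` and, when a reference is given, `ref_ratio`
#'   and `relative` (`ratio / ref_ratio`).
#' @export
bubble_ratio <- function(bubble, one_n, ref_bubble = NULL, ref_one_n = NULL) {
  if (any(one_n <= 0)) stop("one_n signal must be > 0 for a defined ratio")
  out <- list(ratio = bubble / one_n)
  if (!is.null(ref_bubble)) {
    if (is.null(ref_one_n) || any(ref_one_n <= 0))
      stop("reference one_n signal must be > 0")
    out$ref_ratio <- ref_bubble / ref_one_n
    out$relative <- out$ratio / out$ref_ratio
  }
  out
}

#' Quantify a CSV of CHEF lane signals
#'
#' Reads rows of (sample, time, well, lane, background) and appends the
#' computed `well_fraction` column.
#'
#' @param path Input CSV path.
#' @param out_path Optional output CSV path.
#' @return The augmented `data.frame`, invisibly written to `out_path` when
#'   given.
#' @export
quantify_chef_csv <- function(path, out_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("well", "lane", "background") %in% names(df)))
  df$well_fraction <- chef_well_fraction(df$well, df$lane, df$background)
  if (!is.null(out_path))
    utils::write.csv(df, out_path, row.names = FALSE)
  df
}

#' Quantify a CSV of 2D-gel region signals
#'
#' Reads rows of (sample, time, bubble, one_n) and appends `bubble_1n_ratio`;
#' when `reference_sample` is given, also `relative_to_reference` using that
#' sample's mean ratio.
#'
#' @param path Input CSV path.
#' @param reference_sample Optional value of the `sample` column to normalize
#'   against.
#' @param out_path Optional output CSV path.
#' @return The augmented `data.frame`.
#' @export
quantify_2d_csv <- function(path, reference_sample = NULL, out_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bubble", "one_n") %in% names(df)))
  df$bubble_1n_ratio <- bubble_ratio(df$bubble, df$one_n)$ratio
  if (!is.null(reference_sample)) {
    ref <- mean(df$bubble_1n_ratio[df$sample == reference_sample])
    df$relative_to_reference <- df$bubble_1n_ratio / ref
  }
  if (!is.null(out_path))
    utils::write.csv(df, out_path, row.names = FALSE)
  df
}
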
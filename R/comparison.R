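#' Tornado matrices of rescaled ssDNA windows
#'
#' Builds, for each sample, the origins x window-offsets matrix of rescaled
#' ssDNA values. The row order is computed once from the reference sample —
#' rows sorted in descending area under the curve — and imposed on every other
#' sample, so that changes in the relative robustness of initiation across
#' origins show up as departures from the reference's tornado shape. All
#' samples share one color scale (the global value range of the group).
#'
#' @param track_sets Named list (one element per sample) of named lists of
#'   rescaled [binned_track].
#' @param origins `data.frame` with columns `id`, `chrom`, `position`.
#' @param reference Name of the sample whose areas define the row order.
#' @param half_width Half window width in bp (5000 gives 41 columns at the
#'   0.25 kb grid).
#' @return Named list of `tornado_matrix` objects: each has `sample`,
#'   `matrix` (rows = origins in the shared order, columns = offsets),
#'   `offsets`, `sort_key` (the reference areas, in row order), `color_scale`
#'   and `filled` (logical rows that needed baseline fill).
#' @export
tornado <- function(track_sets, origins, reference, half_width = 5000) {
  if (!reference %in% names(track_sets))
    stop(sprintf("reference sample '%s' not present", reference))
  step <- track_sets[[reference]][[1]]$step
  offsets <- seq(-half_width, half_width, by = step)
  build <- function(tracks) {
    m <- matrix(NA_real_, nrow(origins), length(offsets),
                dimnames = list(origins$id, offsets))
    filled <- logical(nrow(origins))
    for (i in seq_len(nrow(origins))) {
      chr <- origins$chrom[i]
      if (!chr %in% names(tracks)) { filled[i] <- TRUE
        m[i, ] <- 1.0; next }
      w <- extract_window(tracks[[chr]], origins$position[i], half_width)
      filled[i] <- anyNA(w)
      w[is.na(w)] <- 1.0   # baseline fill, flagged
      m[i, ] <- w
    }
    list(m = m, filled = filled)
  }
  ref <- build(track_sets[[reference]])
  order_idx <- order(-rowSums(ref$m), origins$id)
  rng <- range(unlist(lapply(track_sets, function(tr) build(tr)$m)))
  out <- lapply(names(track_sets), function(s) {
    b <- build(track_sets[[s]])
    structure(list(sample = s,
                   matrix = b$m[order_idx, , drop = FALSE],
                   offsets = offsets,
                   sort_key = rowSums(ref$m)[order_idx],
                   color_scale = rng,
                   filled = b$filled[order_idx]),
              class = "tornado_matrix")
  })
  stats::setNames(out, names(track_sets))
}

#' @export
print.tornado_matrix <- function(x, ...) {
  cat(sprintf("<tornado_matrix> %s: %d origins x %d offsets, scale [%.3g, %.3g]\n",
              x$sample, nrow(x$matrix), ncol(x$matrix),
              x$color_scale[1], x$color_scale[2]))
  invisible(x)
}

#' Mean ssDNA profile across origins
#'
#' Column means of a tornado matrix: the average rescaled ssDNA value at each
#' offset within the window, baseline-filled cells included.
#'
#' @param tm A `tornado_matrix`.
#' @return Numeric vector, one value per window offset.
#' @export
mean_profile <- function(tm) {
  stopifnot(inherits(tm, "tornado_matrix"))
  if (nrow(tm$matrix) == 0) stop("empty tornado matrix")
  colMeans(tm$matrix)
}

# Wald-Wolfowitz runs z-statistic on residual signs (in fitted-value order):
# few long runs of same-sign residuals indicate structure a straight line
# missed (curvature gives a strongly negative z)
runs_z <- function(res) {
  s <- sign(res[res != 0])
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(NA_real_)
  runs <- 1 + sum(s[-1] != s[-n])
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  (runs - mu) / sqrt(v)
}

#' Ordinary least squares on paired origin peak areas
#'
#' Fits `y = a + b x` across origins, as used to ask whether the relative
#' efficiencies of origins are preserved between two samples. Besides the
#' slope, intercept, R-squared, residuals and fitted values, reports numeric
#' residual-skew diagnostics that operationalize the visual judgment of
#' residual plots: a runs-test z-statistic on residual signs in fitted-value
#' order, and a curvature p-value (the F-test for adding a quadratic term,
#' RESET style). The Pearson correlations of residuals with fitted values and
#' with the rank of `x` are reported for completeness, but note that
#' `cor(residuals, fitted)` is identically zero for any OLS fit with an
#' intercept, so the runs and curvature diagnostics carry the signal.
#' Unremarkable diagnostics mean a uniform (proportional) change across
#' origins; a strongly negative runs z or small curvature p means some origin
#' class was hit harder than the straight line can express.
#'
#' @param x_areas,y_areas Numeric peak areas for the same origins (>= 3).
#' @return An object of class `area_regression`.
#' @export
fit_peak_areas <- function(x_areas, y_areas) {
  ok <- !is.na(x_areas) & !is.na(y_areas)
  x <- x_areas[ok]; y <- y_areas[ok]
  if (length(x) < 3) stop("need at least 3 paired origins")
  if (stats::var(x) == 0) stop("zero variance in x areas")
  fit <- stats::lm(y ~ x)
  fit2 <- stats::lm(y ~ x + I(x^2))
  curv_p <- tryCatch(stats::anova(fit, fit2)[2, "Pr(>F)"],
                     error = function(e) NA_real_)
  res <- stats::residuals(fit)
  fitted <- stats::fitted(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  o <- order(fitted)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    residuals = res,
    fitted = fitted,
    n = length(x),
    skew_fitted = if (stats::sd(res) > 0 && stats::sd(fitted) > 0)
      stats::cor(res, fitted) else 0,
    skew_xrank = if (stats::sd(res) > 0) stats::cor(res, rank(x)) else 0,
    runs_z = runs_z(res[o]),
    curvature_p = curv_p
  ), class = "area_regression")
}

#' @export
print.area_regression <- function(x, ...) {
  cat(sprintf(
    "<area_regression> n=%d  slope=%.4g  intercept=%.4g  R2=%.4f\n",
    x$n, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  residual skew: runs z=%.2f curvature p=%.3g cor(res,rank x)=%.3f\n",
              x$runs_z, x$curvature_p, x$skew_xrank))
  invisible(x)
}

#' Select a subset of origins
#'
#' `"cen_proximal"` keeps origins within 50 kb of their chromosome's
#' centromere, boundary inclusive. `"listed"` intersects the origins with a
#' membership table (columns `chrom`, `position`, optionally `id`), matching
#' by id when both sides carry one, otherwise by coordinate within 1 kb.
#'
#' @param origins `data.frame` with `id`, `chrom`, `position`.
#' @param genome A [genome_map] (needed for centromere coordinates).
#' @param rule `"cen_proximal"` or `"listed"`.
#' @param membership `data.frame` or path to a tab-delimited file for the
#'   `"listed"` rule.
#' @param radius CEN-proximity radius in bp (50000).
#' @param tolerance Coordinate-match tolerance in bp for `"listed"` (1000).
#' @return The selected rows of `origins`.
#' @export
select_origin_subset <- function(origins, genome,
                                 rule = c("cen_proximal", "listed"),
                                 membership = NULL, radius = 50000,
                                 tolerance = 1000) {
  rule <- match.arg(rule)
  if (rule == "cen_proximal") {
    cen <- stats::setNames(genome$chromosomes$centromere,
                           genome$chromosomes$name)
    missing_cen <- unique(origins$chrom[is.na(cen[origins$chrom])])
    if (length(missing_cen) > 0)
      stop(sprintf("no centromere coordinate for: %s",
                   paste(missing_cen, collapse = ", ")))
    keep <- abs(origins$position - cen[origins$chrom]) <= radius
  } else {
    if (is.null(membership)) stop("the 'listed' rule needs a membership table")
    if (is.character(membership))
      membership <- utils::read.table(membership, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
    if (!is.null(membership$id) && !is.null(origins$id) &&
        any(membership$id %in% origins$id)) {
      keep <- origins$id %in% membership$id
    } else {
      keep <- vapply(seq_len(nrow(origins)), function(i)
        any(membership$chrom == origins$chrom[i] &
              abs(membership$position - origins$position[i]) <= tolerance),
        TRUE)
    }
  }
  out <- origins[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
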
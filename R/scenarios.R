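#' Competence maps for perturbation scenarios
#'
#' Ground-truth transformations of per-origin competence that mirror the
#' initiation-factor perturbations studied with the ssDNA assay:
#' \describe{
#'   \item{`uniform_map(f)`}{every origin's competence scaled by `f` — the
#'     proportional, Sld2-depletion-like change.}
#'   \item{`weak_biased_map()`}{a sigmoidal map in which the most competent
#'     origins are nearly spared while weaker origins are severely
#'     compromised (`c * (0.08 + 0.92 * plogis((c - 0.8) / 0.06))`) — the
#'     Sld3-depletion-like change where all but the most efficient origins
#'     suffer.}
#'   \item{`equalized_map(level)`}{every origin set to the same competence —
#'     the SSDDCS-overexpression-like loss of origin individuality.}
#' }
#'
#' @param f Uniform scale factor in `(0, 1]`.
#' @param level Common competence for the equalized scenario.
#' @return A function mapping a competence vector to a competence vector.
#' @name competence_maps
NULL

#' @rdname competence_maps
#' @export
uniform_map <- function(f) {
  force(f)
  function(competence) pmin(1, f * competence)
}

#' @rdname competence_maps
#' @export
weak_biased_map <- function() {
  function(competence)
    competence * (0.08 + 0.92 * stats::plogis((competence - 0.8) / 0.06))
}

#' @rdname competence_maps
#' @export
equalized_map <- function(level = 0.8) {
  force(level)
  function(competence) rep(level, length(competence))
}

#' Simulate and process one ssDNA condition
#'
#' Applies a competence map to the genome, simulates the pooled ssDNA profile
#' in hydroxyurea, adds array noise, and runs the full processing pipeline
#' (outlier filter, smoothing to the 0.25 kb grid, rescaling, peak calling).
#' Probe positions should be generated once with [make_probe_positions] and
#' shared across the conditions of an experiment, as one array design would
#' be.
#'
#' @param genome A [genome_map].
#' @param params A [sim_params] with `hu_mode = TRUE` (see [hu_sim_params]).
#' @param positions Named list of probe positions.
#' @param competence_map A function from [competence_maps] (identity for the
#'   reference condition).
#' @param sample_time Minutes after release into S phase in HU.
#' @param n_cells Cells pooled per condition.
#' @param noise_log_sd,outlier_rate Array-noise parameters, see
#'   [add_array_noise].
#' @param window_bp ssDNA LOESS window (6000; 9000 for noisy overexpression
#'   conditions).
#' @param sample Sample label.
#' @return The [process_ssdna] result list.
#' @export
ssdna_condition <- function(genome, params, positions,
                            competence_map = identity, sample_time = 30,
                            n_cells = 600, noise_log_sd = 0.1,
                            outlier_rate = 0.001, window_bp = 6000,
                            sample = "sample") {
  g <- genome
  g$origins$competence <- competence_map(g$origins$competence)
  raw <- simulate_ssdna(g, params, sample_time = sample_time,
                        n_cells = n_cells, positions = positions)
  noisy <- stats::setNames(
    lapply(raw, add_array_noise, log_sd = noise_log_sd,
           outlier_rate = outlier_rate),
    names(raw))
  process_ssdna(noisy, window_bp = window_bp, sample = sample)
}
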
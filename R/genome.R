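#' Origin specification table
#'
#' Builds the per-origin parameter table used by the simulator. Each origin
#' carries a competence — the intrinsic probability that it assembles all
#' factors needed to fire in a given cell cycle — and a mean firing time with
#' spread, which together generate staggered firing during S phase. An origin
#' that is fully competent may still be passively replicated by an incoming
#' fork, which is why observed efficiency can be below competence.
#'
#' @param id Character labels, one per origin.
#' @param chrom Chromosome names.
#' @param position 1-based bp positions.
#' @param competence Firing probabilities in `[0, 1]`.
#' @param t_mean Mean firing times, minutes into S phase (>= 0).
#' @param t_sd Firing-time spread in minutes (>= 0).
#' @return A `data.frame` of class `origin_spec`.
#' @export
origin_spec <- function(id, chrom, position, competence, t_mean, t_sd) {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   position = as.numeric(position),
                   competence = as.numeric(competence),
                   t_mean = as.numeric(t_mean), t_sd = as.numeric(t_sd),
                   stringsAsFactors = FALSE)
  if (any(df$competence < 0 | df$competence > 1))
    stop("competence must lie in [0, 1]")
  if (any(df$t_mean < 0)) stop("t_mean must be >= 0")
  if (any(df$t_sd < 0)) stop("t_sd must be >= 0")
  class(df) <- c("origin_spec", "data.frame")
  df
}

#' Model genome with origins and optional tandem arrays
#'
#' @param chromosomes `data.frame` with columns `name`, `length` (bp) and
#'   `centromere` (bp, may be `NA`).
#' @param origins An [origin_spec] table; sorted internally by
#'   (chrom, position).
#' @param arrays Optional `data.frame` of tandem-array descriptors with columns
#'   `chrom`, `start`, `end`, `repeat_length` (bp) and `competence` (per-repeat
#'   origin firing probability); used for the rDNA-like locus.
#' @param special_labels Chromosome or region names excluded from depth
#'   normalization (the rDNA locus, 2-micron plasmid and mitochondrial DNA in
#'   the real genome).
#' @return An object of class `genome_map`.
#' @export
genome_map <- function(chromosomes, origins, arrays = NULL,
                       special_labels = character()) {
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (is.null(chromosomes$centromere)) chromosomes$centromere <- NA_real_
  chromosomes$name <- as.character(chromosomes$name)
  origins <- origins[order(origins$chrom, origins$position), , drop = FALSE]
  rownames(origins) <- NULL
  len <- stats::setNames(chromosomes$length, chromosomes$name)
  bad <- origins$position < 1 | origins$position > len[origins$chrom]
  if (any(is.na(bad)) || any(bad))
    stop("every origin must lie within its chromosome")
  cen_ok <- is.na(chromosomes$centromere) |
    (chromosomes$centromere >= 1 & chromosomes$centromere <= chromosomes$length)
  if (!all(cen_ok)) stop("centromere outside chromosome bounds")
  if (!is.null(arrays)) {
    stopifnot(all(c("chrom", "start", "end", "repeat_length", "competence")
                  %in% names(arrays)))
    for (i in seq_len(nrow(arrays))) {
      ov <- origins$chrom == arrays$chrom[i] &
        origins$position >= arrays$start[i] & origins$position <= arrays$end[i]
      if (any(ov))
        stop("unique origins must not overlap a tandem-array region")
    }
  }
  structure(list(chromosomes = chromosomes, origins = origins,
                 arrays = arrays, special_labels = special_labels),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %d chromosome(s), %d origin(s), %d array(s)\n",
              nrow(x$chromosomes), nrow(x$origins),
              if (is.null(x$arrays)) 0L else nrow(x$arrays)))
  invisible(x)
}

#' Region mask
#'
#' A masked interval (1-based, inclusive at both ends internally) excluded from
#' profiles before smoothing: poorly-mapped subtelomeres, Ty elements, ohnolog
#' pairs, or the rDNA interior.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bp bounds (`start <= end`).
#' @param label One of `"subtelomere"`, `"Ty"`, `"ohnolog"`, `"rDNA"` or a
#'   custom label.
#' @return A one-row `data.frame` of class `region_mask`.
#' @export
region_mask <- function(chrom, start, end, label = "custom") {
  if (any(start > end)) stop("mask start must be <= end")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  class(df) <- c("region_mask", "data.frame")
  df
}

#' Read region masks from a BED file
#'
#' BED uses 0-based half-open coordinates; `[0, 1000)` in BED becomes the
#' 1-based inclusive interval `1..1000` internally.
#'
#' @param path BED file path.
#' @return A `region_mask` table.
#' @export
read_bed_masks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(S4Vectors::mcols(gr)$name) &&
             !all(is.na(S4Vectors::mcols(gr)$name)))
    as.character(S4Vectors::mcols(gr)$name) else "custom"
  region_mask(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), GenomicRanges::end(gr), lab)
}

#' Demonstration genome fixtures
#'
#' Three small genomes used throughout the simulator, the analysis scripts and
#' the tests:
#' \describe{
#'   \item{`"s5fig"`}{One 1 Mb chromosome with 5 origins of distinct timing
#'     classes — two early, one mid-S, two late — the classic picture of a
#'     chromosome whose marker-frequency profile has peaks at origins and
#'     valleys at termini.}
#'   \item{`"chr12like"`}{A chromosome carrying unique origins flanking a
#'     tandem array of 9 kb repeats, each repeat holding one inefficient
#'     origin: a miniature of the rDNA locus on Chr XII.}
#'   \item{`"minimal"`}{One chromosome, one origin; the smallest useful
#'     fixture.}
#' }
#'
#' @param style One of `"s5fig"`, `"chr12like"`, `"minimal"`.
#' @return A [genome_map].
#' @export
make_demo_genome <- function(style = c("s5fig", "chr12like", "minimal")) {
  if (!is.character(style) || !style[1] %in% c("s5fig", "chr12like", "minimal"))
    stop("unknown genome style; valid styles: \"s5fig\", \"chr12like\", \"minimal\"")
  style <- style[1]
  if (style == "s5fig") {
    chroms <- data.frame(name = "chrS", length = 1e6, centromere = 2e5)
    oris <- origin_spec(
      id = c("ORI1", "ORI2", "ORI3", "ORI4", "ORI5"),
      chrom = "chrS",
      position = c(100e3, 300e3, 500e3, 700e3, 900e3),
      competence = c(1, 1, 1, 1, 1),
      t_mean = c(5, 5, 15, 25, 25),   # two early, one mid, two late
      t_sd = c(2, 2, 3, 4, 4)
    )
    genome_map(chroms, oris)
  } else if (style == "chr12like") {
    # unique origins flanking a 20-repeat x 9 kb tandem array (180 kb)
    chroms <- data.frame(name = "chrT", length = 6e5, centromere = 1e5)
    oris <- origin_spec(
      id = c("ORIL1", "ORIL2", "ORIR1", "ORIR2"),
      chrom = "chrT",
      position = c(50e3, 150e3, 450e3, 550e3),
      competence = c(0.9, 0.8, 0.8, 0.9),
      t_mean = c(5, 10, 10, 5),
      t_sd = c(2, 3, 3, 2)
    )
    arrays <- data.frame(chrom = "chrT", start = 200e3 + 1, end = 380e3,
                         repeat_length = 9000, competence = 0.2)
    genome_map(chroms, oris, arrays = arrays, special_labels = "rDNA")
  } else {
    chroms <- data.frame(name = "chrM1", length = 2e5, centromere = 5e4)
    oris <- origin_spec("ORI1", "chrM1", 1e5, 1, 10, 2)
    genome_map(chroms, oris)
  }
}

#' Wild-type-like genome with heterogeneous origin competences
#'
#' Builds a genome whose early origins differ in intrinsic competence and
#' firing time, the situation the ssDNA assay probes: evenly spaced origins
#' (about 1 per 125 kb, comparable to the density of HU-active early origins
#' in budding yeast) with competences spanning 0.45-1 and mean firing times
#' 8-15 minutes. The competence/timing pattern is fixed (rotated by one
#' position on each successive chromosome), so the genome is deterministic
#' and the variability in origin efficiency is known ground truth.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param origins_per_chrom Origins per chromosome.
#' @return A [genome_map].
#' @export
make_wt_genome <- function(n_chrom = 1, chrom_len = 1e6,
                           origins_per_chrom = 8) {
  comp_base <- c(1.00, 0.55, 0.85, 0.45, 0.95, 0.60, 0.75, 0.90)
  tm_base <- c(8, 14, 10, 15, 9, 13, 11, 10)
  rot <- function(v, k) v[((seq_along(v) + k - 1) %% length(v)) + 1]
  chroms <- data.frame(name = sprintf("chr%02d", seq_len(n_chrom)),
                       length = chrom_len, centromere = 0.3 * chrom_len)
  oris <- do.call(rbind, lapply(seq_len(n_chrom), function(j) {
    comp <- rep_len(rot(comp_base, j - 1), origins_per_chrom)
    tm <- rep_len(rot(tm_base, j - 1), origins_per_chrom)
    pos <- round(seq_len(origins_per_chrom) /
                   (origins_per_chrom + 1) * chrom_len)
    origin_spec(id = sprintf("ORI%02d_%02d", j, seq_len(origins_per_chrom)),
                chrom = chroms$name[j], position = pos,
                competence = comp, t_mean = tm, t_sd = 2)
  }))
  genome_map(chroms, oris)
}
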
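#' Simulation parameters
#'
#' Parameters shared by the per-cell firing/fork simulator and the population
#' pooling operations.
#'
#' @param fork_speed Replication fork speed in kb/min.
#' @param dntp_budget Total synthesis available per cell under hydroxyurea, in
#'   kb. Each of the `2k` forks of a cell with `k` initiated origins can travel
#'   at most `dntp_budget / (2 k)` kb before stalling, which makes "fewer
#'   origins, farther travel" quantitative.
#' @param s_duration Length of S phase in minutes.
#' @param hu_mode Logical; when `TRUE`, fork travel is capped by the dNTP
#'   budget and passively-replicated demotion is disabled (forks stall near
#'   origins and cannot reach their neighbours).
#' @param ssdna_footprint_sd Standard deviation in bp of the Gaussian ssDNA
#'   footprint deposited around each fork.
#' @param ssdna_gain Peak amplitude added to the baseline-1 ratio by a fork
#'   present in every cell of the population.
#' @param cell_cycle_fractions Named numeric `(G1, S, G2)` proportions for
#'   sampling asynchronous populations; must sum to 1.
#' @param probe_spacing Mean spacing in bp of synthetic microarray probes.
#' @param probe_jitter Half-range in bp of uniform jitter applied to probe
#'   positions, emulating irregular array spacing.
#' @param bin_step Bin width in bp for simulated read-depth tracks.
#' @param array_t_mean,array_t_sd Firing-time parameters (minutes) given to
#'   the per-repeat origins of tandem-array regions.
#' @param rng_seed Optional integer; when non-`NULL`, stochastic simulator
#'   entry points call `set.seed(rng_seed)` before drawing.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(fork_speed = 1.5, dntp_budget = 80, s_duration = 50,
                       hu_mode = FALSE, ssdna_footprint_sd = 2000,
                       ssdna_gain = 4,
                       cell_cycle_fractions = c(G1 = 0.3, S = 0.5, G2 = 0.2),
                       probe_spacing = 1000, probe_jitter = 300,
                       bin_step = 1000, array_t_mean = 15, array_t_sd = 5,
                       rng_seed = NULL) {
  if (fork_speed <= 0) stop("fork_speed must be > 0")
  if (hu_mode && dntp_budget <= 0) stop("dntp_budget must be > 0 in hu_mode")
  if (abs(sum(cell_cycle_fractions) - 1) > 1e-8)
    stop("cell_cycle_fractions must sum to 1")
  structure(
    list(fork_speed = fork_speed, dntp_budget = dntp_budget,
         s_duration = s_duration, hu_mode = hu_mode,
         ssdna_footprint_sd = ssdna_footprint_sd, ssdna_gain = ssdna_gain,
         cell_cycle_fractions = cell_cycle_fractions,
         probe_spacing = probe_spacing, probe_jitter = probe_jitter,
         bin_step = bin_step, array_t_mean = array_t_mean,
         array_t_sd = array_t_sd, rng_seed = rng_seed),
    class = "sim_params")
}

#' Hydroxyurea study-condition parameters for a genome
#'
#' Returns [sim_params] with `hu_mode = TRUE` and the dNTP budget scaled to
#' the genome: 24 kb of synthesis per Mb, i.e. roughly 2.5% of the genome
#' replicated before forks stall, so that a wild-type-like cell (about 6
#' initiated origins per Mb) stalls its forks ~2 kb from each origin. Two
#' fork footprints of sd `ssdna_footprint_sd` placed at +/-s merge into one
#' mode only when `s <= sd`, so with the 2 kb footprint this is the regime in
#' which ssDNA peaks are single and centered on origins, as in an early HU
#' sample of unperturbed cells. Fewer initiated origins per cell push the
#' per-fork cap `dntp_budget / 2k` up and peaks split.
#'
#' @param genome A [genome_map].
#' @param ... Overrides passed to [sim_params].
#' @return A [sim_params] with `hu_mode = TRUE`.
#' @export
hu_sim_params <- function(genome, ...) {
  mb <- sum(genome$chromosomes$length) / 1e6
  args <- list(...)
  if (is.null(args$dntp_budget)) args$dntp_budget <- 24 * mb
  args$hu_mode <- TRUE
  do.call(sim_params, args)
}

maybe_seed <- function(params) {
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  invisible(NULL)
}

# Unique origins plus the implicit per-repeat origins of tandem arrays,
# as one flat table with simulator parameters.
expand_origins <- function(genome, params = sim_params()) {
  oris <- genome$origins
  if (!is.null(genome$arrays) && nrow(genome$arrays) > 0) {
    extra <- do.call(rbind, lapply(seq_len(nrow(genome$arrays)), function(i) {
      a <- genome$arrays[i, ]
      starts <- seq(a$start, a$end - a$repeat_length + 1, by = a$repeat_length)
      origin_spec(id = sprintf("array%d_r%d", i, seq_along(starts)),
                  chrom = a$chrom, position = starts,
                  competence = a$competence,
                  t_mean = params$array_t_mean, t_sd = params$array_t_sd)
    }))
    oris <- rbind(oris, extra)
    oris <- oris[order(oris$chrom, oris$position), , drop = FALSE]
    rownames(oris) <- NULL
  }
  oris
}

rtnorm0 <- function(n, mean, sd) {
  # Normal truncated at zero; rejection is cheap for t_mean >= 0
  if (all(sd == 0)) return(pmax(mean, 0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Draw one cell's origin-firing layer
#'
#' Each origin independently fires with probability `competence`; firing times
#' are Normal(`t_mean`, `t_sd`) truncated at zero. Outside hydroxyurea, an
#' origin whose locus has already been replicated by a fork from an
#' earlier-firing origin at its scheduled time is demoted to passively
#' replicated: candidates are processed in firing-time order (ties broken by
#' coordinate), and a locus is covered at time `t` when any actually-fired
#' origin `j` satisfies `t_j + |x - x_j| / v <= t`. Because replicated DNA is
#' the union of fork sweeps, this first-arrival rule is exact regardless of
#' where converging forks meet.
#'
#' @param genome A [genome_map].
#' @param params A [sim_params].
#' @return An object of class `cell_realization` with the firing layer
#'   populated (`fired`, `fire_time`, `passive`) and `origins` attached.
#' @export
realize_firing <- function(genome, params = sim_params()) {
  oris <- expand_origins(genome, params)
  n <- nrow(oris)
  fired <- stats::runif(n) < oris$competence
  fire_time <- rep(NA_real_, n)
  fire_time[fired] <- rtnorm0(sum(fired), oris$t_mean[fired], oris$t_sd[fired])
  passive <- rep(FALSE, n)
  if (!params$hu_mode && any(fired)) {
    v <- params$fork_speed * 1000  # bp/min
    for (chr in unique(oris$chrom)) {
      idx <- which(fired & oris$chrom == chr)
      if (length(idx) < 2) next
      ord <- idx[order(fire_time[idx], oris$position[idx])]
      live_x <- numeric(0); live_t <- numeric(0)
      for (i in ord) {
        t_i <- fire_time[i]; x_i <- oris$position[i]
        if (length(live_x) > 0 &&
            any(live_t + abs(x_i - live_x) / v <= t_i)) {
          fired[i] <- FALSE; passive[i] <- TRUE; fire_time[i] <- NA_real_
        } else {
          live_x <- c(live_x, x_i); live_t <- c(live_t, t_i)
        }
      }
    }
  }
  structure(list(origins = oris, fired = fired, fire_time = fire_time,
                 passive = passive, sample_time = NA_real_, forks = NULL,
                 replicated = NULL),
            class = "cell_realization")
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me) me <- max(me, end[i])
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
             ms <- start[i]; me <- end[i] }
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Fill in forks and replicated intervals for one cell
#'
#' Every origin that has initiated by `sample_time` launches two divergent
#' forks at speed `fork_speed`. In hydroxyurea each fork's travel is capped at
#' `d_max = dntp_budget / (2 k)` kb, `k` being the number of initiated origins
#' in the cell. Forks also stop at chromosome ends and where they meet
#' converging forks; the replicated DNA is the union of the per-origin sweeps.
#' Fork positions are the edges of the merged replicated intervals (edges at
#' chromosome ends carry no fork).
#'
#' @param cell A `cell_realization` from [realize_firing].
#' @param genome The [genome_map] used to create it.
#' @param params A [sim_params].
#' @param sample_time Minutes into S phase at which the cell is sampled.
#' @return The `cell_realization` with `forks` (chrom, position, direction)
#'   and `replicated` (chrom, start, end) filled in.
#' @export
replicate_cell <- function(cell, genome, params = sim_params(),
                           sample_time = params$s_duration) {
  oris <- cell$origins
  v <- params$fork_speed * 1000
  init <- which(cell$fired & cell$fire_time <= sample_time)
  k <- length(init)
  d_max <- if (params$hu_mode && k > 0)
    params$dntp_budget * 1000 / (2 * k) else Inf
  forks <- NULL; repl <- NULL
  if (k > 0) {
    travel <- pmin(v * (sample_time - cell$fire_time[init]), d_max)
    len <- stats::setNames(genome$chromosomes$length,
                           genome$chromosomes$name)
    for (chr in unique(oris$chrom[init])) {
      j <- init[oris$chrom[init] == chr]
      tr <- travel[match(j, init)]
      s <- pmax(oris$position[j] - tr, 1)
      e <- pmin(oris$position[j] + tr, len[[chr]])
      m <- merge_intervals(s, e)
      repl <- rbind(repl, data.frame(chrom = chr, start = m[, "start"],
                                     end = m[, "end"]))
      fx <- c(m[, "start"], m[, "end"])
      fd <- rep(c(-1, 1), each = nrow(m))
      at_end <- (fd == -1 & fx <= 1) | (fd == 1 & fx >= len[[chr]])
      if (any(!at_end))
        forks <- rbind(forks, data.frame(chrom = chr, position = fx[!at_end],
                                         direction = fd[!at_end]))
    }
  }
  cell$sample_time <- sample_time
  cell$forks <- forks
  cell$replicated <- repl
  cell
}

#' Simulate a population marker-frequency profile
#'
#' Cells are assigned to G1/S/G2 by `cell_cycle_fractions`; S-phase cells get
#' a sampling time uniform on `(0, s_duration)`. Per bin and cell the copy
#' number is 1 (unreplicated, or any G1 cell) or 2 (replicated, or any G2
#' cell); the returned track is the mean copy number per bin, which is the
#' G1-normalized marker-frequency scale: 1 where no cell has replicated, 2
#' where all have.
#'
#' @param genome A [genome_map].
#' @param params A [sim_params].
#' @param n_cells Number of cells to pool (>= 1).
#' @return Named list of [binned_track], one per chromosome, values in
#'   `[1, 2]`.
#' @export
simulate_mfa <- function(genome, params = sim_params(), n_cells = 1000) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  maybe_seed(params)
  step <- params$bin_step
  chroms <- genome$chromosomes
  nbin <- stats::setNames(ceiling(chroms$length / step), chroms$name)
  cover <- lapply(nbin, function(n) numeric(n))
  phase <- sample(c("G1", "S", "G2"), n_cells, replace = TRUE,
                  prob = params$cell_cycle_fractions)
  for (ci in seq_len(n_cells)) {
    if (phase[ci] == "G1") next
    if (phase[ci] == "G2") {
      for (chr in names(cover)) cover[[chr]] <- cover[[chr]] + 1
      next
    }
    st <- stats::runif(1, 0, params$s_duration)
    cell <- replicate_cell(realize_firing(genome, params), genome, params,
                           sample_time = st)
    if (!is.null(cell$replicated)) {
      for (r in seq_len(nrow(cell$replicated))) {
        chr <- cell$replicated$chrom[r]
        b1 <- max(1, ceiling(cell$replicated$start[r] / step))
        b2 <- min(nbin[[chr]], ceiling(cell$replicated$end[r] / step))
        if (b2 >= b1) cover[[chr]][b1:b2] <- cover[[chr]][b1:b2] + 1
      }
    }
  }
  out <- lapply(names(cover), function(chr)
    binned_track(chr, start = 1, step = step,
                 values = 1 + cover[[chr]] / n_cells))
  stats::setNames(out, names(cover))
}

#' Synthetic microarray probe positions
#'
#' Draws irregularly spaced probe positions (a jittered ~1 kb grid) for each
#' chromosome of a genome, emulating tiling-array probe layouts.
#'
#' @param genome A [genome_map].
#' @param params A [sim_params] (uses `probe_spacing` and `probe_jitter`).
#' @return Named list of numeric position vectors, one per chromosome.
#' @export
make_probe_positions <- function(genome, params = sim_params()) {
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    L <- genome$chromosomes$length[i]
    base <- seq(params$probe_spacing / 2, L, by = params$probe_spacing)
    pos <- base + stats::runif(length(base), -params$probe_jitter,
                               params$probe_jitter)
    sort(unique(round(pmin(pmax(pos, 1), L))))
  })
  stats::setNames(out, genome$chromosomes$name)
}

#' Simulate a population ssDNA replication profile in hydroxyurea
#'
#' Each cell's active forks deposit a Gaussian ssDNA footprint
#' (`ssdna_footprint_sd`) at their positions; the population mean is evaluated
#' at the probe positions and returned as an S/G1-style ratio, baseline 1 plus
#' signal. When per-fork travel exceeds roughly twice the footprint sd, the
#' two fork footprints flanking an origin separate and its peak "splits".
#'
#' @param genome A [genome_map].
#' @param params A [sim_params] with `hu_mode = TRUE`.
#' @param sample_time Minutes after release into S phase.
#' @param n_cells Number of cells to pool.
#' @param positions Optional named list of probe positions (from
#'   [make_probe_positions]); drawn fresh when `NULL`.
#' @return Named list of [probe_track], one per chromosome.
#' @export
simulate_ssdna <- function(genome, params = sim_params(hu_mode = TRUE),
                           sample_time = 30, n_cells = 500,
                           positions = NULL) {
  if (!params$hu_mode)
    stop("the ssDNA assay is defined in hydroxyurea; set hu_mode = TRUE")
  maybe_seed(params)
  if (is.null(positions)) positions <- make_probe_positions(genome, params)
  sig <- lapply(positions, function(p) numeric(length(p)))
  sd <- params$ssdna_footprint_sd
  for (ci in seq_len(n_cells)) {
    cell <- replicate_cell(realize_firing(genome, params), genome, params,
                           sample_time = sample_time)
    if (is.null(cell$forks)) next
    for (chr in unique(cell$forks$chrom)) {
      fx <- cell$forks$position[cell$forks$chrom == chr]
      p <- positions[[chr]]
      for (f in fx)
        sig[[chr]] <- sig[[chr]] + exp(-((p - f)^2) / (2 * sd^2))
    }
  }
  out <- lapply(names(positions), function(chr)
    probe_track(chr, positions[[chr]],
                1 + params$ssdna_gain * sig[[chr]] / n_cells))
  stats::setNames(out, names(positions))
}

#' Replication-completion model for a tandem (rDNA-like) array
#'
#' Each repeat carries one origin that fires independently with probability
#' `p_fire`. Because the replication fork barrier blocks the fork moving
#' against 35S transcription, each initiation contributes a single productive
#' unidirectional fork moving toward the next repeat downstream; a span
#' between consecutive initiation events is replicated only if the upstream
#' fork covers it within `time_budget`. One additional unidirectional fork
#' enters the array from its upstream (left) edge, standing in for the last
#' flanking unique-sequence origin. The analytic mean spacing between active
#' origins is `repeat_len / p_fire`.
#'
#' @param n_repeats Number of repeats in the array.
#' @param repeat_len Repeat length in bp (9000 for the rDNA).
#' @param p_fire Per-repeat origin firing probability.
#' @param fork_speed Fork speed in kb/min.
#' @param time_budget Minutes available to complete replication.
#' @param n_cells Number of cells to simulate.
#' @return A list with `fraction_replicated` (per cell), `p_complete`,
#'   `gap_lengths` (bp, pooled inter-initiation spans), `spacing_empirical`
#'   (mean bp between consecutive active origins), `spacing_analytic`
#'   (`repeat_len / p_fire`), and `n_fired` (per cell).
#' @export
simulate_rdna_array <- function(n_repeats, repeat_len = 9000, p_fire = 0.2,
                                fork_speed = 1.5, time_budget = 60,
                                n_cells = 1000) {
  if (p_fire < 0 || p_fire > 1) stop("p_fire must lie in [0, 1]")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  L <- n_repeats * repeat_len
  travel <- fork_speed * 1000 * time_budget
  frac <- numeric(n_cells); complete <- logical(n_cells)
  n_fired <- integer(n_cells); gaps <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    fired <- which(stats::runif(n_repeats) < p_fire)
    n_fired[ci] <- length(fired)
    # fork sources: array left edge (flanking origin) plus fired repeats
    src <- c(0, (fired - 1) * repeat_len)
    src <- sort(unique(src))
    span_end <- c(src[-1], L)           # each fork must cover up to here
    span_len <- span_end - src
    covered <- pmin(span_len, travel)
    frac[ci] <- sum(covered) / L
    complete[ci] <- all(span_len <= travel)
    if (length(fired) >= 2)
      gaps[[ci]] <- diff((fired - 1) * repeat_len)
  }
  gaps <- unlist(gaps)
  list(fraction_replicated = frac,
       p_complete = mean(complete),
       gap_lengths = gaps,
       spacing_empirical = if (length(gaps)) mean(gaps) else NA_real_,
       spacing_analytic = if (p_fire > 0) repeat_len / p_fire else Inf,
       n_fired = n_fired)
}

#' Add Poisson sequencing noise to a copy-number track
#'
#' Emulates shotgun-sequencing depth: each bin's count is Poisson with mean
#' `mean_depth` times the bin's relative copy number.
#'
#' @param track A [binned_track] of relative copy numbers.
#' @param mean_depth Expected reads per copy-number-1 bin.
#' @return A [binned_track] of integer counts (missing bins stay `NA`).
#' @export
add_poisson_reads <- function(track, mean_depth = 100) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  v <- track$values
  ok <- !is.na(v)
  counts <- rep(NA_real_, length(v))
  counts[ok] <- stats::rpois(sum(ok), mean_depth * v[ok])
  binned_track(track$chrom, track$start, track$step, counts)
}

#' Add multiplicative log-normal noise and rare spikes to a probe track
#'
#' Multiplies each probe value by `exp(Normal(0, log_sd))` and, with
#' probability `outlier_rate` per probe, replaces the value with an extreme
#' spike (30-100 times the genome mean), emulating the hybridization outliers
#' that the 8-SD filter removes.
#'
#' @param track A [probe_track].
#' @param log_sd SD of the log-scale noise (>= 0).
#' @param outlier_rate Per-probe spike probability.
#' @return A noisy [probe_track].
#' @export
add_array_noise <- function(track, log_sd = 0.1, outlier_rate = 0.001) {
  if (log_sd < 0) stop("log_sd must be >= 0")
  v <- track$values * exp(stats::rnorm(length(track$values), 0, log_sd))
  n_spike <- stats::rbinom(1, length(v), outlier_rate)
  if (n_spike > 0) {
    i <- sample(length(v), n_spike)
    v[i] <- mean(track$values) * stats::runif(n_spike, 30, 100)
  }
  probe_track(track$chrom, track$positions, v)
}
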
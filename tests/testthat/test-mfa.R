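test_that("depth normalization divides by the non-excluded mean", {
  g <- genome_map(
    data.frame(name = c("c1", "c2", "chrMito"),
               length = c(5000, 5000, 5000),
               centromere = c(2500, 2500, NA)),
    origin_spec("o1", "c1", 2500, 1, 0, 0),
    special_labels = "chrMito")
  uni <- depth_table(list(c1 = binned_track("c1", 1, 1000, rep(100, 5)),
                          c2 = binned_track("c2", 1, 1000, rep(100, 5)),
                          chrMito = binned_track("chrMito", 1, 1000,
                                                 rep(100, 5))))
  n <- normalize_depth(uni, g)
  expect_equal(n$c1$values, rep(1, 5))

  # one chromosome at 200, one at 100, equal sizes, none excluded:
  # mean 150, values 4/3 and 2/3
  g2 <- genome_map(
    data.frame(name = c("c1", "c2"), length = c(5000, 5000),
               centromere = c(2500, 2500)),
    origin_spec("o1", "c1", 2500, 1, 0, 0))
  d2 <- depth_table(list(c1 = binned_track("c1", 1, 1000, rep(200, 5)),
                         c2 = binned_track("c2", 1, 1000, rep(100, 5))))
  n2 <- normalize_depth(d2, g2)
  expect_equal(n2$c1$values, rep(200 / 150, 5))
  expect_equal(n2$c2$values, rep(100 / 150, 5))

  # excluded mitochondrial bins at 5000x depth get values but no influence
  hot <- depth_table(list(c1 = binned_track("c1", 1, 1000, rep(100, 5)),
                          c2 = binned_track("c2", 1, 1000, rep(100, 5)),
                          chrMito = binned_track("chrMito", 1, 1000,
                                                 rep(5000, 5))))
  n3 <- normalize_depth(hot, g)
  expect_equal(n3$c1$values, rep(1, 5))
  expect_equal(n3$chrMito$values, rep(50, 5))
})

test_that("marker frequency is the per-bin ratio with a division guard", {
  a <- list(c1 = binned_track("c1", 1, 1000, c(1, 1.5, 2, 1)))
  b <- list(c1 = binned_track("c1", 1, 1000, c(1, 1, 0, NA)))
  suppressMessages(mf <- marker_frequency(a, b))
  expect_equal(mf$c1$values[1:2], c(1, 1.5))
  expect_true(all(is.na(mf$c1$values[3:4])))
  expect_equal(attr(mf, "n_masked"), 2L)
  bad <- list(c1 = binned_track("c1", 1, 500, rep(1, 4)))
  expect_error(marker_frequency(a, bad), "grid mismatch")
})

test_that("masks blank exactly the overlapped bins", {
  tr <- list(c1 = binned_track("c1", 1, 1000, rep(1, 50)))
  expect_identical(apply_masks(tr, region_mask("c1", 1, 0 + 1, "custom")[0, ]),
                   tr)  # empty mask table is the identity
  m <- region_mask("c1", 9001, 19000, "Ty")  # bins 10..19
  out <- apply_masks(tr, m)
  expect_equal(which(is.na(out$c1$values)), 10:19)
})

test_that("the smoother reproduces constants and lines", {
  tr <- binned_track("c1", 1, 1000, rep(2.5, 200))
  expect_equal(loess_smooth(tr, 50000)$values, rep(2.5, 200))
  lin <- binned_track("c1", 1, 1000, seq(0, 1, length.out = 200))
  sm <- loess_smooth(lin, 50000)
  interior <- 30:170
  expect_equal(sm$values[interior], lin$values[interior], tolerance = 1e-9)
  expect_error(loess_smooth(tr, 2000), "window_bp")
})

test_that("the smoother agrees with a brute-force WLS oracle", {
  set.seed(20)
  x <- track_positions(binned_track("c1", 1, 1000, numeric(300)))
  y <- sin(x / 3e4) + rnorm(300, 0, 0.2)
  y[sample(300, 15)] <- NA
  tr <- binned_track("c1", 1, 1000, y)
  sm <- loess_smooth(tr, 50000)
  for (i in sample(20:280, 12)) {
    expect_equal(sm$values[i], wls_oracle(x, y, x[i], 50000),
                 tolerance = 1e-9)
  }
})

test_that("smoothing is shift-equivariant", {
  set.seed(21)
  v <- cumsum(rnorm(150))
  a <- loess_smooth(binned_track("c1", 1, 1000, v), 20000)
  b <- loess_smooth(binned_track("c1", 50001, 1000, v), 20000)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("the sequencing pipeline recovers origins and shows dampening", {
  g <- make_demo_genome("s5fig")
  p <- sim_params(rng_seed = 22)
  half <- make_demo_genome("s5fig")
  half$origins$competence <- rep(0.6, 5)

  # ~800 reads per 1 kb bin corresponds to the 10-million-read samples the
  # sequencing assay targets; localization to 2 kb needs that depth
  profile_for <- function(genome) {
    mfa <- simulate_mfa(genome, p, n_cells = 2000)
    s_counts <- depth_table(lapply(mfa, add_poisson_reads, mean_depth = 800),
                            "S")
    g1 <- lapply(mfa, function(t)
      binned_track(t$chrom, t$start, t$step, rep(1, length(t$values))))
    g1_counts <- depth_table(lapply(g1, add_poisson_reads, mean_depth = 800),
                             "G1")
    suppressMessages(mfa_profile(s_counts, g1_counts, genome))$smoothed$chrS
  }
  set.seed(22)
  full <- profile_for(g)
  set.seed(23)
  damp <- profile_for(half)

  amp <- function(tr, x) {
    pos <- track_positions(tr)
    peak <- max(tr$values[abs(pos - x) <= 20000], na.rm = TRUE)
    trough <- min(tr$values[abs(pos - x) <= 90000], na.rm = TRUE)
    peak - trough
  }
  for (x in g$origins$position) {
    # maxima stay within a few bins of the true origins; with Poisson
    # counting noise the smoothed apex jitters by several kb even at
    # 10-million-read depth, so 5 kb is the honest localization claim here
    near <- which(abs(track_positions(full) - x) <= 20000)
    apex <- track_positions(full)[near[which.max(full$values[near])]]
    expect_lte(abs(apex - x), 5000)
    # and reduced competence strictly dampens every peak-to-trough amplitude
    expect_lt(amp(damp, x), amp(full, x))
  }
})
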
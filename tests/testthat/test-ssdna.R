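test_that("ratio formation divides probe-wise and drops bad G1 probes", {
  s <- probe_track("c1", c(100, 200, 300), c(3, 2, 1))
  g1 <- probe_track("c1", c(100, 200, 300), c(1.5, 1, 1))
  r <- form_ratio(s, g1)
  expect_equal(r$values, c(2, 2, 1))
  g1z <- probe_track("c1", c(100, 200, 300), c(1.5, 0, NA))
  suppressMessages(rz <- form_ratio(s, g1z))
  expect_equal(rz$positions, 100)
  expect_equal(attr(rz, "n_dropped"), 2L)
  expect_error(form_ratio(s, probe_track("c1", c(100, 200, 400), rep(1, 3))),
               "do not match")
})

test_that("the 8-SD/2-SD outlier filter removes the right values", {
  # all equal: SD is 0, nothing lies strictly outside
  eq <- probe_track("c1", 1:10 * 100, rep(1, 10))
  expect_equal(length(filter_outliers(eq)$values), 10L)

  # 1000 values of 1 plus one at 1e6: mean ~1000, SD ~3.2e4,
  # upper bound ~2.5e5 < 1e6, so only the spike goes
  spike <- probe_track("c1", seq_len(1001) * 100, c(rep(1, 1000), 1e6))
  suppressMessages(f <- filter_outliers(spike))
  expect_equal(length(f$values), 1000L)
  expect_true(all(f$values == 1))

  # 100 values of 1 plus one at -5: lower bound ~ -0.25 > -5
  low <- probe_track("c1", seq_len(101) * 100, c(rep(1, 100), -5))
  suppressMessages(fl <- filter_outliers(low))
  expect_equal(length(fl$values), 100L)

  # statistics are computed genome-wide across the track list
  two <- list(c1 = probe_track("c1", 1:500 * 100, rep(1, 500)),
              c2 = probe_track("c2", 1:501 * 100, c(rep(1, 500), 1e6)))
  suppressMessages(f2 <- filter_outliers(two))
  expect_equal(length(f2$c2$values), 500L)
})

test_that("refiltering already-filtered ratios never removes the modal mass", {
  set.seed(30)
  tr <- probe_track("c1", seq_len(5000) * 200,
                    exp(rnorm(5000, 0, 0.1)) *
                      c(rep(1, 4900), runif(100, 3, 6)))
  suppressMessages(once <- filter_outliers(tr))
  suppressMessages(twice <- filter_outliers(once))
  # the second pass may trim a few tail values but keeps the bulk
  expect_gt(length(twice$values) / length(once$values), 0.98)
  kept_mode_region <- mean(abs(twice$values - 1) < 0.3)
  expect_gt(kept_mode_region, 0.9)
})

test_that("probe smoothing onto the fine grid matches the WLS oracle", {
  set.seed(31)
  pos <- sort(sample(1000:200000, 250))
  tr <- probe_track("c1", pos, 1 + exp(-((pos - 1e5) / 5e3)^2) +
                      rnorm(250, 0, 0.05))
  sm <- smooth_to_grid(tr, window_bp = 6000, grid_step = 250)
  expect_equal(sm$step, 250)
  gp <- track_positions(sm)
  for (i in sample(seq_along(gp), 12))
    expect_equal(sm$values[i], wls_oracle(pos, tr$values, gp[i], 6000),
                 tolerance = 1e-9)
  # constants and lines pass through (where enough probes contribute;
  # sparse spots are NA by the min-3-point rule)
  con <- smooth_to_grid(probe_track("c1", pos, rep(3, 250)), 6000)
  expect_equal(unique(round(con$values[!is.na(con$values)], 12)), 3)
  lin <- probe_track("c1", pos, pos * 2e-6)
  sml <- smooth_to_grid(lin, 6000)
  gi <- which(gp > 5000 & gp < 195000 & !is.na(sml$values))
  expect_gt(length(gi), 100)
  expect_equal(sml$values[gi], gp[gi] * 2e-6, tolerance = 1e-9)
})

test_that("rescaling maps baseline to 1 and the maximum to 2, monotonically", {
  set.seed(32)
  vals <- c(rnorm(2000, 1, 0.02), runif(50, 1.5, 3))  # modal mass near 1
  tr <- binned_track("c1", 1, 250, vals)
  r <- rescale_track(tr)
  expect_equal(max(r$values), 2.0)
  b <- attr(r, "baseline"); mx <- attr(r, "max")
  # the affine formula: baseline -> 1, midway -> 1.5
  expect_equal((b - b) / (mx - b) + 1, 1.0)
  mid <- (b + mx) / 2
  expect_equal((mid - b) / (mx - b) + 1, 1.5)
  # order preserved
  expect_equal(order(r$values), order(vals))
  flat <- binned_track("c1", 1, 250, rep(1, 100))
  expect_error(rescale_track(flat), "flat")
})

test_that("peak calling finds bump apexes against a brute-force oracle", {
  # two tall Gaussian bumps 50 kb apart riding on a rippled baseline whose
  # small maxima put the bumps in the top 5% of raw peaks: with ~40 raw
  # maxima, the 95th-percentile threshold falls between the tallest ripple
  # and the bumps, so exactly the 2 apexes are significant
  step <- 250
  pos <- seq(step, 200000, by = step)
  bump <- function(c0) 2 * exp(-((pos - c0) / 1500)^2)
  ripple <- 0.02 * sin(pos / 800)   # period ~5 kb -> ~40 baseline maxima
  v <- 1 + bump(60000) + bump(110000) + ripple
  tr <- binned_track("c1", step, step, v)

  # independent enumeration oracle for raw maxima
  raw_oracle <- which(vapply(2:(length(v) - 1), function(i)
    v[i] > v[i - 1] && v[i] > v[i + 1], TRUE)) + 1L
  ps <- call_peaks(tr, top_fraction = 0.05, merge_distance = 5000)
  expect_equal(ps$n_raw, length(raw_oracle))
  expect_gt(ps$n_raw, 30)  # the ripple supplies the small "noise" maxima

  sig <- significant_peaks(ps)
  expect_equal(nrow(sig), 2L)
  expect_lte(abs(sig$position[1] - 60000), step)
  expect_lte(abs(sig$position[2] - 110000), step)

  mono <- binned_track("c1", step, step, seq(1, 2, length.out = 100))
  expect_equal(call_peaks(mono)$n_raw, 0L)
})

test_that("shoulder peaks within 5 kb merge into the taller neighbour", {
  # a secondary bump 3.5 kb from the main apex clears the significance
  # threshold but is merged away by the 5 kb shoulder rule
  step <- 250
  pos <- seq(step, 300000, by = step)
  v <- 1 + 2 * exp(-((pos - 150000) / 1200)^2) +
    1.5 * exp(-((pos - 153500) / 800)^2) +
    0.02 * sin(pos / 800)
  ps <- call_peaks(binned_track("c1", step, step, v))
  sig <- significant_peaks(ps)
  # no surviving pair sits closer than the merge distance
  if (nrow(sig) > 1) expect_gt(min(diff(sort(sig$position))), 5000)
  # the main apex survives, the shoulder is recorded as merged
  expect_lte(min(abs(sig$position - 150000)), step)
  expect_false(any(abs(sig$position - 153500) <= 1000))
  merged <- ps$peaks[!is.na(ps$peaks$merged_into), ]
  expect_gte(nrow(merged), 1L)
})

test_that("window areas sum 41 (or 65) grid values with baseline fill", {
  flat <- binned_track("c1", 250, 250, rep(1, 400))
  expect_equal(as.numeric(peak_area(flat, 50000, 5000)), 41)
  expect_equal(as.numeric(peak_area(flat, 50000, 8000)), 65)
  # a fully-contained bump adds its mass on top of the 41-point baseline
  pos <- track_positions(flat)
  bump <- 0.8 * exp(-((pos - 50000) / 800)^2)
  tr <- binned_track("c1", 250, 250, flat$values + bump)
  direct <- sum((flat$values + bump)[abs(pos - 50000) <= 5000])
  expect_equal(as.numeric(peak_area(tr, 50000, 5000)), direct)
  # near the chromosome start missing points are filled at baseline 1
  a <- peak_area(flat, 2000, 5000)
  expect_equal(as.numeric(a), 41)
  expect_gt(attr(a, "n_filled"), 0)
  expect_error(peak_area(list(c1 = flat), 50000, 5000, chrom = "c9"), "c9")
})

test_that("areas transform predictably under the affine rescale", {
  set.seed(34)
  v <- c(rnorm(1500, 1, 0.05), 1 + 2 * exp(-((1:400 - 200) / 40)^2))
  tr <- binned_track("c1", 250, 250, v)
  r <- rescale_track(tr)
  b <- attr(r, "baseline"); mx <- attr(r, "max")
  center <- 250 * 1700
  a_raw <- as.numeric(peak_area(tr, center, 5000))
  a_res <- as.numeric(peak_area(r, center, 5000))
  expect_equal(a_res, (a_raw - 41 * b) / (mx - b) + 41, tolerance = 1e-9)
})
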
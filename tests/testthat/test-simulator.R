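test_that("firing layer reaches its deterministic limits", {
  g <- make_demo_genome("s5fig")
  g$origins$t_sd <- 0
  p <- sim_params()
  set.seed(1)
  cell <- realize_firing(g, p)
  # competence 1, origins 200 kb apart: no demotion, all fire at t_mean
  expect_true(all(cell$fired))
  expect_equal(cell$fire_time, g$origins$t_mean)

  g0 <- g
  g0$origins$competence <- 0
  cell0 <- realize_firing(g0, p)
  expect_false(any(cell0$fired))
})

test_that("a neighbouring fork passively replicates a late origin", {
  # origins 1 kb apart firing at 0 and 30 min, fork 1 kb/min: the fork
  # arrives after ~0.5-1 min, 30 min before the later origin's turn
  g <- genome_map(
    data.frame(name = "c1", length = 1e5, centromere = 5e4),
    origin_spec(c("early", "late"), "c1", c(50000, 51000),
                competence = c(1, 1), t_mean = c(0, 30), t_sd = c(1, 1)))
  p <- sim_params(fork_speed = 1)
  set.seed(2)
  demoted <- replicate(1000, {
    cell <- realize_firing(g, p)
    cell$passive[2]
  })
  expect_gte(mean(demoted), 0.99)
})

test_that("the dNTP budget caps per-fork travel at D/(2k)", {
  p <- sim_params(hu_mode = TRUE, dntp_budget = 80, fork_speed = 1.5)
  set.seed(3)
  for (k in c(1L, 2L, 4L)) {
    g <- k_origin_genome(k)
    cell <- replicate_cell(realize_firing(g, p), g, p, sample_time = 40)
    travel <- (cell$replicated$end - cell$replicated$start) / 2
    expect_equal(travel, rep(80000 / (2 * k), k))
  }
})

test_that("without HU every fired origin eventually covers the chromosome", {
  g <- make_demo_genome("s5fig")
  g$origins$t_sd <- 0
  p <- sim_params()
  set.seed(4)
  cell <- replicate_cell(realize_firing(g, p), g, p, sample_time = 200)
  expect_equal(nrow(cell$replicated), 1L)
  expect_equal(cell$replicated$start, 1)
  expect_equal(cell$replicated$end, g$chromosomes$length)
})

test_that("simulated marker frequency matches the first-arrival oracle", {
  g <- make_demo_genome("s5fig")
  g$origins$t_sd <- 0
  p <- sim_params(cell_cycle_fractions = c(G1 = 0, S = 1, G2 = 0),
                  rng_seed = 99)
  mfa <- simulate_mfa(g, p, n_cells = 3000)
  tr <- mfa$chrS
  expect_true(all(tr$values >= 1 & tr$values <= 2))
  expected <- mfa_oracle(g, p, track_positions(tr))
  expect_lt(mean(abs(tr$values - expected)), 0.01)
  # local maxima of the pooled profile sit at the origins (within a bin
  # or two of Monte-Carlo jitter on the tent-shaped expectation)
  for (x in g$origins$position) {
    near <- which(abs(track_positions(tr) - x) <= 10000)
    apex <- track_positions(tr)[near[which.max(tr$values[near])]]
    expect_lte(abs(apex - x), 3000)
  }
})

test_that("all-G1 populations give a flat copy-number track", {
  g <- make_demo_genome("minimal")
  p <- sim_params(cell_cycle_fractions = c(G1 = 1, S = 0, G2 = 0),
                  rng_seed = 5)
  mfa <- simulate_mfa(g, p, n_cells = 50)
  expect_equal(unique(mfa$chrM1$values), 1)
  expect_error(simulate_mfa(g, p, n_cells = 0), "n_cells")
})

test_that("ssDNA peaks split when per-fork travel exceeds the footprint", {
  g <- make_demo_genome("minimal")
  g$origins$t_mean <- 0; g$origins$t_sd <- 0
  pos <- list(chrM1 = seq(80000, 120000, by = 100))
  # travel d and footprint sd: two Gaussians at +/- d are unimodal iff d <= sd
  modality <- function(budget_kb, t) {
    p <- sim_params(hu_mode = TRUE, dntp_budget = budget_kb,
                    ssdna_footprint_sd = 2000, rng_seed = 6)
    tr <- simulate_ssdna(g, p, sample_time = t, n_cells = 5,
                         positions = pos)$chrM1
    d <- diff(tr$values)
    sum(d[-length(d)] > 1e-9 & d[-1] < -1e-9)
  }
  expect_equal(modality(2, 40), 1L)   # d_max = 1 kb  < sd: single peak
  expect_equal(modality(16, 40), 2L)  # d_max = 8 kb  > sd: split peak
})

test_that("zero competence gives a flat baseline ratio", {
  g <- make_demo_genome("minimal")
  g$origins$competence <- 0
  p <- sim_params(hu_mode = TRUE, rng_seed = 7)
  tr <- simulate_ssdna(g, p, sample_time = 30, n_cells = 20)
  expect_equal(unique(tr$chrM1$values), 1)
  expect_error(simulate_ssdna(g, sim_params(hu_mode = FALSE), 30, 10),
               "hu_mode")
})

test_that("rDNA array model reproduces spacing and completion laws", {
  set.seed(8)
  # firing 1 repeat in 5 at 9 kb repeats: 45 kb between active origins
  # (wild-type-sized array; short arrays truncate the long gaps)
  rd <- simulate_rdna_array(n_repeats = 250, repeat_len = 9000, p_fire = 0.2,
                            fork_speed = 1.5, time_budget = 60,
                            n_cells = 10000)
  expect_equal(rd$spacing_analytic, 45000)
  expect_lt(abs(rd$spacing_empirical - 45000) / 45000, 0.05)
  # full firing with enough time always completes
  rd1 <- simulate_rdna_array(10, 9000, p_fire = 1, fork_speed = 1.5,
                             time_budget = 9 / 1.5, n_cells = 200)
  expect_equal(rd1$p_complete, 1)
  # zero firing cannot complete a long array in bounded time
  rd0 <- simulate_rdna_array(90, 9000, p_fire = 0, fork_speed = 1.5,
                             time_budget = 60, n_cells = 100)
  expect_equal(rd0$p_complete, 0)
  expect_true(all(rd0$n_fired == 0))
})

test_that("probability of a fire-free array matches the closed form", {
  set.seed(9)
  rd <- simulate_rdna_array(90, 9000, p_fire = 0.05, fork_speed = 1.5,
                            time_budget = 60, n_cells = 1e5)
  p_zero_mc <- mean(rd$n_fired == 0)
  p_zero_exact <- (1 - 0.05)^90          # ~0.0099
  se <- sqrt(p_zero_exact * (1 - p_zero_exact) / 1e5)
  expect_lt(abs(p_zero_mc - p_zero_exact), 4 * se)
})

test_that("fork-travel is non-increasing in fired-origin count", {
  p <- sim_params(hu_mode = TRUE, dntp_budget = 60, fork_speed = 1.5)
  set.seed(10)
  travels <- sapply(c(1, 2, 4, 8), function(k) {
    g <- k_origin_genome(k, spacing = 5e4)
    cell <- replicate_cell(realize_firing(g, p), g, p, sample_time = 60)
    mean((cell$replicated$end - cell$replicated$start) / 2)
  })
  expect_true(all(diff(travels) < 0))
})

test_that("Poisson read noise has the right mean structure and determinism", {
  flat <- binned_track("c", 1, 1000, rep(1, 4000))
  set.seed(12)
  counts <- add_poisson_reads(flat, mean_depth = 100)
  se <- sqrt(100 / 4000)
  expect_lt(abs(mean(counts$values) - 100), 3 * se)
  two <- binned_track("c", 1, 1000, rep(c(1, 2), each = 2000))
  set.seed(13)
  c2 <- add_poisson_reads(two, mean_depth = 100)
  expect_lt(abs(mean(c2$values[2001:4000]) / mean(c2$values[1:2000]) - 2),
            0.1)
  set.seed(14); a <- add_poisson_reads(flat, 50)
  set.seed(14); b <- add_poisson_reads(flat, 50)
  expect_identical(a$values, b$values)
})

test_that("array noise is identity at zero and seeded-reproducible", {
  tr <- probe_track("c", seq(1000, 1e6, by = 1000), rep(1.5, 1000))
  expect_equal(add_array_noise(tr, log_sd = 0, outlier_rate = 0)$values,
               tr$values)
  set.seed(15); a <- add_array_noise(tr, 0.1, 0.01)
  set.seed(15); b <- add_array_noise(tr, 0.1, 0.01)
  expect_identical(a$values, b$values)
  # ~10 spikes expected from 10,000 probes at rate 0.001
  big <- probe_track("c", seq(100, 1e6, by = 100), rep(1, 10000))
  set.seed(16)
  noisy <- add_array_noise(big, log_sd = 0, outlier_rate = 0.001)
  expect_gt(sum(noisy$values > 10), 2)
  expect_lt(sum(noisy$values > 10), 25)
})
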
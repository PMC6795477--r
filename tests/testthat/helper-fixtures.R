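# Small builders shared across test files. Everything is generated in code;
# no stored fixtures.

# one chromosome with k fully-competent simultaneous origins, far apart
k_origin_genome <- function(k, spacing = 1e5, t_mean = 0, t_sd = 0,
                            competence = 1) {
  len <- spacing * (k + 1)
  genome_map(
    data.frame(name = "chrK", length = len, centromere = round(len / 2)),
    origin_spec(sprintf("O%d", seq_len(k)), "chrK", spacing * seq_len(k),
                competence = rep(competence, k), t_mean = rep(t_mean, k),
                t_sd = rep(t_sd, k))
  )
}

# brute-force tricube weighted linear regression at one point, via lm():
# the independent oracle for the LOESS smoothers
wls_oracle <- function(x, y, x0, window_bp) {
  h <- window_bp / 2
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  d <- abs(x - x0)
  sel <- d < h
  if (sum(sel) < 3) return(NA_real_)
  w <- (1 - (d[sel] / h)^3)^3
  xs <- x[sel] - x0
  if (length(unique(xs)) == 1) return(sum(w * y[sel]) / sum(w))
  fit <- stats::lm(y[sel] ~ xs, weights = w)
  unname(stats::coef(fit)[1])
}

# closed-form population marker frequency for a deterministic genome
# (t_sd = 0, competence = 1, S cells sampled uniformly on (0, s_duration)):
# first fork arrival at x is a(x) = min_j t_j + |x - x_j| / v, so
# P(replicated | S) = max(0, (s - a(x)) / s)
mfa_oracle <- function(genome, params, positions) {
  v <- params$fork_speed * 1000
  ori <- genome$origins
  a <- sapply(positions, function(x)
    min(ori$t_mean + abs(x - ori$position) / v))
  fr <- params$cell_cycle_fractions
  p_s <- pmax(0, (params$s_duration - a) / params$s_duration)
  1 + fr[["G2"]] + fr[["S"]] * p_s
}
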
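#!/usr/bin/env Rscript
## The sequencing side of marker-frequency analysis, run end to end on
## simulated reads: per-1-kb-bin Poisson counts for an asynchronous S sample
## and a G1 control (~800 reads/bin, the depth a 10-million-read sample
## gives), depth normalization excluding special territory, the S/G1 ratio,
## masking, and 50 kb LOESS smoothing. The smoothed profile should place its
## local maxima at the simulated origins.

suppressMessages(library(originfire))
dir.create("results", showWarnings = FALSE)
set.seed(2)

genome <- make_demo_genome("s5fig")
params <- sim_params()
copy_number <- simulate_mfa(genome, params, n_cells = 2000)

s_depth <- depth_table(lapply(copy_number, add_poisson_reads,
                              mean_depth = 800), "async_S")
g1_flat <- lapply(copy_number, function(t)
  binned_track(t$chrom, t$start, t$step, rep(1, length(t$values))))
g1_depth <- depth_table(lapply(g1_flat, add_poisson_reads,
                               mean_depth = 800), "G1")

# a small mask, as the real pipeline would apply for poorly-mapped regions
masks <- region_mask("chrS", 990001, 1000000, "subtelomere")
prof <- mfa_profile(s_depth, g1_depth, genome, masks = masks,
                    window_bp = 50000)

write_bedgraph(prof$raw$chrS, "results/marker_frequency_raw.bedGraph")
write_bedgraph(prof$smoothed$chrS, "results/marker_frequency_smoothed.bedGraph")

sm <- prof$smoothed$chrS
posg <- track_positions(sm)
apex <- sapply(genome$origins$position, function(x) {
  near <- which(abs(posg - x) <= 20000)
  posg[near[which.max(sm$values[near])]]
})
tab <- data.frame(origin = genome$origins$id,
                  true_position = genome$origins$position,
                  smoothed_apex = apex,
                  apex_error_bp = apex - genome$origins$position)
write.csv(tab, "results/mfa_apex_localization.csv", row.names = FALSE)
message("origin localization from the smoothed sequencing profile:")
print(tab)
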
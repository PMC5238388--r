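#!/usr/bin/env Rscript
# Builds the synthetic protein used throughout the analysis: ten residues,
# a planted directed five-residue chain 1 -> 2 -> 3 -> 4 -> 5 over the phi
# dihedrals (residues 6-10 are uncoupled controls), relaxation times 2-6 ns,
# stationary amplitudes 25 degrees, coarse 3-D backbone positions with
# coupling-dependent positional jitter. Writes the angle series in the
# res<idx>_<dof>.tsv dialect plus the ground truth, so every later step can
# run from the text files alone.

library(tdcf)

out_dir <- "results/series"
seed <- 2026L

sys <- make_system(
  n_res = 10,
  edges = chain_edges(1:5),
  tau_ns = 2:6,
  jitter_mode = "by-coupling",
  seed = seed)

message(sprintf("assembled system: %d dofs, %d planted edges, stationary sds all %.0f deg",
                nrow(sys$vars), nrow(sys$edges), sys$sd_deg[1]))

dat <- generate_synthetic(sys, length_ns = 1500, dt_ns = 0.1, seed = seed + 1L)

dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write_series_dir(dat$series, out_dir)
write_ground_truth(sys, "results/ground_truth.json")

# distance statistics for every pair (used by the path and the
# amplitude-versus-variance analysis)
pairs <- t(combn(10, 2))
dtab <- rbind(distance_table(dat, pairs, "alpha-alpha"),
              distance_table(dat, pairs, "alpha-beta"),
              distance_table(dat, pairs, "beta-beta"))
write.table(dtab, "results/distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("wrote %d series (%d frames each) to %s; %d distance rows",
                length(dat$series), dat$n_frames, out_dir, nrow(dtab)))
message(sprintf("coupled-pair jitter %.3f nm vs uncoupled %.3f nm -> var(d) contrast for the amplitude analysis",
                min(sys$jitter_nm), max(sys$jitter_nm)))
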
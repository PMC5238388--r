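#!/usr/bin/env Rscript
# Transfer-entropy cross-check of the TDCF direction assignments along the
# planted chain: embedding dimension by false nearest neighbours, embedding
# interval from the delayed-MI optimum, plug-in histogram TE in both
# directions with shuffle-bias estimates. Run 01_simulate.R first.

library(tdcf)

series <- read_series_dir("results/series")
dir.create("results/te", showWarnings = FALSE, recursive = TRUE)

chain <- cbind(1:4, 2:5)
rows <- list()
for (k in seq_len(nrow(chain))) {
  i <- chain[k, 1]; j <- chain[k, 2]
  r <- direction_by_te(series[[sprintf("res%d_phi", i)]],
                       series[[sprintf("res%d_phi", j)]],
                       n_shuffle = 10, max_lag_ns = 30, seed = 500L + k)
  write_te_json(r, sprintf("results/te/res%d_res%d.json", i, j))
  rows[[k]] <- data.frame(
    i = i, j = j, m = r$m, tau_embed_ns = r$tau_embed_ns,
    te_fwd_bits = r$te_forward_bits, te_rev_bits = r$te_reverse_bits,
    te_fwd_bias = r$te_forward_bias, direction = r$direction,
    tdcf_direction = r$tdcf_direction, agree = r$agreement_with_tdcf)
  message(sprintf(
    "%d-%d: m = %d, tau = %.1f ns, TE %d->%d = %.3f bits (bias %.3f), TE %d->%d = %.3f -> %s [TDCF %s, %s]",
    i, j, r$m, r$tau_embed_ns, i, j, r$te_forward_bits, r$te_forward_bias,
    j, i, r$te_reverse_bits, r$direction, r$tdcf_direction,
    if (r$agreement_with_tdcf) "agree" else "disagree"))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/te/chain_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("TE direction agrees with TDCF on %d/%d chain edges",
                sum(tab$agree), nrow(tab)))
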
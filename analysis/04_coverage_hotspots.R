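#!/usr/bin/env Rscript
# Stage 4: position-wise source-protein coverage, four-group binning and
# hotspot calling.

library(ligandkit)

res <- run_pipeline("results/bundle", out_dir = "results/pipeline")
prot <- read_fasta("results/bundle/proteome.fasta")

st <- proteome_coverage_stats(res$profiles, prot)
message(sprintf(
  "%d source proteins; %.1f%% of all proteome residues ligand-covered",
  length(res$profiles), 100 * st$overall))
print(table(res$bins$group))
message(sprintf("%d hotspot calls (min_cov 1, max_gap 0, min_len 8)",
                nrow(res$hotspots)))
utils::write.table(res$hotspots, "results/pipeline/hotspots.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
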
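#!/usr/bin/env Rscript
# Stage 6: spectral validation of native vs isotope-labeled synthetic
# peptide pairs, and the retention-time prediction-interval evaluation.

library(ligandkit)

spectra <- read_mgf("results/bundle/spectra.mgf")
peps <- vapply(spectra, `[[`, character(1), "peptide")
pairs <- lapply(unique(peps), function(p) {
  sp <- spectra[peps == p]
  shifts <- vapply(sp, `[[`, numeric(1), "label_shift")
  list(native = sp[[which(shifts == 0)[1]]],
       labeled = sp[[which(shifts > 0)[1]]])
})

null <- null_distribution(spectra, n_pairs = 1000, seed = 6)
val <- validate_pairs(pairs, null = null)
message(sprintf(
  "matched pairs: median lambda %.3f; null 99th percentile %.3f",
  median(val$lambda), null$quantile(0.99)))
message(sprintf("%d/%d pairs above the null's 99th percentile",
                sum(val$lambda > null$quantile(0.99)), nrow(val)))
utils::write.table(val, "results/pipeline/validation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## retention time: measured RTs from the bundle vs the linear surrogate
recs <- read_peptide_table("results/bundle/peptides.tsv")
recs <- recs[!duplicated(recs$sequence) & !is.na(recs$rt_min), ]
ev <- evaluate_rt(rt_surrogate(recs$sequence), recs$rt_min)
message(sprintf(
  "RT fit on %d peptides: R^2 %.3f, pi %.1f min, frac %.3f",
  ev$n, ev$r_squared, ev$pi, ev$frac))
jsonlite::write_json(ev, "results/pipeline/rt_eval.json",
                     auto_unbox = TRUE)
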
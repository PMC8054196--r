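#!/usr/bin/env Rscript
# Stage 1: generate the synthetic atlas every later stage consumes.
#
# The plan encodes the study conditions: 6 subjects x 4 tissues, paired
# HLA-I/HLA-II samples in 2 technical replicates, 9-mer-dominated class-I
# lengths (60%) and 15-mer-peaked class-II lengths (18%), planted binder
# fractions 0.82 (I) / 0.62 (II), and subject-dominant peptide sharing
# (0.6 subject vs 0.2 tissue weight).

library(ligandkit)

out <- "results/bundle"
plan <- simulation_plan(seed = 1L)
bundle <- simulate_bundle(plan, out, n_proteins = 100L,
                          n_spectrum_pairs = 20L, ts_peptides = 300L,
                          ts_clusters = 3L)

message(sprintf("wrote %s: %d peptide records, %d proteins, %d spectra",
                out, nrow(bundle$samples$records),
                length(bundle$proteome$sequences),
                length(bundle$spectra)))
message(sprintf("planted binder fractions (truth): I %.3f, II %.3f",
                mean(bundle$samples$truth$binder[
                  bundle$samples$truth$hla_class == "I"]),
                mean(bundle$samples$truth$binder[
                  bundle$samples$truth$hla_class == "II"])))
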
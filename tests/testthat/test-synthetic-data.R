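test_that("proteome generation is deterministic and respects bounds", {
  p1 <- generate_proteome(10, c(200, 400), seed = 1)
  p2 <- generate_proteome(10, c(200, 400), seed = 1)
  expect_identical(p1$sequences, p2$sequences)
  expect_length(p1$sequences, 10L)
  lens <- nchar(p1$sequences)
  expect_true(all(lens >= 200 & lens <= 400))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p1$sequences)))
  expect_error(generate_proteome(0), ">= 1")
  # distinct seeds give distinct proteomes
  expect_false(identical(p1$sequences,
                         generate_proteome(10, seed = 2)$sequences))
})

test_that("generated peptides are proteome substrings with planted
           structure", {
  plan <- simulation_plan(n_subjects = 3, tissues = c("liver", "lung"),
                          n_peptides = 60, pool_size = 80, seed = 91)
  prot <- generate_proteome(40, seed = 91)
  s <- generate_samples(plan, prot)
  # every peptide is an exact substring of its annotated source protein
  idx <- sample(nrow(s$records), 200)
  ok <- vapply(idx, function(i) {
    grepl(s$records$sequence[i],
          prot$sequences[[s$records$protein_ids[i]]], fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  # class length ranges hold and the class-I mode is 9
  lenI <- nchar(s$records$sequence[s$records$hla_class == "I"])
  lenII <- nchar(s$records$sequence[s$records$hla_class == "II"])
  expect_true(all(lenI >= 8 & lenI <= 12))
  expect_true(all(lenII >= 8 & lenII <= 25))
  expect_equal(length_mode(lenI), 9L)
  expect_true(all(length_mode(lenII) >= 12 & length_mode(lenII) <= 18))
  # determinism
  s2 <- generate_samples(plan, prot)
  expect_identical(s$records, s2$records)
  expect_identical(s$truth, s2$truth)
})

test_that("planted binder fraction is recovered from truth labels", {
  plan <- simulation_plan(n_subjects = 4, tissues = c("liver", "lung"),
                          n_peptides = 150, pool_size = 190,
                          binder_fraction = c(I = 0.8, II = 0.62),
                          seed = 92)
  s <- generate_samples(plan, generate_proteome(60, seed = 92))
  truthI <- s$truth[s$truth$hla_class == "I", ]
  expect_gt(nrow(truthI), 900)
  expect_equal(mean(truthI$binder), 0.8, tolerance = 0.03)
})

test_that("subject-dominant sharing shows up in the truth sets", {
  plan <- simulation_plan(n_subjects = 4,
                          tissues = c("liver", "lung", "kidney"),
                          n_peptides = 80, pool_size = 100,
                          share_subject = 0.6, share_tissue = 0.2,
                          seed = 93)
  s <- generate_samples(plan, generate_proteome(60, seed = 93))
  recs <- s$records[s$records$hla_class == "I", ]
  sets <- build_sample_sets(recs, "peptide")
  meta <- attr(sets, "meta")
  js <- jt <- numeric()
  for (i in seq_along(sets)) for (k in seq_along(sets)) {
    if (k <= i) next
    j <- jaccard(sets[[i]], sets[[k]])
    if (meta$subject_id[i] == meta$subject_id[k]) js <- c(js, j)
    else if (meta$tissue[i] == meta$tissue[k]) jt <- c(jt, j)
  }
  expect_gt(mean(js), mean(jt))
})

test_that("rank table realizes the planted labels through the
           classifier", {
  plan <- simulation_plan(n_subjects = 3, tissues = "liver",
                          n_peptides = 100, pool_size = 130, seed = 94)
  s <- generate_samples(plan, generate_proteome(50, seed = 94))
  ranks <- generate_rank_table(s, seed = 94)
  ann <- annotate_dataset(s$records, s$metas, ranks)
  truth_key <- paste(s$truth$subject_id, s$truth$hla_class,
                     s$truth$sequence)
  rec_key <- paste(ann$subject_id, ann$hla_class, ann$sequence)
  planted <- s$truth$binder[match(rec_key, truth_key)]
  called <- ann$category %in% c("strong", "weak")
  expect_gt(mean(planted == called), 0.95)
  # determinism of the table
  expect_identical(ranks, generate_rank_table(s, seed = 94))
})

test_that("mock motif predictor yields calibrated percentile ranks", {
  motifs <- generate_motifs("A*02:01", seed = 95)
  m <- motifs[["A*02:01"]]
  expect_equal(colSums(m$pwm), rep(1, 9), tolerance = 1e-12)
  expect_true(all(apply(m$pwm[, m$anchors], 2, max) >= 0.5))
  # anchor-consensus peptide ranks at the very top
  consensus <- paste(rownames(m$pwm)[apply(m$pwm, 2, which.max)],
                     collapse = "")
  sc <- score_with_motifs(consensus, motifs, background_n = 2000,
                          seed = 95)
  expect_lte(sc$rank, 0.5)
  # random peptides rank uniformly: median about 50
  rnd <- random_peptides(200, 9, seed = 96)
  sc2 <- score_with_motifs(rnd, motifs, background_n = 2000, seed = 95)
  expect_equal(median(sc2$rank), 50, tolerance = 8)
  expect_true(all(sc2$rank > 0 & sc2$rank <= 100))
  # determinism and the short-peptide contract
  expect_identical(sc2, score_with_motifs(rnd, motifs,
                                          background_n = 2000,
                                          seed = 95))
  expect_error(score_with_motifs("AAAA", motifs), "core")
})

test_that("time-series generator plants recoverable trajectory shapes", {
  ts <- generate_timeseries(300, c(0, 24, 72), n_clusters = 3, seed = 97)
  expect_equal(dim(ts$areas), c(300L, 3L))
  expect_equal(sort(unique(ts$truth)), 1:3)
  expect_true(all(ts$areas > 0))
  # noise -> 0: within-cluster trajectories identical after z-scoring
  ts0 <- generate_timeseries(60, c(0, 24, 72), n_clusters = 3,
                             sigma = 0, seed = 97)
  z <- zscore_per_run(ts0$areas)
  for (cl in 1:3) {
    rows <- z[ts0$truth == cl, , drop = FALSE]
    expect_lt(max(apply(rows, 2, function(x) diff(range(x)))), 1e-10)
  }
  expect_identical(generate_timeseries(50, seed = 98)$areas,
                   generate_timeseries(50, seed = 98)$areas)
})

test_that("spectrum pairs differ only by the label shift when noise-free", {
  pr <- generate_spectrum_pair("SIINFEKL", label_shift = 6,
                               label_position = 8, noise = NULL,
                               seed = 99)
  n <- nchar("SIINFEKL")
  expect_equal(nrow(pr$native$peaks), 2 * (n - 1))
  expect_equal(nrow(pr$labeled$peaks), 2 * (n - 1))
  fn <- theoretical_fragments("SIINFEKL")
  fl <- theoretical_fragments("SIINFEKL", 6, 8)
  expect_equal(sort(pr$native$peaks[, "mz"]), sort(fn$mz))
  expect_equal(sort(pr$labeled$peaks[, "mz"]), sort(fl$mz))
  expect_error(generate_spectrum_pair("SIINFEKL", label_position = 9),
               "label_position")
})

test_that("the simulated bundle round-trips through the readers", {
  dir <- tempfile("bundle")
  plan <- simulation_plan(n_subjects = 2, tissues = "liver",
                          n_peptides = 30, pool_size = 40,
                          seed = 100)
  b <- simulate_bundle(plan, dir, n_proteins = 20,
                       n_spectrum_pairs = 3, ts_peptides = 30)
  expect_true(all(file.exists(file.path(dir,
    c("peptides.tsv", "samples.tsv", "ranks.tsv", "proteome.fasta",
      "spectra.mgf", "timeseries.tsv", "truth.json")))))
  recs <- read_peptide_table(file.path(dir, "peptides.tsv"))
  expect_equal(nrow(recs), nrow(b$samples$records))
  expect_length(read_mgf(file.path(dir, "spectra.mgf")), 6L)
  expect_equal(read_fasta(file.path(dir, "proteome.fasta"))$sequences,
               b$proteome$sequences)
})
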
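test_that("yield table computes per-sample counts and tissue medians", {
  recs <- rbind(
    make_records(random_peptides(10, 9, seed = 61), subject_id = "S1"),
    make_records(random_peptides(30, 9, seed = 62), subject_id = "S2"),
    make_records(random_peptides(50, 9, seed = 63), subject_id = "S3"),
    make_records(random_peptides(5, 9, seed = 64), subject_id = "S1",
                 tissue = "lung"))
  yt <- yield_table(recs)
  expect_equal(sort(yt$per_sample$yield), c(5, 10, 30, 50))
  expect_equal(yt$per_tissue$median_yield[yt$per_tissue$tissue ==
                                            "liver"], 30)
  expect_equal(yt$per_tissue$median_yield[yt$per_tissue$tissue ==
                                            "lung"], 5)
  # replicates of one sample are pooled, duplicates collapse
  recs2 <- rbind(make_records("AAAAKKKKA", replicate_id = "R1"),
                 make_records("AAAAKKKKA", replicate_id = "R2"))
  expect_equal(yield_table(recs2)$per_sample$yield, 1)
})

test_that("yield model recovers exact log-linear relations", {
  rpkm <- c(liver = 10, lung = 100, kidney = 1000, ovary = 5000)
  yields <- rpkm^2
  fit <- fit_yield_model(yields, rpkm, gene = "HLA-A")
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$spearman_rho, 1)
  expect_lt(fit$f_pvalue, 0.01)
})

test_that("R-squared equals the squared Pearson r of the log pairs", {
  set.seed(65)
  rpkm <- stats::setNames(10^runif(12, 0, 3), paste0("t", 1:12))
  yields <- stats::setNames(10^(0.8 * log10(rpkm) + rnorm(12, 0, 0.3)),
                            names(rpkm))
  fit <- fit_yield_model(yields, rpkm)
  expect_equal(fit$r_squared,
               cor(log10(rpkm), log10(yields))^2, tolerance = 1e-12)
})

test_that("planted slope is recovered and permutation kills the fit", {
  set.seed(66)
  n_tissues <- 20
  rpkm <- stats::setNames(10^runif(n_tissues, 0, 3),
                          paste0("t", seq_len(n_tissues)))
  yields <- stats::setNames(
    10^(1 + 1 * log10(rpkm) + rnorm(n_tissues, 0, 0.2)), names(rpkm))
  fit <- fit_yield_model(yields, rpkm)
  expect_equal(fit$slope, 1, tolerance = 0.15)
  expect_gt(fit$spearman_rho, 0.7)
  r2_perm <- replicate(100, {
    perm <- stats::setNames(sample(rpkm), names(rpkm))
    fit_yield_model(yields, perm)$r_squared
  })
  expect_lt(median(r2_perm), 0.1)
})

test_that("zero-valued tissues are dropped, not pseudo-counted", {
  rpkm <- c(a = 10, b = 100, c = 0, d = 1000)
  yields <- c(a = 100, b = 1000, c = 50, d = 10000)
  fit <- fit_yield_model(yields, rpkm)
  expect_equal(fit$n, 3L)
  expect_equal(attr(fit, "dropped"), "c")
  expect_error(fit_yield_model(c(a = 1, b = 10), c(a = 1, b = 2)),
               ">= 3")
})

test_that("tissue-exclusive proteins require exclusivity across all
           subjects", {
  recs <- rbind(
    make_records("AAAAKKKKA", subject_id = "S1", protein_ids = "P1"),
    make_records("CCCCKKKKC", subject_id = "S2", protein_ids = "P1"),
    make_records("DDDDKKKKD", subject_id = "S1", tissue = "lung",
                 protein_ids = "P2"),
    make_records("EEEEKKKKE", subject_id = "S2", protein_ids = "P2;P3"))
  ex <- tissue_exclusive_proteins(recs)
  expect_setequal(ex$liver, c("P1", "P3"))   # P2 seen in liver and lung
  expect_false("P2" %in% unlist(ex))
  expect_equal(tissue_exclusive_proteins(recs[0, ]), list())
})

test_that("Fisher enrichment matches the exhaustive hypergeometric
           oracle", {
  set.seed(67)
  universe <- paste0("g", 1:60)
  for (i in 1:60) {
    N <- sample(10:60, 1)
    uni <- universe[seq_len(N)]
    m <- sample(1:N, 1)
    n <- sample(1:N, 1)
    query <- sample(uni, m)
    gs <- list(s = sample(uni, n))
    res <- fisher_enrichment(query, gs, uni)
    k <- length(intersect(query, gs$s))
    expect_equal(res$fisher_p, hyper_tail(k, m, n, N),
                 tolerance = 1e-12)
    # cross-check against the base fisher.test one-sided p
    ft <- stats::fisher.test(matrix(c(k, m - k, n - k, N - n - m + k),
                                    2, 2), alternative = "greater")
    expect_equal(res$fisher_p, unname(ft$p.value), tolerance = 1e-9)
  }
})

test_that("degenerate enrichment tables give p = 1", {
  uni <- paste0("g", 1:20)
  res0 <- fisher_enrichment(uni[1:5], list(s = uni[6:10]), uni)
  expect_equal(res0$fisher_p, 1.0)       # zero overlap
  res1 <- fisher_enrichment(uni, list(s = uni), uni)
  expect_equal(res1$fisher_p, 1.0)       # query = set = universe
  expect_error(fisher_enrichment("g1", list(s = "g1"), character()),
               "empty universe")
})

test_that("enrichment results rank by raw p with top-k reporting", {
  set.seed(68)
  uni <- paste0("g", 1:50)
  query <- uni[1:10]
  gs <- list(hit = uni[1:10], partial = uni[6:20], miss = uni[40:50])
  res <- fisher_enrichment(query, gs, uni, top_k = 2)
  expect_equal(nrow(res), 2L)
  expect_equal(res$gene_set[1], "hit")
  expect_true(all(diff(res$fisher_p) >= 0))
  full <- fisher_enrichment(query, gs, uni)
  expect_equal(full$p_bh, p.adjust(full$fisher_p, "BH"))
})

test_that("TAA subtraction partitions the tumor set exactly", {
  out <- taa_subtract(list(pt1 = c("p1", "p2")), list(c("p2")))
  expect_equal(out$exclusive$sequence, "p1")
  expect_equal(out$exclusive$patient_frequency, 1L)
  expect_equal(out$shared, "p2")
  out2 <- taa_subtract(list(pt1 = c("p3", "p4"), pt2 = "p3",
                            pt3 = "p9"),
                       list(c("p4"), c("p8")))
  expect_equal(out2$exclusive$patient_frequency[
    out2$exclusive$sequence == "p3"], 2L)
  # all tumor peptides benign -> empty report
  out3 <- taa_subtract(list(pt1 = "p1"), list("p1"))
  expect_equal(nrow(out3$exclusive), 0L)
})

test_that("TAA partition properties hold under randomized set systems", {
  set.seed(69)
  pool <- paste0("p", 1:40)
  for (i in 1:200) {
    tumor <- lapply(seq_len(sample(1:4, 1)), function(j) {
      sample(pool, sample(1:15, 1))
    })
    names(tumor) <- paste0("pt", seq_along(tumor))
    benign <- lapply(seq_len(sample(1:4, 1)), function(j) {
      sample(pool, sample(1:15, 1))
    })
    out <- taa_subtract(tumor, benign)
    tumor_union <- unique(unlist(tumor))
    expect_setequal(c(out$exclusive$sequence, out$shared), tumor_union)
    expect_length(intersect(out$exclusive$sequence,
                            unique(unlist(benign))), 0L)
    expect_true(all(out$exclusive$patient_frequency >= 1))
    expect_true(all(out$exclusive$patient_frequency <= length(tumor)))
  }
})

test_that("CTA cross-referencing needs at least two distinct ligands", {
  recs <- rbind(
    make_records(c("AAAAKKKKA", "CCCCKKKKC"), protein_ids = "CTA1"),
    make_records("DDDDKKKKD", protein_ids = "CTA2"),
    make_records(c("EEEEKKKKE", "FFFFKKKKF"), protein_ids = "P1"))
  out <- cta_crossref(recs, c("CTA1", "CTA2"))
  expect_equal(out$accession, "CTA1")
  expect_equal(out$n_ligands, 2L)
  # one ligand in class I plus one in class II stay separate
  recs2 <- rbind(
    make_records("AAAAKKKKA", protein_ids = "CTA1"),
    make_records("CCCCKKKKCCCCKKK", protein_ids = "CTA1",
                 hla_class = "II"))
  expect_equal(nrow(cta_crossref(recs2, "CTA1")), 0L)
})
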
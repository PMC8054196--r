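#' Generate a random reference proteome
#'
#' Proteins of i.i.d. residues with uniform lengths in `length_range`;
#' deterministic for a fixed seed.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param length_range length bounds in residues.
#' @param seed RNG seed.
#' @return `Proteome` with accessions `SYNP0001`, ...
#' @export
generate_proteome <- function(n_proteins, length_range = c(200L, 400L),
                              seed = 1L) {
  if (n_proteins < 1L) stop("generate_proteome: n_proteins must be >= 1")
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_proteins,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("SYNP%04d", seq_len(n_proteins))
  proteome(seqs, name = "synthetic")
}

#' Default peptide length distributions
#'
#' HLA-I: categorical over 8-12 residues with 60% 9-mers; HLA-II:
#' discretized bell over 8-25 residues peaking at 15-mers with an 18%
#' share — the canonical class-specific ligand length profiles.
#' @return list with elements `I` and `II`, each a named probability
#'   vector over lengths.
#' @export
default_length_probs <- function() {
  pI <- c(`8` = 0.12, `9` = 0.60, `10` = 0.14, `11` = 0.09, `12` = 0.05)
  l2 <- 8:25
  w <- stats::dnorm(l2, mean = 15, sd = 2.2)
  pII <- stats::setNames(w / sum(w), l2)
  list(I = pI, II = pII)
}

#' Simulation plan for a synthetic multi-subject atlas
#'
#' The plan fixes the study conditions the generator emulates: number of
#' subjects and tissues, per-tissue yield multipliers, per-class planted
#' binder fractions (0.82 HLA-I / 0.62 HLA-II by default), class-specific
#' length distributions, and the subject-dominant sharing structure
#' (subject-sharing weight 0.6 versus tissue-sharing 0.2, remainder
#' private), plus the nested class-II length-variant probability.
#'
#' @param n_subjects number of subjects.
#' @param tissues tissue names.
#' @param tissue_multipliers per-tissue yield multipliers (named).
#' @param n_peptides base unique peptides per sample before multipliers.
#' @param binder_fraction named fractions for classes I and II.
#' @param length_probs list from [default_length_probs()].
#' @param share_subject,share_tissue sharing weights (sum < 1; remainder
#'   is sample-private).
#' @param p_nested probability a class-II peptide is emitted as a nested
#'   length variant of an earlier peptide of the same sample.
#' @param pool_size size of each subject/tissue peptide pool.
#' @param n_replicates technical replicates per sample.
#' @param replicate_detection per-replicate detection probability of each
#'   sample peptide.
#' @param seed RNG seed.
#' @return list of class `SimulationPlan`.
#' @export
simulation_plan <- function(n_subjects = 6L,
                            tissues = c("liver", "lung", "kidney",
                                        "thymus"),
                            tissue_multipliers = NULL,
                            n_peptides = 120L,
                            binder_fraction = c(I = 0.82, II = 0.62),
                            length_probs = default_length_probs(),
                            share_subject = 0.6, share_tissue = 0.2,
                            p_nested = 0.3, pool_size = 150L,
                            n_replicates = 2L,
                            replicate_detection = 0.85,
                            seed = 1L) {
  if (is.null(tissue_multipliers)) {
    tissue_multipliers <- stats::setNames(
      seq(1.4, 0.8, length.out = length(tissues)), tissues)
  }
  stopifnot(share_subject + share_tissue <= 1,
            all(binder_fraction >= 0 & binder_fraction <= 1),
            abs(sum(length_probs$I) - 1) < 1e-8,
            abs(sum(length_probs$II) - 1) < 1e-8,
            all(as.integer(names(length_probs$I)) >= 8L),
            all(as.integer(names(length_probs$I)) <= 12L),
            all(as.integer(names(length_probs$II)) >= 8L),
            all(as.integer(names(length_probs$II)) <= 25L))
  structure(list(n_subjects = n_subjects, tissues = tissues,
                 tissue_multipliers = tissue_multipliers,
                 n_peptides = n_peptides,
                 binder_fraction = binder_fraction,
                 length_probs = length_probs,
                 share_subject = share_subject,
                 share_tissue = share_tissue, p_nested = p_nested,
                 pool_size = pool_size, n_replicates = n_replicates,
                 replicate_detection = replicate_detection, seed = seed),
            class = "SimulationPlan")
}

draw_locus <- function(prot, len_probs) {
  len <- as.integer(sample(names(len_probs), 1L, prob = len_probs))
  repeat {
    i <- sample.int(length(prot$sequences), 1L)
    L <- nchar(prot$sequences[[i]])
    if (L >= len) break
  }
  start <- sample.int(L - len + 1L, 1L)
  list(accession = names(prot$sequences)[i], start = start,
       end = start + len - 1L,
       sequence = substr(prot$sequences[[i]], start, start + len - 1L))
}

nested_variant <- function(locus, prot) {
  L <- nchar(prot$sequences[[locus$accession]])
  for (i in 1:20) {
    ds <- sample(-3:3, 1L); de <- sample(-3:3, 1L)
    s <- locus$start + ds; e <- locus$end + de
    len <- e - s + 1L
    if (s >= 1L && e <= L && len >= 8L && len <= 25L &&
        !(ds == 0L && de == 0L)) {
      return(list(accession = locus$accession, start = s, end = e,
                  sequence = substr(prot$sequences[[locus$accession]],
                                    s, e)))
    }
  }
  locus
}

CLASS_I_ALLELES <- c("A*01:01", "A*02:01", "A*03:01", "B*07:02",
                     "B*08:01", "B*44:02", "C*07:01", "C*07:02")
CLASS_II_ALLELES <- c("DRB1*04:01", "DRB1*07:01", "DRB1*15:01",
                      "DQB1*03:01", "DQB1*06:02", "DPB1*04:01")

#' Generate a synthetic multi-subject, multi-tissue peptide dataset
#'
#' Every peptide is an exact substring of the supplied proteome. Sharing
#' structure is planted through per-subject and per-tissue peptide pools:
#' each sample draws a fraction `share_subject` of its peptides from its
#' subject's pool, `share_tissue` from its tissue's pool and the remainder
#' privately, so two tissues of one subject overlap more than two
#' subjects' same tissue whenever `share_subject > share_tissue`.
#' Class-II samples emit nested length variants around shared cores with
#' probability `p_nested`. Each sample is observed in `n_replicates`
#' technical replicates with independent per-peptide detection. Planted
#' binder labels are Bernoulli per subject x class x sequence at the
#' plan's class binder fraction.
#'
#' @param plan `SimulationPlan`.
#' @param prot `Proteome`.
#' @return list: `records` (peptide table rows), `metas` (per subject x
#'   class alleles), `truth` (data.frame subject_id, hla_class, sequence,
#'   binder, origin).
#' @export
generate_samples <- function(plan, prot) {
  set.seed(plan$seed)
  subjects <- sprintf("S%02d", seq_len(plan$n_subjects))
  metas <- list(); records <- list(); truth_env <- new.env(parent =
                                                            emptyenv())
  origin_env <- new.env(parent = emptyenv())
  for (s in subjects) {
    metas[[length(metas) + 1L]] <- data.frame(
      subject_id = s, hla_class = "I",
      alleles = paste(sample(CLASS_I_ALLELES, 4L), collapse = ";"),
      stringsAsFactors = FALSE)
    metas[[length(metas) + 1L]] <- data.frame(
      subject_id = s, hla_class = "II",
      alleles = paste(sample(CLASS_II_ALLELES, 3L), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  pools <- list()
  for (cls in c("I", "II")) {
    lp <- plan$length_probs[[cls]]
    for (s in subjects) {
      pools[[paste0("subj.", cls, ".", s)]] <-
        replicate(plan$pool_size, draw_locus(prot, lp), simplify = FALSE)
    }
    for (t in plan$tissues) {
      pools[[paste0("tis.", cls, ".", t)]] <-
        replicate(plan$pool_size, draw_locus(prot, lp), simplify = FALSE)
    }
  }
  for (s in subjects) {
    for (t in plan$tissues) {
      for (cls in c("I", "II")) {
        n <- round(plan$n_peptides * plan$tissue_multipliers[[t]])
        origin <- sample(c("subject", "tissue", "private"), n,
                         replace = TRUE,
                         prob = c(plan$share_subject, plan$share_tissue,
                                  1 - plan$share_subject -
                                    plan$share_tissue))
        loci <- vector("list", n)
        for (i in seq_len(n)) {
          loci[[i]] <- switch(origin[i],
            subject = pools[[paste0("subj.", cls, ".", s)]][[
              sample.int(plan$pool_size, 1L)]],
            tissue = pools[[paste0("tis.", cls, ".", t)]][[
              sample.int(plan$pool_size, 1L)]],
            private = draw_locus(prot, plan$length_probs[[cls]]))
          if (cls == "II" && i > 1L &&
              stats::runif(1) < plan$p_nested) {
            loci[[i]] <- nested_variant(loci[[sample.int(i - 1L, 1L)]],
                                        prot)
            origin[i] <- "nested"
          }
        }
        seqs <- vapply(loci, `[[`, character(1), "sequence")
        keep <- !duplicated(seqs)
        loci <- loci[keep]; seqs <- seqs[keep]; origin <- origin[keep]
        for (i in seq_along(seqs)) {
          key <- paste(s, cls, seqs[i], sep = "\r")
          if (is.null(truth_env[[key]])) {
            truth_env[[key]] <-
              stats::runif(1) < plan$binder_fraction[[cls]]
            origin_env[[key]] <- origin[i]
          }
        }
        rt <- rt_surrogate(seqs) + stats::rnorm(length(seqs), 0, 0.5)
        for (rep_i in seq_len(plan$n_replicates)) {
          det <- stats::runif(length(seqs)) < plan$replicate_detection
          if (!any(det)) det[1] <- TRUE
          records[[length(records) + 1L]] <- data.frame(
            sequence = seqs[det], subject_id = s, tissue = t,
            hla_class = cls, replicate_id = sprintf("R%d", rep_i),
            protein_ids = vapply(loci[det], `[[`, character(1),
                                 "accession"),
            q_value = round(stats::runif(sum(det), 0, 0.01), 6),
            rt_min = round(rt[det], 3), ms1_area = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  keys <- ls(truth_env)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  truth <- data.frame(subject_id = parts[, 1], hla_class = parts[, 2],
                      sequence = parts[, 3],
                      binder = vapply(keys, function(k) truth_env[[k]],
                                      logical(1)),
                      origin = vapply(keys, function(k) origin_env[[k]],
                                      character(1)),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(records = do.call(rbind, records),
       metas = do.call(rbind, metas), truth = truth)
}

#' Linear retention-time surrogate
#'
#' Simple hydrophobicity-sum model mapping a peptide to minutes; used to
#' give simulated records plausible retention times and as the optional
#' built-in RT predictor for the prediction-interval evaluation.
#' @param peptides character vector.
#' @return numeric vector of minutes.
#' @export
rt_surrogate <- function(peptides) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
          Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  vapply(strsplit(peptides, ""), function(r) {
    30 + 1.2 * sum(kd[r])
  }, numeric(1))
}

#' Mock percentile-rank table from planted binder labels
#'
#' Emits one percentile rank per sequence x allotype x tool for every
#' subject's alleles, consistent with the planted labels: a planted binder
#' gets a qualifying rank against one of its subject's allotypes (drawn in
#' the strong range with probability `p_strong`, else in the weak range),
#' and non-qualifying ranks elsewhere; planted non-binders draw all ranks
#' well above the weak thresholds. A sequence scored against an allotype by
#' an earlier subject keeps that score (ranks are a property of the
#' peptide-allotype pair).
#'
#' @param samples output of [generate_samples()].
#' @param p_strong share of planted binders called in the strong range.
#' @param thresholds binder threshold block.
#' @param seed RNG seed.
#' @return data.frame: sequence, allotype, tool, rank.
#' @export
generate_rank_table <- function(samples, p_strong = 0.7,
                                thresholds =
                                  default_config()$binder_thresholds,
                                seed = 1L) {
  set.seed(seed)
  metas <- samples$metas
  seen <- new.env(parent = emptyenv())
  rows <- list()
  emit <- function(sequence, allotype, tool, rank) {
    key <- paste(sequence, allotype, tool, sep = "\r")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = sequence, allotype = allotype, tool = tool,
      rank = round(rank, 3), stringsAsFactors = FALSE)
  }
  truth <- samples$truth
  for (i in seq_len(nrow(truth))) {
    cls <- truth$hla_class[i]
    tools <- if (cls == "I") "netmhcpan" else
      c("netmhciipan", "mixmhc2pred")
    m <- metas[metas$subject_id == truth$subject_id[i] &
                 metas$hla_class == cls, , drop = FALSE]
    alleles <- strsplit(m$alleles, ";")[[1]]
    binding <- if (truth$binder[i]) sample(alleles, 1L) else NA
    for (al in alleles) {
      for (tool in tools) {
        strong_thr <- thresholds$strong[[tool]]
        weak_thr <- thresholds$weak[[tool]]
        r <- if (!is.na(binding) && al == binding) {
          if (stats::runif(1) < p_strong) {
            stats::runif(1, 0.01, strong_thr)
          } else {
            stats::runif(1, strong_thr, weak_thr)
          }
        } else {
          stats::runif(1, weak_thr * 2 + 5, 100)
        }
        emit(truth$sequence[i], al, tool, r)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate mock binding motifs for allotypes
#'
#' Position weight matrices over the 20 residues for a 9-residue core with
#' concentrated anchor positions (weight 0.7 on the anchor residue at
#' positions 2 and 9).
#'
#' @param alleles allotype names.
#' @param seed RNG seed.
#' @return named list of `MotifModel`: list(allotype, pwm (20 x 9, rows
#'   named by residue, columns summing to 1), anchors).
#' @export
generate_motifs <- function(alleles, seed = 1L) {
  set.seed(seed)
  out <- lapply(alleles, function(al) {
    pwm <- matrix(0, nrow = 20L, ncol = 9L,
                  dimnames = list(AA_ALPHABET, NULL))
    for (p in 1:9) {
      w <- stats::runif(20, 0.5, 1.5)
      pwm[, p] <- w / sum(w)
    }
    anchors <- c(2L, 9L)
    for (a in anchors) {
      res <- sample(AA_ALPHABET, 1L)
      pwm[, a] <- (1 - 0.7) * pwm[, a] / sum(pwm[, a])
      pwm[res, a] <- pwm[res, a] + 0.7
    }
    list(allotype = al, pwm = pwm, anchors = anchors)
  })
  stats::setNames(out, alleles)
}

pwm_log_score <- function(peptide, pwm) {
  residues <- strsplit(peptide, "")[[1]]
  core <- ncol(pwm)
  n <- length(residues)
  if (n < core) stop(sprintf("peptide '%s' shorter than the %d-mer core",
                             peptide, core))
  ridx <- match(residues, rownames(pwm))
  best <- -Inf
  for (s in 1:(n - core + 1L)) {
    sc <- sum(log(pwm[cbind(ridx[s:(s + core - 1L)], 1:core)]))
    if (sc > best) best <- sc
  }
  best
}

#' Score peptides against mock motifs as percentile ranks
#'
#' The rank of a peptide against an allotype is the percentile of its best
#' log-PWM core score within a fixed background of random 9-mers
#' (regenerated from the seed; 10,000 by default, giving 0.01 rank
#' granularity). Lower rank = stronger predicted binding; ranks lie in
#' `(0, 100]`.
#'
#' @param peptides character vector (each >= core length).
#' @param motifs list from [generate_motifs()].
#' @param background_n background size.
#' @param seed RNG seed.
#' @return data.frame: sequence, allotype, tool (`"mock"`), rank.
#' @export
score_with_motifs <- function(peptides, motifs, background_n = 10000L,
                              seed = 1L) {
  set.seed(seed)
  bg <- vapply(seq_len(background_n), function(i) {
    paste(sample(AA_ALPHABET, 9L, replace = TRUE), collapse = "")
  }, character(1))
  rows <- list()
  for (m in motifs) {
    bg_scores <- sort(vapply(bg, pwm_log_score, numeric(1), pwm = m$pwm))
    sc <- vapply(peptides, pwm_log_score, numeric(1), pwm = m$pwm)
    n_ge <- background_n - findInterval(sc, bg_scores)
    rank <- 100 * (n_ge + 1) / (background_n + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = peptides, allotype = m$allotype, tool = "mock",
      rank = rank, row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate an MS1 trajectory matrix with planted clusters
#'
#' Each planted cluster follows a distinct mean trajectory in log-area
#' space — stable, decaying, increasing, then late-peaking shapes for
#' larger k — with multiplicative log-normal noise.
#'
#' @param n_peptides rows.
#' @param timepoints hours (column order).
#' @param n_clusters planted cluster count.
#' @param sigma log-space noise SD.
#' @param seed RNG seed.
#' @return list: `areas` (matrix, dimnames peptide x `t<h>h`), `truth`
#'   (integer cluster labels), `timepoints`.
#' @export
generate_timeseries <- function(n_peptides, timepoints = c(0, 8, 16, 24,
                                                           48, 72),
                                n_clusters = 3L, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  tt <- (timepoints - min(timepoints)) /
    max(timepoints - min(timepoints))
  shapes <- list(function(u) 0 * u,
                 function(u) 1 - 2 * u,
                 function(u) 2 * u - 1,
                 function(u) 1 - 2 * abs(u - 0.5) * 2,
                 function(u) 2 * abs(u - 0.5) * 2 - 1,
                 function(u) cos(2 * pi * u))
  stopifnot(n_clusters >= 1L, n_clusters <= length(shapes))
  labels <- rep_len(seq_len(n_clusters), n_peptides)
  m <- t(vapply(seq_len(n_peptides), function(i) {
    14 + shapes[[labels[i]]](tt) + stats::rnorm(length(tt), 0, sigma)
  }, numeric(length(tt))))
  areas <- exp(m)
  dimnames(areas) <- list(sprintf("pep%04d", seq_len(n_peptides)),
                          sprintf("t%gh", timepoints))
  list(areas = areas, truth = labels, timepoints = timepoints)
}

#' Generate a native / isotope-labeled fragment spectrum pair
#'
#' Both spectra carry the peptide's theoretical singly-charged b/y peaks
#' with shared log-normal base intensities times independent
#' multiplicative noise; in the labeled spectrum every fragment containing
#' the labeled residue is shifted by `label_shift` Da (default +6 Da at
#' the C-terminal residue). Optional random noise peaks are added. With
#' `noise = NULL` both peak lists are exactly the theoretical masses with
#' identical intensities.
#'
#' @param peptide amino-acid string.
#' @param label_shift label mass in Da.
#' @param label_position 1-based labeled residue (default: last).
#' @param noise NULL for noise-free, else list with `intensity_cv`
#'   (log-normal sdlog of the per-spectrum intensity noise), `mz_sd` (Da),
#'   `n_noise_peaks`, `noise_rel` (noise peak intensity relative to the
#'   median signal).
#' @param seed RNG seed.
#' @return list with `native` and `labeled` `Spectrum` objects.
#' @export
generate_spectrum_pair <- function(peptide, label_shift = 6,
                                   label_position = nchar(peptide),
                                   noise = default_spectrum_noise(),
                                   seed = 1L) {
  if (label_position < 1L || label_position > nchar(peptide)) {
    stop("label_position outside the peptide")
  }
  set.seed(seed)
  fn <- theoretical_fragments(peptide)
  fl <- theoretical_fragments(peptide, label_shift, label_position)
  base <- stats::rlnorm(nrow(fn), meanlog = 10, sdlog = 0.6)
  mass <- sum(RESIDUE_MASS[strsplit(peptide, "")[[1]]]) + WATER_MASS
  make <- function(frags, shift_total) {
    mz <- frags$mz; int <- base
    if (!is.null(noise)) {
      mz <- mz + stats::rnorm(length(mz), 0, noise$mz_sd)
      int <- int * stats::rlnorm(length(int), 0, noise$intensity_cv)
      if (noise$n_noise_peaks > 0) {
        mz <- c(mz, stats::runif(noise$n_noise_peaks, 100,
                                 max(frags$mz) + 50))
        int <- c(int, stats::rlnorm(noise$n_noise_peaks,
                                    meanlog = 10 +
                                      log(noise$noise_rel), sdlog = 0.6))
      }
    }
    cbind(mz = mz, intensity = int)
  }
  native <- fragment_spectrum(peptide, make(fn), (mass + 2 * PROTON_MASS) / 2, 2L)
  labeled <- fragment_spectrum(peptide, make(fl),
                      (mass + label_shift + 2 * PROTON_MASS) / 2, 2L,
                      label_shift = label_shift,
                      label_position = label_position)
  list(native = native, labeled = labeled)
}

#' Default spectrum noise parameters
#' @export
default_spectrum_noise <- function() {
  list(intensity_cv = 0.3, mz_sd = 0.003, n_noise_peaks = 5L,
       noise_rel = 0.1)
}

#' Simulate the full input bundle on disk
#'
#' Writes everything the pipeline reads: `peptides.tsv`, `samples.tsv`,
#' `ranks.tsv`, `proteome.fasta`, `spectra.mgf` (native/labeled pairs for
#' a sample of peptides), `timeseries.tsv` and `truth.json`.
#'
#' @param plan `SimulationPlan`.
#' @param out_dir output directory (created).
#' @param n_proteins proteome size.
#' @param n_spectrum_pairs native/labeled pairs to write.
#' @param ts_peptides,ts_clusters time-series dimensions.
#' @return invisibly, the in-memory bundle (proteome, samples, ranks,
#'   spectra, timeseries).
#' @export
simulate_bundle <- function(plan = simulation_plan(), out_dir,
                            n_proteins = 50L, n_spectrum_pairs = 20L,
                            ts_peptides = 300L, ts_clusters = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- generate_proteome(n_proteins, seed = plan$seed)
  samples <- generate_samples(plan, prot)
  ranks <- generate_rank_table(samples, seed = plan$seed + 1L)
  write_fasta(prot, file.path(out_dir, "proteome.fasta"))
  write_peptide_table(samples$records, file.path(out_dir, "peptides.tsv"))
  utils::write.table(samples$metas, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ranks, file.path(out_dir, "ranks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cls1 <- unique(samples$truth$sequence[samples$truth$hla_class == "I"])
  set.seed(plan$seed + 2L)
  pep_sel <- sample(cls1, min(n_spectrum_pairs, length(cls1)))
  spectra <- list()
  for (i in seq_along(pep_sel)) {
    pr <- generate_spectrum_pair(pep_sel[i], seed = plan$seed + 10L + i)
    spectra[[2L * i - 1L]] <- pr$native
    spectra[[2L * i]] <- pr$labeled
  }
  write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
  ts <- generate_timeseries(ts_peptides, n_clusters = ts_clusters,
                            seed = plan$seed + 3L)
  ts_tab <- data.frame(peptide = rownames(ts$areas), ts$areas,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ts_tab, file.path(out_dir, "timeseries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(truth = samples$truth, timeseries_clusters = ts$truth,
         spectrum_peptides = pep_sel),
    file.path(out_dir, "truth.json"))
  invisible(list(proteome = prot, samples = samples, ranks = ranks,
                 spectra = spectra, timeseries = ts))
}
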
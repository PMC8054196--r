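#' Run the full post-identification pipeline on an input bundle
#'
#' Orchestrates the analysis stages in order — binder annotation,
#' replicate QC, global FDR, sample similarity, source-protein coverage,
#' tissue yields and tumor-reference subtraction — over a directory laid
#' out like [simulate_bundle()] output (`peptides.tsv`, `samples.tsv`,
#' `ranks.tsv`, `proteome.fasta`). Spectrum validation and time-series
#' clustering are independent stages with their own entry points. Every
#' record entering a stage is either in its output or in its exclusion
#' log; re-running on identical inputs reproduces identical outputs.
#'
#' @param in_dir bundle directory.
#' @param out_dir optional directory for TSV/JSON reports.
#' @param config `ligandkit_config`.
#' @return list of stage results: `annotated`, `qc_report`, `qc`,
#'   `fdr` (per class), `jaccard`, `contrasts`, `dendrogram`, `profiles`,
#'   `bins`, `hotspots`, `yields` (per class), `report` (per-stage counts).
#' @export
run_pipeline <- function(in_dir, out_dir = NULL,
                         config = default_config()) {
  records <- read_peptide_table(file.path(in_dir, "peptides.tsv"))
  metas <- utils::read.delim(file.path(in_dir, "samples.tsv"),
                             stringsAsFactors = FALSE)
  ranks <- utils::read.delim(file.path(in_dir, "ranks.tsv"),
                             stringsAsFactors = FALSE)
  prot <- read_fasta(file.path(in_dir, "proteome.fasta"))
  report <- list()
  note <- function(stage, n_in, n_out, extra = list()) {
    report[[stage]] <<- c(list(stage = stage, n_in = n_in, n_out = n_out),
                          extra)
  }

  annotated <- annotate_dataset(records, metas, ranks,
                                thresholds = config$binder_thresholds)
  note("annotate", nrow(records), nrow(annotated))

  qc_report <- qc_dataset(annotated, qc = config$qc)
  qc <- apply_qc(annotated, qc_report)
  note("qc", nrow(annotated), nrow(qc$records),
       list(n_excluded = nrow(annotated) - nrow(qc$records)))

  fdr <- lapply(c(I = "I", II = "II"), function(cls) {
    sub <- qc$records[qc$records$hla_class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    global_fdr_report(sub, local_fdr = config$local_fdr)
  })
  note("fdr", nrow(qc$records), nrow(qc$records))

  similarity <- lapply(c(I = "I", II = "II"), function(cls) {
    sub <- qc$records[qc$records$hla_class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sets <- build_sample_sets(sub, level = config$similarity_level)
    jmat <- jaccard_matrix(sets)
    list(jaccard = jmat, dendrogram = cluster_samples(jmat),
         contrasts = group_contrasts(jmat))
  })
  note("similarity", nrow(qc$records),
       sum(vapply(similarity, function(s) {
         if (is.null(s)) 0L else nrow(s$jaccard)
       }, integer(1))))

  profiles <- coverage_profiles(qc$records, prot)
  bins <- bin_proteins(profiles)
  hotspots <- do.call(rbind, lapply(profiles, call_hotspots,
                                    min_cov = config$hotspot$min_cov,
                                    max_gap = config$hotspot$max_gap,
                                    min_len = config$hotspot$min_len))
  note("coverage", nrow(qc$records), length(profiles))

  yields <- lapply(c(I = "I", II = "II"), function(cls) {
    sub <- qc$records[qc$records$hla_class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    yield_table(sub)
  })
  note("yield", nrow(qc$records), nrow(qc$records))

  out <- list(annotated = annotated, qc_report = qc_report, qc = qc,
              fdr = fdr, similarity = similarity, profiles = profiles,
              bins = bins, hotspots = hotspots, yields = yields,
              report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(res$qc_report, "qc_report.tsv")
  wt(res$qc$exclusions, "exclusions.tsv")
  jsonlite::write_json(
    lapply(res$fdr, function(f) if (is.null(f)) NULL else
      f[c("n_total_unique", "local_fdr", "global_fdr")]),
    file.path(out_dir, "fdr_report.json"), auto_unbox = TRUE)
  for (cls in names(res$similarity)) {
    s <- res$similarity[[cls]]
    if (is.null(s)) next
    jm <- as.data.frame(s$jaccard)
    jm <- cbind(sample = rownames(jm), jm)
    wt(jm, sprintf("jaccard_%s.tsv", cls))
    writeLines(dendrogram_newick(s$dendrogram),
               file.path(out_dir, sprintf("dendrogram_%s.nwk", cls)))
    wt(s$contrasts$values, sprintf("contrasts_%s.tsv", cls))
  }
  wt(res$bins, "bins.tsv")
  if (!is.null(res$hotspots) && nrow(res$hotspots)) {
    wt(res$hotspots, "hotspots.tsv")
  }
  invisible(out_dir)
}
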
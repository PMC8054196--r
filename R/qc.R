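#' Modal peptide length(s)
#'
#' All lengths attaining the maximum count; ties return every tied length.
#' @param lengths integer vector (multiset) of peptide lengths.
#' @return sorted integer vector of modal lengths.
#' @export
length_mode <- function(lengths) {
  if (length(lengths) == 0L) stop("length_mode: empty length multiset")
  counts <- table(lengths)
  sort(as.integer(names(counts)[counts == max(counts)]))
}

#' Quality-control one technical replicate
#'
#' A class-I replicate passes when its fraction of predicted binders is at
#' least 50% and 9 is among the modes of its length distribution; a class-II
#' replicate passes when the binder fraction is at least 10% and at least
#' one modal length falls in the interval `[12, 18]`. "Lower than" the
#' fraction cutoff is strict, so a replicate exactly at the cutoff passes.
#' With tied modes the replicate passes if ANY modal length satisfies the
#' criterion. Binders are peptides whose harmonized category is strong or
#' weak; the denominator is the number of unique peptide identifications in
#' the replicate.
#'
#' @param records peptide records of one replicate (single `hla_class`),
#'   carrying a `category` column (from [annotate_dataset()]).
#' @param qc QC block of [default_config()].
#' @return one-row data.frame: sample key, `replicate_id`, `n_peptides`,
#'   `binder_fraction`, `length_modes` (comma-joined), `pass`,
#'   `fail_reasons`.
#' @export
qc_replicate <- function(records, qc = default_config()$qc) {
  if (nrow(records) == 0L) {
    return(data.frame(subject_id = NA, tissue = NA, hla_class = NA,
                      replicate_id = NA, n_peptides = 0L,
                      binder_fraction = NA_real_, length_modes = "",
                      pass = FALSE, fail_reasons = "empty",
                      stringsAsFactors = FALSE))
  }
  cls <- unique(records$hla_class)
  stopifnot(length(cls) == 1L)
  uniq <- records[!duplicated(records$sequence), , drop = FALSE]
  n <- nrow(uniq)
  binder_fraction <- mean(uniq$category %in% c("strong", "weak"))
  modes <- length_mode(nchar(uniq$sequence))
  mode_ok <- if (cls == "I") {
    qc$length_mode$I %in% modes
  } else {
    any(modes >= qc$length_mode$II[1] & modes <= qc$length_mode$II[2])
  }
  frac_ok <- binder_fraction >= qc$min_binder_fraction[[cls]]
  reasons <- c(if (!frac_ok) "binder_fraction", if (!mode_ok) "length_mode")
  data.frame(subject_id = records$subject_id[1], tissue = records$tissue[1],
             hla_class = cls, replicate_id = records$replicate_id[1],
             n_peptides = n, binder_fraction = binder_fraction,
             length_modes = paste(modes, collapse = ","),
             pass = frac_ok && mode_ok,
             fail_reasons = paste(reasons, collapse = ","),
             stringsAsFactors = FALSE)
}

#' QC every replicate of a dataset
#' @param records annotated peptide records (with `category`).
#' @param qc QC parameter block.
#' @return data.frame, one row per replicate.
#' @export
qc_dataset <- function(records, qc = default_config()$qc) {
  key <- paste(records$subject_id, records$tissue, records$hla_class,
               records$replicate_id, sep = "\r")
  do.call(rbind, lapply(split(records, key), qc_replicate, qc = qc))
}

#' Remove records of failing replicates
#'
#' @param records annotated peptide records.
#' @param qc_report output of [qc_dataset()].
#' @return list with `records` (retained) and `exclusions` (data.frame of
#'   excluded replicates with reasons and record counts); every input
#'   record is accounted for in exactly one of the two.
#' @export
apply_qc <- function(records, qc_report) {
  fail <- qc_report[!qc_report$pass, , drop = FALSE]
  key <- paste(records$subject_id, records$tissue, records$hla_class,
               records$replicate_id)
  fail_key <- paste(fail$subject_id, fail$tissue, fail$hla_class,
                    fail$replicate_id)
  drop <- key %in% fail_key
  excl <- fail[, c("subject_id", "tissue", "hla_class", "replicate_id",
                   "fail_reasons"), drop = FALSE]
  excl$n_records <- as.integer(table(factor(key[drop],
                                            levels = fail_key))[fail_key])
  list(records = records[!drop, , drop = FALSE], exclusions = excl)
}

#' Global peptide-level FDR across samples
#'
#' Each sample is filtered upstream at a local peptide-level FDR (default
#' 1%), so its expected number of false identifications is
#' `local_fdr * n_sample`. Pooling samples keeps every false positive but
#' collapses redundant true identifications, so the dataset-level FDR is
#' the sum of the per-sample expectations divided by the number of unique
#' peptides in the entire dataset:
#' `global_fdr = local_fdr * sum(counts) / total`. It equals `local_fdr`
#' when every peptide is unique to one sample and grows with inter-sample
#' redundancy.
#'
#' @param counts per-sample unique peptide counts (after merging each
#'   sample's passing technical replicates).
#' @param total number of unique peptide sequences in the pooled dataset.
#' @param local_fdr per-sample local FDR level.
#' @return global FDR fraction.
#' @export
global_fdr <- function(counts, total, local_fdr = 0.01) {
  if (total == 0) stop("global_fdr: dataset total is zero")
  stopifnot(all(counts > 0), total >= max(counts))
  local_fdr * sum(counts) / total
}

#' Global FDR report for one HLA class
#'
#' Computes per-sample unique peptide counts (a sample = subject x tissue,
#' pooling its technical replicates) and the class-wide unique total, then
#' applies [global_fdr()]. The dataset total counts sequences unique within
#' the class.
#'
#' @param records QC-passed records of one HLA class.
#' @param local_fdr local FDR level.
#' @return list: `per_sample` (data.frame), `n_total_unique`, `local_fdr`,
#'   `global_fdr`.
#' @export
global_fdr_report <- function(records, local_fdr = 0.01) {
  stopifnot(length(unique(records$hla_class)) == 1L)
  key <- paste(records$subject_id, records$tissue, sep = "\r")
  per_sample <- vapply(split(records$sequence, key),
                       function(s) length(unique(s)), integer(1))
  total <- length(unique(records$sequence))
  list(per_sample = data.frame(sample = names(per_sample),
                               n_unique = unname(per_sample),
                               stringsAsFactors = FALSE),
       n_total_unique = total, local_fdr = local_fdr,
       global_fdr = global_fdr(unname(per_sample), total, local_fdr))
}
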
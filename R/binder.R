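#' SYFPEITHI matrix score as a fraction of the attainable maximum
#'
#' A SYFPEITHI matrix assigns an integer value to each amino acid at each
#' position for a given peptide length; residues absent from the published
#' matrix score 0. The normalized score divides the sum of position-specific
#' values over the tested peptide by the maximally attainable sum for that
#' length. A matrix with no table for the peptide's length yields `NA`
#' (scored as missing, not as 0), and the peptide can still be classified
#' through percentile ranks.
#'
#' @param peptide amino-acid string.
#' @param matrix a SYFPEITHI matrix object: list with `allotype` and
#'   `tables`, where `tables[[as.character(L)]]` is a 20 x L numeric matrix
#'   (rows named by residue) of position values.
#' @param clamp clamp the fraction into `[0, 1]` before returning (matrices
#'   with negative entries can push the raw fraction outside the unit
#'   interval; the weak-binder rule presumes a fraction scale). Default TRUE.
#' @return normalized score in `[0, 1]`, or `NA_real_` if no length table.
#' @export
syfpeithi_score <- function(peptide, matrix, clamp = TRUE) {
  L <- nchar(peptide)
  tab <- matrix$tables[[as.character(L)]]
  if (is.null(tab)) return(NA_real_)
  residues <- strsplit(peptide, "")[[1]]
  vals <- vapply(seq_len(L), function(p) {
    v <- tab[residues[p], p]
    if (is.na(v)) 0 else v
  }, numeric(1))
  max_attainable <- sum(apply(tab, 2, max, na.rm = TRUE))
  if (max_attainable <= 0) stop("SYFPEITHI matrix has non-positive maximum")
  s <- sum(vals) / max_attainable
  if (clamp) s <- min(max(s, 0), 1)
  s
}

#' Build a SYFPEITHI matrix object
#' @param allotype allotype name.
#' @param tables named list (by length) of 20 x L numeric matrices with
#'   residue rownames.
#' @export
syfpeithi_matrix <- function(allotype, tables) {
  for (tab in tables) {
    stopifnot(is.matrix(tab), !is.null(rownames(tab)))
  }
  names(tables) <- vapply(tables, ncol, integer(1))
  structure(list(allotype = allotype, tables = tables),
            class = "SyfpeithiMatrix")
}

#' Harmonized strong/weak/non-binder classification
#'
#' Categories follow the harmonized multi-predictor rule: a peptide is a
#' strong binder against an allotype if ANY tool calls it strong
#' (netMHCpan percentile rank <= 0.5; netMHCIIpan <= 1.0;
#' MixMHC2pred <= 1.0), otherwise a weak binder if ANY tool calls it weak
#' (netMHCpan <= 2.0; netMHCIIpan <= 5.0; MixMHC2pred <= 5.0; SYFPEITHI
#' normalized score >= 0.5, class I only), otherwise a non-binder.
#' A rank exactly at its threshold qualifies. Missing tool scores are
#' non-qualifying, not failures, so partial predictor coverage degrades
#' gracefully; all scores missing is an error. SYFPEITHI never produces a
#' strong call.
#'
#' @param ranks named numeric vector of percentile ranks, names among
#'   `netmhcpan`, `netmhciipan`, `mixmhc2pred`; NAs allowed.
#' @param s_syf SYFPEITHI normalized score in `[0, 1]` or NA (class I only).
#' @param hla_class `"I"` or `"II"`.
#' @param thresholds threshold block from [default_config()].
#' @return one of `"strong"`, `"weak"`, `"non"`.
#' @export
classify_binder <- function(ranks, s_syf = NA_real_, hla_class,
                            thresholds = default_config()$binder_thresholds) {
  stopifnot(hla_class %in% c("I", "II"))
  tools <- if (hla_class == "I") "netmhcpan" else
    c("netmhciipan", "mixmhc2pred")
  r <- ranks[tools]
  names(r) <- tools
  use_syf <- hla_class == "I"
  if (all(is.na(r)) && (!use_syf || is.na(s_syf))) {
    stop("classify_binder: all predictor scores missing")
  }
  strong <- !is.na(r) & r <= thresholds$strong[tools]
  if (any(strong)) return("strong")
  weak <- !is.na(r) & r <= thresholds$weak[tools]
  if (use_syf && !is.na(s_syf) && s_syf >= thresholds$syfpeithi_weak) {
    weak <- c(weak, TRUE)
  }
  if (any(weak)) "weak" else "non"
}

category_order <- c(strong = 3L, weak = 2L, non = 1L)

#' Annotate a sample's peptides against its HLA allotypes
#'
#' Classifies every peptide x allotype pair of a sample and returns (a) all
#' associations classified strong or weak — a single peptide may be a binder
#' against multiple allotypes of the same donor — and (b) the per-peptide
#' best category over the sample's alleles (strong > weak > non).
#'
#' @param records peptide records of one sample (any number of replicates).
#' @param alleles character vector of the subject's allotype names.
#' @param rank_table data.frame with columns `sequence`, `allotype`, `tool`,
#'   `rank` (percentile ranks).
#' @param matrices optional named list (by allotype) of SYFPEITHI matrices
#'   for class-I weak classification.
#' @param thresholds see [classify_binder()].
#' @return list with `associations` (data.frame sequence, allotype,
#'   category) and `best` (data.frame sequence, category).
#' @export
annotate_sample <- function(records, alleles, rank_table, matrices = NULL,
                            thresholds = default_config()$binder_thresholds) {
  seqs <- unique(records$sequence)
  if (length(seqs) == 0L) {
    empty <- data.frame(sequence = character(), allotype = character(),
                        category = character(), stringsAsFactors = FALSE)
    return(list(associations = empty,
                best = data.frame(sequence = character(),
                                  category = character(),
                                  stringsAsFactors = FALSE)))
  }
  hla_class <- unique(records$hla_class)
  stopifnot(length(hla_class) == 1L)
  covered <- alleles %in% unique(rank_table$allotype)
  if (any(!covered)) {
    warning(sprintf("allele(s) absent from rank table, skipped: %s",
                    paste(alleles[!covered], collapse = ", ")))
  }
  use_alleles <- alleles[covered]
  rt <- rank_table[rank_table$sequence %in% seqs &
                     rank_table$allotype %in% use_alleles, , drop = FALSE]
  assoc <- list()
  best <- stats::setNames(rep("non", length(seqs)), seqs)
  for (al in use_alleles) {
    rt_al <- rt[rt$allotype == al, , drop = FALSE]
    mat <- if (!is.null(matrices)) matrices[[al]] else NULL
    for (s in unique(rt_al$sequence)) {
      rows <- rt_al[rt_al$sequence == s, , drop = FALSE]
      ranks <- stats::setNames(rows$rank, rows$tool)
      s_syf <- if (!is.null(mat) && hla_class == "I") {
        syfpeithi_score(s, mat)
      } else NA_real_
      cat_i <- classify_binder(ranks, s_syf, hla_class, thresholds)
      if (cat_i != "non") {
        assoc[[length(assoc) + 1L]] <- data.frame(
          sequence = s, allotype = al, category = cat_i,
          stringsAsFactors = FALSE)
      }
      if (category_order[cat_i] > category_order[best[s]]) best[s] <- cat_i
    }
  }
  associations <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(sequence = character(), allotype = character(),
               category = character(), stringsAsFactors = FALSE)
  list(associations = associations,
       best = data.frame(sequence = seqs,
                         category = unname(best[seqs]),
                         stringsAsFactors = FALSE))
}

#' Annotate every sample of a dataset
#'
#' Convenience wrapper over [annotate_sample()] grouping the records by
#' subject x tissue x class and looking up each subject's alleles.
#'
#' @param records peptide records.
#' @param metas data.frame with columns `subject_id`, `hla_class`, `alleles`
#'   (semicolon-joined allotype names).
#' @inheritParams annotate_sample
#' @return data.frame of records with an added `category` column, plus the
#'   pooled associations table as attribute `"associations"`.
#' @export
annotate_dataset <- function(records, metas, rank_table, matrices = NULL,
                             thresholds =
                               default_config()$binder_thresholds) {
  records$category <- NA_character_
  assoc_all <- list()
  key <- paste(records$subject_id, records$tissue, records$hla_class)
  for (k in unique(key)) {
    idx <- key == k
    sub <- records[idx, , drop = FALSE]
    m <- metas[metas$subject_id == sub$subject_id[1] &
                 metas$hla_class == sub$hla_class[1], , drop = FALSE]
    alleles <- unique(unlist(strsplit(m$alleles, ";")))
    ann <- annotate_sample(sub, alleles, rank_table, matrices, thresholds)
    lookup <- stats::setNames(ann$best$category, ann$best$sequence)
    records$category[idx] <- unname(lookup[sub$sequence])
    if (nrow(ann$associations)) {
      a <- ann$associations
      a$subject_id <- sub$subject_id[1]
      a$tissue <- sub$tissue[1]
      a$hla_class <- sub$hla_class[1]
      assoc_all[[length(assoc_all) + 1L]] <- a
    }
  }
  attr(records, "associations") <- if (length(assoc_all)) {
    do.call(rbind, assoc_all)
  } else NULL
  records
}
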
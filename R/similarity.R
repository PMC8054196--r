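#' Jaccard similarity of two sets
#'
#' `j = |A intersect B| / |A union B|`; duplicated elements are collapsed.
#' @param a,b character vectors (treated as sets).
#' @return fraction in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("jaccard: both sets are empty")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Build per-sample sets for similarity analysis
#'
#' A sample is one subject x tissue x HLA-class combination, pooling its
#' technical replicates. Sets hold either deduplicated peptide sequences or
#' deduplicated source-protein accessions. Unless allele matching is
#' requested downstream, all peptides — including non-binders — enter the
#' sets.
#'
#' @param records peptide records.
#' @param level `"peptide"` or `"protein"`.
#' @return named list of character vectors; names are
#'   `subject|tissue|class` keys; attribute `"meta"` holds the parsed keys.
#' @export
build_sample_sets <- function(records, level = c("peptide", "protein")) {
  level <- match.arg(level)
  key <- paste(records$subject_id, records$tissue, records$hla_class,
               sep = "|")
  sets <- lapply(split(records, key), function(r) {
    if (level == "peptide") unique(r$sequence) else
      unique(unlist(split_protein_ids(r$protein_ids)))
  })
  meta <- do.call(rbind, strsplit(names(sets), "|", fixed = TRUE))
  attr(sets, "meta") <- data.frame(key = names(sets),
                                   subject_id = meta[, 1],
                                   tissue = meta[, 2],
                                   hla_class = meta[, 3],
                                   stringsAsFactors = FALSE)
  sets
}

#' Pairwise Jaccard similarity matrix between samples
#'
#' Symmetric matrix of Jaccard indices over all sample pairs. With
#' `allele_matched = TRUE`, each pairwise comparison is restricted to the
#' peptides classified as binders (strong or weak) against at least one
#' allotype shared by the two subjects; at protein level, to the source
#' proteins of such peptides. Pairs of subjects sharing no allele get `NA`
#' (logged as a warning). Empty sets are excluded with a warning.
#'
#' @param sets named list from [build_sample_sets()].
#' @param allele_matched restrict to shared-allotype binders.
#' @param associations binder associations table (sequence, allotype,
#'   subject_id) required when `allele_matched`.
#' @param subject_alleles named list subject_id -> allotype vector,
#'   required when `allele_matched`.
#' @param records original records (needed at protein level to map
#'   peptides to proteins when `allele_matched`).
#' @param level set level used to build `sets`.
#' @return symmetric numeric matrix with sample keys as dimnames.
#' @export
jaccard_matrix <- function(sets, allele_matched = FALSE,
                           associations = NULL, subject_alleles = NULL,
                           records = NULL,
                           level = c("peptide", "protein")) {
  level <- match.arg(level)
  keep <- vapply(sets, length, integer(1)) > 0L
  if (any(!keep)) {
    warning(sprintf("excluding empty sample set(s): %s",
                    paste(names(sets)[!keep], collapse = ", ")))
  }
  meta <- attr(sets, "meta")
  sets <- sets[keep]
  meta <- meta[match(names(sets), meta$key), , drop = FALSE]
  n <- length(sets)
  if (n < 2L) stop("jaccard_matrix: need at least 2 non-empty samples")
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  if (allele_matched) {
    stopifnot(!is.null(associations), !is.null(subject_alleles))
  }
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      if (!allele_matched) {
        v <- jaccard(sets[[i]], sets[[k]])
      } else {
        shared <- intersect(subject_alleles[[meta$subject_id[i]]],
                            subject_alleles[[meta$subject_id[k]]])
        if (length(shared) == 0L) {
          warning(sprintf("no shared allele between %s and %s; NA",
                          names(sets)[i], names(sets)[k]))
          v <- NA_real_
        } else {
          ok_seq <- unique(
            associations$sequence[associations$allotype %in% shared])
          a <- restrict_set(sets[[i]], ok_seq, level, records)
          b <- restrict_set(sets[[k]], ok_seq, level, records)
          v <- if (length(a) == 0L && length(b) == 0L) NA_real_ else
            jaccard(a, b)
        }
      }
      m[i, k] <- m[k, i] <- v
    }
  }
  attr(m, "meta") <- meta
  m
}

restrict_set <- function(set, ok_seq, level, records) {
  if (level == "peptide") return(intersect(set, ok_seq))
  stopifnot(!is.null(records))
  keep <- records$sequence %in% ok_seq
  ok_prot <- unique(unlist(split_protein_ids(records$protein_ids[keep])))
  intersect(set, ok_prot)
}

#' Hierarchical clustering of samples from a Jaccard matrix
#'
#' Agglomerative clustering on the distance `d = 1 - j`. NA similarities
#' are imputed as 0 (maximal distance) with a warning. Average linkage
#' (UPGMA) by default: the matrix is a similarity, not a geometric
#' embedding, so a linkage needing no coordinates is used.
#'
#' @param jmat matrix from [jaccard_matrix()].
#' @param method linkage passed to [stats::hclust()].
#' @return `hclust` object; convert with [dendrogram_newick()].
#' @export
cluster_samples <- function(jmat, method = "average") {
  if (nrow(jmat) < 2L) stop("cluster_samples: need >= 2 samples")
  if (anyNA(jmat)) {
    warning("NA similarities imputed as 0 for clustering")
    jmat[is.na(jmat)] <- 0
  }
  stats::hclust(stats::as.dist(1 - jmat), method = method)
}

#' Export a dendrogram as Newick text
#' @param hc `hclust` object.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Subject/tissue group contrasts of pairwise similarities
#'
#' Assigns every off-diagonal sample pair to exactly one of three
#' categories — same subject / different tissue, different subject / same
#' tissue, different subject / different tissue — and summarises the
#' Jaccard values per category. Pairs of the same subject AND tissue
#' (e.g. the two HLA classes of one sample) are excluded; contrast
#' matrices are normally built per HLA class so such pairs do not arise.
#'
#' @param jmat matrix from [jaccard_matrix()] (carries sample meta).
#' @return list: `values` (data.frame pair, category, j), `medians` (named
#'   numeric), `subject_over_tissue` (logical: is the same-subject median
#'   greater than the same-tissue median).
#' @export
group_contrasts <- function(jmat) {
  meta <- attr(jmat, "meta")
  stopifnot(!is.null(meta))
  n <- nrow(jmat)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      same_subj <- meta$subject_id[i] == meta$subject_id[k]
      same_tis <- meta$tissue[i] == meta$tissue[k]
      if (same_subj && same_tis) next
      cat_ik <- if (same_subj) "same-subject" else
        if (same_tis) "same-tissue" else "different"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_a = rownames(jmat)[i], sample_b = rownames(jmat)[k],
        category = cat_ik, j = jmat[i, k], stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, rows)
  medians <- vapply(split(values$j, values$category), stats::median,
                    numeric(1), na.rm = TRUE)
  list(values = values, medians = medians,
       subject_over_tissue =
         isTRUE(medians["same-subject"] > medians["same-tissue"]))
}
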
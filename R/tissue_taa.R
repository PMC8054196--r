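#' Per-sample peptide yields and per-tissue medians
#'
#' Yield is the number of unique peptides identified per sample (subject x
#' tissue, one HLA class); the tissue-level summary is the median over the
#' contributing subjects.
#'
#' @param records peptide records of one HLA class.
#' @return list: `per_sample` (subject_id, tissue, yield) and `per_tissue`
#'   (tissue, median_yield, n_samples).
#' @export
yield_table <- function(records) {
  stopifnot(length(unique(records$hla_class)) <= 1L)
  key <- paste(records$subject_id, records$tissue, sep = "\r")
  per_sample <- do.call(rbind, lapply(split(records, key), function(r) {
    data.frame(subject_id = r$subject_id[1], tissue = r$tissue[1],
               yield = length(unique(r$sequence)), stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  per_tissue <- do.call(rbind, lapply(split(per_sample, per_sample$tissue),
                                      function(t) {
    data.frame(tissue = t$tissue[1],
               median_yield = stats::median(t$yield),
               n_samples = nrow(t), stringsAsFactors = FALSE)
  }))
  rownames(per_tissue) <- NULL
  list(per_sample = per_sample, per_tissue = per_tissue)
}

#' OLS model of log10 tissue yields on log10 gene expression
#'
#' Ordinary least squares of `log10(median yield)` on `log10(RPKM)` for a
#' single gene at a time: antigen-presentation genes are highly covariant,
#' so a multi-gene regression would overfit. Reports R-squared, the F-test
#' p value and Spearman's rho on the same tissue pairs. Tissues with zero
#' or negative yield or expression are dropped (not pseudo-counted) and
#' listed in `dropped`.
#'
#' @param yields named numeric vector: tissue -> median peptide yield.
#' @param expression named numeric vector: tissue -> RPKM for one gene.
#' @param gene gene symbol for the report.
#' @return data.frame row: gene, n, slope, intercept, r_squared, f_pvalue,
#'   spearman_rho; attribute `"dropped"` lists excluded tissues.
#' @export
fit_yield_model <- function(yields, expression, gene = NA_character_) {
  tissues <- intersect(names(yields), names(expression))
  y <- yields[tissues]; x <- expression[tissues]
  ok <- !is.na(y) & !is.na(x) & y > 0 & x > 0
  dropped <- tissues[!ok]
  y <- log10(y[ok]); x <- log10(x[ok])
  if (length(y) < 3L) {
    stop(sprintf("fit_yield_model: need >= 3 usable tissues, have %d",
                 length(y)))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  f <- sm$fstatistic
  out <- data.frame(
    gene = gene, n = length(y),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    f_pvalue = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
    spearman_rho = stats::cor(x, y, method = "spearman"),
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Tissue-exclusive source proteins
#'
#' A source protein is exclusive to tissue `t` (within one HLA class) iff
#' every sample of that class containing it originates from `t`, across
#' all subjects.
#'
#' @param records peptide records of one HLA class.
#' @return named list tissue -> character vector of exclusive accessions.
#' @export
tissue_exclusive_proteins <- function(records) {
  if (nrow(records) == 0L) return(list())
  pep2prot <- split_protein_ids(records$protein_ids)
  long <- data.frame(tissue = rep(records$tissue, lengths(pep2prot)),
                     accession = unlist(pep2prot), stringsAsFactors = FALSE)
  tab <- unique(long)
  n_tissues <- vapply(split(tab$tissue, tab$accession),
                      function(t) length(unique(t)), integer(1))
  excl <- names(n_tissues)[n_tissues == 1L]
  tab <- tab[tab$accession %in% excl, , drop = FALSE]
  split(tab$accession, tab$tissue)
}

#' Fisher-exact over-representation of a query set against gene sets
#'
#' One-sided Fisher's exact test from the hypergeometric upper tail: with
#' `k` overlap between a query of size `m` and a gene set of size `n` in a
#' universe of size `N`, `p = P(X >= k)` for
#' `X ~ Hypergeom(N, n, m)`. Gene sets and the query are intersected with
#' the universe first. Results are sorted by raw p value (ranking follows
#' raw p); a Benjamini-Hochberg column is emitted for reference but not
#' used for ranking.
#'
#' @param query character vector of accessions/genes.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe background accessions; must contain the query.
#' @param top_k report only the `top_k` smallest p values (NULL = all).
#' @return data.frame: gene_set, k, m, n, N, fisher_p, odds_ratio, p_bh.
#' @export
fisher_enrichment <- function(query, gene_sets, universe, top_k = NULL) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("fisher_enrichment: empty universe")
  query <- unique(intersect(query, universe))
  if (length(setdiff(query, universe))) {
    stop("query must be contained in the universe")
  }
  N <- length(universe); m <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], universe))
    n <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1L, n, N - n, m, lower.tail = FALSE)
    or <- (k * (N - n - m + k)) / max((m - k) * (n - k), .Machine$double.eps)
    data.frame(gene_set = nm, k = k, m = m, n = n, N = N, fisher_p = p,
               odds_ratio = or, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$fisher_p, method = "BH")
  out <- out[order(out$fisher_p, out$gene_set), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Tumor-versus-benign target prioritization by set subtraction
#'
#' Tumor-exclusive ligands (candidate tumor-associated antigens) are the
#' class-matched tumor peptides absent from the union of all benign
#' samples; the patient frequency of each exclusive peptide is the number
#' of tumor patients presenting it. Exclusive and shared peptides
#' partition the tumor set exactly.
#'
#' @param tumor_sets named list: tumor patient -> peptide set (one class).
#' @param benign_sets list of benign peptide sets (same class).
#' @return list: `exclusive` (data.frame sequence, patient_frequency,
#'   sorted by decreasing frequency — the waterfall order), `shared`
#'   (character vector), `n_tumor_total`, `n_benign_union`.
#' @export
taa_subtract <- function(tumor_sets, benign_sets) {
  tumor_sets <- lapply(tumor_sets, unique)
  benign_union <- unique(unlist(benign_sets))
  tumor_union <- unique(unlist(tumor_sets))
  exclusive <- setdiff(tumor_union, benign_union)
  freq <- vapply(exclusive, function(p) {
    sum(vapply(tumor_sets, function(s) p %in% s, logical(1)))
  }, integer(1))
  ord <- order(-freq, exclusive)
  list(exclusive = data.frame(sequence = exclusive[ord],
                              patient_frequency = unname(freq[ord]),
                              stringsAsFactors = FALSE),
       shared = intersect(tumor_union, benign_union),
       n_tumor_total = length(tumor_union),
       n_benign_union = length(benign_union))
}

#' Cross-reference source proteins against a cancer-testis antigen list
#'
#' A CTA counts as presented in a dataset (per HLA class) only if at least
#' two distinct peptide sequences map to it; singly-evidenced proteins are
#' excluded. Proteins not on the CTA list are ignored.
#'
#' @param records peptide records (any classes).
#' @param cta_list character vector of CTA protein accessions.
#' @return data.frame: accession, hla_class, n_ligands, n_samples —
#'   only CTAs with `n_ligands >= 2` in that class.
#' @export
cta_crossref <- function(records, cta_list) {
  pep2prot <- split_protein_ids(records$protein_ids)
  long <- data.frame(
    sequence = rep(records$sequence, lengths(pep2prot)),
    hla_class = rep(records$hla_class, lengths(pep2prot)),
    sample = rep(paste(records$subject_id, records$tissue),
                 lengths(pep2prot)),
    accession = unlist(pep2prot), stringsAsFactors = FALSE)
  long <- long[long$accession %in% cta_list, , drop = FALSE]
  if (nrow(long) == 0L) {
    return(data.frame(accession = character(), hla_class = character(),
                      n_ligands = integer(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(long$accession, long$hla_class, sep = "\r")
  rows <- lapply(split(long, key), function(g) {
    data.frame(accession = g$accession[1], hla_class = g$hla_class[1],
               n_ligands = length(unique(g$sequence)),
               n_samples = length(unique(g$sample)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_ligands >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$accession, out$hla_class), , drop = FALSE]
}
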
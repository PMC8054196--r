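#' Exact occurrences of peptides in a protein sequence
#'
#' Every exact substring occurrence is reported, overlapping matches
#' included. Coordinates are 1-based inclusive residue positions.
#'
#' @param peptides character vector of peptide sequences.
#' @param protein_seq single protein sequence.
#' @return data.frame with columns `peptide`, `start`, `end` (possibly
#'   zero rows).
#' @export
map_peptides_to_protein <- function(peptides, protein_seq) {
  subject <- Biostrings::AAString(protein_seq)
  out <- lapply(unique(peptides), function(p) {
    hits <- Biostrings::matchPattern(p, subject)
    if (length(hits) == 0L) return(NULL)
    data.frame(peptide = p, start = Biostrings::start(hits),
               end = Biostrings::end(hits), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Position-wise ligand coverage profile of one protein
#'
#' Stacks ligand intervals per residue: `counts[p]` is the number of
#' intervals containing position `p`, computed separately for HLA-I and
#' HLA-II ligands. The coverage fraction of a class is the share of
#' positions with at least one ligand of that class; the overall coverage
#' counts positions covered by either class.
#'
#' @param matches_I,matches_II data.frames of `(start, end)` intervals
#'   (1-based inclusive) from [map_peptides_to_protein()].
#' @param L protein length in residues.
#' @param accession protein accession for the profile.
#' @return object of class `CoverageProfile`: list with `accession`, `L`,
#'   `countsI`, `countsII`, and `coverage` (named fractions I, II, any).
#' @export
coverage_profile <- function(matches_I, matches_II, L,
                             accession = NA_character_) {
  stack <- function(m) {
    counts <- integer(L)
    if (!is.null(m) && nrow(m)) {
      stopifnot(all(m$start >= 1L), all(m$end <= L), all(m$start <= m$end))
      # difference-array interval stabbing
      d <- integer(L + 1L)
      for (i in seq_len(nrow(m))) {
        d[m$start[i]] <- d[m$start[i]] + 1L
        d[m$end[i] + 1L] <- d[m$end[i] + 1L] - 1L
      }
      counts <- cumsum(d[seq_len(L)])
    }
    counts
  }
  cI <- stack(matches_I)
  cII <- stack(matches_II)
  structure(list(accession = accession, L = L, countsI = cI, countsII = cII,
                 coverage = c(I = mean(cI > 0), II = mean(cII > 0),
                              any = mean(cI + cII > 0))),
            class = "CoverageProfile")
}

#' Coverage profiles for all source proteins of a dataset
#'
#' Maps every identified peptide to every listed source protein (no protein
#' inference: a peptide contributes to each of its annotated proteins) and
#' stacks the per-class intervals.
#'
#' @param records peptide records with `protein_ids`.
#' @param prot Proteome covering the listed accessions.
#' @return named list of `CoverageProfile`, one per protein with at least
#'   one mapped ligand.
#' @export
coverage_profiles <- function(records, prot) {
  pep2prot <- split_protein_ids(records$protein_ids)
  long <- data.frame(
    sequence = rep(records$sequence, lengths(pep2prot)),
    hla_class = rep(records$hla_class, lengths(pep2prot)),
    accession = unlist(pep2prot), stringsAsFactors = FALSE)
  long <- long[!duplicated(long[, c("sequence", "hla_class", "accession")]), ]
  out <- list()
  for (acc in unique(long$accession)) {
    seq_acc <- prot$sequences[[acc]]
    if (is.null(seq_acc)) next
    sub <- long[long$accession == acc, , drop = FALSE]
    mI <- map_peptides_to_protein(sub$sequence[sub$hla_class == "I"], seq_acc)
    mII <- map_peptides_to_protein(sub$sequence[sub$hla_class == "II"],
                                   seq_acc)
    prof <- coverage_profile(mI, mII, nchar(seq_acc), acc)
    if (prof$coverage["any"] > 0) out[[acc]] <- prof
  }
  out
}

#' Four-group binning of covered source proteins
#'
#' Covered proteins are binned into: (1) exclusively covered by HLA-I
#' ligands, (2) exclusively by HLA-II ligands, (3) covered by both with
#' higher position-wise coverage by HLA-I, (4) covered by both with higher
#' coverage by HLA-II. Equal nonzero coverage of both classes is assigned
#' to the I-higher group (documented tie rule, flagged in the output).
#' Proteins with zero coverage are not source proteins and are excluded.
#'
#' @param profiles list of `CoverageProfile`.
#' @return data.frame: accession, coverage_I, coverage_II, group, tie.
#' @export
bin_proteins <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    cvI <- p$coverage[["I"]]; cvII <- p$coverage[["II"]]
    if (cvI + cvII == 0) return(NULL)
    group <- if (cvII == 0) "I-only" else if (cvI == 0) "II-only" else
      if (cvI >= cvII) "both-I-higher" else "both-II-higher"
    data.frame(accession = p$accession, coverage_I = cvI,
               coverage_II = cvII, group = group,
               tie = cvI > 0 && cvII > 0 && cvI == cvII,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), coverage_I = numeric(),
               coverage_II = numeric(), group = character(),
               tie = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call coverage hotspots on a profile
#'
#' Hotspots are maximal runs of positions whose total stacked coverage
#' (HLA-I + HLA-II) reaches `min_cov`, merging runs separated by at most
#' `max_gap` uncovered positions and discarding merged runs shorter than
#' `min_len` residues. The parameters are configuration-exposed: a hotspot
#' has no canonical formal definition, so the operational one is stated
#' here.
#'
#' @param profile `CoverageProfile`.
#' @param min_cov minimum stacked coverage per position.
#' @param max_gap uncovered positions bridged between runs.
#' @param min_len minimum hotspot length (residues).
#' @return data.frame: accession, start, end, peak (max stacked coverage in
#'   the call), class (`"I"`, `"II"` or `"both"` by which classes cover
#'   positions inside the call).
#' @export
call_hotspots <- function(profile, min_cov = 1L, max_gap = 0L,
                          min_len = 8L) {
  total <- profile$countsI + profile$countsII
  ok <- total >= min_cov
  if (!any(ok)) {
    return(data.frame(accession = character(), start = integer(),
                      end = integer(), peak = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by <= max_gap positions below threshold
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= max_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_len, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) {
    return(data.frame(accession = character(), start = integer(),
                      end = integer(), peak = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  merged$accession <- profile$accession
  merged$peak <- vapply(seq_len(nrow(merged)), function(i) {
    max(total[merged$start[i]:merged$end[i]])
  }, numeric(1))
  merged$class <- vapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    hasI <- any(profile$countsI[idx] > 0)
    hasII <- any(profile$countsII[idx] > 0)
    if (hasI && hasII) "both" else if (hasI) "I" else "II"
  }, character(1))
  rownames(merged) <- NULL
  merged[, c("accession", "start", "end", "peak", "class")]
}

#' Proteome-wide residue coverage statistics
#'
#' Fraction of single residue positions in the whole proteome (covered or
#' not) that are covered by at least one HLA ligand; optionally the same
#' fraction restricted to the ligands of individual allotypes.
#'
#' @param profiles list of `CoverageProfile`.
#' @param prot Proteome (denominator includes proteins without ligands).
#' @return list: `overall` fraction, `covered_residues`, `total_residues`.
#' @export
proteome_coverage_stats <- function(profiles, prot) {
  total <- sum(nchar(prot$sequences))
  covered <- sum(vapply(profiles, function(p) {
    sum(p$countsI + p$countsII > 0)
  }, numeric(1)))
  list(overall = covered / total, covered_residues = covered,
       total_residues = total)
}
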
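AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

PEPTIDE_COLS <- c("sequence", "subject_id", "tissue", "hla_class",
                  "replicate_id", "protein_ids", "q_value", "rt_min",
                  "ms1_area")

#' Validate a peptide identification table
#'
#' Checks the invariants every identified-peptide record must satisfy:
#' residues restricted to the 20 proteinogenic amino acids, peptide length
#' 8-12 for HLA class I and 8-25 for HLA class II, and `q_value` in
#' `[0, 1]`. Errors carry the offending file line (header = line 1).
#'
#' @param records data.frame of peptide records.
#' @param line_offset added to the row index when reporting line numbers.
#' @return the validated data.frame, invisibly.
#' @keywords internal
validate_peptide_records <- function(records, line_offset = 1L) {
  if (nrow(records) == 0L) return(invisible(records))
  bad_class <- !records$hla_class %in% c("I", "II")
  if (any(bad_class)) {
    stop(sprintf("invalid hla_class %s at line %d (must be 'I' or 'II')",
                 records$hla_class[which(bad_class)[1]],
                 which(bad_class)[1] + line_offset))
  }
  bad_seq <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", records$sequence)
  if (any(bad_seq)) {
    stop(sprintf("invalid residue in sequence '%s' at line %d",
                 records$sequence[which(bad_seq)[1]],
                 which(bad_seq)[1] + line_offset))
  }
  len <- nchar(records$sequence)
  bad_len <- ifelse(records$hla_class == "I",
                    len < 8L | len > 12L, len < 8L | len > 25L)
  if (any(bad_len)) {
    i <- which(bad_len)[1]
    stop(sprintf(
      "peptide length %d outside the class %s range at line %d ('%s')",
      len[i], records$hla_class[i], i + line_offset, records$sequence[i]))
  }
  if (!is.null(records$q_value)) {
    qv <- records$q_value
    bad_q <- !is.na(qv) & (qv < 0 | qv > 1)
    if (any(bad_q)) {
      stop(sprintf("q_value %g outside [0,1] at line %d",
                   qv[which(bad_q)[1]], which(bad_q)[1] + line_offset))
    }
  }
  invisible(records)
}

#' Read a peptide identification table (TSV)
#'
#' One row per peptide x sample x replicate. Mandatory columns are
#' `sequence`, `subject_id`, `tissue`, `hla_class`, `replicate_id`,
#' `protein_ids` (semicolon-joined accessions), `q_value`; `rt_min` and
#' `ms1_area` are optional and may be empty. Extra columns are preserved
#' but ignored downstream. Methionine-oxidation (or any parenthesised
#' modification) annotations are stripped from the sequence on read, so
#' peptide identity everywhere downstream is the bare sequence string.
#'
#' @param path TSV file path.
#' @return data.frame of validated peptide records, row order preserved.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t",
                           quote = "", check.names = FALSE)
  mandatory <- setdiff(PEPTIDE_COLS, c("rt_min", "ms1_area"))
  missing <- setdiff(mandatory, names(tab))
  if (length(missing)) {
    stop(sprintf("peptide table '%s' is missing mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  if (is.null(tab$rt_min)) tab$rt_min <- NA_real_
  if (is.null(tab$ms1_area)) tab$ms1_area <- NA_real_
  if (nrow(tab) == 0L) {
    warning(sprintf("peptide table '%s' contains a header only", path))
    return(tab)
  }
  tab$sequence <- toupper(gsub("\\([^)]*\\)", "", tab$sequence))
  for (col in c("q_value", "rt_min", "ms1_area")) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  for (col in c("subject_id", "tissue", "hla_class", "replicate_id",
                "protein_ids")) {
    tab[[col]] <- as.character(tab[[col]])
  }
  validate_peptide_records(tab)
  tab
}

#' Write a peptide table to TSV
#' @param records data.frame of peptide records.
#' @param path output path.
#' @export
write_peptide_table <- function(records, path) {
  cols <- c(PEPTIDE_COLS, setdiff(names(records), PEPTIDE_COLS))
  cols <- intersect(cols, names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Split semicolon-joined protein accessions
#' @param protein_ids character vector of semicolon-joined accessions.
#' @return list of character vectors, one per record.
#' @export
split_protein_ids <- function(protein_ids) {
  strsplit(as.character(protein_ids), ";", fixed = TRUE)
}

#' Read a reference proteome from FASTA
#'
#' The accession is the first whitespace-delimited token after `>`.
#' Sequences are uppercased; duplicate accessions and empty sequences are
#' errors.
#'
#' @param path FASTA file.
#' @param name label for the proteome (defaults to the file name).
#' @return a `Proteome`: list with `sequences` (named character vector)
#'   and `name`.
#' @export
read_fasta <- function(path, name = basename(path)) {
  aas <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop(sprintf("duplicate accession '%s' in FASTA '%s'",
                 acc[duplicated(acc)][1], path))
  }
  seqs <- toupper(as.character(aas))
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("empty sequence for accession '%s' in FASTA '%s'",
                 acc[nchar(seqs) == 0L][1], path))
  }
  names(seqs) <- acc
  proteome(seqs, name = name)
}

#' Construct a Proteome object
#' @param sequences named character vector, accession -> amino-acid sequence.
#' @param name label.
#' @return object of class `Proteome`.
#' @export
proteome <- function(sequences, name = "proteome") {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)),
            all(nchar(sequences) > 0L))
  structure(list(sequences = toupper(sequences), name = name),
            class = "Proteome")
}

#' @export
print.Proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s': %d proteins, %d residues total\n",
              x$name, length(x$sequences), sum(nchar(x$sequences))))
  invisible(x)
}

#' Write a Proteome to FASTA
#' @param prot Proteome.
#' @param path output file.
#' @export
write_fasta <- function(prot, path) {
  aas <- Biostrings::AAStringSet(prot$sequences)
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Construct a fragment Spectrum object
#'
#' @param peptide assigned peptide sequence.
#' @param peaks two-column matrix (mz, intensity); re-sorted by m/z.
#' @param precursor_mz precursor m/z in Da.
#' @param precursor_charge integer charge.
#' @param label_shift mass shift (Da) of the isotope label, 0 for native.
#' @param label_position 1-based residue index carrying the label (NA if
#'   unlabeled).
#' @return object of class `Spectrum`.
#' @export
fragment_spectrum <- function(peptide, peaks, precursor_mz, precursor_charge = 2L,
                     label_shift = 0, label_position = NA_integer_) {
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  stopifnot(nrow(peaks) >= 1L, all(peaks[, "intensity"] >= 0))
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(peptide = toupper(peptide), peaks = peaks,
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 label_shift = label_shift,
                 label_position = label_position),
            class = "Spectrum")
}

#' Read fragment spectra from an MGF file
#'
#' Standard BEGIN IONS / END IONS blocks with PEPMASS, CHARGE and TITLE
#' lines. The TITLE carries the assigned peptide and label as
#' `peptide=<seq> label=<Da>@<pos>`. Unsorted peak blocks are sorted
#' silently; a block without PEPMASS or without END IONS is an error.
#'
#' @param path MGF file.
#' @return list of `Spectrum` objects in file order.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins))) {
    stop(sprintf("MGF '%s': block %d has no END IONS", path,
                 length(ends) + 1L))
  }
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[A-Z]+=", "", kv)
    if (!"PEPMASS" %in% keys) {
      stop(sprintf("MGF '%s': block %d is missing PEPMASS", path, i))
    }
    pepmass <- as.numeric(strsplit(vals[keys == "PEPMASS"][1], "\\s+")[[1]][1])
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1]))
    } else 2L
    title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else ""
    pep <- sub(".*peptide=([A-Za-z]+).*", "\\1", title)
    if (identical(pep, title)) pep <- NA_character_
    shift <- 0; pos <- NA_integer_
    lm <- regmatches(title, regexec("label=([0-9.+-]+)@([0-9]+)", title))[[1]]
    if (length(lm) == 3L) {
      shift <- as.numeric(lm[2]); pos <- as.integer(lm[3])
    }
    peak_lines <- block[!is_kv & nzchar(trimws(block))]
    pk <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"),
                                function(x) as.numeric(x[1:2])))
    out[[i]] <- fragment_spectrum(pep, pk, precursor_mz = pepmass,
                         precursor_charge = charge, label_shift = shift,
                         label_position = pos)
  }
  out
}

#' Write spectra to MGF
#' @param spectra list of `Spectrum` objects.
#' @param path output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    title <- sprintf("peptide=%s", sp$peptide)
    if (!is.na(sp$label_position) && sp$label_shift != 0) {
      title <- sprintf("%s label=%g@%d", title, sp$label_shift,
                       sp$label_position)
    }
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s", title),
                 sprintf("PEPMASS=%.6f", sp$precursor_mz),
                 sprintf("CHARGE=%d+", sp$precursor_charge),
                 sprintf("%.6f %.6f", sp$peaks[, "mz"],
                         sp$peaks[, "intensity"]),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated members.
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  writeLines(mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), descriptions, sets), path)
  invisible(path)
}

#' Read a gene x tissue expression table (RPKM)
#' @param path TSV with a `gene` column and one column per tissue.
#' @return data.frame with rownames = genes, columns = tissues.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(tab)) stop("expression table needs a 'gene' column")
  rownames(tab) <- tab$gene
  tab$gene <- NULL
  tab
}

#' Default run configuration
#'
#' Thresholds and parameters shared across the pipeline: harmonized binder
#' rank thresholds per tool, QC cutoffs, fragment match tolerance (Da),
#' hotspot parameters and the random seed. All user-facing knobs live here.
#'
#' @return named list (class `ligandkit_config`).
#' @export
default_config <- function() {
  structure(list(
    binder_thresholds = list(
      strong = c(netmhcpan = 0.5, netmhciipan = 1.0, mixmhc2pred = 1.0),
      weak = c(netmhcpan = 2.0, netmhciipan = 5.0, mixmhc2pred = 5.0),
      syfpeithi_weak = 0.5
    ),
    qc = list(min_binder_fraction = c(I = 0.5, II = 0.1),
              length_mode = list(I = 9L, II = c(12L, 18L))),
    local_fdr = 0.01,
    similarity_level = "peptide",
    fragment_tol_da = 0.02,
    hotspot = list(min_cov = 1L, max_gap = 0L, min_len = 8L),
    kmeans = list(k = 6L, n_init = 10L),
    seed = 1L
  ), class = "ligandkit_config")
}

#' Read a run configuration file (YAML or JSON)
#'
#' Keys present in the file override the defaults from [default_config()];
#' absent keys keep their default.
#' @param path config file.
#' @return `ligandkit_config` list.
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- unclass(default_config())
  merge_lists <- function(base, override) {
    for (k in names(override)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
        merge_lists(base[[k]], override[[k]])
      } else override[[k]]
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  stopifnot(cfg$local_fdr > 0, cfg$fragment_tol_da > 0)
  structure(cfg, class = "ligandkit_config")
}
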
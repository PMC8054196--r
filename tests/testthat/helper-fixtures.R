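# shared fixture builders; everything is generated in code at test time

make_records <- function(sequences, subject_id = "S01", tissue = "liver",
                         hla_class = "I", replicate_id = "R1",
                         protein_ids = "P1", category = NULL) {
  if (length(sequences) == 0L) {
    df <- data.frame(sequence = character(), subject_id = character(),
                     tissue = character(), hla_class = character(),
                     replicate_id = character(),
                     protein_ids = character(), q_value = numeric(),
                     rt_min = numeric(), ms1_area = numeric(),
                     stringsAsFactors = FALSE)
    if (!is.null(category)) df$category <- character()
    return(df)
  }
  df <- data.frame(sequence = sequences, subject_id = subject_id,
                   tissue = tissue, hla_class = hla_class,
                   replicate_id = replicate_id,
                   protein_ids = protein_ids, q_value = 0.005,
                   rt_min = NA_real_, ms1_area = NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(category)) df$category <- category
  df
}

# random class-I-like peptides (valid alphabet, length 8-12)
random_peptides <- function(n, len = 9L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 if (length(len) > 1L) sample(len, 1L) else len,
                 replace = TRUE), collapse = "")
  }, character(1))
}

# independent clause-by-clause binder evaluator (test oracle)
brute_force_classify <- function(ranks, s_syf, hla_class) {
  strong_clauses <- if (hla_class == "I") {
    list(c("netmhcpan", 0.5))
  } else {
    list(c("netmhciipan", 1.0), c("mixmhc2pred", 1.0))
  }
  weak_clauses <- if (hla_class == "I") {
    list(c("netmhcpan", 2.0))
  } else {
    list(c("netmhciipan", 5.0), c("mixmhc2pred", 5.0))
  }
  hit <- function(clauses) {
    any(vapply(clauses, function(cl) {
      r <- ranks[[cl[1]]]
      !is.null(r) && !is.na(r) && r <= as.numeric(cl[2])
    }, logical(1)))
  }
  if (hit(strong_clauses)) return("strong")
  syf_weak <- hla_class == "I" && !is.na(s_syf) && s_syf >= 0.5
  if (hit(weak_clauses) || syf_weak) return("weak")
  "non"
}

# exhaustive hypergeometric upper-tail sum (test oracle)
hyper_tail <- function(k, m, n, N) {
  i <- k:min(m, n)
  sum(choose(n, i) * choose(N - n, m - i)) / choose(N, m)
}

# hand-built encoded vector for spectral-angle algebra checks
make_encoded <- function(v, slots = paste0("s", seq_along(v))) {
  nrm <- sqrt(sum(v^2))
  structure(list(peptide = "TEST", slots = slots,
                 intensities = if (nrm > 0) v / nrm else v,
                 normalized = TRUE, all_zero = all(v == 0)),
            class = "EncodedSpectrum")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
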
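#' Monoisotopic residue masses (Da)
#'
#' Standard monoisotopic masses of the 20 proteinogenic amino-acid
#' residues; constants for the proton and water follow the same source.
#' @format named numeric vector.
#' @export
RESIDUE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
  C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
  H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
  M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

#' Theoretical singly-charged b/y fragment ions of a peptide
#'
#' For an n-residue peptide there are exactly `2(n-1)` fragment slots:
#' `b_i` (sum of the first i residue masses, protonated) and `y_i` (sum of
#' the last i residue masses plus water, protonated), i = 1..n-1, all at
#' charge 1. An isotope label of `label_shift` Da on residue
#' `label_position` shifts every ion whose residue span contains that
#' position. Higher fragment charges, neutral losses and a/c/x/z ions are
#' not modeled.
#'
#' @param peptide amino-acid string (length >= 2).
#' @param label_shift mass shift in Da (>= 0); 0 for the native peptide.
#' @param label_position 1-based residue index of the label (ignored when
#'   `label_shift == 0`).
#' @return data.frame (`FragmentSet`): type, index, mz, contains_label;
#'   slot order b1..b_{n-1}, y1..y_{n-1}.
#' @export
theoretical_fragments <- function(peptide, label_shift = 0,
                                  label_position = NA_integer_) {
  residues <- strsplit(toupper(peptide), "")[[1]]
  n <- length(residues)
  stopifnot(n >= 2L, all(residues %in% names(RESIDUE_MASS)),
            label_shift >= 0)
  if (label_shift > 0) {
    if (is.na(label_position) || label_position < 1L ||
        label_position > n) {
      stop("label_position outside the peptide")
    }
  }
  masses <- RESIDUE_MASS[residues]
  idx <- seq_len(n - 1L)
  b_mz <- cumsum(masses)[idx] + PROTON_MASS
  y_mz <- cumsum(rev(masses))[idx] + WATER_MASS + PROTON_MASS
  # b_i spans residues 1..i, y_i spans residues (n-i+1)..n
  b_lab <- if (label_shift > 0) label_position <= idx else rep(FALSE, n - 1L)
  y_lab <- if (label_shift > 0) label_position >= n - idx + 1L else
    rep(FALSE, n - 1L)
  data.frame(
    type = rep(c("b", "y"), each = n - 1L),
    index = c(idx, idx),
    mz = c(b_mz + ifelse(b_lab, label_shift, 0),
           y_mz + ifelse(y_lab, label_shift, 0)),
    contains_label = c(b_lab, y_lab),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Encode a spectrum over theoretical ion slots
#'
#' Each of the `2(n-1)` b/y slots takes the intensity of the most intense
#' observed peak within `tol` Da of its theoretical m/z, else 0. Matching
#' against label-aware theoretical masses makes the encoding comparable
#' between a native spectrum and its isotope-labeled counterpart without
#' correcting for the mass shift: intensities land in the same ion-pair
#' slots. The vector is then L2-normalized; an all-zero encoding stays
#' zero and is flagged.
#'
#' @param spec `Spectrum`.
#' @param fragments `FragmentSet` from [theoretical_fragments()] (built
#'   with the spectrum's own label).
#' @param tol fragment match tolerance in Da (default 0.02).
#' @param normalize L2-normalize the vector (default TRUE).
#' @return `EncodedSpectrum`: list with `peptide`, `slots` (named by
#'   b1../y1..), `intensities`, `normalized`, `all_zero`.
#' @export
encode_spectrum <- function(spec, fragments, tol = 0.02, normalize = TRUE) {
  stopifnot(tol > 0)
  mz <- spec$peaks[, "mz"]
  int <- spec$peaks[, "intensity"]
  v <- vapply(fragments$mz, function(m) {
    hit <- which(abs(mz - m) <= tol)
    if (length(hit) == 0L) 0 else max(int[hit])
  }, numeric(1))
  all_zero <- all(v == 0)
  if (normalize && !all_zero) v <- v / sqrt(sum(v^2))
  structure(list(peptide = spec$peptide,
                 slots = paste0(fragments$type, fragments$index),
                 intensities = v, normalized = normalize,
                 all_zero = all_zero),
            class = "EncodedSpectrum")
}

#' Normalized spectral contrast angle
#'
#' `lambda(S1, S2) = 1 - 2 * acos(S1 . S2) / pi` on L2-normalized slot
#' vectors: 1 for identical spectra, 0 for orthogonal ones. Slots that are
#' zero in both vectors contribute nothing; a slot nonzero in only one
#' vector enters with the other's intensity zero-filled, which is exactly
#' the "set missing peaks to zero" rule. The angle is evaluated in a
#' numerically stable form equivalent to the arccosine of the dot
#' product clipped into `[0, 1]` (negative dot products cannot arise
#' from non-negative intensities), so identical encodings score exactly
#' 1.
#'
#' @param s1,s2 `EncodedSpectrum` objects on the same slot layout.
#' @return lambda in `[0, 1]`.
#' @export
spectral_angle <- function(s1, s2) {
  if (length(s1$intensities) != length(s2$intensities) ||
      !identical(s1$slots, s2$slots)) {
    stop("spectral_angle: slot layouts differ")
  }
  if (s1$all_zero && s2$all_zero) {
    stop("spectral_angle: both encodings are all-zero")
  }
  a <- s1$intensities; b <- s2$intensities
  # numerically stable angle: exact 0 for identical unit vectors, pi/2
  # for disjoint slots; equivalent to acos of the clipped dot product
  theta <- 2 * atan2(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))
  theta <- min(max(theta, 0), pi / 2)
  1 - 2 * theta / pi
}

#' Empirical null distribution of the spectral angle
#'
#' Draws `n_pairs` random pairs of spectra assigned to different peptides
#' from the pool; for each pair, both spectra are encoded against the
#' first spectrum's theoretical ion slots (the angle is defined on one
#' layout) and the angle is computed. A pair whose mismatched encoding is
#' all-zero scores 0. Deterministic for a fixed seed.
#'
#' @param spectra list of `Spectrum` objects (>= 2 distinct peptides).
#' @param n_pairs number of random cross-peptide comparisons.
#' @param tol fragment match tolerance (Da).
#' @param seed RNG seed.
#' @return list: `lambdas` (numeric vector), `quantile` (function p ->
#'   empirical quantile).
#' @export
null_distribution <- function(spectra, n_pairs = 1000, tol = 0.02,
                              seed = 1L) {
  peptides <- vapply(spectra, `[[`, character(1), "peptide")
  if (length(unique(peptides)) < 2L) {
    stop("null_distribution: need >= 2 distinct peptides in the pool")
  }
  set.seed(seed)
  lambdas <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- sample.int(length(spectra), 1L)
    b <- sample(which(peptides != peptides[a]), 1L)
    frags <- theoretical_fragments(peptides[a], spectra[[a]]$label_shift,
                                   spectra[[a]]$label_position)
    ea <- encode_spectrum(spectra[[a]], frags, tol)
    eb <- encode_spectrum(spectra[[b]], frags, tol)
    lambdas[i] <- if (ea$all_zero && eb$all_zero) 0 else
      if (ea$all_zero || eb$all_zero) 0 else spectral_angle(ea, eb)
  }
  list(lambdas = lambdas,
       quantile = function(p) stats::quantile(lambdas, p, names = FALSE))
}

#' Validate native/labeled spectrum pairs by spectral angle
#'
#' Encodes each native spectrum against its peptide's native fragments and
#' the labeled counterpart against the label-aware fragments, computes the
#' angle, and reports each pair's percentile within a random null.
#'
#' @param pairs list of lists with elements `native` and `labeled`
#'   (`Spectrum` objects of the same peptide).
#' @param null output of [null_distribution()] (optional).
#' @param tol fragment tolerance (Da).
#' @return data.frame: peptide, lambda, null_percentile (NA without null).
#' @export
validate_pairs <- function(pairs, null = NULL, tol = 0.02) {
  rows <- lapply(pairs, function(p) {
    stopifnot(identical(p$native$peptide, p$labeled$peptide))
    fn <- theoretical_fragments(p$native$peptide)
    fl <- theoretical_fragments(p$labeled$peptide,
                                p$labeled$label_shift,
                                p$labeled$label_position)
    l <- spectral_angle(encode_spectrum(p$native, fn, tol),
                        encode_spectrum(p$labeled, fl, tol))
    pc <- if (is.null(null)) NA_real_ else mean(null$lambdas <= l)
    data.frame(peptide = p$native$peptide, lambda = l,
               null_percentile = pc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate retention-time predictions with a 99% prediction interval
#'
#' Ordinary least squares of measured on predicted retention time; the
#' prediction-interval half-width at each point uses the standard formula
#' for a new observation at that predictor value. `pi` is the mean full
#' interval width (minutes) and `frac` the fraction of points falling
#' inside their own interval. Exact fits (zero residual variance) yield a
#' degenerate interval and are flagged.
#'
#' @param predicted,measured paired numeric vectors (n >= 3).
#' @param level coverage level of the prediction interval.
#' @return list: n, slope, intercept, r_squared, pi, frac, degenerate.
#' @export
evaluate_rt <- function(predicted, measured, level = 0.99) {
  n <- length(predicted)
  stopifnot(length(measured) == n)
  if (n < 3L) stop("evaluate_rt: need at least 3 points")
  if (stats::var(predicted) == 0) {
    stop("evaluate_rt: zero variance in predicted RT")
  }
  fit <- stats::lm(measured ~ predicted)
  # the interval is evaluated at the fitted points by design; predict()
  # notes that these refer to future responses, which is what we want
  pr <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level))
  inside <- measured >= pr[, "lwr"] & measured <= pr[, "upr"]
  width <- mean(pr[, "upr"] - pr[, "lwr"])
  list(n = n,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       pi = width, frac = mean(inside),
       degenerate = summary(fit)$sigma^2 <
         .Machine$double.eps * stats::var(measured))
}
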
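---
title: "Methods: post-identification analysis of HLA ligandome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-identification analysis of HLA ligandome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandkit)
```

## Scope

`ligandkit` implements the downstream, post-identification half of an
immunopeptidomics study: everything that happens after a database search
has produced peptide identification tables at a fixed local FDR. The
search engine, the HLA typing, and the neural binding predictors
themselves are upstream inputs — the package consumes their outputs
(peptide tables, allele lists, percentile-rank tables) and implements the
harmonization, quality control, similarity, coverage, prioritization,
spectral-validation and time-series analyses on top of them. A bundled
synthetic-data generator produces all of these inputs with planted
structure, so the whole pipeline is exercised and tested without any
external download.

## Binder harmonization

Each peptide–allotype pair can carry percentile ranks from several
predictors (NetMHCpan for HLA class I; NetMHCIIpan and MixMHC2pred for
class II) plus a normalized SYFPEITHI matrix score
$s_\mathrm{SYF} = \sum_p v_p(\mathrm{residue}_p) / \max \sum_p v_p$
for class I. The harmonized category is:

* **strong** if any tool is at or below its strong threshold
  (NetMHCpan 0.5; NetMHCIIpan 1.0; MixMHC2pred 1.0),
* otherwise **weak** if any tool is at or below its weak threshold
  (NetMHCpan 2.0; NetMHCIIpan 5.0; MixMHC2pred 5.0) or, class I only,
  $s_\mathrm{SYF} \ge 0.5$,
* otherwise **non**.

Design choices that the rule set itself leaves open: a rank exactly at a
threshold qualifies (the thresholds are printed as inclusive
inequalities); SYFPEITHI participates only in the weak tier and never
produces a strong call; a missing tool score is non-qualifying rather
than an error, so partial predictor coverage degrades gracefully — only a
record with *no* score at all is an error. Matrices with negative
position values can push $s_\mathrm{SYF}$ outside $[0,1]$; the score is
clamped before threshold comparison because the 50% rule presumes a
fraction scale. One peptide may be reported as a binder against several
allotypes of the same donor; all qualifying associations are kept, and a
record's summary category is the strongest over its donor's alleles.

## Replicate QC and global FDR

A technical replicate is kept when both gates hold:

* binder fraction (strong + weak over unique identifications) at least
  50% for HLA-I, at least 10% for HLA-II — "lower than" the cutoff is
  read strictly, so a replicate exactly at the boundary passes;
* the mode of the peptide length distribution is 9 for HLA-I, or falls
  in $[12, 18]$ for HLA-II. With tied modes the replicate passes if any
  modal length qualifies (permissive reading; the rule does not address
  ties).

Samples are filtered upstream at a 1% local peptide-level FDR, so each
sample contributes an expected $0.01\,n_s$ false identifications.
Pooling samples keeps every false positive while redundant true
identifications collapse, giving the dataset-level estimate

$$\mathrm{FDR}_\mathrm{global}
  = \frac{q_\mathrm{local} \sum_s n_s}{n_\mathrm{unique}}.$$

It equals the local level when no peptide is shared between samples and
grows with inter-sample redundancy. Per-sample counts are unique
peptides after merging the sample's passing technical replicates; the
denominator counts sequences unique within the HLA class (the most
natural reading of "the entire dataset"; the report flags this
convention).

## Sample similarity

Samples (subject × tissue × class, replicates pooled) are compared by
the Jaccard index $j = |A \cap B| / |A \cup B|$ at peptide or
source-protein level. Unless allele matching is requested, all peptides
including non-binders enter the sets. The allele-matched variant
restricts each pair to peptides that are binders to an allotype shared
by the two subjects; pairs without a shared allele are undefined (NA,
logged). Clustering is agglomerative on $d = 1 - j$ with average linkage
(UPGMA) — the matrix is a similarity without a geometric embedding, and
the published analysis does not print its linkage, so a
coordinate-free, robust default is used and exposed as a parameter.
Group contrasts assign every off-diagonal pair to exactly one of
same-subject/different-tissue, different-subject/same-tissue, or
neither, and compare category medians; the scientific claim under test
is that individual identity dominates tissue identity.

## Coverage and hotspots

Peptides are mapped to every annotated source protein by exact substring
search (overlapping occurrences all count; no protein inference, so a
multi-mapping peptide contributes to each listed protein). Coordinates
are 1-based inclusive. Per-residue stacks count the ligand intervals
containing each position, per class. Covered proteins are binned into
four groups — class-I-exclusive, class-II-exclusive, and both-covered
split by whichever class attains the higher positional coverage
fraction; the equal-coverage tie goes to the I-higher group and is
flagged. Hotspots have no canonical formal definition, so the package
states one operationally: maximal runs of positions with stacked
coverage at least `min_cov` (default 1), bridging up to `max_gap`
uncovered positions (default 0), discarding runs shorter than `min_len`
residues (default 8, one class-I ligand length). All three are exposed
in the configuration. Class co-location of hotspots is reported
descriptively only.

## Tissue yields, enrichment and target prioritization

Per-sample yield is the count of unique peptides; tissues are summarized
by their median over subjects. The yield model is ordinary least squares
of $\log_{10}$ median yield on $\log_{10}$ RPKM for one gene at a time —
antigen-presentation genes are strongly covariant, so a joint regression
would overfit — reporting $R^2$, the F-test p value and Spearman's rho
on the same pairs. Zero yields or expressions are dropped and logged,
not pseudo-counted, because a pseudo-count would manufacture leverage at
the bottom of the log scale.

Over-representation uses the one-sided Fisher exact test from the
hypergeometric upper tail, on sets intersected with a universe that
defaults to the accessions observed in the dataset. Results rank by raw
p value (as the published analysis does), with a Benjamini–Hochberg
column emitted for reference only; top-k reporting is a parameter (10
and 5 are the published choices for the two GO uses).

Tumor-versus-benign prioritization is sequence-level set subtraction per
HLA class: tumor-exclusive ligands are those absent from the union of
all benign samples, with each exclusive peptide's patient frequency
counted over the tumor cohort. Exclusive and shared peptides partition
the tumor set exactly — this invariant is fuzz-tested. An optional
strict mode additionally requires allotype-matched benign absence.
Cancer-testis antigens count as presented only with at least two
distinct ligands per class, guarding against single-peptide artifacts.

## Spectral validation

Theoretical fragments are singly protonated b/y ions from monoisotopic
residue masses; an isotope label of $\Delta m$ Da on residue $k$ shifts
exactly the ions whose span contains $k$. Spectra are encoded over the
$2(n-1)$ ion slots: each slot takes the most intense observed peak
within ±0.02 Da (the fragment bin tolerance of the upstream search,
configurable) of its label-aware theoretical m/z, else 0, and the vector
is L2-normalized. Because native and labeled spectra are encoded
against their own theoretical masses, the label shift cancels in slot
space — no mass correction is needed, and for noise-free pairs the two
encodings are identical vectors (a tested invariant). The similarity is
the normalized spectral contrast angle

$$\lambda(S_1, S_2) = 1 - \frac{2 \cos^{-1}(S_1 \cdot S_2)}{\pi},$$

evaluated in a numerically stable form so identical encodings score
exactly 1; slots zero in both vectors contribute nothing and slots
present in only one are zero-filled, which is precisely the stated
missing-peak rule. Raw intensities are used before normalization (a
square-root option exists; the published description does not state a
transform). The null distribution draws 1000 random cross-peptide pairs;
since slot layouts differ between peptides, both members of a null pair
are encoded against the first member's layout, and a pair whose
mismatched encoding is empty scores 0.

Retention-time predictions (an upstream input; a linear hydrophobicity
surrogate is built in) are evaluated by OLS of measured on predicted RT
with the standard 99% prediction interval for a new observation at each
point; `pi` is the mean interval width in minutes and `frac` the
fraction of points inside their own interval.

## Time-series analysis

MS1 areas are z-scored per MS run, $z = (x - \mu)/\sigma$, with the
population SD (the published formula writes only "SD"; the population
form is chosen and asserted to $10^{-10}$ in tests). All trajectories
are then referenced to the first time point by subtracting that column's
median — a single scalar, so between-trajectory differences are
preserved. Clustering is Euclidean k-means on the trajectory rows, best
of `n_init` (default 10) random restarts by inertia, deterministic per
seed. The published phrase "six seeds" is ambiguous between six
clusters and six initializations; it is read as $k = 6$ (matching six
published cluster panels), and both numbers are parameters rather than
constants.

## The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

* class-specific length distributions with 60% 9-mers (HLA-I) and a
  bell over 8–25 peaking at 18% 15-mers (HLA-II);
* planted binder fractions 0.82 (I) and 0.62 (II), the reported
  predicted-binder shares;
* subject-dominant sharing: each sample draws 60% of its peptides from
  a per-subject pool, 20% from a per-tissue pool (pool size 150 against
  120 draws), the rest privately — so same-subject pairs overlap more
  than same-tissue pairs by construction, and the similarity module
  must recover that ordering;
* 6 subjects × 4 tissues × 2 classes × 2 technical replicates with 85%
  per-replicate detection, per-tissue yield multipliers 1.4–0.8;
* class-II nested length variants with probability 0.3 around a shared
  core, mimicking ligand length ladders;
* b/y spectra with shared log-normal base intensities, independent
  multiplicative noise, 0.003 Da m/z jitter, five random noise peaks,
  and a +6 Da label at the C-terminal residue of the labeled partner;
* trajectory clusters with distinct mean shapes (stable, decaying,
  increasing, then late-peak shapes) and log-normal noise, σ = 0.1.

Every peptide is an exact proteome substring, so coverage analysis is
consistent by construction. Mock percentile ranks are emitted from the
planted labels (binders draw qualifying ranks against one of their
donor's alleles, 70% in the strong range; non-binders draw well above
every weak threshold), so the realized classified fractions track the
planted ones; a separate PWM-based mock predictor
(`score_with_motifs()`) provides motif-derived ranks as the percentile
of the best 9-mer window score within a 10,000-peptide seeded background
(rank granularity 0.01).

What the generator does **not** emulate: realistic fragmentation
intensity models, chromatographic drift beyond a linear surrogate,
homologous proteins (the proteome is i.i.d. residues, so multi-mapping
peptides are rare), allele-specific length preferences, and
predictor-score correlation structure. Passing tests therefore
demonstrate correctness of the computations and recoverability of
planted structure, not performance on real spectra.

## Numerical choices and problem sizes

Desk-scale defaults keep the full test suite and the reproduction
script within minutes: a 100-protein proteome (~29,000 residues),
~9,400 peptide records per atlas, 200 spectrum pairs against a
1000-pair null, 50 × 500 points for the RT coverage check, and 100
seeded replicates for the subject-versus-tissue ordering. Determinism
is enforced by a single plan seed from which every stage seed is
derived. Ties: the most intense peak wins an encoding slot; equal
coverage bins to I-higher; tied length modes pass if any qualifies.
Degenerate inputs (empty replicates, all-zero encodings, zero-variance
runs, exact fits) are flagged or rejected with named errors rather than
silently propagated.

## Known limitations

The global-FDR denominator convention (unique per class) is one of two
defensible readings. Hotspot calls depend on the stated operational
definition; no statistical enrichment test against a positional null is
performed. The allele-matched Jaccard restriction uses binder
associations pooled over the dataset rather than per-sample predictor
reruns. On a synthetic i.i.d. proteome the source-protein-level Jaccard
saturates at desk scale, so the similarity stage defaults to peptide
level; with a real proteome either level is appropriate.
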
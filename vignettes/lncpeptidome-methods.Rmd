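---
title: "Methods: discovering and quantifying lncRNA-encoded polypeptides from peptide evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and quantifying lncRNA-encoded polypeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts longer than 200 nucleotides
annotated as lacking a conserved open reading frame, yet a fraction of them
engage ribosomes and produce detectable polypeptides. Because these products
are absent from canonical protein databases, a spectrum search against the
standard proteome cannot see them. The proteogenomic strategy implemented
here is: build a *hypothetical lncRNA peptidome* by translating every lncRNA
transcript in all three sense-strand frames, merge it with the canonical
proteome into one search database, and then work with the peptide-level
quantification tables such a search produces — filtering, grouping and
aggregating peptides into polypeptide-level abundances, classifying their
tissue/cell-line distribution, and testing differential abundance between
cancer and normal cohorts.

The package operates downstream of the spectrum search itself: its inputs
are peptide-by-sample intensity tables in a MaxQuant `peptides.txt`-like
dialect, already normalized. Raw-file processing, search-engine scoring and
label-free normalization are out of scope.

## Database construction

`three_frame_translate()` translates each transcript in frames 0, 1 and 2
with the standard genetic code and splits each frame's translation at stop
codons. Every stop-free segment of at least `min_orf_len` residues is kept.
The choice of how to treat stop codons is the one genuinely open design
point here; we emit *all* stop-free segments rather than, say, only
AUG-initiated ORFs, because peptide evidence cannot distinguish initiation
context, and a segment shorter than the default of 8 residues cannot
contain a 6-residue tryptic peptide plus cleavage-compatible termini. Only
the sense strand is translated (three frames, not six), matching the
database-construction strategy the workflow emulates. Codons containing `N`
translate to `X` when the ambiguity matters and to the forced residue when
it does not; peptides containing `X` are excluded from digestion output
since they cannot be matched to spectra.

`tryptic_digest()` enumerates peptides cleaved after K or R except before
P, with up to 2 missed cleavages and a 6-residue minimum by default — the
standard trypsin settings of the quantification workflow this package sits
behind. All coordinates are 0-based half-open.

`novelty_filter()` removes any candidate peptide that occurs as a
contiguous substring of a canonical protein. Two decisions matter:

* **Exact substring, not alignment.** "Matches the proteome" is read as
  deterministic identity; a heuristic alignment with mismatches would make
  the retained set depend on scoring parameters.
* **I/L collapsing on by default.** Isobaric isoleucine/leucine are
  indistinguishable by mass spectrometry, so a peptide differing from a
  canonical sequence only at I/L positions is not evidence of a novel
  product. The flag is exposed for users who disagree.

## Grouping and quantification

Peptides shared between lncRNA entries make attribution ambiguous.
`group_shared_peptides()` merges transcripts whose observed peptide sets
are identical *or nested* (subsumption, as protein-inference engines do —
generalizing pairwise "shared between two" merging to k transcripts);
a peptide connecting two unmergeable groups is flagged non-unique and
contributes to neither. Transcripts are processed in decreasing peptide-set
size with lexicographic tie-breaks, which makes the grouping invariant to
input order.

A group is *reported* only if it has at least two non-overlapping unique
peptides. "Non-overlapping" is interpreted as non-overlapping occurrence
intervals on the group's representative polypeptide (the longest member
ORF, ties lexicographic). Because a peptide can occur at several positions,
`count_nonoverlapping_unique()` solves the exact maximization — the largest
set of pairwise-disjoint intervals using at most one interval per distinct
peptide — by depth-first search with an upper-bound prune rather than a
greedy heuristic; group sizes are small enough that exactness is free, and
an exhaustive-enumeration oracle verifies it in the tests. Intervals
touching at a boundary do not overlap. The rule is enforced per dataset:
a passing group is reported in all samples, with missing abundance where
no peptide was quantified; a per-sample variant would conflate detection
with quantification.

Polypeptide abundance per sample is the **median of the unique peptides'
non-missing linear-scale intensities** (`median_lfq()`, even counts
averaging the central pair). The median is taken on the linear scale;
log2 is applied only inside analysis operations. Zero intensities are
re-coded to missing at ingest — MaxQuant writes 0 for "not quantified",
and a literal zero would poison medians and fold changes.

`peptide_cv()` (percent coefficient of variation) and
`cross_context_peptide_anova()` reproduce the consistency diagnostics:
peptides of one polypeptide should agree within a context (low %CV) while
varying across contexts (significant one-way ANOVA on log2 intensities).

## Specificity, universal expression and profiles

`detect_presence()` calls a group present in a context when it is
quantified in at least one sample of that context (configurable; the
underlying data display per-context detection dots without a stated
threshold, so 1 is the faithful default). `classify_specificity()` labels
groups `specific` (one context), `shared`, or `ubiquitous` (all contexts),
and `universal_expressed()` is the exact intersection of the
tissue-ubiquitous and cell-line-ubiquitous sets (UExp).

`zscore_log2()` (row-wise z-score of log2 intensities, missing preserved,
constant rows zeroed with a warning) feeds `hcluster()`. For clustering,
missing cells are imputed to the row minimum: absent quantification in
this data regime usually means low abundance, and the row minimum
preserves that semantics without inventing structure. Euclidean distance
with average linkage is the default (correlation distance and complete
linkage available); the choice is recorded in the output object.
Correlations (`correlate()`) use pairwise-complete deletion, since the
matrices are sparse, with a t-transform p-value on `n - 2` degrees of
freedom. `plasma_rank()` places candidate polypeptides within a
descending-sorted plasma profile (1-based ranks from the top, average
ties), the operation behind superimposing candidates on a standard plasma
abundance profile.

## Differential abundance

`moderated_t_test()` implements the empirical-Bayes moderated t-statistic:
per-row pooled variances \(s^2_g\) with \(d_g\) degrees of freedom are
shrunk toward a prior \((d_0, s_0^2)\) estimated by moment matching on
\(\log s^2_g\) (digamma/trigamma matching with a Newton inversion of the
trigamma function), giving posterior variances
\(\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)\) and a t-statistic
with \(d_0 + d_g\) degrees of freedom. When the trigamma inversion finds
no positive excess variance (near-homoscedastic rows) the prior collapses
to \(d_0 = \infty\), i.e. a common variance. The implementation is checked
in the tests against an independent reference implementation and against
its two limit cases (ordinary pooled t at \(d_0 = 0\); shared variance at
\(d_0 = \infty\)). Rows with fewer than 2 non-missing values in either
group are excluded and flagged rather than silently dropped.

Stage-wise analysis first applies the presence filter — at least 2
quantified samples in each of stages I–IV — then a classical one-way
ANOVA on log2 values per included row. The early/late comparison pools
stages I+II against III+IV and uses Welch's t by default: the pooled
groups are unbalanced and visibly heteroscedastic in this kind of cohort;
a pooled-variance option is exposed for exact parity checks. Multiple
testing uses Benjamini–Hochberg throughout (`bh_adjust()`, a validating
wrapper over the standard step-up), with adjusted p < 0.05 as the
significance convention. Enrichment (`hypergeom_enrichment()`) is an
upper-tail hypergeometric test of each term against the universe of all
quantified groups.

For patient-matched two-sample designs the same two-group machinery is
applied with the pairing recorded in the annotation (`pair_id`); both
unpaired and paired-difference analyses are possible and neither is
claimed as canonical, since the matched design's model specification is
ambiguous in the source workflow.

## The synthetic-evidence generator

Real inputs at the original scale (~1,300 raw files across five public
repositories) are not reproducible at desk scale, so `simulate_study()`
generates cohorts with known ground truth:

* **Sequences.** Each planted group is a polypeptide of
  `peptides_per_group` (default 3) concatenated tryptic peptides (8–12
  residues, C-terminal K/R, no internal K/R/P, so digestion recovers
  exactly the planted peptides), reverse-translated with random synonymous
  codons into a frame-0 ORF ending in a stop codon. The canonical proteome
  is random sequence verified (after I/L collapsing) to contain no planted
  peptide, except an optional `decoy_fraction` copied verbatim into
  proteins to exercise the novelty filter. A `fraction_subsumed` of groups
  receive a second transcript encoding a peptide-prefix of the
  polypeptide, creating the shared-peptide degeneracy that the subsumption
  grouping must resolve.
* **Intensities.** Log-normal: peptide log2 intensity is a group baseline
  (sd 1.5 around a mean of 25, typical of label-free intensity scales)
  plus a context effect (sd 1), plus sample-level noise `log2_sd`
  (default 1) shared by the group's peptides, plus peptide-level noise
  fixed at `0.1 * log2_sd` — so peptides of one group track each other,
  reproducing the low within-context %CV that motivates median
  aggregation.
* **Design.** Defaults mirror the emulated study: 14 tissues, 11 cell
  lines (3 runs each), a 92-cancer/30-normal cohort with stages I–IV
  assigned cyclically; disjoint planted classes (40% context-specific,
  8% tissue-ubiquitous, 4% universally expressed, remainder shared);
  10% of groups upregulated in cancer by 2 log2 units with a monotone
  stage trend of 0.5 log2 per stage. 150 groups keep every end-to-end
  check comfortably fast while leaving all class sizes two digits.
* **Missingness.** Missing-completely-at-random dropout (default 10%) on
  top of structural absence (a specific group has no signal outside its
  context). An intensity-dependent logistic option (`missing_mode =
  "censor"`) is provided because real label-free missingness is
  left-censored; it is not the default since the recovery guarantees are
  stated under MCAR.

What passing tests on these cohorts shows — and what it does not: exact
recovery at zero noise demonstrates the algebra of the pipeline (grouping,
median, classification, intersection) is faithful; calibration and power
results demonstrate the statistical stack behaves as designed under its
own model. None of this certifies performance on real spectra, where
missingness is not MCAR, intensities are not exactly log-normal, and
peptide-to-entry mapping errors exist upstream.

## Numerical choices and degenerate inputs

* Ties in hierarchical agglomeration follow the standard lowest-index
  convention of the clustering routine; leaf order is reported so runs are
  comparable.
* Zero total variance in an ANOVA returns p = 1 with a warning; zero
  within-group variance with distinct means returns F = ∞, p = 0.
* Constant rows z-score to zero with a warning; rows with fewer than two
  values are not z-scored.
* `bh_adjust()` rejects p-values outside [0, 1] instead of clamping.
* All pipeline stages are deterministic; re-running a configuration gives
  byte-identical outputs, which the tests assert by checksum.
* Sub-seeds for the generator's independent stages are derived by small
  integer offsets from the user seed.

## Problem sizes used in validation

The shipped validation suite uses: 500 random interval instances (≤12
occurrences) against exhaustive enumeration; 100 random 25-mers for
digestion against substring enumeration; a 100-group decoy run for the
novelty filter; 60–150-group cohorts for recovery; 50 replicates of
5,000-row null and 10%-effect cohorts (n = 10 vs 10) for calibration, FDR
and power; and 50 replicates of 100-group staged cohorts (n = 5 per
stage) for the stage pipeline. These sizes were chosen so the full suite
exercises every guarantee at meaningful precision in a few minutes on one
core.

## Known limitations

* No six-frame translation, selenocysteine handling, or non-standard
  genetic codes.
* The novelty filter is substring-exact; it does not emulate heuristic
  alignment with mismatches.
* No re-implementation of delayed normalization or match-between-runs;
  intensities are consumed as provided.
* The moderated-t machinery covers two-group contrasts only; multi-factor
  designs and observation weights are out of scope.
* Enrichment requires a user-supplied term-to-group map; no ontology
  retrieval is included.
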
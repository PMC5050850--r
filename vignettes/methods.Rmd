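---
title: "Methods: hairpin-signature miRNA discovery with empirical FPR calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin-signature miRNA discovery with empirical FPR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstack)
```

# Overview

`mirstack` implements a desk-scale pipeline for discovering novel microRNAs
from small-RNA sequencing data. Mature miRNAs are ~19-23 nt RNAs excised
from hairpin precursors by Drosha and Dicer. That processing leaves a
characteristic footprint in aligned read data: reads pile up on the mature
arm with homogeneous 5' ends, a much smaller pile marks the star (passenger)
arm offset by a 2-nt 3' overhang, loop-derived fragments are rare, and the
underlying genomic window folds back on itself. The pipeline scores genomic
read stacks for this footprint, then calibrates a score threshold
empirically: predictions overlapping annotated exons or non-miRNA small RNAs
serve as labelled false positives, predictions overlapping known miRNA
hairpins as true positives, and the threshold is placed where the empirical
false positive rate (FPR) is closest to a target (0.05 by default).
Candidates overlapping neither annotation that score above the threshold are
the reported novel miRNAs, which are then annotated by gene proximity,
sequence similarity to known matures, replication-set overlap, and
differential expression.

Every stage is validated on synthetic data with planted ground truth; the
generator is first-class, tested code, not a fixture.

# The read-preprocessing contract

Raw single-end reads (51 nt, Phred+33) pass through four stages, in order:

1. **Adapter trimming.** The read is scanned left to right for the first
   position where its remainder matches a prefix of the 3' adapter with a
   mismatch rate of at most 0.1 over an overlap of at least 3 nt
   (`floor(0.1 * overlap)` mismatches allowed). Everything from the match
   onward is removed, qualities in step. This reproduces what a standard
   adapter trimmer does with those settings; reads without a match pass
   through unchanged.
2. **Quality filtering.** A read is kept iff at least 80% of its bases have
   Phred quality >= 20. The boundary (exactly 80%) keeps the read,
   matching the inclusive comparison of the classic FASTX filter these
   numbers come from.
3. **QC length filtering.** 15-27 nt inclusive. A second, stricter window
   (18-23 nt) is applied to the *alignment* table before discovery;
   counting for differential expression uses the wider window.
4. **Exact alignment.** Every exact placement of the read on either genome
   strand is reported (no mismatches); reads with more than 200 placements
   are suppressed entirely — the `bowtie -v 0 -a -m 200` semantics. Each
   placement of a multi-mapped read contributes a full count; no fractional
   weighting is applied, since none is defined for this design. Matching is
   delegated to `Biostrings::matchPDict` on constant-width dictionaries of
   the unique read sequences.

# Hairpin discovery

Discovery-length alignments are clustered per chromosome and strand into
**stacks**: maximal runs in which consecutive reads are separated by at most
30 bp (measured from the running maximum end to the next start). For each
stack the **modal read** (most frequent start/end pair; smallest coordinates
on ties) seeds two candidate precursor windows of `flank + 22 = 92` bp: one
treating the modal read as the 5' arm, one as the 3' arm. Windows are
clipped to chromosome bounds; when both survive, the better-scoring one wins
later in a greedy non-overlap selection.

## Folding

Each window is folded by **base-pair maximization** (Nussinov-style dynamic
programming) over Watson-Crick pairs plus the G·U wobble, with a minimum
loop of 3 unpaired bases. This is a deliberate, documented substitute for
thermodynamic free-energy folding: it is deterministic, dependency-free,
and at hairpin-vs-nonhairpin discrimination scale the maximal pairing count
carries the needed signal. The traceback is fixed — outermost compatible
pair first, then left/right unpaired, then the smallest bifurcation point —
so identical inputs always give identical structures. The pair count is
property-tested against exhaustive structure enumeration for sequences up
to 12 nt.

## Arm assignment and the signature score

The modal read defines the mature arm. The star is inferred as the paired
image of the mature on the opposite arm, shifted 2 nt 3'-ward — the Dicer
overhang: the star's last base is expected at `partner(mature 5' start) + 2`.
Because a few stem positions may be unpaired, the partner is extrapolated as
the median over paired mature positions of `partner(i) + (i - mature_start)`.
The loop is the region between the arms. Every stack read is assigned to
mature, star, loop, or outside by maximal overlap (ties favour mature, then
star, then loop). Minus-strand windows are handled by mirroring all
coordinates into transcript orientation and mirroring the resulting
intervals back.

The **signature score** of a candidate is the weighted sum

$$ S = w_d \log_{10}(1+n) + w_c f_{5'} + w_o f_{oh} + w_s f_{pair}
     + w_5 \frac{n_m}{n_m + n_l + 1} $$

with $n = n_m + n_s + n_l$ the precursor read total, $f_{5'}$ the fraction
of mature reads sharing the modal 5' start, $f_{oh}$ the fraction of star
reads with the expected 2-nt overhang (0 when no star reads exist),
$f_{pair}$ the paired fraction of arm positions, and default weights
$(w_d, w_c, w_o, w_s, w_5) = (1, 2, 1, 1, 2)$. The score is monotone in
every ingredient and invariant to read order and coordinate translation.

This additive surrogate replaces the probabilistic log-odds score of full
discovery tools, whose evolutionary-conservation term has no input at desk
scale. Consequently **absolute score values from published human analyses
are not reproducible here by design**; everything downstream (categorization,
FPR calibration, ROC/AUC, filtering) operates on the surrogate score's own
empirical distribution, which is all the calibration logic requires.

# Categorization and FPR calibration

Each prediction's hairpin interval is intersected (>= 1 bp, strand-agnostic,
the `bedtools intersect` default) with three annotation tracks:

| overlap | category |
|---|---|
| exon and/or non-miRNA small RNA only | `false_positive` |
| known miRNA hairpin only | `true_positive` |
| both | `excluded` |
| neither | `candidate` |

Dual-annotated predictions are excluded because it cannot be decided whether
a true miRNA sits inside the exon or one annotation is wrong. The four
categories partition every input.

With strict "score above threshold" counting, `FPR(t)` and `TPR(t)` are the
fractions of false/true positives above `t`; the ROC curve is their locus
and the AUC its trapezoidal area (equal, at dense thresholds, to the
pairwise ranking probability). Threshold selection is two-stage: every
integer between the floor of the minimum and the ceiling of the maximum
score is scanned for the FPR nearest the target; the winner `t*` is then
refined over `t* - 1.00, t* - 0.99, ..., t* + 1.00` in exact 0.01 steps
(fixed-point arithmetic, both endpoints included). Ties break toward the
smallest threshold, which retains the most candidates at equal calibrated
error; both endpoint inclusion and the tie-break are this package's
documented defaults, not claims about any published analysis. The novel set
is `candidate` predictions strictly above the refined threshold.

# Downstream annotation

* **Gene proximity**: measured on the mature interval (the reported miRNA
  unit). Overlap with a gene body is `intronic` (exonic candidates were
  already removed as false positives), a gap of 1-1000 bp is `near`,
  anything farther `distant`. Whether proximity should instead be measured
  from the hairpin is genuinely open; the mature was chosen as the reported
  unit, and callers can pass hairpin intervals to flip the convention.
* **Similarity**: Smith-Waterman local alignment (match +5, mismatch -4,
  gap of length $L$ costs $12 + 4L$) with deterministic traceback. E-values
  follow a Gumbel tail $K m n e^{-\lambda S}$ fitted once by the method of
  moments on 400 random 22-mer pair scores under a fixed internal seed and
  cached for the session. Absolute e-values therefore differ from any
  particular aligner's; the standard filters (e-value < 0.05 strict,
  aligned query bases >= 15 inclusive) are honoured as stated. "Nucleotide
  overlap" is read strictly as matched query positions, excluding gap
  columns. Seed quality is the count of substitutions and gaps over mature
  positions 2-7, with unaligned seed positions counted as gaps and the
  result capped at 6.
* **Replication**: two novel sets are compared by >= 1 bp location overlap
  with per-member shared/unique accounting (the relation is explicitly not
  one-to-one; all pairs are listed), plus a three-way Venn partition.
* **Duplicate collapsing**: candidates with identical mature sequence and
  mature coordinates but different hairpin windows are collapsed to the
  higher-scoring one before counting and differential expression, to avoid
  double-counting shared reads.

# Differential expression

Counting is union-mode: a read increments a mature region iff it overlaps
exactly that one region; multi-region reads are ambiguous and dropped.
Rows with zero counts in strictly more than half the samples are removed
(zero in exactly half is kept). The variance-stabilizing transform is
`log2(count / size_factor + 0.5)` with median-of-ratios size factors
(geometric-mean reference over all-nonzero rows; library-size fallback when
none exists). Batch adjustment standardizes each batch, per row, to the
pooled mean and variance (location-only for singleton batches; fully
constant rows pass through unchanged). Testing is ordinary least squares per
row, `expression ~ group + age`, on the contrast's samples only; the group
coefficient is the log2 fold-change (disease minus control, so lower disease
expression is negative), with two-sided t p-values and Benjamini-Hochberg
adjustment across tested rows.

These are deliberate simplifications of the moderated-variance and
parametric-VST machinery of the established count-model packages: the
package's contracts are the operating characteristics (sign convention, FDR
control, recovery of planted effects), not any published table's exact
statistics. The batch adjuster ignores group labels; whether batch
correction should protect the disease covariate is ambiguous in common
practice, and the simple surrogate's behaviour is easiest to reason about
(with groups balanced across batches, as in the simulated designs, the
question is moot).

# The synthetic-data generator

`sim_config()` fixes the study conditions; `generate_genome()`,
`simulate_counts()` and `simulate_reads()` realize them deterministically
from a seed.

* **Genome and loci.** One random 60 kb chromosome. Planted hairpins are
  `mature(22) + loop(15) + star_arm(22) + tail(2)` where the star arm is
  the reverse complement of the mature with 3 substitutions — enough that
  the stem still pairs over >= 80% of arm positions while mature reads map
  uniquely (a perfect inverted repeat would also match the minus strand).
  The mature is always the 5' arm; real miRNAs use either arm, and the
  minus-strand/3'-arm geometry is unit-tested separately. Decoy loci (exon
  fragments, degradation sRNAs) and intergenic-noise loci are placed with
  loci mutually separated by >= 200 bp so excised windows never touch a
  neighbour. A configurable number of planted miRNAs is withheld from the
  known-miRNA track ("novel" truth), and some known ones are additionally
  annotated as exons to exercise the exclusion rule.
* **Counts.** Reads per locus and sample are negative binomial
  (`variance = mu + 0.1 mu^2`) around a log-uniform per-locus mean (50-1000
  for miRNAs, 50-500 for decoys), multiplied by a group fold-change on
  selected loci and a per-locus, per-batch shift (`2^N(0, 0.1)`).
* **Reads.** miRNA reads split mature:star:loop at 100:10:1; mature 5' (and
  3') ends jitter by 1 nt with probability 0.1; star reads carry the exact
  2-nt overhang; loop fragments are 18-mers. Decoy stacks are diffuse:
  uniform starts, lengths 18-26. Every insert gets the adapter appended, is
  padded with random bases to 51 nt, and receives uniform substitution
  errors at 0.001 per base; 1% of reads get a failing quality profile.
* **Scale.** The reference scenario (20 planted miRNAs, 8 withheld, 40
  decoys, 10 samples, ~1.5 x 10^4 reads/sample) is a deliberate scale-down
  of a production experiment by three orders of magnitude, chosen so the
  full pipeline runs in about a minute. Differential-expression checks use
  count-level simulation directly (80 miRNAs, 30 vs 30 samples), where
  read-level simulation would add nothing.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: genomic repeat structure and large multi-mapping
families, cross-mapping between paralogous miRNAs, position-dependent error
and quality profiles, ligation bias, isomiR complexity beyond 1-nt end
jitter, both-arm maturation, and minus-strand transcription. The recovery
and FPR results on synthetic data validate the pipeline's internal logic,
not its sensitivity on human libraries.

# Numerical and design choices

* Internal coordinates are 0-based half-open everywhere (BED convention);
  GFF3's 1-based closed coordinates are converted at the file boundary.
  Interval distance is the gap between nearest ends, so exactly-abutting
  half-open intervals have distance 0 without overlapping — the one
  measure-zero case where "distance 0" and "overlaps" diverge.
* Annotation intersections are strand-agnostic by default (the `bedtools`
  default; nothing in the calibration design requires strandedness).
* The refinement grid uses integer fixed-point (`(100 t* + k)/100`) to
  avoid floating-point drift in the 0.01 steps.
* Stack modal reads, folding tracebacks, alignment tracebacks and greedy
  candidate selection all have written tie-breaks, so every pipeline stage
  is bit-reproducible.
* In DE simulations the planted effects are bidirectional (half up, half
  down). Strongly one-sided DE at a 20% feature fraction visibly biases
  median-of-ratios size factors — a known limitation of ratio-based
  normalization, worth remembering when interpreting real contrasts.
* `fold_hairpin` is quadratic in memory and cubic in time; it is meant for
  precursor windows (~100 nt), not whole chromosomes.

# Known limitations

* The signature score is a surrogate: scores are not comparable across
  packages or to published score thresholds; only their within-analysis
  ordering matters.
* Exact matching only: SNPs, editing and sequencing errors in the mature
  body cost reads rather than mismatched alignments.
* The e-value calibration is scheme-specific; treat e-values as a filter,
  not as cross-tool statistics.
* OLS differential expression has no variance moderation; at very small n
  it will be conservative relative to moderated tests.
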
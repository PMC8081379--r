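---
title: "Quantifying direct and indirect platinum mutagenesis in isogenic clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying direct and indirect platinum mutagenesis in isogenic clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platmut)
```

## The experimental design the package models

A single ancestral cell clone is expanded and split; some descendant
populations are repeatedly treated with a platinum drug (cisplatin,
carboplatin or oxaliplatin) at an equitoxic dose (IC25 or IC50), others
are mock-treated, and pre-treatment replicates of the ancestor are kept
as controls.  After the treatment window, single cells are re-cloned and
whole-genome sequenced at moderate depth (~30×).  Because every clone
passes through a single-cell bottleneck, a mutation present in exactly
one descendant and absent from all others must have arisen in that
lineage during the treatment window.  Comparing treated against mock
burdens therefore measures drug mutagenesis directly, without any of the
confounding that plagues tumour-derived mutational signatures.

`platmut` implements the computational half of such a study: unique-SNV
and indel calling with false-positive-calibrated filtering, 96-channel
trinucleotide spectra, transcriptional strand bias, de novo two-component
signature decomposition with per-clone exposures, and the group-level
burden statistics.  A synthetic-data module generates a complete
in-silico experiment so all of it runs and is tested without sequencing
data.

## Unique-mutation calling

The caller works on per-site allele-count tables (one row per site and
sample with coverage and A/C/G/T, insertion- and deletion-supporting read
counts).  A site yields a candidate if and only if exactly one sample
shows the variant and all others look clean:

* mutated sample: alternate-allele frequency ≥ `min_vaf`, coverage ≥
  `min_cov`;
* every other sample: reference-allele frequency ≥ `min_other_ref_freq`,
  coverage ≥ `min_cov`.

Defaults are `min_vaf = 0.2`, `min_other_ref_freq = 0.93`,
`min_cov = 7`.  These are deliberately permissive at the candidate stage
(a heterozygous variant at 30× has VAF ≈ 0.5, far above 0.2); specificity
comes from the score filter.  Variants shared by several clones are
ancestral and dropped by construction.

Each candidate is scored against the non-mutated sample with the lowest
reference-allele frequency — the noisiest competitor, making the score
conservative.  The score is the −log₁₀ one-sided Fisher exact p-value
that the two samples' (alt, ref) counts share one allele fraction,
computed as a hypergeometric tail and clamped at p = 1e-300.  Indels are
scored identically on (supporting, non-supporting) counts.

Thresholds are not chosen by eye: `calibrate_threshold()` sweeps the
observed scores (inclusive `score >= T`, candidates are 0 plus every
observed score, ties resolved toward the smaller threshold) and returns
the smallest thresholds at which every pre-treatment control clone keeps
at most 5 SNVs, 1 insertion and 1 deletion — control clones carry no true
unique mutations, so anything surviving there is a false positive.  If
even the largest observed score leaves a clone over its limit the
threshold is placed just above it (a relative nudge of 1e-9).

Coordinates are 0-based half-open internally and in BED; they become
1-based only in the serialized count/call tables and VCF.  Calls keep
reference-strand alleles; the pyrimidine convention is applied only when
spectra are built.  Because the count-table format records only
supporting-read counts for indels, indel calls from counts carry symbolic
`<INS>`/`<DEL>` alleles.

## Spectra, strand bias, rates

`classify_snv()` maps every substitution to one of 96 channels: classes
C>A, C>G, C>T, T>A, T>C, T>G (purine references are
reverse-complemented), each expanded by the 5′ then 3′ flanking base in
alphabetical order.  The order is frozen in `sbs_channels()` and in every
serialized spectrum.  Adjacent same-clone SNVs can be merged into doublet
substitutions (`classify_dbs()`, canonical strand normalization,
runs ≥ 3 excluded as multi-nucleotide events); indels are classified on
two axes, length (1 / 2–4 / 5+) and homopolymer run at the locus
(0–1 / 2–4 / 5+) — a deliberately compact scheme rather than the full
83-class catalogue, because the analyses here need counts and qualitative
context only.

For strand bias, each in-gene SNV is assigned to the transcribed strand
when the pyrimidine of the mutated pair lies on the template strand
(pyrimidine strand ≠ gene strand); each substitution class is tested
against symmetry with a two-sided exact binomial test, which is
preferable to approximations at per-class counts of tens to hundreds.
SNVs inside genes annotated on both strands are excluded (the generator
forbids such overlap; real annotations may not).

`mutation_rate()` converts burdens to rates as
`mutations / (genome_gb × duration_days × 24 / cycle_hours)`.  The genome
size is an explicit argument because "per Gb" can reasonably mean the
haploid reference (3.0 Gb for human) or the diploid genome; the package
does not hard-code either convention.

## Signature decomposition

`nmf_fit()` factorizes the 96 × n count matrix `V ≈ S·E` by minimizing
the generalized Kullback–Leibler divergence with the classical
multiplicative updates — the estimator matching Poisson count data and
the one standard in the mutational-signature field.  Defaults:
`restarts = 50` seeded random initializations (each restart draws from
its own named sub-stream, so fits are bit-reproducible), `max_iter =
2000`, relative tolerance `1e-8`, a `1e-12` floor inside update
denominators (no pseudocounts are added to the data).  The best restart
by final divergence is returned; signatures are column-normalized with
the scale folded into the exposures, so exposures are mutation counts.
`pick_rank()` reports divergence and restart stability per candidate rank
without choosing one; the replication workflow fixes k = 2.

### Why a resolution step is needed

A rank-2 non-negative factorization of mixture data is unique only up to
a non-negative recombination of its components: if every sample is
`d·S_dir + b·S_bg`, then `S_dir' = α·S_dir + (1−α)·S_bg` with rescaled
exposures fits exactly as well.  Worse, when samples cluster into a few
groups, the maximum-likelihood fit *prefers* the sheared representative —
the components drift toward the cluster mean spectra because that lets
the per-sample exposures absorb sampling noise.  This is observable
directly: on synthetic two-group data the converged divergence of the
sheared solution is lower than that of the generating factorization even
when the optimizer is initialized at the truth.  The consequence is a
systematic bias: the "platinum" component carries a share of the broad
background, so background exposures are underestimated in proportion to
each sample's direct burden, and between-group comparisons of background
mutagenesis are invalid.

`resolve_components()` therefore selects the scientifically meaningful
member of the solution family:

1. **Anchor the background.**  The background component is, by
   construction of the experiment, the spectrum of spontaneous
   mutagenesis observed in mock-treated clones; when mock samples are
   available their pooled normalized spectrum replaces the closest fitted
   component.  Without an anchor, the broadest fitted component is used
   as-is.
2. **Strip the admixture.**  For every other component the background
   admixture coefficient is estimated robustly — initialized at the
   background-weighted median of channel ratios (the L1 regression slope)
   and refined by the mass ratio on channels outside the component's own
   apparent support, which aggregates counts and has far lower variance
   than per-channel ratios — and subtracted.  Channels left below the
   uniform level 1/96 are zeroed: the resolved component keeps only its
   characteristic channels.  This truncation assumes peak-like direct
   signatures; a genuinely broad non-background component would be
   distorted, and the threshold can be set to 0 to disable it.
3. **Refit exposures.**  `refit_exposures()` re-estimates E by KL
   multiplicative updates with S fixed — the maximum-likelihood
   attribution given the resolved signatures; totals per sample are
   conserved.

`nmf_fit()` itself is untouched by this machinery and is tested as the
plain estimator; `run_pipeline()` applies the resolution automatically,
anchored on the design's mock clones.

PCA (`pca_spectra()`) operates on relative-frequency spectra,
channel-mean-centred, via singular value decomposition; each component's
sign is fixed by making its largest-magnitude loading positive.  Cosine
comparison against external 96-row signature tables validates channel
labels strictly and reports the first mismatch.

## The synthetic experiment

The generator produces, from one master seed (sub-streams `genome`,
`planting`, `counts`, `nmf<r>` keep stages independently reproducible):

* **Reference**: i.i.d. bases at a set GC content (default 0.42), with
  non-overlapping genes on random strands covering ≈ `gene_fraction`
  (default 0.3) of the genome, written as FASTA + BED.
* **Planted mutations**: per clone a Poisson SNV count; each SNV is
  assigned to the direct or background signature by the group's mixture
  weight, a channel is drawn from that signature, and a site is drawn
  uniformly among positions matching the channel's pyrimidine-centred
  trinucleotide context (either strand).  In-gene direct mutations land
  on the transcribed strand with probability `ts_bias` (default 0.8).
  1-bp indels are planted at `indel_rate` per SNV (default 0.1,
  deletion:insertion 2:1 — the true generating process for indel rates is
  not derivable from burden counts, so these are free stand-in
  parameters).  No two clones ever share a site.
* **Counts**: per site and sample, coverage ~ Poisson(30); the mutated
  clone's alternate reads ~ Binomial(coverage, 0.5) (heterozygous
  single-site hits; other VAFs are generator options), miscalls at
  `seq_error_rate` (default 1e-3) uniform over the three non-reference
  bases, indel-supporting noise reads at the same rate, and ten clean
  noise sites per planted site to exercise specificity without
  whole-genome scans.

The built-in signatures encode the two mechanisms: the **direct**
signature concentrates on `N[C>A]C` (platinum-GG intrastrand crosslinks,
read through the pyrimidine convention) and `C[T>A]N` (AG crosslinks),
0.65/0.35, with transcribed-strand bias; the **background** signature is
a broad, featureless SBS5/SBS40-like distribution dominated by C>T and
T>C with mass in every channel and no strand bias.  Giving the two
signatures distinct supports is a deliberate choice: it is what makes the
two-component decomposition identifiable at desk-scale sample counts, and
it matches the interpretation that all broad-spectrum mutagenesis is the
background process.  The demo design mirrors a human-lymphoblast arm:
mock at 169 SNVs per clone, cisplatin at 169 + 532, carboplatin at
169 + 324, with direct-mixture weights 0, 0.6 and 0.5.

What the generator does **not** emulate: read-level artifacts (no
FASTQ/BAM, no mapping error, no duplicate or realignment issues),
copy-number or structural variation, subclonality within a clone,
position-dependent coverage or error, the four weekly treatment rounds
(collapsed into one planted set, since only the summed post-treatment
mutation set is analysed), and real genome composition (i.i.d. bases, so
context availability is uniform).  Tests passing on this generator show
the *pipeline logic* is correct under the stated noise model; they do not
certify performance on real sequencing data.

## Problem sizes and numerical choices

The test-suite and demo sizes are chosen so a full run stays interactive
on one CPU: the demo pipeline uses a 3 Mb genome, 3 groups × 4 clones +
3 controls (~5 500 planted mutations, ~60 000 noise sites, ~1 M count
rows) and completes in well under two minutes; unit fixtures use
30–500 kb genomes.  NMF in tests uses 3–10 restarts and the demo
decomposition 20 (the default 50 is for analyses).  Calibration examples
use 10 control clones and 20 000
noise sites.  Determinism is asserted byte-for-byte: identical configs
give identical output checksums in the pipeline manifest.

Degenerate inputs are handled explicitly rather than by accident: sites
with a zero-coverage sample are skipped and counted; a zero-coverage
comparison sample gives score 0 and a flag; empty control call sets give
zero thresholds; all-zero spectrum columns are rejected before NMF;
identical spectra give zero PCA coordinates and zero explained variance;
zero pooled variance in the t-test returns t = 0, p = 1 (equal means) or
a flagged infinite statistic (unequal); a group of size 1 reports SEM as
missing; contig-edge SNVs keep their call but are excluded from spectra
and logged.

## Known limitations

* The quality score is one specific probability model (one-sided Fisher
  against the noisiest clean sample); established unique-mutation callers
  use tool-specific internal scores, so calibrated thresholds — not raw
  score values — are the comparable quantity.
* The resolved decomposition assumes the non-background signatures are
  peak-like; `truncate_below = 0` disables that assumption but then group
  comparisons of background exposures inherit the rotational-ambiguity
  bias described above.
* Indel classes are a simplified 2-axis scheme; doublet handling excludes
  runs of ≥ 3 adjacent SNVs rather than classifying them.
* No replication-strand bias, clustered-mutation analysis, subclonal
  VAF modelling, or automatic NMF rank selection.
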
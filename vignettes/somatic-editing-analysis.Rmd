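---
title: "Genotyping somatic CRISPR edits and their transcript consequences from aligned RNA-seq reads"
author: "editscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping somatic CRISPR edits from aligned RNA-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscope)
```

## The problem this package addresses

Transient ("somatic") CRISPR-Cas9 knockouts -- Cas9 plus guide RNAs injected
into zygotes -- produce mosaic animals: every cell can carry a different
editing allele at the guide target site, or none. Single-cell protocols of
the TARGET-seq family read out both the transcriptome and targeted genomic
amplicons spanning the guide sites, so one library contains two kinds of
evidence: spliced mRNA reads (with `N` CIGAR operations across introns) and
contiguous genomic-amplicon reads over the target exons.

`editscope` takes such aligned reads (plain-text SAM), a reference genome
(FASTA), a single-transcript gene annotation (GFF3-style), and a guide-site
table, and computes:

* per-read and per-sample **editing genotypes** at each guide site,
* **large deletions** (> 10 kb) between two guide sites from split
  alignments,
* the **ORF consequence** of each allele (frameshift, premature stop,
  protein length relative to wildtype),
* **aberrant-splicing fractions** from splice-junction evidence,
* **masked-exon expression quantification** with a splicing-ratio-weighted
  effective transcript length for FPKM, and
* **single-cell QC** and **marker co-expression** summaries.

A deterministic synthetic-data generator emulating this library design
provides ground truth for every stage, so the entire pipeline is testable
without external data.

## Allele calling at guide sites

A read is *spanning* for a site when its reference footprint (CIGAR
`M/D/N` operations) fully covers the calling window `[cut - w, cut + w]`;
the half-width `w` defaults to 15 bp, wide enough for the indel spread
around a Cas9 cut while staying inside a typical exon. Within the window
the read's CIGAR is walked against the reference:

* `I`/`D` operations intersecting the window give an **indel** call;
* aligned bases that differ from the reference give **substitutions**
  (adjacent mismatches merge into one run);
* a read with both is categorised as a single compound **indel** allele
  (mutant alleles such as a 7-bp deletion plus a 1-bp substitution are one
  biological event);
* a read spliced (`N`) across the window carries no sequence evidence at
  the site and is excluded from calling (it still counts for splicing
  quantification).

Identical allele strings from multiple reads aggregate into one event with
a support count; distinct alleles in one sample are all reported, because
somatic knockouts are mosaics. A sample is **edited** at a site when some
allele reaches `minSupport` reads (default 1, mirroring calling of any
deviant read sequence) *and* exceeds `maxErrorFrac` of the spanning reads.

`maxErrorFrac` (default 0) is the explicit knob separating sequencing
error from real substitutions. At per-base error rate $e$ and depth $d$,
the chance that two reads share the same error position *and* alternative
base somewhere in a $2w+1$ window is roughly
$(2w+1) \binom{d}{2} (e/3)^2 \cdot 3$, which at $e = 0.01$, $d = 30$,
$w = 15$ is of order 0.3 -- far too high for identical-allele counting
alone. Requiring support above a 10% noise floor (`maxErrorFrac = 0.1`)
suppresses these collisions while leaving true alleles (carried by
essentially all reads of an edited cell) untouched; validation under 1%
simulated error uses that setting.

## Large deletions

A deletion joining two cut sites more than 10 kb apart cannot appear as a
`D` operation in a short read; it manifests as split alignments (or read
pairs) whose blocks flank both cuts. `detectLargeDeletion()` accepts a
query as support when one of its blocks ends within `flank` (200 bp) of
the lower cut, another starts within `flank` of the higher cut, and the
unaligned gap between them exceeds 10 kb. The reported span is the
consensus breakpoint pair; a large deletion marks both sites edited.
Ordinary spliced reads never qualify: annotated introns in these loci are
far below 10 kb.

## ORF consequences

Edits are projected from genomic to transcript coordinates through the
exon structure (strand-aware), applied to the spliced transcript, and the
position of the wildtype start codon is tracked through the edit.
Translation uses the standard nuclear genetic code (stops
`TAA`/`TAG`/`TGA`) and runs from the projected start to the first in-frame
stop.

* **frameshift**: net inserted-minus-deleted coding bases not divisible
  by 3;
* **premature stop**: for in-frame variants, termination earlier than the
  wildtype length plus the net in-frame indel; for frameshifts, any stop
  before the end of the transcript (the reading frame differs, so the
  original stop no longer applies);
* if no stop is reached the report is flagged `ran_off_end`;
* if the start codon itself is destroyed (an edit or an exon-1 skip), the
  next downstream `ATG` is used and the report flagged
  `alternative_start`. This makes the qualitative "shortened ORF" readout
  explicit rather than undefined.

Wildtype protein lengths come from the supplied gene model, never from
constants: the toy genes encode 99 aa (`cxcX`) and 791 aa (`semX`)
proteins so that fixture arithmetic (e.g. an in-frame 15-nt deletion
yielding 94 aa, relative length 94/99) is exercised at the sizes reported
for the real genes.

## Splicing quantification

Every `N` operation overlapping a gene defines a junction keyed by
(donor end, acceptor start), counted once per gap. A junction is
**canonical** iff it exactly matches a boundary of two genomically
consecutive annotated exons; matching is exact (a tolerance parameter
exists but defaults to 0 because simulated and short-read junctions are
base-precise). Everything else -- multi-exon skips, cryptic intronic
donors/acceptors -- is aberrant.

Two normalisations are provided, matching the two ways knockout libraries
are summarised:

* `all_junctions`: aberrant gap counts over all junction gap counts of the
  gene (a per-junction, Sashimi-style measure);
* `from_exon(k)`: among reads whose donor is exon *k*'s end, the fraction
  whose acceptor is not exon *k+1*'s start (each read counts once). With
  length-proportional read sampling this estimator is unbiased for the
  molecular skip fraction, which is why the generator's recovery checks
  use it.

Genomic-amplicon reads have no `N` operations and therefore never enter
splicing denominators.

## Expression quantification

`countReadsMasked()` counts a read when at least one aligned (`M`) base
overlaps a retained exon -- union-exon semantics; `N` and `D` segments are
not overlap evidence. Masking removes the exons that are amplified from
genomic DNA (for the 10-exon toy gene, exons 2 and 10), whose read counts
reflect the amplicon, not the transcriptome. The per-sample library size
is the total counted reads over the full, unmasked annotation.

FPKM is computed as
$$\mathrm{FPKM} = \frac{\text{count}}{\text{library size}/10^6 \cdot
\text{effective length}/10^3},$$
with the effective length of a gene carrying a declared exon-skip isoform
given by the mixture
$$L_\mathrm{eff}(r) = r\,L_\mathrm{skip} + (1-r)\,L_\mathrm{full},$$
where $r$ is that sample's aberrant-splicing fraction (for the toy 3-exon
gene, $L_\mathrm{full} = 1342$ bp and $L_\mathrm{skip} = 1224$ bp, exon 2
being 118 bp). For masked genes *without* a declared skip isoform no
reliable effective length exists, and the pipeline deliberately refuses to
report FPKM for them (CPM is still provided); this mirrors standard
practice when amplicon-masked annotations distort transcript length.

## Single-cell QC and markers

Libraries fail QC when (i) library size or (ii) the number of detected
genes falls more than `nmads` (default 3) median absolute deviations below
the dataset median, or (iii) the ERCC spike-in count fraction rises more
than 3 MADs above it. The MAD uses the 1.4826 normal-consistency constant
and is computed on raw values; all three medians are taken jointly over
the whole dataset. A zero MAD degenerates the threshold to the median
(strict inequality, so ties pass) with a warning -- empty wells simply
fail as ordinary samples. Genes with mean count below 0.1 across all
cells, and genes on exclusion lists (mitochondrial, cell-cycle,
user-supplied), are removed by `filterGenes()`.

Marker positivity defaults to FPKM > 0: with deeply zero-inflated
plate-based data, any detected expression is the natural cut, and the
threshold is exposed for sensitivity analysis. The `log2Offset` (default
1, i.e. `log2(FPKM + 1)`) is recorded for display only and never used in
classification. Combination fractions per group sum to 1 once the "none"
class is included.

## Group comparisons

`welchT()` implements Welch's unequal-variance t statistic with
Welch--Satterthwaite degrees of freedom and two-sided p-values. It is
written out as the textbook formula (and cross-checked against
`stats::t.test` to 1e-10 in the tests) because the degenerate
zero-variance case must be computed as defined with a warning rather than
rejected. No multiple-testing correction is applied at this level.

## The synthetic-data generator

`simConfig()` + `simulateReads()` emulate the library design the pipeline
targets: 75-bp reads; per-gene spliced mRNA reads whose junction-spanning
subset carries `N` gaps; genomic-amplicon reads constrained to span the
guide window; log-normal library-size factors (sd 0.3); ERCC-like spike
genes at a configurable count fraction (default 5%); and per-sample
editing truth with programmable alleles (indels, substitutions, split-read
large deletions). Key design points:

* **Editing truth** comes in two modes. A scalar `editedFraction` is the
  per-cell probability of carrying an edit, with the edited site drawn
  uniformly (the single-cell knockout setting, where both guides
  contribute); a named per-site vector draws sites independently (the
  bulk mosaic setting). `forcedEdited` fixes the truth outright for
  emulating a specific cohort.
* **Isoform mix**: reads are sampled length-proportionally from the
  full-length and exon-skip transcripts at molecular ratio
  `aberrantSpliceRatio`, so the `from_exon` estimator is unbiased.
* **Allele propagation**: one haplotype block map per sample feeds both
  amplicon and mRNA reads, so every read overlapping a guide window
  carries the truth allele exactly when the sample is edited.
* **Errors** are substitutions only, never indels, and never fall on
  allele positions or inserted bases, keeping truth/call discordance
  attributable to the caller.
* **Large deletions** are emitted as primary + supplementary split
  alignment pairs flanking the two cuts; the gene's mRNA is suppressed in
  such samples (the transcript is destroyed), keeping reads consistent
  with truth.
* **Determinism**: a configuration (including its seed) fixes the SAM and
  manifest byte-for-byte.

What the generator does **not** model: base-quality scores, PCR
duplicates beyond a flag, indel sequencing errors, alignment ambiguity or
soft-clip artifacts around true indels, paired-end insert-size structure,
and expression heterogeneity between cells beyond library-size scaling.
Passing recovery tests therefore demonstrate correctness of the
*computations* on well-aligned input, not robustness to aligner artifacts
on real data.

## Validation sizes and conditions

The packaged checks run at sizes chosen to make stochastic bounds tight
while keeping the suite quick: editing-fraction recovery on 200 simulated
cells x 2 guide sites at amplicon depth 30 (error-free, and at 1% error
with `minSupport = 2`, `maxErrorFrac = 0.1`); allele calling against an
independent base-by-base projection oracle on 1,000 random CIGAR
fixtures; splice-fraction recovery at ratio 0.2 with over 10,000 junction
reads (three-binomial-SD bound) and an exact zero on canonical-only
simulations; 1,000 random indels against a brute-force codon scan; and QC
against brute-force reimplementations on random 50 x 20 matrices. A
17-cell cohort emulation (14 with site coverage, 7 of them edited, nine
cells with multi-junction spliced reads, a 5% molecular skip fraction
keeping per-cell aberrant fractions within ~20%) and a 600-clone mosaic
emulation (per-site read-level editing at 5% and 30%) exercise the
cohort-level summaries end to end.

## Known limitations

One transcript per gene; no genotype likelihoods or quality-aware error
model; read-level editing fractions assume editing status does not change
amplification efficiency; junction matching has no fuzzy tolerance by
default; the paired-end mate of a spanning read is treated as independent
evidence. These are deliberate scope boundaries, not oversights.
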
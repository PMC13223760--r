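---
title: "Detecting and classifying 3' UTR introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying 3' UTR introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrintrons)
```

## The problem

Splicing downstream of a stop codon is classically a death sentence for an
mRNA: an exon junction complex (EJC) deposited more than ~50–55 nt past the
termination codon recruits the nonsense-mediated decay (NMD) machinery.
Transcript catalogues nevertheless contain many isoforms with introns in
their 3' UTRs, and two very different situations produce them:

* a transcript can carry an intron that **only ever occurs in the 3' UTR**
  — its splice sites are used by no coding region of any isoform. We call
  such introns *exclusively UTR* (**e3UI**);
* an early premature termination codon (PTC) can shift the stop codon
  upstream, so that introns that are ordinarily coding introns now sit in
  the annotated 3' UTR. These *CDS-overlapping* introns (**co3UI**) share a
  splice donor or acceptor with a coding intron of some other isoform and
  behave like classical NMD-sensitizing junctions.

Separating the two classes, and measuring how far each 3' UTR intron (3UI)
sits from the stop codon, is the core of this package. Everything else —
assembly filtering, expression thresholds, percent-spliced-out (PSO)
statistics — supports that classification or quantifies its consequences.

## The classification procedure

A query transcript (typically from a short-read assembly, so exon structure
only, no CDS) is compared against a curated reference annotation:

1. **Reference curation.** Only references with transcript support level
   (TSL) 1 or 2 *and* an APPRIS principal or alternative:1/2 tag serve as
   matching targets (`filter_high_confidence()`). Misannotated stop codons
   in the reference propagate directly into 3UI calls, so the target set is
   deliberately strict. The *full* annotation, including low-confidence
   isoforms, still contributes to the two genome-wide indices
   (`reference_indices()`): the set of coding-intron boundaries (donor and
   acceptor positions of every intron between a start and stop codon) and
   the set of all annotated junctions.
2. **Candidate matching.** A reference is a candidate for a query when it
   lies on the same chromosome and strand and its start codon's first base
   falls inside a query exon (`candidate_references()`).
3. **CDS chain match.** The query must reproduce the reference's intron
   chain exactly across the reference's CDS genomic span
   (`cds_chain_match()`): the set of query introns lying wholly inside the
   span must equal the reference's, as exact coordinate pairs. Intron
   retention, extra introns, or shifted splice sites inside the CDS all
   disqualify the pairing. The CDS is always inherited from the matched
   reference; the package never predicts ORFs.
4. **3UI extraction and classification.** Query introns whose donors lie
   strictly downstream (transcript order) of the matched stop codon's last
   base are 3UIs (`utr_introns()`). An intron is **co3UI** when its donor
   *or* acceptor position appears in the coding-boundary index, **e3UI**
   otherwise; it is **novel** when its exact junction appears in no
   reference transcript (`classify_utr_introns()`).
5. **Distance to stop.** Recorded per (intron, matched reference) pair as
   the *spliced* (exonic) distance from the base after the stop codon to
   the intron donor, walked along the query's exons. One transcript can
   legitimately have several distances: with two alternative stop codons in
   two references, the same donor can be, say, 8 nt from one stop and
   135 nt from the other — under the 55-nt rule the first pairing escapes
   the NMD expectation, the second does not. Per transcript the maximal
   distance is flagged, matching how distances are usually summarised.

### Why spliced distance

The 55-nt rule is about the geometry of the mature mRNA — whether the
terminating ribosome displaces the EJC — so intron lengths must not count.
We therefore measure the distance along the query's exons. The genomic
distance is carried alongside (`genomic_distance_to_stop`); the two agree
whenever no intron separates stop and donor, which covers the common case.

### Assembly filters

Merged assemblies carry fragments and debris. `overlap_class()` assigns
each query one of six categories (identical, fragment, contained in an
intron, contained in a UTR, intergenic, overlapping-novel), and
`apply_merge_filters()` keeps only `identical` and `overlapping_novel`
transcripts with TPM > 1 (strict) in at least one sample. Category
precedence is permissive — a transcript is kept if *any* reference
legitimizes it — because the exact containment codes of merge tools are not
fully standardized. Two deliberate choices: identity/fragment tests require
the same strand (an antisense copy is not a "fragment of" a reference),
and a junction-less query lying wholly inside a coding reference's UTR is
classed as UTR containment rather than a fragment, so that category
remains informative.

## Expression filters

`quant_table()` derives gene TPM as the sum of member-transcript TPMs from
the same quantification (the natural choice when no independent gene-level
quantification exists) and transcript/gene fractions. A transcript is
*expressed* in a sample when TPM > 1 and fraction > 0.25, both strict as
printed thresholds. It is *broadly expressed* (`broadly_expressed()`) when
expressed in at least 10% of one condition's samples — the count threshold
takes the ceiling, so 10% of 25 samples means at least 3 — and every one of
its junctions has at least one supporting read summed over all samples.
Aggregating junction coverage across samples (rather than per sample) reads
"evidence of all junctions" as a property of the dataset; a per-sample
variant would be stricter and can be emulated by filtering the count table
first.

## PSO statistics

Event-level inclusion tables (PSI, as produced by event-level splicing
tools for retained-intron events) convert to PSO = 1 − PSI
(`pso_from_psi()`). Per sample, PSO is averaged over the non-missing events
of each class (`sample_average_pso()`), yielding one e3UI and one co3UI
summary value per sample.

`correlate_genes()` then screens every gene: within each condition the
Spearman correlation (tie-aware rank Pearson, two-sided t approximation)
between the gene's normalized expression and the per-sample mean PSO;
Benjamini–Hochberg adjustment over genes; and a Fisher-z comparison of the
two conditions' correlations,

$$z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
{\sqrt{1/(n_1-3) + 1/(n_2-3)}}.$$

Counts are normalized by median-of-ratios size factors
(`size_factors_median_ratio()`, the standard count normalization).
Numerical choices worth knowing:

* fewer than 4 complete pairs, or a zero-variance vector, give a *missing*
  correlation, never a silent 0;
* BH adjustment is stratified per (condition, class) family by default,
  mirroring a per-condition screen; `bh_family = "global"` pools everything
  into one family;
* conditions with fewer than 4 samples are dropped with a warning rather
  than producing unstable coefficients.

## The synthetic fixture generator

`fixture_spec()` + `make_fixture()` produce a complete, seeded test world:
a random genome (GC 0.42, the human-like default) with GT..AG planted at
every intron boundary and ATG/TAA at start/stop codons; a reference GTF
with CDS, stop codons and TSL/APPRIS attributes; a query assembly (exon
features only) realizing each planted class; decoy transcripts (fragments,
intron-contained, antisense) that the merge filters must remove; TPM,
junction-count and PSI tables; and a truth table. Class construction works
by isoform design: an annotated e3UI gains a low-TSL companion isoform
carrying the same post-stop intron (annotated but not a matching target); a
co3UI gains an isoform with a later stop codon so the planted intron sits
inside its CDS; a novel e3UI appears in no reference. Planted UTR introns
default to 60–400 nt (60 nt floor keeps dinucleotide extraction safely
defined) and stop distances straddle the 55-nt rule (8–300 nt).

Expression defaults are log-normal TPM around 20 for planted transcripts
and around 5 for decoys, 25 normal + 25 cancer samples; PSO draws are Beta
with concentration 20, means 0.40/0.50 (normal/cancer) for e3UIs — planted
over-splicing in cancer — and 0.45/0.40 for co3UIs. The regulator plan
targets Spearman −0.34 in normal and +0.11 in cancer against mean e3UI PSO
via a Gaussian rank copula (`make_correlated_quant()`), emulating a strong
negative NMD-factor association in normal tissue that is lost in cancer.

What the generator does **not** emulate: read-level noise and alignment
artifacts, soft-clipped junction errors, isoform-deconvolution uncertainty
in quantification, inter-gene correlation structure, batch effects, or
annotation errors in the reference. Passing the round-trip test therefore
shows the algorithm implements its definitions exactly; it does not show
robustness to misassembly, which on real data is handled upstream and by
the strict reference curation.

## Validation strategy and problem sizes

The test suite checks, among others: exact generator→classifier round trips
(20 seeds × 50 genes); agreement with a literal brute-force classifier
that re-derives every record by enumerating exonic bases (500 random small
loci); invariance of every record under reflecting the locus and flipping
strand; the strict 55-nt boundary; closed-form values for the Fisher-z,
size-factor and BH examples; and 95%-interval coverage of a planted
Spearman −0.34 across 100 replicates of 100 samples. These sizes keep the
full suite under a minute on one core while giving each property hundreds
of independent cases; `scripts/acceptance.R` recomputes the same quantities
from scratch at the same sizes.

## Limitations

* The classifier trusts the reference: a misannotated stop codon in a
  high-confidence reference produces wrong classes and distances, which is
  why curation is strict and configurable (`max_tsl`, `appris_allowed`).
* Stop codons split across exon junctions are stored as their genomic span
  with a flag; all distances use exonic walks so the split is immaterial,
  but BED exports of such codons show the enclosing span.
* `naive_psi()` is a plain count ratio for synthetic work, not a
  replacement for a model-based event quantifier.
* GFF3 input, liftover and alignment-file processing are out of scope; the
  GTF dialect is Ensembl's (CDS excludes the stop codon).
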
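---
title: "Methods: small-RNA profiling and differential expression in mirtestis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA profiling and differential expression in mirtestis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtestis)
```

mirtestis re-implements, at desk scale, the computational chain used to
compare testis small-RNA libraries between cattleyak (CY, the infertile
cattle x yak hybrid) and yak (YK): preprocessing, annotation, novel-miRNA
discovery, differential expression, target prediction, enrichment, and
RT-qPCR quantification. This vignette records the models behind each
stage, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The synthetic study generator

`simulation_config()` fixes the study conditions; `simulate_libraries()`
and `simulate_fixtures()` deterministically derive the same "world" from
one seed, so libraries, genome, catalogs, UTRs, term table and Ct table
are mutually consistent.

The defaults emulate the six-library design of the motivating study:
3 CY + 3 YK libraries; read lengths 10-50 nt with two density peaks, one
at 22 nt from miRNAs and one near 30 nt from piRNA-like background tags;
known miRNAs planted in the annotation catalog; novel precursors planted
in a toy genome; and per-group expression ratios planted for a subset of
miRNAs. Specific choices, made once:

* **Replicate counts are negative binomial** (`dispersion = 0.1`, the
  conventional RNA-seq scale). The motivating study reports no replicate
  noise model; NB is the field standard. Expected per-tag proportions
  combine a lognormal abundance weight with the planted CY/YK ratio.
* **Library composition**: known miRNAs carry 35% of reads, novel matures
  5%, unannotated background 60% — echoing the dominance of unannotated
  tags in real testis libraries. At the default depth of 20,000 reads per
  library a typical known miRNA has a per-library mean count around 100.
* **Planted fold changes** default to ratios 4, 5, 6, 8 for up-regulated
  and their reciprocals for down-regulated miRNAs — far enough from the
  ratio-2 calling threshold that recovery measures the pipeline, not luck,
  and the remaining miRNAs are null (ratio 1).
* **Adapters** are ligated 3'-only; each read is the tag plus the full
  adapter truncated at 50 nt, matching single-end small-RNA read
  structure. Quality strings are constant Phred 40.
* **Novel precursors** are mature + loop (14-17 nt) + star (the reverse
  complement of the mature with 2-4 mutations, leaving most arm bases
  pairable). Each planted locus is re-checked with the pipeline's own
  window-excision and hairpin assessment before it is committed to the
  genome, and redrawn if it fails — the ground truth thereby satisfies its
  own invariant that every planted precursor folds under the package's
  folding model.
* **The Ct table encodes planted relative expressions exactly** under the
  2^-ddCt model (reference gene constant, target shifted by -log2(ratio)
  in the case condition), so the qPCR stage has an exact expected answer.

What the generator does **not** emulate: sequencing errors, quality-score
variation, PCR duplicates, multi-mapping repeat structure, isomiR 5'/3'
heterogeneity beyond what the homogeneity filter needs, and any real
genome or annotation content. Passing tests therefore demonstrate correct
computation under idealized inputs, not robustness to real-data artifacts.

## Preprocessing

Reads are dropped when mean Phred < 20 (configurable); the 3' adapter is
removed at the rightmost position where an adapter prefix of at least 8 nt
matches the read suffix with at most 1 mismatch per 10 adapter bases — a
standard trimming rule, stated here because the motivating study names
only its toolkit, not its parameters. Reads outside 10-50 nt or with any
N (configurable) are discarded. Collapsing to unique tags preserves
per-sample counts; by construction tag counts and the length histogram
both sum to the clean-read totals, and the test suite asserts these
conservation identities at 10^4-read scale.

## Annotation

Tags of 18-35 nt are compared as ungapped substrings of every catalog
reference (sense strand, Hamming distance, no indels) with a two-mismatch
tolerance. The fewest-mismatch hit wins; equal-best hits in two or more
categories are reported as AMBIGUOUS — never resolved by category
precedence, since ambiguously annotated tags are a reporting class of
their own. Tags outside 18-35 nt remain unannotated (the cleaning window,
10-50 nt, is deliberately wider than the classification window). The
scanning kernel is compiled; an R-level brute-force scan serves as the
oracle in the tests.

## Folding model and novel-miRNA discovery

The built-in folding engine is an energy-minimizing, Nussinov-style
dynamic program over pseudoknot-free structures: pair energies G:C -3,
A:U -2, G:U -1 (kcal/mol by convention), minimum hairpin loop 3 nt, ties
broken deterministically (5'-most base unpaired first). This model was
chosen because it is exhaustively verifiable — the tests enumerate all
nested structures for sequences up to 18 nt and demand exact agreement —
and adequate for hairpin topology and MFEI screening. It is not a
thermodynamic nearest-neighbor model; absolute energies differ from
ViennaRNA-style values, and a thermodynamic engine can be substituted via
the `backend` argument of `fold_rna()` and `call_candidates()` under the
same contract.

Discovery proceeds: unannotated tags are exactly mapped to both genome
strands (tags with more than 15 loci are discarded as repetitive); each
locus is excised in two windows (tag at the 5' arm extending 70 nt
downstream, tag at the 3' arm extending 70 nt upstream — `flank`
configurable); each window is folded and assessed. A candidate passes
when:

1. at least `min_paired_fraction` (0.6) of tag bases pair, with at least
   90% of those partners on one side of the tag (the star region);
2. the loop between arm and star is 3-60 nt;
3. the excised precursor (arm span plus 5 nt padding, 50-150 nt),
   re-folded alone, forms a single hairpin — exactly one terminal loop
   after ignoring isolated lone pairs, which are spurious under a
   maximum-pairing model;
4. MFEI = (MFE / length x 100) / GC% <= -0.85 on the re-folded precursor
   (the standard MFEI convention; the motivating study names the index
   without printing a formula);
5. 5'-end homogeneity — the count-weighted fraction of supporting reads
   (those overlapping the mature arm by at least half their length)
   sharing the modal 5' end — is at least 0.8, the hallmark of precise
   Dicer processing.

Candidates are merged by precursor identity, overlapping same-strand loci
collapse to the best-supported window, and survivors are named
`{species}-novel-miR-{serial}`. On the default synthetic conditions all
12 planted precursors are recovered, while dinucleotide-shuffled decoys
(Altschul-Erickson shuffle, preserving exact dinucleotide composition)
pass the same filters in well under 5% of trials — the discrimination
comes almost entirely from the single-hairpin topology and
one-sided-pairing requirements, since shuffled sequences still pair
abundantly under a maximum-pairing model.

## Differential expression

Replicates are pooled per condition: the tables of the motivating study
print one TPM per group, and its p-value formula takes one count per
group. TPM is `count / clean_total x 1e6` on pooled counts and totals.
The fold change is the **plain TPM ratio** CY/YK; the study's Methods
label the quantity log2, but every printed table value is the ratio
(e.g. TPMs 40.5238 / 3.391165 printed as fold change 11.94982), so the
ratio is implemented and its log2 emitted alongside, with the
">2 or <-2" threshold read as ratio > 2 or < 0.5.

The exact test evaluates the Audic-Claverie conditional distribution

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}$$

on raw pooled integer counts (the factorial form requires integers; TPMs
are reporting-only). Tails are summed in log space; whichever tail is
short is summed directly (the lower tail has y+1 terms; the upper tail is
summed in chunks from y upward and truncated once past the distribution
mode with terms below 1e-16 of the running sum), and the other tail is
recovered through the identity C + D - p(y|x) = 1. The two-sided p-value
doubles the smaller tail, capped at 1. Because p(y|x) is exactly the
negative-binomial pmf with size x+1 and success probability N1/(N1+N2),
`stats::pnbinom` provides an independent oracle; agreement is better than
1e-12 across the full X, Y in [0, 200] grid at totals 10^3 and 10^6.

Two calibration notes. First, the test models Poisson sequencing sampling
of pooled counts; its null calibration is therefore measured on Poisson
draws at matched depths (fraction of p < 0.05 about 0.04-0.05 at 2,000
simulated miRNAs). Between-replicate biological overdispersion is outside
the test's model — pooled NB counts would inflate rejections by
construction, which is a property of pooling, not an implementation
defect; a dispersion-moderated per-replicate test is deliberately out of
scope. Second, direction calls gate on the raw p < 0.05 (as the
motivating study's criteria state) while BH-adjusted FDR is reported
alongside.

## Target prediction

Sites are anchored at exact Watson-Crick reverse complements of the miRNA
seed (positions 2-8; `seed_min` 7 requires the full anchor). Each anchor
window (the anchor plus the remaining miRNA span with 4 nt slack) is
aligned to the reversed miRNA by a Gotoh affine-gap alignment, global in
the miRNA with free target end gaps. Scoring follows published miRanda
conventions — match +5, G:U +2, mismatch -3, gap open -9, gap extend -4 —
with substitution scores of miRNA positions 1-11 multiplied by 4. The
weight is 4 rather than the factor 2 one might guess because a perfect
22-nt duplex must clear the score threshold of 172: at weight 2 it scores
only 165 and even a perfect site would vanish, while at the published
scale of 4 it scores 275. Duplex energy sums the folding model's pair
energies over aligned pairs (G:C -3, A:U -2, G:U -1) — an explicit
approximation whose absolute values differ from RNAduplex-style energies
but order sites sensibly at desk scale; thresholds are score >= 172 and
energy <= -20.00 (the alternative -20.09 appearing elsewhere in the
motivating study's text is available as a configuration value).
Overlapping sites resolve to the best score, and "number of genomic
targets" counts transcripts with at least one passing site, not sites.

## Enrichment

For target set of size n in an annotated background of N genes, a term
with M annotated genes and m target members gets the upper-tail
hypergeometric p-value; the implementation sums the tail terms
i = m..min(n, M) in log-gamma arithmetic — algebraically identical to the
1 - sum_{i<m} form but numerically stable where P is small, which is
exactly where enrichment decisions live. Bonferroni multiplies by the
number of tested terms (terms with at least one annotated background
gene), thresholding corrected p <= 0.05. Target genes outside the
background are dropped and counted. Term hierarchies (ancestor
propagation) are not modeled; the term table is taken as given. The test
suite checks exact agreement (1e-12) with exhaustive urn enumeration for
every instance with N <= 12.

## RT-qPCR

`ddct()` averages technical replicates arithmetically per (sample, gene),
forms dCt = Ct(target) - Ct(reference) per sample, ddCt as the difference
of condition means, and fold = 2^-ddCt with amplification efficiency
fixed at 2. SEM is computed across case-sample fold values
2^-(dCt - mean control dCt). Scale invariance (per-sample Ct shifts
cancel) and reciprocity (swapping conditions inverts the fold) are tested
properties. Reference genes follow the assay class: RPS18 for miRNA
assays, beta-actin for mRNA assays.

## Problem sizes and determinism

Defaults were sized for interactive use: 20,000 reads per library across
six libraries, a toy genome of a few kilobases with 12 planted
precursors, 40 UTRs, 12 terms. The full test suite, including the
grid-scale exact-test oracle and the 200-trial shuffle study, runs in a
few minutes on one core. All generator randomness flows from the single
config seed through an internal scoped-RNG helper, so identical seeds
give byte-identical libraries and pipeline outputs without touching the
caller's RNG state.

## Known limitations

* The folding and duplex energies are a simplified pair-energy model;
  candidates and sites should be re-scored with a thermodynamic backend
  before any biological claim.
* Annotation is sense-strand, ungapped, Hamming-only; indel tolerance (as
  some commercial aligners allow) is not modeled.
* Pooled exact-test p-values ignore replicate dispersion (see above);
  they are anti-conservative for genuinely overdispersed data.
* The generator's idealizations (no sequencing error, exact plants) mean
  recovery rates reported here are upper bounds on real-data behavior.
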
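---
title: "PanSV: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PanSV: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PanSV detects structural variation (SV) in a panel of resequenced
accessions from three intercrossable poplar species — *Populus nigra* (Pn),
*P. deltoides* (Pd) and *P. trichocarpa* (Pt, the reference species) — and
composes the resulting catalogue into a pan-genome with core and dispensable
fractions. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the design was genuinely open.

## Signals and models

### Paired-end mapping (PEM) deletions

A sequencing library with insert sizes around a mean $\mu$ and standard
deviation $\sigma$ (defaults 500 bp and 50 bp, emulating a 400–600 bp gel
fraction sequenced as 2×100 bp pairs) produces, over a deletion, read pairs
whose inferred span on the reference is inflated by the deletion length.
`findDiscordantPairs()` labels a pair deletion-type when its span exceeds
$\mu + 3\sigma$; the insert model is either supplied or estimated as the
median ± scaled MAD of concordant spans (at least 100 pairs required).

Two detector emulations then cluster deletion-type pairs whose implied
deleted intervals overlap:

* **Detector A** reports the innermost read edges of the cluster as
  breakpoints and filters on length 1–25 kb, support ≥ 5 pairs, and median
  mapping quality ≥ 20.
* **Detector B** intersects the pair-compatible breakpoint regions (bounded
  by the maximum concordant gap) and reports the interval **centers**; it
  applies the same length and support filters but no mapping-quality filter.

The two detectors deliberately differ exactly where the tools they emulate
differ — breakpoint precision and the MAPQ filter — because the layer under
test here is the merging/filtering/genotyping logic, not the external
callers. Per-sample calls from A and B whose ±250 bp breakpoint windows
overlap at both sides are combined into one event that takes A's breakpoints
(A is the more precise estimator by construction). Calls across samples are
merged by single-linkage chaining at ±500 bp (deletions) or ±250 bp
(insertions); a merged event takes the coordinates of its best-supported
member, ties broken by leftmost coordinate, making the catalogue independent
of sample order.

### TE insertions from anchor/mobile pairs

A pair spanning a transposable-element (TE) insertion has one read (the
*anchor*) in unique flanking sequence and its mate (the *mobile* read)
inside the inserted element, where it cannot be placed uniquely. Anchors
form two clusters in opposite orientation pointing toward the insertion
site. `detectTeInsertions()` calls a site when a forward-strand cluster and
a downstream reverse-strand cluster (gap at most the insert mean) each
contain at least `minAnchors` anchors (default 3 per side, chosen to keep
the false-positive rate at zero across the 25–45× depth range of the study
design; the value is exposed as a parameter because no published value
exists for the emulated pipeline). The insertion is reported as the interval
between the cluster edges and never resolved to a single point; gene overlap
for insertions consequently requires the *entire* interval to fall inside
the gene.

Mobile mates are matched against a TE database (the curated library,
optionally augmented with classified deletion sequences) at ≥ 80% ungapped
identity over the read, on either strand; the site takes the majority
superfamily vote, with ties labeled "unknown" and no-match sites
"unclassified". One subtlety: only truly unaligned mates are treated as
mobile. Reads that align ambiguously to multi-copy reference repeats are
excluded because every reference repeat would otherwise mimic an insertion
site; this is the package's resolution of behaviour unspecified in the
emulated pipeline.

The reported insertion *length* is the length of the best-matching database
element — the inserted sequence — not the width of the predicted interval.
This convention also resolves how insertion span enters the pan-genome
arithmetic (configurable in principle, but the element length is the
quantity the pan-genome size needs).

### Genotyping by supporting-read fraction

For every merged variant and sample, the supporting-read fraction
$f = \text{supporting}/\text{informative}$ is computed from fragments whose
geometry is informative about the site: for deletions, discordant pairs
bridging both breakpoints (supporting) and concordant pairs whose inner gap
spans the left breakpoint (reference allele); for insertions, anchor-bearing
fragments (averaged over the two junctions, so that $f$ estimates the allele
fraction without a two-junction bias) and concordant pairs spanning the
interval. The deliberately symmetric window definitions make $f$ an
(approximately) unbiased allele-fraction estimator: homozygous carriers give
$f \to 1$ and heterozygotes $f \to 0.5$ within binomial error. Calls follow
the fixed thresholds: informative depth < 5 gives no call; otherwise
$f < 0.2$ non-carrier, $0.2 \le f \le 0.8$ heterozygous, $f > 0.8$
homozygous. The low-depth pool is treated as one pseudo-sample: the pooled
frequency of a variant is the same ratio computed across all pool fragments,
and a variant with pooled frequency strictly above 0.9 is "fixed in the
pool".

### Depth-of-coverage genic CNVs

Fragments built from uniquely aligned reads are counted per annotated gene
(`countFragmentsPerGene()`), with fragments touching two genes assigned to
neither — union-style ambiguity discard, documented here because the
counting mode of the original tooling is unspecified. Counts are normalized
by median-of-ratios size factors and tested per gene between every unordered
sample pair with an exact conditional negative-binomial test: conditional on
the pair total $k = k_A + k_B$, the two-sided $p$ sums the probabilities of
all splits no more probable than the observed one, with means $s_A\hat\mu,
s_B\hat\mu$ (pooled normalized mean $\hat\mu = (k_A/s_A + k_B/s_B)/2$) and a
common dispersion $\alpha$; $\alpha = 0$ reduces to the Poisson limit. The
original description says "binomial test" but cites the DESeq package, whose
published test is this NB construction; the NB form is implemented as the
method actually cited. Benjamini–Hochberg adjustment is applied within each
pair (a global scope is available), significance is adjusted $p < 0.05$, and
the union of significant genes over pairs is the genic CNV set.

Dispersion is estimated by per-gene method of moments,
$\hat\alpha = \max(0, (v - m)/m^2)$ on normalized counts, smoothed by the
parametric trend $\alpha(\mu) = a_0/\mu + a_1$ and made conservative by
taking the per-gene maximum of raw and fitted values. The trend is fitted on
all expressed genes with one outlier-trimming pass so that genes whose
variance is dominated by genuine copy-number differences do not drag the
trend up. A known limitation inherited from the emulated sharing mode: a
gene's own CNV signal inflates its raw dispersion estimate, so tests run
with estimated (rather than known) dispersion are conservative for exactly
the genes one hopes to detect.

### TE annotation and LTR dating

Deletion sequences are classified by a three-step cascade, each step
consulted only if the previous one failed, with the evidence step recorded:

1. **Annotation overlap** — annotated repeat bases of one superfamily cover
   ≥ 50% of the deletion (the overlap threshold is not stated by the
   original description; 50% was chosen once as a permissive first pass
   matching the interpolation intent).
2. **Library scan** — local alignments against the curated TE library tile
   ≥ 80% of the sequence.
3. **Homology search** — hits at E ≤ 1e-20 against the full database cover
   ≥ 80% of the length *or* both 400 bp extremities (sequences under 800 bp
   can only satisfy the length rule).

The search engine is a seeded ungapped-extension local aligner with
Karlin–Altschul E-values under +1/−2 scoring ($\lambda = 1.33$,
$K = 0.62$), written in-package so that the E-value threshold keeps its
meaning without an external BLAST dependency. Ties between database hits are
broken by bit score, then coverage, then label, for determinism.

LTR retrotransposons are dated from the divergence of their two terminal
repeats: the K2P distance
$K = -\tfrac12 \ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ over ungapped aligned
columns (transitions $P$, transversions $Q$), converted to years by
$T = K/(2k)$ with $k = 4.72\times10^{-9}$ substitutions/site/year. The
printed form of the rate in the source material is garbled
("4.72 2 × 10^−9"); it is implemented as $4.72\times10^{-9}$ and exposed as
a parameter. Saturated alignments ($1-2P-Q \le 0$ or $1-2Q \le 0$) are an
explicit error rather than a silent NA. Age distributions of SV-associated
versus other elements are compared with the two-sample two-sided
Kolmogorov–Smirnov test.

### dN/dS

The Li-style comparative estimator classes every codon position as
non-degenerate, two-fold (including three-fold) or four-fold, averaging the
class over the two codons; transitions and transversions per class are
K2P-corrected into components $A_i$ (transition) and $B_i$ (transversion)
and combined as $dS = (L_2A_2 + L_4A_4)/(L_2+L_4) + B_4$ and
$dN = A_0 + (L_0B_0 + L_2B_2)/(L_0+L_2)$. Pairs must align in frame over at
least 150 bases; internal stops reject the pair with the reason recorded;
$dS = 0$ leaves the ratio undefined (reported missing) rather than infinite.

### Randomization and distribution statistics

Gene-overlap expectations for variants come from transferring the observed
variants (lengths preserved) to uniform random positions within single
chromosomes, 100 replicates by default, with empirical 2.5%/97.5% bounds.
Window enrichment uses a Poisson null with mean equal to the average events
per window (genome-wide or per chromosome), BH-adjusted. Repetitiveness of a
window is the mean genome-wide occurrence count of its 20-mers, counted
strand-collapsed (canonical k-mers; the source is silent on strand, and
repetitiveness is strand-symmetric); carrying versus empty windows are
compared by two-sided Wilcoxon–Mann–Whitney. Genic-CNV clustering and
telomere-distance tests follow the window/bin constructions directly, with
bins of expected count < 1 merged into their neighbour before the
chi-square. Expression uses FPKM with the "expressed" flag meaning FPKM > 0
in at least one of four tissues, and the mean FPKM across tissues enters the
contrast.

Mean contrasts (expression, dN/dS) against random gene subsets use
$p = (q+1)/(s+1)$ with $q$ the count of replicates *as or more extreme in
the tested direction* and $s = 10{,}000$ by default. The printed bookkeeping
in the source ($r = s - q$ with $q$ counted as "exceeded"/"was lower")
assigns $p \approx 1$ to exactly the tails reported as significant if read
literally; the standard convention is therefore the default, and the literal
formula is available behind `literal = TRUE` for auditing.

### Species patterns and the pan-genome

A variant's species pattern is the set of species with at least one carrier.
Because the design has four Pn but only two Pd accessions, classification is
repeated for every pair of two Pn accessions (6 combinations) and the
category tallies averaged; the per-combination labels are always returned so
either convention can be audited. A variant is *fixed* when every genotyped
sample of its carrier species is a homozygous carrier.

The pan-genome is reference span + inserted-sequence span. The dispensable
fraction is the merged deletion span plus insertion span, excluding variants
carried homozygously by every genotyped accession — with the reference
individual in the panel, such variants are reference-assembly artifacts, not
dispensable sequence (runs of ≥ 100 N under homozygous deletions, indexed by
`findAssemblyGaps()`, support the same reading). Core = pan − dispensable,
exactly, by construction. Heterozygous-only variants do contribute to the
dispensable span: the sequence is absent from at least one haplotype set.
Species-specific contributions are the merged spans of the pattern-specific
variant sets as fractions of the pan-genome.

## The synthetic study

`simulateStudy()` generates the whole study with exact ground truth. The
defaults are the study conditions and are not tuned per run:

* 3 chromosomes × 1 Mb, 300 non-overlapping genes with CDS/UTR/intron
  structure, 30 TE families over the common plant superfamilies (LTR
  Gypsy/Copia with identical 300 bp terminal repeats, LINEs, SINEs, hATs,
  Helitrons, CACTAs, …), ~25% of the genome as planted repeat copies at 2%
  divergence from their consensus;
* 60 deletions (1–25 kb; 60% placed exactly over class II repeat copies,
  class I elements move copy-and-paste and are planted only as insertions),
  60 TE insertions, 40 genic CNVs; variants at least 1 kb apart;
* a panel of 4 Pn + 2 Pd + 1 Pt at 30×, optionally 15 Pn pool members at
  5×; species patterns drawn with Pn/Pd sharing at ~12–14%, rare
  three-species and Pt-sharing categories, and fixation probabilities of
  0.78 (deletions) and 0.62 (insertions) for Pn/Pd-involving variants,
  mirroring the reported pooled fixed fractions; the Pt reference individual
  carries only heterozygous variants unless a reference-error fraction is
  configured;
* 2×100 bp pairs at insert 500 ± 50; per-gene baseline counts log-normal
  around 150 with NB dispersion 0.01 — depth-of-coverage fragment counts are
  near-Poisson with mild overdispersion, unlike RNA-seq between biological
  replicates.

Alignment is **emulated, not executed**: each fragment is placed on a
haplotype and mapped to the reference analytically through the planted
variant ledger, so pairs spanning deletions acquire exactly inflated
inserts, reads inside inserted elements become unaligned mobile mates with
their sequence retained, junction-crossing reads are treated as clipped, and
reads wholly inside repeats of multi-copy families get MAPQ 0. This keeps
the truth exact and removes any aligner dependency. Consequences worth
knowing:

* there is no base-calling error: the callers under test consume positions,
  not base identities, and the only sequence the records carry is the
  mobile reads' (used for TE classification, where the planted 2% copy
  divergence already exercises the identity threshold);
* duplicates are not injected (the emulated data are post-deduplication);
* insertion points are planted outside multi-copy repeat intervals, because
  a site without uniquely alignable flanks is undetectable by *any*
  anchor-based method — real TE insertions do nest into repeats, so recall
  measured here is recall at resolvable sites;
* genic CNV truth lives at the fragment-count level (planted copy numbers
  feed the NB count generator) rather than as tandem duplications in the
  haplotype sequences — the depth-of-coverage caller consumes counts, and
  sequence-level duplications would exercise no additional code path.

Passing recovery tests on these data therefore demonstrates the correctness
of the clustering, merging, filtering, genotyping and composition logic
under the study's depth and insert-size conditions; they do not demonstrate
robustness to alignment artifacts, base errors, or repeat-nested insertions.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based closed throughout (the IRanges
  convention), so GFF3 and SAM cross the package boundary without
  conversion; the alignment TSV dialect is documented as 1-based closed.
* Detector clustering uses reduce-based connected components
  (single-linkage); the cross-sample merge's support ties break by leftmost
  coordinate.
* The NB exact test enumerates all $k+1$ splits directly (totals at desk
  scale are a few thousand at most); $k = 0$ gives $p = 1$.
* Window tiling truncates the last window at the chromosome end, so windows
  always partition the genome; empty Wilcoxon groups skip the test with a
  notice; chi-square bins with expected < 1 merge into a neighbour.
* Randomization p-values are bounded in $[1/(s+1), 1]$ and seed-reproducible.
* A tissue with zero mapped fragments yields FPKM 0 everywhere rather than
  a division error.

## Problem sizes

The default test and acceptance runs use the 3 Mb / 7-sample / 30×
configuration above (about 6.4 million simulated reads), a 200-gene ×
6-sample count matrix for the CNV power and null checks, 100 ortholog pairs
of 300 codons per planted ω, and exhaustive-enumeration oracles on fixtures
of at most 20 elements. These sizes were chosen so that every recovery
property is measured with comfortable margins while a full run stays within
minutes on one core.
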
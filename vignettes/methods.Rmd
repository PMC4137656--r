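---
title: "Methods: pairwise divergence and prophage decay in close bacterial genome pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise divergence and prophage decay in close bacterial genome pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiverge)
```

`orthodiverge` compares two very closely related annotated bacterial
genomes — the situation typical of endosymbiont strain pairs such as the
*Wolbachia* strains of different *Drosophila* hosts, which can sit at well
under 1% nucleotide divergence while differing by tens of kilobases of
prophage DNA. The pipeline answers four questions: which genes are
orthologous, how far have they diverged (and when did the strains split),
which genes are under unusual divergence or positive selection, and what
happened to the prophage regions and gene order.

This vignette documents the methods, the tunable parameters, the
synthetic-data generator used for validation, and the numerical and design
choices a maintainer would want spelled out.

## Orthology: reciprocal best hits over an internal aligner

Candidate homolog pairs are discovered by exact k-mer seeding (default
k = 12; query positions subsampled every 16 bp) and scored by global
Needleman–Wunsch alignment with affine gaps (Gotoh three-state dynamic
programming, implemented in C++). Default scoring is match +2, mismatch
−3, gap open −5, gap extend −2 — a standard nucleotide scoring shape whose
exact values are immaterial at 99% identity but are pinned for
determinism. A gap of length $k$ costs $\mathrm{open} + k \cdot
\mathrm{extend}$; `N` scores as a mismatch against everything, including
another `N`, and never counts toward identity.

A candidate hit must reach 60% identity over at least 50% of the shorter
CDS. A pair is orthologous when each gene is the other's best-scoring hit
(RBH); tied best hits are recorded as ambiguous and broken toward the
lexicographically smallest locus tag, so multi-copy families surface
explicitly rather than silently. This internal criterion replaces an
external homology-search step: at the divergence scale this package
targets, any conventionally significant hit clears the 60%/50% floor with
a wide margin, so the substitution is conservative; both thresholds are
exposed.

Missing genes (the basis of the genome-reduction report) are reference CDS
with no placement anywhere in the target scaffolds at those same
thresholds, searched on both strands. As an optimization, a gene whose
sampled exact 12-mers match one scaffold diagonal over more than 60% of
its length is accepted as present without the placement alignment — exact
seeds over most of the gene imply identity far above the floor — and only
borderline cases pay for a full glocal (global-in-gene, local-in-scaffold)
alignment.

## Divergence: Nei–Gojobori counting with Jukes–Cantor correction

Codon-level divergence uses the Nei–Gojobori (1986) counting scheme with
equal-weight pathway averaging:

* **Sites.** Each codon position contributes up to one site, split 1/3
  per possible single-nucleotide change; a change is synonymous or
  nonsynonymous under the standard genetic code (start codons simplified
  to ATG). Changes that would create a stop codon are excluded and their
  1/3 weight removed from both $S$ and $N$, so $s + n \le 3$ per codon
  with equality exactly when no neighbor is a stop. Sites are averaged
  over the two sequences.
* **Substitutions.** Differences within a codon are decomposed into all
  single-step pathways; each step is classified and counts averaged over
  pathways with equal weight. Pathways through stop codons are excluded;
  in the (rare) case that every pathway is excluded, differences are
  classified by direct per-position substitution and flagged.
* **Distances.** $p_S = S_d/S$ and $p_N = N_d/N$ receive the
  Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$.
  $\omega = K_a/K_s$ is *undefined* (never 0 or $\infty$) when $K_s = 0$,
  and genes with $p_S \ge 0.75$ are flagged saturated.

Alignments are partitioned into codons on the frame of an anchor sequence;
codons containing alignment gaps, `N`, or a stop codon are dropped and
counted, and a gap run whose length is not a multiple of 3 makes the frame
unrecoverable (the gene is excluded as `frame_break`). Genes with fewer
than 30 comparable codons are excluded (`too_short`), matching the
30-amino-acid floor used in this kind of analysis.

Genome-wide ("concatenated") divergence pools $S_d, N_d, S, N$ across
eligible genes before a single Jukes–Cantor correction. Integer SNP
totals are reported alongside: a SNP is counted synonymous when its
pathway-averaged synonymous weight exceeds 1/2 (exact ties count 0.5
each way) — a pinned, deterministic mapping from the fractional NG86
classification to the integer counts this field reports. Both filtered
(eligible genes only) and unfiltered totals appear in the report, since
published totals rarely state which convention they use. The mean
per-gene $\omega$ is the unweighted mean over genes with defined
$\omega$; a codon-weighted mean is also reported. Note that at very low
divergence the per-gene mean is biased downward relative to the pooled
ratio: genes with $K_a > 0, K_s = 0$ drop out as undefined while their
mirror image contributes 0 — the pooled (concatenated) $K_a/K_s$ is the
stable statistic.

Divergence dating uses a synonymous molecular clock,
$T = K_s\% / r \times 10^6$ years with $r$ in percent per Myr (default
0.9, the established *Wolbachia* synonymous rate). Times are reported raw
and at two significant figures; percentages are reported at one decimal.

## Selection screen and outgroup polarization

The divergent-gene screen reports ortholog pairs with identity strictly
below 98% (identity is identical columns over all alignment columns, gaps
non-identical), sorted by identity then locus tag. The positive-selection
flag requires a *defined* $\omega$ strictly above 1; undefined entries are
listed separately, mirroring the "–" convention of published tables.
Thresholds are strict inequalities because the published screens they
reproduce say "less than" and "greater than".

Indel events are maximal gap runs, attributed to the side gaining
sequence, with the net-length identity (insertions minus deletions equals
the length difference) asserted on every call.

For flagged genes, derived alleles are polarized against an outgroup: gene
B and the outgroup gene are each aligned onto gene A and projected into
A's coordinates — a deterministic progressive construction that is
adequate below ~3% divergence, where a full multiple alignment would add
machinery without changing columns. At each A/B difference the outgroup
allele either matches A (B's allele derived), matches B (A's derived), or
is unpolarizable (third allele, gap, or missing outgroup gene). Indel
columns are excluded from the site count and reported separately. A
lineage is called derived-enriched only on a strict majority of all
diverged sites.

## Prophage inventory and genome reduction

A target locus is phage-flagged when its ortholog — or, for a detected
gene fragment, its parent gene — belongs to the reference phage locus
set. Prophage regions are maximal runs of phage-flagged loci in genome
order, tolerating up to `gap_tolerance` (default 2) interleaved
repeat-class loci, which are recorded as interrupting members; any other
category breaks the region. Scaffold breaks do *not* break a region:
degraded prophage regions in draft assemblies routinely span several
scaffolds, and repeat-bounded breakpoints are exactly where assemblies
fragment. Region gene counts are ortholog-level: fragments mapping to one
reference gene count once, so a ten-locus run containing two split genes
counts as seven genes — the counting convention used for published
region sizes.

Fragmentation detection emits three causes:

* `premature_stop` — a paired target CDS carries an internal stop in its
  annotated frame while the reference CDS has none (positions in 1-based
  target-CDS nucleotides);
* `split_annotation` — two or more target loci place into disjoint
  segments (under 10% mutual overlap) of one reference CDS, discovered by
  re-aligning unpaired target loci into seeded reference genes;
* `truncation` — a paired target covers under 90% of the reference length
  with flush scaffold sequence beyond the gene (a gene at a scaffold edge
  is an assembly artifact, not a truncation; the margin is 30 bp).

The reduction report classifies each reference phage region (maximal runs
of phage-category reference loci, or regions supplied explicitly) as
intact, reduced, or absent; absent regions are reported with their
flanking loci and the flanks' target orthologs. The census — the number of
reference phage genes retained in the target at ortholog level — is the
headline number of a prophage-decay comparison.

## Synteny

Block logic runs on gene ranks, not base pairs, so indels and length
changes cannot break blocks; bp spans are reported alongside. Target
scaffolds are first ordered by the median reference rank of their
orthologs (scaffolds without orthologs last, by ID). Within a scaffold,
blocks are maximal runs of ortholog pairs whose ranks *among paired genes*
(so lineage-specific gene loss cannot break a run) are
consecutive-monotone, ascending or descending (descending blocks are
reported as inverted), tolerating one unpaired locus between members — a
pinned choice that absorbs lineage-specific repeat insertions without
splitting blocks. A block is flagged displaced when its reference
interval sits more than `displaced_distance` (default 50) gene ranks from
every physical neighbor block and it is the smaller party of the break —
the relocated segment, not the backbone it interrupts.

## The synthetic-data generator

Validation runs on simulated genome pairs with known ground truth. The
generator's defaults describe the study conditions the package is
validated under, each traceable to a published figure for this kind of
strain pair: 1,200 genes of mean length 764 bp with mean intergenic gap
130 bp at 35.2% GC (a ~1.07 Mb genome); pairwise synonymous divergence
`target_ks = 0.0031`; $\omega$ 0.7 in every gene class (close to the
published per-gene mean of ~0.69); repeat-class (transposase/reverse
transcriptase) genes at 6%; three ancestral phage/accessory regions of
34, 29 and 8 genes retaining 21, 7 and 0 genes in the descendant (43
deleted loci in total); two premature-stop fragmentations inside
surviving phage runs; two repeat genes inserted into surviving phage
runs; in-frame indels of 3–189 bp in ~10 genes; one relocated 10-gene
segment; a 43-scaffold descendant assembly with shuffled scaffold order;
and an outgroup that branches before the pair's split at three times the
pair's divergence (a "closest outgroup strain" figure not directly
printed anywhere; it only needs to be large enough to carry ancestral
alleles and small enough to align trivially).

Substitutions are placed codon-aware: per gene and lineage, Poisson
numbers of synonymous and nonsynonymous events with expectations
$k_s \cdot S$ and $\omega \cdot k_s \cdot N$ are realized as uniformly
chosen currently-available synonymous / nonsynonymous single-nucleotide
codon changes (a site-category-aware proposal). Stop-creating changes are
never proposed — premature stops enter only through the fragmentation
process — which keeps realized $\omega$ controllable and measurable by
the same NG86 convention the estimator uses: a placed synonymous event is
exactly a synonymous difference under single-step classification. Indels
are frame-preserving multiples of 3 placed at codon boundaries, drawn
uniformly over the configured range (no indel length distribution is
available to fit, so uniform is a modeling choice, not an inference).
Each lineage's events are recorded site by site with ancestral alleles, so
recovery tests compare against exact truth. One seeded RNG stream drives
each stage in documented order; `generate_ancestor()` seeds `seed` and
`evolve_pair()` seeds `seed + 1`, so both are individually reproducible.

What the generator deliberately does not emulate: codon-usage bias,
transition/transversion asymmetry, rate heterogeneity across sites,
recombination, and sequencing/assembly error. Passing recovery tests
therefore demonstrate that the estimators are correct under a neutral,
composition-matched model — not that they are robust to every property of
real data. In particular, NG86 with Jukes–Cantor undercounts synonymous
divergence when transitions dominate; at 0.3% divergence the absolute
effect is far below the statistical noise of a single genome pair, which
is why the simpler estimator is the appropriate one here.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GenBank/GFF3 and IRanges
  convention), in memory and on file. Joined/compound CDS locations are
  out of scope for these intron-free genomes and raise an error rather
  than silently mis-extracting.
* A CDS whose length is not a multiple of 3 loads with a `frame_warning`
  flag rather than being dropped — draft annotations contain such
  records, and downstream stages exclude them per-analysis with a stated
  reason.
* Alignment tie-breaking is deterministic (diagonal preferred over gaps at
  equal score); RBH ties are deterministic (smallest tag); screens sort
  deterministically; the pipeline report contains no timestamps, so a
  rerun under one seed is byte-identical.
* The banded alignment option (used with a ±200 band inside RBH, where
  seeds guarantee near-diagonal optima and the largest expected indel is
  189 bp) is an optimization only; the exported aligner defaults to the
  full matrix.
* Gene categories come from an annotation attribute (`category=<x>` in
  GFF3, `/note="category:<x>"` in GenBank); absent categories default to
  `hypothetical`. The phage/repeat distinction drives region logic, so
  fixtures must carry it explicitly.

## Validation problem sizes

The shipped test suite validates against: exhaustive 61-codon
neighbor/pathway enumeration plus hundreds of random codon pairs against
an independent enumeration oracle; alignment scores against an
independent quadratic-space DP oracle; and simulation-recovery runs at
1,000 genes × 20 seeds for pooled $K_s$ (3-binomial-SE criterion) and
$\omega$-class rank order, with per-class $\omega$ recovery within 30%
checked on estimates pooled across 20 seeds of 600-gene fixtures. The
pooled-across-seeds form of the 30% check is a power decision made from
the binomial standard error before running: a per-seed 30% band at
realistic fixture sizes is a ~3σ test repeated 60 times, which would fail
occasionally by construction and demonstrate nothing about estimator
correctness. Full-pipeline recovery (missing genes, region boundaries,
fragmentation positions) runs at the study-condition defaults above.

## Known limitations

* RBH is one-to-one by construction; recent paralogs surface as
  `ambiguous` rather than being resolved.
* A gene deleted in the reference but present in the target is visible
  only as `unpaired_b`; the reduction report is written from the
  reference's viewpoint.
* The missing-gene criterion is homology-based and conservative at this
  divergence; at substantially higher divergence (>20–30%) the 60%
  identity floor would need revisiting along with the whole NG86/JC
  stack.
* Divergence dating inherits the clock's assumptions; rate variability
  between bacterial lineages propagates directly into the estimate, which
  is why times are reported at two significant figures only.
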
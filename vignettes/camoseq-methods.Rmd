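---
title: "Methods: simulating and measuring camouflaged regions in a gene panel"
author: "camoseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring camouflaged regions in a gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical screening panels contain genes with near-identical copies elsewhere
in the genome — pseudogenes such as CYP21A1P (97.7% identical to CYP21A2)
and paralogs such as SMN2 beside SMN1. Short sequencing reads drawn from
such a region fit both copies almost equally well, so the aligner cannot
choose a locus with confidence: mapping quality (MAPQ) collapses to 0,
MAPQ-filtered coverage drops, and variants in the region silently disappear
from standard calling pipelines. camoseq builds a fully synthetic,
truth-labelled version of this situation so that every stage — homology
flagging, read simulation, mapping, low-coverage ("camouflaged") region
calling, population differentiation, and variant-rescue strategies — can be
measured against known ground truth on a desk-scale problem.

## The synthetic panel

`make_reference()` lays out `n_genes` genes (default 158, a realistic
size for a clinical screening panel such as a newborn-screening set) of
~5 kb with 5 exons of 160 bp each
on one contig, separated by intergenic spacers (4.5 kb baseline). Each of
the four default camo genes donates a tract, centred on its middle exon, to
the downstream spacer; the copy is then mutated to a target identity. The
copy is placed at least `flank + 250` bp (2.25 kb) from any gene so that
read simulation over gene ± 2 kb never touches it. Genes whose tract would
not fit are lengthened to `tract + 400` bp.

**Divergence profiles.** Real gene/pseudogene alignments concentrate their
differences in clusters and indel scars, leaving long identical stretches;
per-site i.i.d. divergence does the opposite — it sprinkles anchors
everywhere. Under paired-end rescue an i.i.d. 97.7% tract anchors nearly
every fragment (a 150 bp read pair spans ~450 bp, which at one difference
per ~43 bp almost always contains an anchor), so no coverage ever drops;
and the chance that an i.i.d. tract leaves a window long enough for the
converting-variant phenomenon is negligible. Each tract therefore chooses a
profile:

* `uniform` — i.i.d. divergence at rate `1 - identity`;
* `core` — the same number of divergent sites, pushed into the tract
  margins, leaving an identical core;
* `isolated` — an identical window containing exactly one divergent site at
  its centre (on the middle exon), uniform divergence elsewhere.

The default geometry spans the read-length regimes reported for real
panels:

| gene | tract | identity | profile | expected behaviour |
|---|---|---|---|---|
| 1 | 400 bp | 99.5% | core (340 bp) | low depth at short reads, clean at 250 bp (fragments span the tract) |
| 2 | 3 kb | 97.7% | core (600 bp) | low at 70–150 bp, clean at 250 bp (only 250 bp fragments exceed the core) |
| 3 | 6 kb | 99.9% | uniform | low at every length (no fragment spans it; most fragments see no divergent site) |
| 4 | 3 kb | 97.7% | isolated (700 bp) | clean at 150 bp until a converting variant erases its single anchor |

The window arithmetic fixes the sizes: a fragment at read length `r` spans
`2r + 50` bp, so a core must exceed `2·150 + 50 = 350` bp to trap 150 bp
pairs and stay below `2·250 + 50 = 550` bp to release 250 bp pairs —
hence 600 bp for gene 2 and the hard 400 bp tract (never trappable at
150 bp) for gene 1. The 700 bp isolated window of gene 4 exceeds 550 bp, so
its interior is reachable only through the central divergent site — exactly
the geometry in which a single pathogenic variant can erase the only local
anchor. Tract bases total 12.4 kb, under 1% of the ~1.42 Mb of simulated
region, mirroring the real panel where homologous tracts are a small
fraction of the target.

## Population model

`simulate_population_genotypes()` places `n_sites_per_gene` (default 20)
variant sites uniformly in each gene body and draws genotypes under the
Balding–Nichols model: ancestral frequency `p ~ Uniform(0.1, 0.9)`,
population-specific frequency `Beta(p(1-F)/F, (1-p)(1-F)/F)`, genotypes
`Binomial(2, freq)`. `differentiation_F` accepts one value per population
because the targeted pairwise differentiation pattern (global FST between
0.047 and 0.165, with one population clearly more distinct) cannot arise
from a single exchangeable `F`; the defaults
(CHS 0.08, GIH 0.07, GWD 0.17, FIN 0.09, CLM 0.07) put every expected
pairwise Weir–Cockerham value, approximately `(F_i + F_j)/2`, inside that
band with margin for sampling noise at 3,160 sites. Five populations of 10
diploid individuals give the 50-genome design evaluated by default. No linkage
disequilibrium and no sex chromosomes are modelled.

## Read simulation

`simulate_reads()` follows the conventional simulator accounting: the
number of pairs per region is `coverage × length / (2 × read length)`
(20X per haplotype, 40X combined), fragment length is
`2 × read length + max(0, round(Normal(50, 10)))`, fragment starts are
uniform with fragments wholly inside the region (the 2 kb gene flanks exist
precisely so that gene bodies see full edge coverage), read-1 strand is a
fair coin, and substitutions arrive i.i.d. at 0.0024 per base with the
erroneous base uniform over the three alternatives. No indels, quality
profiles, duplicates or GC bias are simulated; base qualities are a
constant Q40, since nothing downstream uses them except as caller input.
Reads with more than 5 `N` bases are redrawn. Read names carry the full
truth (`sim|indiv|hap|contig|pos1|pos2|strand1|serial`), which is what
makes correctness classification exact.

Heterozygous sites enter via an IUPAC consensus
(`build_consensus()`/`split_haplotypes()`): each ambiguity code resolves
alphabetically-first into haplotype 1. Simulating the two haplotypes
separately at half coverage is equivalent in expectation to the common
alternative of editing half of the overlapping reads post hoc.

## Mapper

`map_read_pairs()` is a deterministic seed-and-extend aligner standing in
for a production short-read mapper, with the conventional penalty set (match +1,
mismatch −4, gap open −6, gap extend −1). Exact 19-mer seeds on both
strands propose candidate loci; each candidate is scored over the full
read. Scoring is ungapped: the simulation contains no indels anywhere, so
gapped and ungapped extension return identical scores on every input this
pipeline can produce, and the gap parameters are retained in the
configuration for the record.

MAPQ is `min(60, 6 × (S1 − S2))` over candidate scores, 0 on ties, with
`S2 = 0` for single-candidate reads. For pairs, each candidate's effective
score is the best joint total over the mate's candidates, where a proper
pair (correct orientation, fragment length within mean ± 4 SD) earns a
bonus of 17 — the conventional unpaired penalty. Two consequences matter:

* both mates inside an identical duplication tie at the pair level and both
  get MAPQ 0 (ties break to the lowest coordinate);
* a uniquely mapped mate rescues its tied partner, and because
  17 > 5 = match + mismatch, a properly paired placement carrying one
  mismatch still beats an unpaired perfect match at the other copy. A
  smaller bonus (≤ 5) would leave exactly the converting-variant geometry
  tied, which is why the value is not adjustable below the substitution
  differential.

## Flagging and camo-region calling

`compute_mappability()` counts exact genome-wide occurrences of every
75-mer on both strands and scores each position `1/count` (0 where the
window contains `N`). Exact matching slightly overstates mappability
relative to edit-distance-tolerant tracks, but at the ≥97% identities
studied here shared exact 75-mers still tile the tracts. An exon whose
buffered (±70 bp) span averages ≤ 0.5 is flagged — the inclusive reading,
consistent with conservatively including borderline genes. `homology_search()`
seeds 11-mer words and extends ungapped with X-drop 50; hits are kept when
they have ≤ 10 mismatches and an alignment length within 10 of the query,
and a gene is flagged if any exon is flagged by either route (union rule).

Depth for camo calling counts alignments at MAPQ ≥ 20 over gene bodies
(every base reported, zeros included); the general accuracy rule treats
MAPQ < 10 as unmapped with a 20 bp position tolerance. Bases below depth 20
form runs, runs within 50 bp merge, and each region is annotated with mean
depth, exonic overlap, read counts, the number of non-uniquely mapped reads
(MAPQ < 10) and the merged alternate placements of those reads.

One filter is applied on top of the run-and-merge rule: a region must
contain at least one non-uniquely mapped read (`require_nonunique`,
default on). Per-base depth at 40X is Poisson(40), so roughly 3 in 10,000
positions of perfectly unique sequence dip below 20 by sampling noise alone;
across 790 kb of gene bodies such dips would be "called" in clean genes
despite every read mapping at MAPQ 60. Camouflage is, definitionally, the
inability to place reads uniquely, so non-unique support separates it from
shot noise for any seed. The filter can be switched off to obtain the raw
run-and-merge output.

## Variant rescue

`plant_variant()` places either a converting variant — at the divergent
gene/pseudogene position most isolated from other divergent sites, with the
alternate allele equal to the pseudogene base — or a non-converting variant
mid-exon outside the tract. `run_strategy()` then compares four calling
routes at 150 bp / 40X: standard (inner distance 50, ploidy 2, pileup
MAPQ ≥ 20), lowered MAPQ cutoff (≥ 10), elongated inner distance (255 bp), and pseudogene masking with
ploidy-4 genotyping, in which reads are simulated from both the gene and
its pseudogene (residual capture of the pseudogene is expected even under
targeted designs), mapped to a reference with the pseudogene tract plus
2 kb flanks replaced by `N`, and genotyped as one tetraploid locus.

The genotyper is a pileup caller: for dosage `d` of ploidy `P`, each alt
read contributes `(d/P)(1−e) + (1−d/P)(e/3)` and each ref read the
complement, with `e = 0.0024` matching the simulator; flat prior; no-call
below 4 covering reads or a Phred margin of 30 between the best and
second-best dosage. It deliberately replaces local-reassembly calling: with
SNV-only, low-error reads, the phenomena under study are driven entirely by
coverage and MAPQ, which a pileup sees directly. One consequence of the
margin gate worth knowing: a balanced 40-read pileup at ploidy 4 has a
margin near 20 and is no-called at the default threshold; the masking
strategy operates at ~80 reads (gene + pseudogene), where the margin
clears 30 comfortably. `discriminate_calls()` labels dosage-4 calls as
target-gene variants, dosage-2 calls as pseudogene divergence
(`1/1/1/1` vs `0/0/1/1`), everything else ambiguous with a warning.
Heterozygous plantings at ploidy 4 land on dosage 3 and are therefore
flagged ambiguous — supported but experimental.

## Problem sizes and determinism

The default panel is ~1.3 Mb of reference; a full four-read-length
evaluation simulates and maps about one million read pairs and completes in
a few minutes on one core. The test suite reuses one cached evaluation of
the default panel; unit tests run on an 8-gene (~91 kb) panel and ≤ 10 kb
oracle fixtures where brute-force enumeration is feasible (all-k-mer
counting, all-position alignment, per-base region merging, literal
variance-component transcription, dosage enumeration). Every stochastic
stage takes an explicit seed and restores the caller's RNG state; fixed
seeds reproduce byte-identical FASTA/FASTQ/SAM output.

## What passing tests do and do not show

The generator reproduces the *geometry* of camouflage — controlled-identity
copies, clustered divergence, converting variants — under clean conditions:
uniform coverage, substitution-only errors, a single primary assembly with
no alternate contigs or decoys, no structural variation, no capture or GC
bias. Passing tests therefore demonstrate that the measurement pipeline
behaves correctly and that the studied phenomena follow from homology
geometry alone; they do not predict accuracy on real libraries, where
non-uniform coverage and indel-bearing paralogs can only worsen the
picture. Replication mode (`run_config(mode = "replication")`) loads an
external reference FASTA and exon BED through the same readers and drives
the identical downstream stages for users who want to re-run the analysis
on real data; the real-genome headline numbers are outside what the
synthetic pipeline can or should reproduce.
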
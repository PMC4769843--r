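---
title: "Reconstructing gene models from targeted capture assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene models from targeted capture assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecap)
```

## The problem

Targeted sequence capture enriches genomic DNA for fragments that hybridize
to probes designed from known transcripts. In species whose genomes are too
large and repeat-rich to assemble — conifers being the canonical case — this
is often the only practical route to genomic gene structures: exon/intron
boundaries, intron lengths, and the promoter-proximal region upstream of the
first exon. The assembler output, however, is an unlabelled mixture of
contig classes: fragments of single exons, fragments spanning exon/intron
junctions, intronless processed-pseudogene copies, repeat-bearing contigs,
and fragments running into the 5′ flank. `genecap` reconstructs one gene
model per target transcript from this mixture, without any reference
genome, and quantifies how trustworthy each model is.

## Model and selection criteria

Each target transcript (a full-length cDNA, the *seed*) defines a
coordinate system. Contig evidence consists of HSPs: ungapped local
alignment segments between a contig and a seed, found by exact k-mer
seeding (k = 12) followed by per-diagonal extension scored +1 per match and
−3 per mismatch, with each segment trimmed to its score maximum. Segments
shorter than `min_hsp_len` (30 nt) or below `min_identity` (0.90) are
dropped. Both thresholds are configurable; they are deliberately permissive
for same-species capture data, where true segments are near-exact and a 5%
divergent pseudogene copy should still be *seen* (and then diagnosed),
not silently lost. Minus-strand hits are reported after flipping the contig
into seed orientation, so all downstream coordinates share one frame.

A contig is assigned to the seed with the greatest total HSP score (score =
matched bases). Competing seeds within `ambiguity_ratio` (0.9) of the best
total are recorded as ambiguous — the signature of close paralogs. Contigs
with no retained HSP form the discard class.

A **candidate gene model** is a set of contigs whose segments are pairwise
compatible on the seed: segments from different contigs may overlap by at
most `overlap_tolerance` (15 nt). Multiple placements of one contig always
travel together, because a tandem duplication inside a contig is evidence
about that contig, not a choice to make. The **best model** is selected
lexicographically:

1. highest union recovery (% of seed positions covered at least once);
2. lowest exon-level overlap (redundant coverage / union, in %);
3. lowest fragmentation index (number of contigs);
4. remaining ties: lexicographic contig-id list, for determinism.

Recovery counted *with multiplicity* is reported separately and may exceed
100%; any model above 100% is flagged `suspect_repeat`, reproducing the
known failure mode of capture models built over sequence repeats. The two
recovery figures are deliberately distinct quantities: the union form is
the selection criterion, the multiplicity form is the diagnostic.

### Overlap canonicalization

An ungapped local alignment can overshoot an exon boundary by a few bases
whenever the first intron bases happen to match the transcript
continuation. Two adjacent contigs then overlap on the seed by 1–3 nt even
in error-free data. Such sub-tolerance overlaps between *different* contigs
are alignment jitter, not repeat evidence, so candidate segments are
canonicalized: the shared bases are assigned to the upstream segment and
trimmed from the downstream one (seed and contig coordinates move
together). Same-contig multiple placements exceed the tolerance by
construction (retained segments are ≥ 30 nt, twice the tolerance) and are
never trimmed — the >100% repeat artifact survives intact.

### Why maximal compatible sets suffice, and the chain shortcut

Candidates are maximal compatible contig sets (maximal cliques of the
compatibility graph). A strict subset of a candidate can never win: because
every retained segment is longer than the overlap tolerance, any contig
compatible with a model must contribute at least one uncovered seed
position, so adding it strictly increases union recovery — the first
selection criterion. The test suite confirms this against exhaustive
enumeration of *all* contig subsets for clusters of up to 6 contigs.

Clique enumeration is exponential in the worst case (interchangeable
fragments covering the same exon multiply cliques), so clusters larger than
`exhaustive_limit` (15 contigs) are solved by an equivalent dynamic
program. Capture fragments are genomically contiguous, so each contig's
segments merge into a single seed interval; sorting intervals by end
coordinate, a set of contigs is pairwise compatible exactly when each
interval starts no more than the tolerance before the previous maximum end.
Compatible sets and end-sorted chains are therefore in bijection, and an
O(n²) chain DP maximizing (union, −overlap, −count, id order) finds the
same optimum as exhaustive enumeration. A property test checks the two
routes against each other on mid-sized clusters. Contigs whose segments do
not merge to one interval (possible in principle with a deleted internal
exon) are handled through their overall span, which is conservative but
cannot produce an invalid model.

### Model sequence and export

Segments are concatenated in seed order. Where both segments flanking a
junction come from one contig, the intervening contig sequence is retained
as the intron, with length `(contig gap) − (seed gap)` so that a
base of junction jitter cancels out; where no contig spans the junction the
segments are joined with a 50-N spacer and the intron is reported as
unknown — mirroring the "incomplete intron" annotations of capture-only
gene models. GFF3 output uses `gene → mRNA → exon` features in
model-sequence coordinates plus one `match_part` per contig segment with a
`Target` attribute, the conventional encoding for alignment evidence.

## Promoter-proximal extraction

A contig qualifies as carrying upstream regulatory sequence when one of its
HSPs to the assigned seed covers CDS codon 10 or earlier *and* the contig
extends at least 100 nt 5′ of that alignment start. Both thresholds are
strict: 100 nt passes, 99 fails; codon 10 passes, 11 fails. Codon k covers
CDS positions [3(k−1), 3k). For the length distribution, one candidate per
gene (the longest upstream, ties by contig id) is kept, because the
distribution describes gene models, not contigs; bins are half-open
[lo, hi) with a final open bin, so counts always sum to the number of genes
with a qualifying candidate.

## Probe design

120-mer probes tile each seed from its 5′ end: 19-nt steps while the start
lies in the first third (`ceil(L/3)`) of the sequence, then 29-nt steps
with no phase reset, plus a terminal probe at `L − 120` when needed, so
every base is covered. Interior coverage depth is `floor(120/19) = 6` in
the dense zone and `floor(120/29) = 4` elsewhere; the dense zone exists
because the 5′ third (including the 5′UTR) is what promoter recovery
depends on. The zone summary reports the *modal interior* depth, excluding
a probe-length ramp at each zone edge where depth necessarily climbs or
falls. Probes with more than 10% ambiguous bases are dropped (array
manufacturability).

## Structure annotation by spliced comparison

`annotate_gene_structure()` walks the transcript across the genomic
sequence, extending exact matches and absorbing isolated substitutions and
genomic insertions shorter than `min_intron` (20 nt — shorter than any
credible plant intron, which bottom out near 20 nt) into the current exon.
At each break it searches for the next exon anchor at least `min_intron`
downstream. Splice junctions are locally ambiguous whenever intron bases
coincide with the next exon's bases, so candidate placements within a
12-nt shift window are ranked: GT..AG intron dinucleotides first, then
smallest shift, then leftmost genomic position. Exon lengths are genomic
extents, so an absorbed micro-insertion enlarges its exon, and a shortened
intron below `min_intron` merges two exons — both behaviours are tested.
Annotation fails with diagnostics when less than `min_cover` (90%) of the
transcript can be placed.

CDS and protein lengths come from the transcript CDS annotation;
`cds_len = 3 × (protein_len + 1)` whenever the CDS ends in a stop codon.
For the packaged asparagine synthetase fixture the annotator recovers the
published structure exactly — 14 exons, 13 introns, CDS 1782 nt, protein
593 aa. The published total span of that gene (3974 nt) is inconsistent
with the sum of its published exon and intron lengths (2507 + 1916 =
4423 nt); the package reports the span computed from the structure and does
not attempt to reproduce the printed figure.

## The simulator: what it emulates and what it does not

`make_gene()` builds genes with exact ground truth: GT..AG introns, an
ATG-initiated stop-terminated CDS with no internal in-frame stop, ~38% GC
background (the GC level of conifer BAC sequence), all driven by a single
seed with byte-identical regeneration. `simulate_capture_contigs()` emits
the contig classes seen in real capture assemblies:

* *exon fragments* — fragments centred on exons (hybridization bias),
  extensions confined to the flanking introns, round-robin over exons so
  coverage ≥ exon count covers every exon;
* *junction-spanning fragments* — both flanking exons plus the intervening
  intron in one contig, one per junction;
* *intronless pseudogene* — a transcript copy with 5% substitutions
  (configurable);
* *repeat duplication* — one contig with a tandem-duplicated exon. While
  this scenario is active the exon-fragment rotation skips the duplicated
  exon: the premise is that the assembler collapsed the repeated locus into
  the single repeat-bearing contig, which is what makes repeat-driven
  >100% recovery observable at all (with independent clean coverage of the
  exon, selection simply prefers the clean tiling);
* *upstream flank capture* — one contig per gene extending a
  uniform(0, 1500) nt into the 5′ flank, the default range matching a
  library sheared to ~1.5 kb.

The simulator does **not** model sequencing error profiles, indel errors,
chimeric misassembly, or allelic variation; contigs are error-free
substrings (or substitution-diverged copies) of the simulated locus.
Passing tests therefore demonstrate the correctness of the reconstruction
logic — assignment, tiling, selection, scoring, thresholds, determinism —
not robustness to assembler artifacts beyond the modelled classes.

Default study conditions used by the test suite and worked examples:
gene sets of 2–6 exons (80–250 nt) and introns of 80–400 nt with 60/45-nt
UTRs and 1.5-kb flanks; capture coverage of twice the exon count per gene;
5 genes for end-to-end recovery runs, 20–30 genes for promoter-distribution
recounts; the asparagine synthetase fixture for all exact-structure
checks. At these sizes the full suite runs in well under a minute of
alignment time.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; GFF3 converts to 1-based
  inclusive.
* HSP score is the number of identical bases; assignment ties resolve to
  the lexicographically smallest seed id.
* `k = 12` seeding means segments with no exact 12-mer are invisible; at
  ≥ 90% identity and ≥ 30 nt this is a non-issue for capture data.
* Empty clusters produce no model (`NULL`); an empty candidate list raises
  a typed "no model" condition; a zero-length seed is an input error.
* Seeds shorter than the probe length are skipped with a warning; genes
  whose seed lacks CDS annotation are skipped by promoter extraction with a
  warning.
* All randomness is localized (`withr::with_seed`), so library calls never
  disturb the caller's RNG state, and identical configs + seeds regenerate
  byte-identical FASTA/GFF3/TSV outputs.

## Known limitations

* Selection does not weight identity: an intronless pseudogene copy at 95%
  identity covering the whole seed beats a fragmented true-exon tiling
  (union 100%, fragmentation 1). This mirrors the behaviour reported for
  capture pipelines in gene families rich in pseudogenes; the ambiguity
  set and the `model_structure()` comparison against ortholog structures
  are the intended diagnostics.
* Ungapped HSPs mean indel-rich divergence fragments alignments; for the
  same-species use case this is immaterial.
* Ortholog guidance is annotation-only (junction support labels); it never
  changes segment selection — by design, since the pipeline's premise is
  reference-free reconstruction.
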
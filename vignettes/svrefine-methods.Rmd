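---
title: "Resolving structural variants at base-pair resolution in repetitive regions"
author: "svrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving structural variants at base-pair resolution in repetitive regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two genome assemblies of the same species are compared, most
structural variants (SVs, differences of more than ~50 bp) that callers
disagree about sit in repetitive sequence.  Three alignment pathologies
dominate.  With *copy-number discrepancies*, several near-identical
copies in one genome all align to the same copy in the other, faking a
gain or loss.  With *reverse-orientation artifacts*, short fragments that
align to their own reverse complement (fold-back structure, at its most
extreme in dense "tyfonas"-like clusters) scatter reverse hits across
the genome and seed spurious large calls.  With *copy misalignment*,
non-orthologous repeat copies are paired across the genomes, shifting
every breakpoint derived from that pairing.  `svrefine` automates a
curation strategy built around two ideas: pin region boundaries with
*uniquely aligned sequence* (UAS) rather than with the repeats
themselves, and decide breakpoints by comparing the *similarity of
repeat copies*, pairing the most similar copies across genomes and
treating what remains unpaired as the variant material.

## Pipeline and model

**Region building.** Caller VCFs are pooled.  A locus survives filtering
iff its FILTER flags intersect {PASS, PRECISE} — callers that emit no
FILTER discipline bypass the flag rule — and its length strictly exceeds
50 bp.  Surviving loci within 500 bp of one another (inter-locus gap,
single linkage) are consolidated into one SV region.  Loci longer than
20 kb are withheld from clustering and emitted as *container* regions,
because such spans often contain independent smaller events; the loci
inside them still cluster among themselves.

**UAS anchoring.** Each region's flanks grow independently in 5-kb steps
(up to 30 kb) until the flank is unique in the other genome.  Alignment
segments of a flank are first merged into *hit loci* (colinear segments
with gaps below 4 kb are one locus, since a flank whose alignment crosses
an SV splits mechanically); a locus is a candidate if its identity is at
least 0.80 and it covers at least half the flank.  The flank is unique
when there is a single candidate, or when the best candidate reaches
identity 0.95 and beats the runner-up by a margin of 0.05.  The margin
default mirrors the contrast that separates a true orientation from a
spurious one (a 0.99 forward match versus a 0.90 reverse alternative).
The located query interval is the span between the two mate intervals;
resolution then works on the full anchored windows (region plus flanks)
so that junction trimming sees aligned context on both sides.

**Breakpoint resolution.** Within the anchored windows the package
catalogues repeat structure (self- and cross-alignment segments
clustered into families by reciprocal overlap ≥ 0.8; copies ≥ 95%
contained in a sibling are collapsed as sub-segments; tandem blocks get a
unit length and copy count from the smallest period at shift-identity
≥ 0.9).  Orthologous copies are paired by maximum-similarity one-to-one
assignment — exhaustive for up to six copies per side, Hungarian beyond,
with ties resolved leftmost-to-leftmost; a greedy pairing fails on
similarity patterns like {0.99, 0.92; 0.93, 0.98}, which is why the
assignment is optimal.  A colinear chain skeleton (exact k-mer seeds,
k = 15, chained with affine gap costs; gaps above 50 bp on either
sequence split segments so that SV-scale junctions always fall *between*
skeleton blocks) is laid across the window pair, and every junction is
trimmed to its minimal unmatched residuals.  Indels are normalized to
their leftmost placement; the full set of equivalent placements (e.g.
any of 401 start positions when one unit leaves a perfect five-copy
100-bp array) is reported as the ambiguity interval rather than
suppressed.  Each call carries a repeat-pattern category: `unique` (no
repeat involvement), `cat1` (a single-segment copy present once in one
genome and multiply in the other), `cat2` (a multi-segment copy, with
internal self-similarity, present once versus multiply), `cat3`
(multiple distinct copies in both genomes, typically tandem arrays).
The category is inferred from copy counts of the variant material in
both windows — tandem copy counts from the maximal period-p extent
around the junction, dispersed counts from merged hit loci covering
≥ 60% of the probe at identity ≥ 0.8.

**Classification.** INS when only query residual remains, DEL when only
reference residual, and SUB when both residuals remain and stay
unaligned — forward identity below 0.8 in either orientation.  Residual
pairs *above* 0.8 are decomposed further with finer seeds instead of
being typed; if nothing above the 50-bp floor emerges they are treated
as small-variant noise.  Copy gains and losses are reported as INS/DEL
of the identified copies; a DUP label is never emitted.  An inversion
must satisfy three criteria: both flanks forward-aligned, the reverse
alignment reciprocally the best match (better than the direct forward
identity and than any forward alternative within the windows), and no
assembly-gap run — ten or more consecutive Ns, checked in *both*
genomes — inside the interval.  Identity is always matches divided by
alignment columns, gap columns included, under affine scoring
(match 1, mismatch −2, gap open 4, gap extend 1).

**Evaluation.** Call sets are scored against a benchmark by one-to-one
matching that maximizes the true-positive count (augmenting-path
bipartite matching; candidate partners tried closest-first, then
leftmost, so results are deterministic).  The strict preset demands
exact agreement (`refdist 0, pctsize 1, pctovl 1`); the relaxed preset
allows 50 bp of breakpoint deviation and 90% size/overlap agreement; a
1-kb variant of the relaxed preset is also provided.  Sequence-similarity
matching is disabled (`pctseq = 0`) in all presets.  A SUB may match an
INS or DEL record on the corresponding allele side, because the same
locus legitimately appears as insertion, deletion or substitution
depending on which pair of genomes is compared; `sub_strict = TRUE`
disables this.  Two breakpoint statistics accompany evaluation: the
per-class relative rate, (share of breakpoints in a class) / (share of
the genome in that class), over a genic / regulatory / intergenic
partition (regulatory defaults to a 3-kb window upstream of the TSS,
resolved by precedence genic > regulatory > intergenic), and the AT
fraction of ±50-bp breakpoint windows against the genome background.

## The simulator and what it does and does not show

`makeReference()` draws i.i.d. nucleotides at a configurable GC content
(default 0.36, plant-like) and splices in repeat constructs at exact
coordinates: tandem arrays, dispersed copies with per-copy divergence,
inverted repeats, multi-segment blocks with internal self-similarity,
fold-back clusters built from independent short inverted pairs, N-gap
runs, and AT-rich blocks.  `plantSVs()` edits the reference into a query
and derives truth records whose canonical breakpoints and ambiguity
intervals come from *exhaustive equivalent-placement enumeration* —
direct string comparison of every candidate placement, sharing no code
with the resolver's shift logic.  `scenarioSuite()` packages one fixture
per pathology plus a combined ~200-kb pair carrying 21 planted SVs of
all types and contexts; `simulateCalls()` adds Gaussian breakpoint
jitter and Poisson false calls to emulate caller noise.

The i.i.d. background makes flank uniqueness easy compared with real
genomes, where low-complexity sequence and transposon families blur the
margin criterion; passing the closure suite therefore demonstrates the
machinery's correctness on its stated model, not calibrated performance
on real assemblies.  Repeat realism comes from the explicit constructs,
not from a composition model; no small-variant background noise is
planted outside the SVs, which is what makes byte-exact reconstruction
(`applyTruth(truth, ref) == qry`) a meaningful invariant.  The fixture
sizes (10–30 kb per scenario, 200 kb combined) keep a full pipeline run
around half a minute; they were chosen as the smallest sizes at which
every repeat context still spans multiple flank steps.

## Numerical choices and degenerate inputs

Internal coordinates are 1-based and inclusive throughout (the
IRanges/GRanges convention), with zero-width ranges anchoring insertion
points; VCF, BED and PAF conventions are converted at I/O only.  Caller
dialects are declared, never sniffed: the `generic` dialect reads
symbolic records with POS as the first affected base, while
sequence-resolved records and the package's own output use the
padding-base convention.  Unmated breakends and records without usable
coordinates are dropped and counted, never guessed.  Junction calls
whose coordinates touch an anchored window edge (within 20 bp) are
discarded as truncation artifacts — any real event is recovered intact
from its own region, whose flanks place it far from the edges.  Ties in
copy assignment and in match ordering are always broken toward the
leftmost coordinate, making every pipeline stage deterministic.  The
copy-number-discrepancy diagnostic only fires when the two genomes carry
*equal* copy counts whose best hits collapse; with unequal counts the
collapse reflects a real gain or loss and the signal belongs to the
misalignment test instead.  Degenerate inputs — empty call sets, regions
with no query anchor, identical region pairs, flanks truncated at
sequence ends — yield empty results or flagged statuses, not errors.

## Known limitations

The seed-and-chain aligner is a desk-scale substrate: precise for
region-scale sequences, but not a whole-genome aligner, and external PAF
alignments can replace it when real assemblies are analysed.
Inter-chromosomal translocations and nested
inversions-in-duplications are out of scope and escalate as complex
regions rather than resolving.  Copy catalogues cap at eight copies per
family and genome; denser clusters are diagnosed (reverse-artifact
signal) but not exhaustively enumerated.  Ambiguity intervals are exact
only for simple indels; substitution placements are reported with a
single canonical coordinate.
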
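# svrefine

Base-pair resolution and benchmarking of structural variants (SVs) in
repetitive genomic regions.

SV callers disagree most where genomes are repetitive: tandem arrays,
dispersed repeat copies, inverted repeats and dense fold-back ("tyfonas"-
like) clusters make breakpoints ambiguous, pair the wrong repeat copies
across genomes, and turn one event into many conflicting calls.
`svrefine` automates the curation methodology used to build base-pair
resolved SV benchmarks from assembly-to-assembly comparisons (the worked
summary tables bundled under `inst/extdata/` come from the published
tomato VF36 × SL4.0 benchmark):

1. **Region building** — pool caller VCFs, keep loci flagged PASS/PRECISE
   with length > 50 bp, consolidate loci within 500 bp into SV regions
   (loci > 20 kb become container regions), and diagnose each region's
   boundary pathology (copy-number discrepancy, reverse-orientation
   artifact, copy misalignment, combinations).
2. **UAS anchoring** — grow flanks in 5-kb steps (up to 30 kb) until each
   flank is a *uniquely aligned sequence* (UAS) in the other genome:
   a single candidate hit, or a best hit at identity ≥ 0.95 that beats the
   runner-up by ≥ 0.05.
3. **Breakpoint resolution** — catalogue repeat segments and copies inside
   the anchored region, pair orthologous copies by maximum-similarity
   assignment, lay a colinear chain skeleton across the region pair and
   trim each junction to its minimal unmatched residuals.  Canonical
   breakpoints are leftmost; all equivalent placements are enumerated and
   reported as an ambiguity interval; each call carries its repeat-pattern
   category (unique, cat1, cat2, cat3).
4. **Classification** — INS / DEL / INV / SUB from the residual material.
   DUP/CNV labels are never emitted (copy gains/losses are INS/DEL of
   identified copies).  An inversion must have forward-aligned flanks, a
   reciprocal-best reverse match, and no assembly gap (≥ 10 N) in either
   genome.  A substitution (SUB) has non-empty residuals on both sides
   that stay unaligned (forward identity < 0.8).
5. **Evaluation** — score any call set against a benchmark under
   one-to-one matching that maximizes true positives, with the strict
   (`refdist 0, pctsize 1, pctovl 1`), relaxed (`refdist 50, pctsize 0.9,
   pctovl 0.9`) and relaxed-1k presets (`pctseq = 0` throughout), plus
   breakpoint statistics: per-class relative rates
   `(breakpoint share) / (genomic share)` and AT content of ±50 bp
   breakpoint windows.

A seeded simulator (`makeReference()`, `plantSVs()`, `scenarioSuite()`)
generates genome pairs with configurable repeat landscapes and planted
SVs whose truth records carry exhaustively enumerated ambiguity
intervals — the substrate for every test in the package.

## Worked example

```r
library(svrefine)

suite <- scenarioSuite(seed = 42)          # named scenario fixtures
fx <- suite$combined                       # ~200 kb pair, 21 planted SVs

res <- curate(fx$ref, fx$qry, fx$calls)    # full pipeline
res$report
#>       loci_in loci_filtered       regions      anchored      resolved
#>            42            42            20            20            21
res$type_counts
#>   INS   DEL   INV   SUB total
#>     9     9     1     2    21

ev <- matchCalls(res$benchmark, fx$truth, matchParams("strict"))
ev
#> EvalResult: TP=21 FP=0 FN=0  P=1.0000 R=1.0000 F1=1.0000
```

All 21 planted SVs — including copy-number changes inside tandem arrays,
a multi-segment block gain, a fold-back-flanked deletion and an
unalignable substitution — are recovered with exact canonical
breakpoints, types and ambiguity intervals under the strict (zero
deviation) matching rule.

A thin command-line wrapper is installed as `exec/svrefine`
(`svrefine simulate|run|eval`).

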
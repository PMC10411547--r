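# traitanchor

Comparative physical mapping of agronomic trait loci on a pair of
collinear reference genomes.

Forty years of linkage and association mapping in tomato, potato and
their relatives located resistance genes and QTL on *genetic* maps whose
recombination-based coordinates are not comparable across studies,
populations, or species. Once both reference genomes are sequenced, every
marker with a known sequence or primer pair has a physical address — and
with it every trait locus whose evidence is expressed in markers.
`traitanchor` performs that translation end to end, for people who
curate mapping literature into physical maps and for anyone who needs a
tested, self-contained implementation of the pipeline:

1. **Anchoring** — a built-in k-mer seed-and-extend matcher (plus an
   in-silico PCR engine for primer pairs) places each marker on each
   genome, accepting hits strictly above 70% identity, and resolves
   multi-hit markers by best-hit margin, clustered-family collapsing, or
   the chromosome known from genetic mapping.
2. **Cross-mapping** — anchors of the same locus in both genomes become
   matched pairs; the unmatched remainder is classified (matched in one
   genome, in neither, or placed on conflicting chromosomes).
3. **Rearrangement detection** — per chromosome, pair order is oriented
   (the chromosome-12-style global flip), decomposed into maximal
   monotone blocks, and chained: the backbone is the longest increasing
   subsequence of positions, and off-chain blocks under minimum-event
   parsimony become inversion or intra-chromosomal translocation calls
   with physical spans in both genomes. Intervals project between
   genomes through the resulting block map.
4. **Trait projection** — per-study marker evidence becomes a physical
   interval: flanking markers bound it exactly; a single linked marker
   gets the ±2 Mbp rule (scaled for synthetic genomes); intervals merge
   across studies by single-linkage overlap, carry a support count with
   the `*`/`**` star notation (2–3 / >3 studies), receive uniform names
   like `pLBR5.1` or `tSS9.2`, and loci wider than 15 Mbp are excluded
   from comparisons.
5. **Comparative layer** — within-genome colocalization, cross-genome
   syntenic trait pairs via interval projection, and resistance hotspots
   (dense, multi-pathogen-class segments containing both qualitative
   genes and QRL).
6. **Reporting** — per-class summary tables and deterministic SVG
   chromosome maps (tomato axis left, potato right, colour-coded trait
   bars, dotted pairing lines, red inside translocations).

A synthetic-data generator (`sim_config()`, `simulate_all()`) produces a
diverged genome pair with planted inversions, translocations,
duplications, markers, and mapping studies around hidden causal
positions — with the full ground truth — so every stage is testable with
no external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
default synthetic system (two genomes of 4 × 3 Mbp, 5% divergence, 10
planted inversions + 5 translocations, 1,500 markers, 60 studies):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_anchor.R
Rscript analysis/03_crossmap_rearrange.R
Rscript analysis/04_traitproject.R
Rscript analysis/05_coloc.R
Rscript analysis/06_report.R
```

which prints, stage by stage:

```
genome A: ambiguous=10, resolved_by_prior=12, unique=1478
genome B: ambiguous=2, resolved_by_prior=20, unique=1392, unplaced=86
matched pairs: 1402 (both=1402, one=98, neither=0)
10 inversions + 5 translocations called; vs truth: precision 1.000, recall 1.000
60 study reports -> 60 candidates -> 21 named loci (0 excluded >750,000 bp);
  causal coverage 1.000 (60/60)
support distribution: 1x6, 2x3, 3x6, 6x1, 4x4, 8x1
5 syntenic pairs across genomes
```

Reading these numbers: 1,478 of 1,500 markers anchor uniquely on the
source genome and 1,392 on the diverged one (the deficit is dominated by
primer pairs whose exact 3'-seed requirement fails under 5% divergence —
the realistic failure mode of PCR assays across species). All 15 planted
rearrangements are recovered with correct kind and span, every merged
locus contains its hidden causal position, and support counts spread
from single-study loci (no star) to an eight-study locus (`**`). Tables
land under `results/`, dotplots under `results/dotplots/`, and
publication-style chromosome maps under `results/maps/`.

The same machinery runs on real inputs via `run_pipeline_files()`
(two genome FASTAs, a marker TSV, a study TSV; see `?read_tables` for
the column contracts) with the real-scale defaults `half_width = 2e6`
and `large_cutoff = 15e6`.

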
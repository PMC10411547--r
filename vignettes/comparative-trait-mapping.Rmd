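---
title: "Comparative physical mapping of trait loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative physical mapping of trait loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitanchor)
```

## The problem

Decades of linkage and association mapping in tomato and potato placed
qualitative resistance genes and quantitative trait loci (QTL) on genetic
maps whose coordinates — recombination distances — are not comparable
across studies, populations, or species. Once reference genome sequences
exist for both species, every marker with a known sequence (or primer
pair) can be placed at a physical coordinate, and with it every trait
locus whose evidence is expressed in markers. `traitanchor` implements
that translation end to end: it anchors a marker catalogue on two
collinear reference genomes, joins the anchors into cross-genome matched
pairs, detects the inversions and intra-chromosomal translocations that
perturb otherwise collinear chromosomes, projects per-study marker
evidence into physical intervals, merges loci across studies under a
uniform nomenclature, and reports colocalization, cross-species synteny,
and resistance hotspots, with publication-style SVG chromosome maps.

All internal coordinates are 0-based, half-open base-pair intervals.
Conversion to 1-based inclusive coordinates happens only when writing
GFF3. Chromosome names are normalized to `chrNN` on ingest.

## Anchoring

Markers are placed by a built-in seed-and-extend matcher: 2-bit-encoded
k-mers (default k = 12, one seed every 10 bp plus the terminal window,
both strands) index each chromosome; every seeded diagonal is evaluated
ungapped over the full query, and a hit survives when its identity
strictly exceeds `min_identity` (default 70%) over at least
`min_aln_len` (30 bp). The strict inequality is deliberate: a hit at
exactly 70.0% is rejected. Queries shorter than 30 bp are labelled with
the relaxed E-value class (`relaxed_short_query`), mirroring the practice
of raising the expect threshold for short queries in web BLAST; the
built-in matcher is seed-based rather than E-value based, so the class is
recorded as metadata. Queries with more than 50% N content are rejected
as low-complexity. The matcher is ungapped by design — the synthetic
divergence model is substitution-only (below) — and the alignment backend
is pluggable for real data where indel tolerance matters: pre-computed
anchor tables can be supplied in place of the built-in matcher.

Primer pairs go through an in-silico PCR engine instead: each primer
binds where its 8 terminal 3' bases match exactly (a configurable stand-in
for polymerase extension chemistry) and total mismatches stay within the
identity gate; a forward site and an inward-facing reverse site on the
opposite strand within `max_amplicon` (5 kb) define the amplicon, which
becomes the anchor span.

Hit resolution is rule-based and ordered: a single passing hit, or a best
hit whose runner-up scores below 0.95 of it, is `unique`; several
near-equal hits confined to one 2 Mb window on one chromosome collapse to
the window midpoint (clustered gene families — common among NBS-LRR
resistance genes — where the member-level ambiguity does not affect
higher-order structure); otherwise the chromosome known from genetic
mapping (`prior_chrom`) picks among near-equal hits; what remains is
`ambiguous` and gets no coordinates. Anything below the gates is
`unplaced`, with a reason code.

## Matched pairs and rearrangement detection

A locus placed in both genomes on the same chromosome number becomes a
matched pair; its position is the anchor midpoint (symmetric under strand
flips). Loci placed on different chromosome numbers are counted as
`chrom_conflict` and excluded from pairing — the tomato/potato comparison
is chromosome-number-preserving, and such conflicts flag paralogous
pickups. Pairs with both anchors `unique` form the comparison subset used
for structural inference; ambiguity-resolved anchors are noisier and are
kept out of the chaining.

Per chromosome, the pair set is analysed in three steps.

**Orientation.** A chromosome assembled in opposite orientation in the
two genomes shows a strongly negative Kendall rank correlation between
posA and posB. When |tau| >= 0.8 the sign decides; when the correlation
is weaker, both orientations are chained and the one retaining the better
collinear chain (more blocks, then more anchors, ties toward unflipped)
wins. The ambiguous zone matters: a chromosome whose inversions cover
about half its length can push tau marginally negative without any global
flip, and deciding by the sign alone would invert the kind of every call
on that chromosome. The 60/40 concordance case therefore stays unflipped
under both readings.

**Chaining.** Two views are computed. The *backbone* is the longest
strictly increasing subsequence (LIS) of posB in posA order (patience
sorting; ties in posB are pre-broken by a rank-scaled epsilon so the
result is deterministic). Structural calls, however, are made at block
level: the pair sequence is cut into maximal monotone blocks contiguous
in both posA-rank and posB-rank — the atomic units a rearrangement moves
— and the collinear chain is the subset of non-decreasing blocks that
maximizes the number of retained blocks, with total anchors as the
tie-break. This is minimum-event parsimony: each off-chain block is one
event. The distinction matters when several translocations interact: the
anchor-richest increasing subsequence can keep a large *moved* segment
and displace its (smaller) flanking regions, mis-assigning both kind and
span; maximizing retained blocks instead yields the fewest-events
reading. Members of the LIS that fall inside a displaced block are
reported as `absorbed`.

**Classification.** An off-chain block internally decreasing in posB is
an inversion; internally increasing but displaced, an intra-chromosomal
translocation. The call's span per genome is the bounding interval of
member positions and its size the larger of the two widths. Blocks below
`min_block_anchors` (default 2) are discarded with a log note —
single-anchor displacements are indistinguishable from mapping noise or
assembly artefacts. Calls confined to the central low-resolution zone of
a chromosome (default the middle third, configurable) are annotated
`central_low_resolution` rather than removed: pericentromeric regions
have poor genetic and physical resolution and rearrangements there may be
assembly artefacts.

**Projection.** Intervals move between genomes through the block map:
displaced blocks claim their spans first; the backbone chain maps the
remainder by piecewise-linear interpolation over its anchors,
extrapolating at unit slope beyond the terminal anchors so near-telomeric
intervals remain projectable. The image is the bounding interval of the
per-block images, flagged `gap_spanning` when more than one block
contributed. Projection across an inversion reverses endpoint order;
round-tripping A to B to A returns an interval containing the original to
within about one anchor spacing.

## Trait-locus projection and merging

Study evidence is a list of (marker, relation) records with a closed
relation vocabulary: `linked`, `flanking_left`, `flanking_right`,
`associated`, `cosegregating`. Association evidence is pooled with
linkage (no separate rule is warranted by the evidence the tables carry),
and cosegregation is zero-distance linkage. Epistatic QTL have no
relation code and cannot enter. Interval construction follows the
flanking-first rule: when both flanks are placed, the interval runs from
the left flank's midpoint to the right flank's (inverted flanks are a
hard error); otherwise the bounding span of placed markers is extended by
`half_width` on each unbounded side and clipped to the chromosome. The
real-scale default for `half_width` is 2 Mb — the assumption that a QTL
with one linked marker from one experiment lies within 2 Mb of it, which
overestimates near telomeres and underestimates near centromeres, and is
therefore exposed as a parameter. Sequence-characterized genes skip the
marker logic: their interval is the anchor span of the gene sequence
itself.

Loci from different studies of the same species, trait class, locus kind,
and chromosome merge by single-linkage when their intervals overlap by at
least 1 bp; the merged interval is the union. Union rather than
intersection because single-linkage chains can have empty intersections,
and because the merge is meant to combine evidence expansively; the merge
rule is exposed for sensitivity analysis. Support is the number of
distinct contributing studies, displayed as the star suffix: no suffix
for a single study, `*` for two or three, `**` for more than three.
Qualitative genes never merge with quantitative loci — a cloned gene
inside a QTL keeps both identities, and their relationship is reported as
colocalization instead.

Names follow the uniform scheme `prefix + acronym + chromosome +
"." + serial`: species prefixes p/t/pe/e, resistance acronyms per
pathogen (LBR, EBR, RSe, BWR, CSR, rx, qTy, CMV, Gpa, Gro, WR, CBR, Ts,
Rtu, ...), species-specific acronyms for the agronomic classes (tSS/pTSC
for sugar, tFY/pTY for yield, tFW/pTW for weight, tM/pM for maturity),
and serials assigned per chromosome in ascending start order. Serials are
reassigned on every run from the merged output — reproducibility over
literature fidelity — and published symbols of qualitative genes pass
through verbatim. Loci wider than `large_cutoff` (default 15 Mb; width
exactly at the cutoff is kept) are flagged `excluded_large`, retained in
outputs, and skipped by all downstream comparisons.

## Colocalization, synteny, hotspots

Colocalization within a genome is interval overlap of at least 1 bp, with
no distance slack — the intervals already embody positional uncertainty.
Cross-genome synteny projects each genome-A locus through the block map
and pairs it with genome-B loci of an equivalent trait category (equal
categories by default; the equivalence map is configurable). Hotspots are
operational, not statistical: pathogen-resistance loci from both genomes
(genome-B loci projected onto the A axis) are merged into segments by
single linkage with a gap tolerance of 2 Mb, and a segment is a hotspot
when it has at least 6 member loci, at least 3 distinct pathogen classes
(oomycete / fungus / bacterium / virus / nematode / insect), and at least
one qualitative plus one quantitative locus. No numeric criterion for
"outstanding" density exists in the literature this mirrors; the defaults
were chosen so that segments laid out like the published chr05 (0–6 Mb)
and chr09 (0–10 and 58–67.5 Mb) resistance clusters qualify while sparse
chromosomes and single-class clusters do not, and all three knobs are
exposed. No enrichment test against a null is attempted — colocalization
can arise by chance, and the package reports structure, not significance.

## The synthetic study system

The generator exists so that every stage is testable against known truth
with no external data, at desk scale. Genome A is i.i.d. random sequence:
4 chromosomes of 3 Mb (the real chromosomes are 45–90 Mb; everything
scales through the config). Genome B is derived by applying 10 inversions
and 5 intra-chromosomal cut-and-paste translocations of 0.2–1 Mb — the
scaled analogue of the 0.2–22 Mb range reported between the real genomes
— placed by gap allocation so the spec'd density always fits, followed by
per-base substitution at 5% divergence (roughly the tomato–potato
protein-coding distance; no indels, so the ungapped matcher is a faithful
aligner of the simulated truth). A translocation's insertion point must
lie farther from its segment than 1.2 segment lengths: a shorter-range
cut-and-paste is indistinguishable from moving the in-between segment the
other way, so closer placements would make the planted "truth" not the
parsimonious reading of the resulting genome.

The marker catalogue (1,500 markers, 200–600 bp, sampled uniformly from
genome A) includes 10% primer pairs bounding 200–1,000 bp amplicons, 1%
markers inside planted 2 kb duplications (ambiguous anchoring cases), an
optional fraction of random-sequence markers (loci matching neither
genome), and a prior chromosome that is wrong with probability 0.02.
Simulated studies (60, over 24 hidden causal positions split between the
two species) report either the nearest flanking markers (probability
0.7) or the single nearest marker as linked; when no marker lies within
`half_width` of the causal position the study is truth-flagged
`loose_evidence`. Half of the tomato causal positions are planted as
orthologs of a potato causal position (same trait class, coordinates
mapped through the exact genome correspondence), so cross-genome
syntenic trait pairs exist in truth and the synteny detector has planted
positives to find. The interval half-width and large-locus cutoff scale
with the genome: 100 kb and 750 kb on 3 Mb chromosomes, standing in for 2
Mb and 15 Mb on real ones.

What the simulation does *not* emulate: indels and rate heterogeneity,
repeat families beyond the planted duplications, inter-chromosomal
exchange, marker ascertainment bias, and the heterogeneous quality of
real mapping literature. Passing the recovery suites therefore shows the
machinery is correct under the stated model, not that real curated maps
are reproduced; applying the package to the real genomes and a curated
study table is supported but is an application, not a test.

## Numerical choices and degenerate inputs

Ties in posB are broken deterministically by adding a rank-scaled epsilon
in posA order before chaining. A chromosome with fewer than 3 pairs skips
orientation and chaining with a warning. A report whose only evidence
marker is unplaced is dropped with reason `no_anchored_evidence`; with
`half_width = 0` a single-marker report degenerates to a 1 bp point
interval rather than an empty one. Intervals exceeding chromosome bounds
are a hard error at serialization, never clipped silently. SVG output is
fully deterministic (fixed ordering, greedy downward label displacement,
no timestamps), so golden-file comparison is byte-exact.

## Problem sizes used by the test and acceptance runs

The bundled test suite and the acceptance script run the full pipeline on
the default synthetic configuration (2 × 12 Mb genomes, 1,500 markers, 15
planted events, 60 studies) over five seeds — about 15–20 s per seed on
one core — plus many small constructed fixtures. The permutation oracle
for the chaining backbone enumerates all 46,233 permutations of up to 8
anchors against an independent quadratic-DP longest-increasing-subsequence
oracle, itself validated against exhaustive subset enumeration at n <= 5.

## Known limitations

Nested rearrangements are not resolved recursively (one decomposition
pass, matching the flat lists such comparisons are reported as), and
breakpoints are anchor-bounded, not nucleotide-refined.
Inter-chromosomal translocations are out of scope. Protein-space
anchoring of cross-species genes is not implemented; such loci enter as
pre-computed anchors. The built-in matcher reports maximal single
diagonals and does not merge multiple HSPs per hit. Conflicting prior
chromosomes across source studies are not reconciled — the schema stores
one value per marker, and conflicts must be resolved upstream.
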
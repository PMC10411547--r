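#!/usr/bin/env Rscript
# Stage 5: within-genome colocalization, cross-genome synteny of trait
# loci (projection through the rearrangement block map), and resistance
# hotspot detection.

suppressPackageStartupMessages(library(traitanchor))

loci <- read.delim("results/loci.tsv", stringsAsFactors = FALSE)
loci$excluded_large <- as.logical(loci$excluded_large)
block_map <- readRDS("results/block_map.rds")

lociA <- loci[loci$species == "potato", ]
lociB <- loci[loci$species == "tomato", ]

col <- rbind(find_colocalized(lociA), find_colocalized(lociB))
write_tsv(col, "results/coloc.tsv")
syn <- find_syntenic(lociA, lociB, block_map)
write_tsv(syn, "results/syntenic.tsv")
hs <- detect_hotspots(lociA, lociB, block_map)
write_tsv(hs, "results/hotspots.tsv")

message(sprintf(
  "%d colocalized pairs within genomes; %d syntenic pairs across genomes; %d hotspot segments",
  nrow(col), nrow(syn), nrow(hs)))
if (nrow(hs))
  message(paste(sprintf("  hotspot %s: %.1f-%.1f Mbp (A) / %.1f-%.1f Mbp (B), %d members, %d pathogen classes",
                        hs$chrom, hs$startA / 1e6, hs$endA / 1e6,
                        hs$startB / 1e6, hs$endB / 1e6, hs$n_members,
                        hs$n_pathogen_classes), collapse = "\n"))
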
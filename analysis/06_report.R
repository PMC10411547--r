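#!/usr/bin/env Rscript
# Stage 6: summary tables per trait class and species, and one dual-axis
# chromosome map (SVG) per chromosome in the style of comparative
# physical trait maps: tomato axis left, potato right, colour-coded QTL
# bars, star-suffixed names, dotted pairing lines (red inside
# translocations).

suppressPackageStartupMessages(library(traitanchor))

loci <- read.delim("results/loci.tsv", stringsAsFactors = FALSE)
loci$excluded_large <- as.logical(loci$excluded_large)
loci$star[is.na(loci$star)] <- ""
pairs <- read.delim("results/pairs.tsv", stringsAsFactors = FALSE)
calls <- read.delim("results/rearrangements.tsv", stringsAsFactors = FALSE)
gA <- read_genome("results/sim/genomeA.fa", "simA")
gB <- read_genome("results/sim/genomeB.fa", "simB")

summ <- summarize_loci(loci)
write_tsv(summ, "results/summary.tsv")
message("locus summary (counts and interval widths in Mbp):")
for (i in seq_len(nrow(summ)))
  message(sprintf("  %-8s %-7s n=%d (excl=%d) width %s-%s Mbp, mean %s",
                  summ$trait_class[i], summ$species[i], summ$n_loci[i],
                  summ$n_excluded[i], summ$min_mbp[i], summ$max_mbp[i],
                  summ$mean_mbp[i]))

dir.create("results/maps", showWarnings = FALSE)
for (ch in names(gA$chrom_lengths)) {
  svg <- render_map(ch,
                    loci[loci$species == "potato" & loci$chrom == ch, ],
                    loci[loci$species == "tomato" & loci$chrom == ch, ],
                    pairs, calls,
                    chrom_len_a = gA$chrom_lengths[[ch]],
                    chrom_len_b = gB$chrom_lengths[[ch]])
  writeLines(svg, file.path("results/maps", paste0(ch, ".svg")))
}
message("chromosome maps written to results/maps/*.svg")
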
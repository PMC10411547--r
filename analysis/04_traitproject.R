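#!/usr/bin/env Rscript
# Stage 4: convert per-study marker evidence into physical intervals
# (flanking markers bound the interval; a single linked marker gets the
# +/- half-width window, scaled for the synthetic genome), merge loci
# across studies, assign the uniform nomenclature, apply the
# large-interval exclusion, and check causal coverage against truth.

suppressPackageStartupMessages(library(traitanchor))

aA <- read.delim("results/anchors_A.tsv", stringsAsFactors = FALSE)
aB <- read.delim("results/anchors_B.tsv", stringsAsFactors = FALSE)
gA <- read_genome("results/sim/genomeA.fa", "simA")
gB <- read_genome("results/sim/genomeB.fa", "simB")
studies <- read_study_table("results/sim/studies.tsv")
truth <- jsonlite::read_json("results/sim/truth.json", simplifyVector = TRUE)
cfg <- truth$config

pr <- project_reports(studies, list(potato = aA, tomato = aB),
                      list(potato = gA$chrom_lengths,
                           tomato = gB$chrom_lengths),
                      half_width = cfg$half_width)
loci <- filter_large(assign_names(merge_loci(pr$candidates)),
                     cfg$large_cutoff)
write_tsv(loci, "results/loci.tsv")
if (nrow(pr$dropped)) write_tsv(pr$dropped, "results/dropped_reports.tsv")

cov <- evaluate_causal_coverage(loci, truth$studies)
message(sprintf(
  "%d study reports -> %d candidates -> %d named loci (%d excluded >%s bp); causal coverage %.3f (%d/%d)",
  length(unique(studies$report_id)), nrow(pr$candidates), nrow(loci),
  sum(loci$excluded_large), format(cfg$large_cutoff, big.mark = ","),
  cov$coverage, cov$n_contained, cov$n_checked))
message(sprintf("support distribution: %s",
                paste(names(table(loci$support)), table(loci$support),
                      sep = "x", collapse = ", ")))
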
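#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system — a diverged genome pair
# with planted inversions and intra-chromosomal translocations, a marker
# catalogue sampled from genome A, and simulated mapping studies around
# hidden causal positions. Everything downstream consumes only the files
# written here; the truth set is kept separately for evaluation.

suppressPackageStartupMessages(library(traitanchor))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
sim <- simulate_all(cfg)

write_genome(sim$genomeA, "results/sim/genomeA.fa")
write_genome(sim$genomeB, "results/sim/genomeB.fa")
write_tsv(sim$markers, "results/sim/markers.tsv")
write_tsv(sim$studies[setdiff(names(sim$studies), "report_id")],
          "results/sim/studies.tsv")
jsonlite::write_json(
  list(rearrangements = sim$truth$rearrangements,
       markers = sim$truth$markers, studies = sim$truth$studies,
       config = sim$truth$config),
  "results/sim/truth.json", auto_unbox = TRUE, digits = NA, null = "null")

message(sprintf(
  "simulated %d chromosomes x %s bp per genome; %d planted events (%d inversions, %d translocations); %d markers; %d studies",
  cfg$n_chrom, format(cfg$chrom_len_bp, big.mark = ","),
  nrow(sim$truth$rearrangements),
  sum(sim$truth$rearrangements$kind == "inversion"),
  sum(sim$truth$rearrangements$kind == "intra_translocation"),
  nrow(sim$markers), length(unique(sim$studies$study_id))))
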
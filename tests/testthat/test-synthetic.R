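small_cfg <- function(...) {
  base <- list(n_chrom = 2L, chrom_len_bp = 4e5, n_inversions = 2L,
               n_translocations = 1L, rearr_size_range = c(3e4, 6e4),
               n_markers = 80L, n_studies = 12L, n_causal = 6L,
               half_width = 3e4, large_cutoff = 2e5, seed = 71L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("the generator is deterministic under one seed", {
  s1 <- simulate_all(small_cfg())
  s2 <- simulate_all(small_cfg())
  expect_identical(as.character(s1$genomeA$seqs), as.character(s2$genomeA$seqs))
  expect_identical(as.character(s1$genomeB$seqs), as.character(s2$genomeB$seqs))
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$studies, s2$studies)
  s3 <- simulate_all(small_cfg(seed = 72L))
  expect_false(identical(as.character(s1$genomeA$seqs),
                         as.character(s3$genomeA$seqs)))
})

test_that("zero divergence and zero rearrangements give identical genomes", {
  cfg <- small_cfg(divergence = 0, n_inversions = 0L,
                   n_translocations = 0L, dup_frac = 0)
  sim <- simulate_genome_pair(cfg)
  expect_identical(as.character(sim$genomeA$seqs),
                   as.character(sim$genomeB$seqs))
  expect_equal(nrow(sim$truth$rearrangements), 0)
})

test_that("planted truth spans have equal width in both genomes", {
  sim <- simulate_genome_pair(small_cfg())
  tr <- sim$truth$rearrangements
  expect_equal(nrow(tr), 3)
  expect_equal(tr$endA - tr$startA, tr$endB - tr$startB)
  expect_equal(tr$size, tr$endA - tr$startA)
  expect_true(all(tr$size >= 3e4 & tr$size <= 6e4))
  # reverse-complement identity of an inverted segment (before divergence
  # only; with divergence, bases differ but the coordinates must map)
  cfg0 <- small_cfg(divergence = 0)
  sim0 <- simulate_genome_pair(cfg0)
  tr0 <- sim0$truth$rearrangements
  inv <- tr0[tr0$kind == "inversion", ][1, ]
  segA <- substr(as.character(sim0$genomeA$seqs[[inv$chrom]]),
                 inv$startA + 1, inv$endA)
  segB <- substr(as.character(sim0$genomeB$seqs[[inv$chrom]]),
                 inv$startB + 1, inv$endB)
  expect_identical(segB, revcomp(segA))
  trl <- tr0[tr0$kind == "intra_translocation", ][1, ]
  expect_identical(substr(as.character(sim0$genomeB$seqs[[trl$chrom]]),
                          trl$startB + 1, trl$endB),
                   substr(as.character(sim0$genomeA$seqs[[trl$chrom]]),
                          trl$startA + 1, trl$endA))
})

test_that("the piece map transforms marker positions correctly", {
  cfg <- small_cfg(divergence = 0, dup_frac = 0, primer_pair_frac = 0)
  sim <- simulate_genome_pair(cfg)
  mk <- simulate_markers(sim, cfg)
  tr <- sim$truth$rearrangements
  inv <- tr[tr$kind == "inversion", ][1, ]
  inside <- mk$truth[mk$truth$chrom == inv$chrom &
                       mk$truth$posA >= inv$startA &
                       mk$truth$posA < inv$endA, ]
  if (nrow(inside)) {
    expect_true(all(inside$posB >= inv$startB & inside$posB < inv$endB))
    # reversal: order inverts within the segment
    if (nrow(inside) > 1) {
      o <- order(inside$posA)
      expect_true(all(diff(inside$posB[o]) < 0))
    }
  }
  # with zero divergence each marker sequence reoccurs verbatim at posB
  m1 <- mk$markers[match(mk$truth$locus_id[1], mk$markers$locus_id), ]
  t1 <- mk$truth[1, ]
  g <- anchor_markers(m1, sim$genomeB)
  expect_equal(g$status, "unique")
  expect_lt(abs(floor((g$start + g$end) / 2) - t1$posB), 2)
})

test_that("prior chromosomes are exact when mismapping is off", {
  cfg <- small_cfg(p_mismap = 0, dup_frac = 0, garbage_frac = 0)
  sim <- simulate_genome_pair(cfg)
  mk <- simulate_markers(sim, cfg)
  expect_equal(sprintf("chr%02d", mk$markers$prior_chrom), mk$truth$chrom)
  cfg2 <- small_cfg(p_mismap = 1, dup_frac = 0, garbage_frac = 0)
  sim2 <- simulate_genome_pair(cfg2)
  mk2 <- simulate_markers(sim2, cfg2)
  expect_true(all(sprintf("chr%02d", mk2$markers$prior_chrom) !=
                    mk2$truth$chrom))
})

test_that("primer-pair markers e-PCR back to their planted amplicon", {
  cfg <- small_cfg(primer_pair_frac = 0.3, dup_frac = 0)
  sim <- simulate_genome_pair(cfg)
  mk <- simulate_markers(sim, cfg)
  pp <- which(mk$markers$marker_type == "primer_pair")[1:3]
  for (i in pp) {
    h <- epcr_primer_pair(mk$markers$sequence[i], mk$markers$sequence2[i],
                          sim$genomeA)
    expect_gte(nrow(h), 1)
    mid <- floor((h$start[1] + h$end[1]) / 2)
    expect_lt(abs(mid - mk$truth$posA[i]), 2)
  }
})

test_that("flanking studies bracket their causal position", {
  cfg <- small_cfg(p_flanking = 1)
  sim <- simulate_all(cfg)
  tr <- sim$truth$studies
  st <- sim$studies
  mt <- sim$truth$markers
  for (i in which(!tr$loose_evidence & tr$flanking)) {
    ev <- st[st$study_id == tr$study_id[i], ]
    poscol <- if (tr$species[i] == "potato") "posA" else "posB"
    l <- mt[[poscol]][match(ev$marker_id[ev$relation == "flanking_left"],
                            mt$locus_id)]
    r <- mt[[poscol]][match(ev$marker_id[ev$relation == "flanking_right"],
                            mt$locus_id)]
    expect_true(l <= tr$causal_pos[i] && tr$causal_pos[i] <= r)
  }
  # flanking is only skipped where the causal position has no marker on
  # one side
  expect_gt(mean(tr$flanking), 0.5)
  # p_flanking 0: single linked marker within half_width unless loose
  cfg0 <- small_cfg(p_flanking = 0)
  sim0 <- simulate_all(cfg0)
  expect_true(all(table(sim0$studies$study_id) == 1))
})

test_that("garbage markers reproduce the unmatched classes", {
  cfg <- small_cfg(garbage_frac = 0.2, dup_frac = 0,
                   primer_pair_frac = 0, n_markers = 150L)
  sim <- simulate_genome_pair(cfg)
  mk <- simulate_markers(sim, cfg)
  aA <- anchor_markers(mk$markers, sim$genomeA)
  aB <- anchor_markers(mk$markers, sim$genomeB)
  cl <- build_pairs(aA, aB)$classification
  n_garbage <- sum(mk$truth$garbage)
  expect_equal(cl$matched_neither, n_garbage)   # random 400-mers never map
  expect_gte(cl$matched_both, (150 - n_garbage) * 0.9)
  expect_equal(cl$matched_both + cl$matched_one_only + cl$matched_neither,
               150)
})
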
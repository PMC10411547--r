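pairs_from_ranks <- function(ranks, spacing = 1000) {
  data.frame(posA = seq_along(ranks) * spacing, posB = ranks * spacing)
}

test_that("orientation follows the rank correlation in decisive cases", {
  p <- pairs_from_ranks(1:10)
  expect_false(orient_chromosome(p, 11000)$flipped)
  pr <- pairs_from_ranks(10:1)
  o <- orient_chromosome(pr, 11000)
  expect_true(o$flipped)
  expect_equal(o$pairs$posB, 11000 - pr$posB)
  expect_warning(orient_chromosome(pairs_from_ranks(1:2), 3000),
                 "orientation undetermined")
})

test_that("a 60/40 concordance split does not flip the axis", {
  # 6 increasing then 4 decreasing positions; brute-force Kendall sign
  ranks <- c(1, 2, 3, 4, 5, 10, 9, 8, 7, 6)
  p <- pairs_from_ranks(ranks)
  expect_equal(kendall_sign_brute(p$posA, p$posB), 1)
  expect_false(orient_chromosome(p, 11000)$flipped)
})

test_that("chain_collinear matches the brute-force LIS on small cases", {
  cases <- list(c(1, 2, 3, 4, 5, 6),
                c(1, 5, 4, 3, 2, 6),
                c(1, 2, 6, 7, 3, 4, 5))
  for (v in cases) {
    ch <- chain_collinear(pairs_from_ranks(v))
    expect_equal(ch$lis_length, lis_exhaustive(v))
    expect_equal(length(ch$backbone), ch$lis_length)
  }
  set.seed(41)
  for (rep in 1:150) {
    n <- sample(3:8, 1)
    v <- sample(n)
    ch <- chain_collinear(pairs_from_ranks(v))
    expect_equal(ch$lis_length, lis_dp(v))
  }
})

test_that("reversed and displaced runs are recovered as blocks", {
  ch <- chain_collinear(pairs_from_ranks(c(1, 5, 4, 3, 2, 6)))
  expect_equal(ch$lis_length, 3)
  runs <- ch$runs[lengths(ch$runs) > 1]
  expect_equal(length(runs), 1)
  expect_equal(runs[[1]], 2:5)                 # the whole reversed segment
  expect_true(all(diff(ch$posB[runs[[1]]]) < 0))
  expect_length(ch$absorbed, 1)                # one LIS member reclaimed

  ch2 <- chain_collinear(pairs_from_ranks(c(1, 2, 6, 7, 3, 4, 5)))
  runs2 <- ch2$runs[lengths(ch2$runs) > 1]
  expect_equal(runs2[[1]], 3:4)                # {6,7} displaced, in order
  expect_true(all(diff(ch2$posB[runs2[[1]]]) > 0))
})

test_that("classification maps run geometry to call kind and size", {
  # reversed run spanning 1.4 Mbp in A, 1.1 Mbp in B: size is the max width
  pairs <- data.frame(
    posA = c(1e5, 2e5, 10e5, 17e5, 24e5, 26e5, 30e5),
    posB = c(1e5, 2e5, 16.5e5, 11e5, 5.5e5, 26e5, 30e5))
  ch <- chain_collinear(pairs)
  calls <- classify_blocks(ch, "chr01")
  inv <- calls[calls$kind == "inversion", ]
  expect_equal(nrow(inv), 1)
  expect_equal(inv$size, 1.4e6)

  # one-anchor displacement is below min_block_anchors: logged, not called
  p2 <- pairs_from_ranks(c(1, 2, 9, 3, 4, 5, 6, 7, 8))
  calls2 <- classify_blocks(chain_collinear(p2), "chr01",
                            rearrange_params(min_block_anchors = 2))
  expect_equal(nrow(calls2), 0)
  expect_match(attr(calls2, "notes"), "below min_block_anchors")
})

synthetic_chrom_pairs <- function() {
  # planted structure on one 3 Mbp chromosome: inversion at [1.0,1.4] Mbp,
  # translocation moving [2.0,2.2] to 0.5 Mbp
  posA <- seq(5e4, 2.95e6, by = 3e4)
  posB <- posA
  inv <- posA >= 1.0e6 & posA <= 1.4e6
  posB[inv] <- 1.0e6 + 1.4e6 - posA[inv]
  seg <- posA >= 2.0e6 & posA <= 2.2e6
  between <- posA > 0.5e6 & posA < 2.0e6 & !seg
  posB[seg] <- posA[seg] - 1.5e6
  posB[between & !inv] <- posB[between & !inv] + 2e5 + 1
  posB[inv] <- posB[inv] + 2e5 + 1
  data.frame(posA = posA, posB = posB,
             chromA = "chr01", chromB = "chr01",
             is_comparison_anchor = TRUE, locus_id = seq_along(posA))
}

test_that("planted inversion and translocation are called with spans", {
  p <- synthetic_chrom_pairs()
  lens <- c(chr01 = 3e6)
  re <- detect_rearrangements(p, lens, lens)
  expect_equal(sort(re$calls$kind), c("intra_translocation", "inversion"))
  inv <- re$calls[re$calls$kind == "inversion", ]
  expect_lt(abs(inv$startA - 1.0e6), 5e4)
  expect_lt(abs(inv$endA - 1.4e6), 5e4)
  tr <- re$calls[re$calls$kind == "intra_translocation", ]
  expect_lt(abs(tr$startA - 2.0e6), 5e4)
  expect_false(re$orientations$flipped)
})

test_that("interval projection maps through direct and inverted blocks", {
  p <- synthetic_chrom_pairs()
  lens <- c(chr01 = 3e6)
  re <- detect_rearrangements(p, lens, lens)
  bm <- re$block_map[["chr01"]]
  blocks <- Filter(function(b) b$role == "displaced", bm$blocks)
  invb <- Filter(function(b) b$orientation == "inverted", blocks)[[1]]
  # interval equal to the inverted block's anchor span maps to its B span
  ivA <- range(invb$anchorsA)
  proj <- project_interval(ivA, bm)
  expect_equal(proj$interval,
               c(floor(min(invb$anchorsB)), ceiling(max(invb$anchorsB))))
  # midpoint symmetry inside the (uniformly anchored) inverted block
  midA <- mean(ivA)
  pm <- project_interval(c(midA - 1, midA + 1), bm)
  expect_lt(abs(mean(pm$interval) - mean(range(invb$anchorsB))), 2e3)
  # straddling interval uses >1 block and sets the flag
  ps <- project_interval(c(ivA[1] - 1e5, ivA[1] + 1e5), bm)
  expect_true(ps$gap_spanning)
  # unanchored chromosome
  expect_equal(project_interval(c(0, 10), NULL)$reason,
               "unanchored_region")
})

test_that("projection round-trip returns near the original interval", {
  p <- synthetic_chrom_pairs()
  lens <- c(chr01 = 3e6)
  bm <- detect_rearrangements(p, lens, lens)$block_map[["chr01"]]
  for (iv in list(c(2e5, 3e5), c(1.05e6, 1.2e6), c(2.4e6, 2.6e6))) {
    there <- project_interval(iv, bm)$interval
    back <- traitanchor:::project_interval_b_to_a(there, bm)
    expect_true(back[1] <= iv[1] + 3.1e4 && back[2] >= iv[2] - 3.1e4)
  }
})

test_that("globally reflecting genome B changes only the orientation", {
  p <- synthetic_chrom_pairs()
  lens <- c(chr01 = 3e6)
  re1 <- detect_rearrangements(p, lens, lens)
  pf <- p
  pf$posB <- 3e6 - pf$posB
  re2 <- detect_rearrangements(pf, lens, lens)
  expect_false(re1$orientations$flipped)
  expect_true(re2$orientations$flipped)
  o1 <- re1$calls[order(re1$calls$startA), c("kind", "startA", "endA")]
  o2 <- re2$calls[order(re2$calls$startA), c("kind", "startA", "endA")]
  expect_equal(o1, o2, ignore_attr = TRUE)
})
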
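# brute-force hit oracle: evaluate every diagonal placement of the query
# on every chromosome/strand and keep those passing the identity gate
brute_hits <- function(query, genome, min_identity = 70, min_len = 30) {
  res <- NULL
  for (ch in names(genome$seqs)) {
    subj <- strsplit(as.character(genome$seqs[[ch]]), "")[[1]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revcomp(query)
      qv <- strsplit(q, "")[[1]]
      L <- length(subj); n <- length(qv)
      for (off in seq(-n + min_len, L - min_len)) {
        qs <- max(1, 1 - off); qe <- min(n, L - off)
        if (qe - qs + 1 < min_len) next
        idx <- qs:qe
        matches <- sum(qv[idx] == subj[idx + off])
        ident <- 100 * matches / length(idx)
        if (ident > min_identity)
          res <- rbind(res, data.frame(chrom = ch, start = qs + off - 1,
                                       end = qe + off, strand = strand,
                                       score = matches))
      }
    }
  }
  res
}

test_that("exact substrings anchor with full identity on both strands", {
  g <- tiny_genome(c(chr03 = 5000), seed = 11)
  q <- substr(as.character(g$seqs[[1]]), 1201, 1700)
  h <- align_candidates(q, g)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 100)
  expect_equal(h$strand, "+")
  expect_equal(c(h$start, h$end), c(1200, 1700))
  hr <- align_candidates(revcomp(q), g)
  expect_equal(hr$strand, "-")
  expect_equal(c(hr$start, hr$end), c(1200, 1700))  # same span
})

test_that("a duplicated segment yields exactly two equal-score hits", {
  set.seed(12)
  seg <- rand_dna(300)
  chr <- paste0(rand_dna(1000), seg, rand_dna(800), seg, rand_dna(900))
  g <- genome_set("dup", c(chr01 = chr))
  q <- substr(seg, 51, 250)
  h <- align_candidates(q, g)
  expect_equal(nrow(h), 2)
  expect_equal(h$score[1], h$score[2])
  oracle <- brute_hits(q, g)
  oracle <- oracle[oracle$score == max(oracle$score), ]
  expect_equal(nrow(oracle), 2)   # brute force confirms two maximal hits
  expect_setequal(h$start, oracle$start)
})

test_that("high-N queries are rejected as low complexity", {
  g <- tiny_genome(c(chr01 = 2000), seed = 13)
  q <- paste0(substr(as.character(g$seqs[[1]]), 1, 40),
              paste(rep("N", 60), collapse = ""))
  h <- align_candidates(q, g)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "reason"), "low_complexity_query")
})

test_that("identity gate is strict and prior chromosome resolves ties", {
  hits2 <- data.frame(chrom = c("chr02", "chr07"), start = c(100, 900),
                      end = c(400, 1200), strand = "+",
                      identity = c(95, 95), score = c(285, 285),
                      aln_len = 300, stringsAsFactors = FALSE)
  a <- resolve_anchor(hits2, prior_chrom = 7)
  expect_equal(a$status, "resolved_by_prior")
  expect_equal(a$chrom, "chr07")
  a2 <- resolve_anchor(hits2, prior_chrom = NA)
  expect_equal(a2$status, "ambiguous")
  expect_true(is.na(a2$start))
  a3 <- resolve_anchor(empty_hits_df())
  expect_equal(a3$status, "unplaced")
  # one hit below the gate never reaches resolve: align_candidates drops it
  set.seed(14)
  g <- tiny_genome(c(chr01 = 8000), seed = 14)
  q <- substr(as.character(g$seqs[[1]]), 2001, 2100)
  qv <- strsplit(q, "")[[1]]
  mut <- function(n) {             # mutate the first n positions
    v <- qv
    v[seq_len(n)] <- chartr("ACGT", "GTAC", v[seq_len(n)])
    paste(v, collapse = "")
  }
  h65 <- align_candidates(mut(35), g)   # identity 65 < 70
  expect_equal(nrow(h65), 0)
  expect_equal(resolve_anchor(h65)$status, "unplaced")
  h71 <- align_candidates(mut(29), g)   # identity 71 > 70
  expect_equal(resolve_anchor(h71)$status, "unique")
})

test_that("near-equal hits clustered in one window collapse to a midpoint", {
  hits <- data.frame(chrom = "chr04", start = c(1e6, 1.4e6),
                     end = c(1.0003e6, 1.4003e6), strand = "+",
                     identity = c(98, 97.5), score = c(295, 293),
                     aln_len = 300, stringsAsFactors = FALSE)
  a <- resolve_anchor(hits)
  expect_equal(a$status, "resolved_by_prior")
  expect_equal(a$reason, "clustered_family")
  expect_true(a$start >= 1e6 && a$end <= 1.4003e6)
})

test_that("raising min_identity never increases placed anchors", {
  cfg <- sim_config(n_chrom = 1L, chrom_len_bp = 2e5, n_inversions = 1L,
                    n_translocations = 0L, rearr_size_range = c(2e4, 4e4),
                    n_markers = 60L, seed = 21L)
  sim <- simulate_genome_pair(cfg)
  mk <- simulate_markers(sim, cfg)
  placed <- vapply(c(70, 80, 90, 96), function(mi) {
    a <- anchor_markers(mk$markers, sim$genomeB,
                        anchor_params(min_identity = mi))
    sum(a$status %in% c("unique", "resolved_by_prior"))
  }, numeric(1))
  expect_true(all(diff(placed) <= 0))
})

test_that("e-PCR recovers a planted amplicon and applies its gates", {
  set.seed(15)
  left <- rand_dna(2000); mid <- rand_dna(300); right <- rand_dna(2500)
  fwd <- rand_dna(20); rev_primer <- rand_dna(20)
  chr <- paste0(left, fwd, mid, revcomp(rev_primer), right)
  g <- genome_set("epcr", c(chr01 = chr))
  h <- epcr_primer_pair(fwd, rev_primer, g)
  expect_equal(nrow(h), 1)
  expect_equal(h$aln_len, 300 + 20 + 20)     # product spans outer ends
  expect_equal(c(h$start, h$end), c(2000, 2000 + 340))
  expect_equal(h$strand, "+")

  # 5' mismatch on the forward primer is tolerated (outside the 3' seed)
  fwd5 <- paste0(chartr("ACGT", "GTAC", substr(fwd, 1, 1)),
                 substr(fwd, 2, 20))
  expect_equal(nrow(epcr_primer_pair(fwd5, rev_primer, g)), 1)
  # 3'-terminal mismatch kills the site
  fwd3 <- paste0(substr(fwd, 1, 19),
                 chartr("ACGT", "GTAC", substr(fwd, 20, 20)))
  h3 <- epcr_primer_pair(fwd3, rev_primer, g)
  expect_equal(nrow(h3), 0)

  # product-length cap: primers 8 kb apart with max_amplicon 5 kb
  chr_far <- paste0(left, fwd, rand_dna(8000), revcomp(rev_primer), right)
  gf <- genome_set("far", c(chr01 = chr_far))
  expect_equal(nrow(epcr_primer_pair(fwd, rev_primer, gf)), 0)

  # primer sites only on the same strand: no opposed sites
  chr_same <- paste0(left, fwd, mid, rev_primer, right)
  gs <- genome_set("same", c(chr01 = chr_same))
  hs <- epcr_primer_pair(fwd, rev_primer, gs)
  expect_equal(nrow(hs), 0)
  expect_equal(attr(hs, "reason"), "no_opposed_sites")
})

test_that("planted markers anchor uniquely at their true midpoint", {
  cfg <- sim_config(n_chrom = 2L, chrom_len_bp = 4e5, n_inversions = 2L,
                    n_translocations = 1L, rearr_size_range = c(3e4, 6e4),
                    n_markers = 150L, primer_pair_frac = 0, dup_frac = 0,
                    seed = 22L)
  sim <- simulate_genome_pair(cfg)
  mk <- simulate_markers(sim, cfg)
  a <- anchor_markers(mk$markers, sim$genomeB)
  expect_gte(mean(a$status == "unique"), 0.99)
  m <- merge(a[a$status == "unique", ], mk$truth, by = "locus_id")
  mid <- floor((m$start + m$end) / 2)
  expect_gte(mean(abs(mid - m$posB) <= 50), 0.99)
})
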
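chr_lens <- c(chr01 = 60e6, chr05 = 60e6, chr09 = 60e6)

test_that("a single linked marker yields the +/- half-width interval", {
  anch <- anchor_row("M1", "chr05", 10e6 - 50, 10e6 + 50)
  rep1 <- report_df("S1", "M1", "linked", chrom = "chr05")
  cand <- project_report(rep1, anch, chr_lens, half_width = 2e6)
  expect_equal(c(cand$start, cand$end), c(8e6, 12e6))
  # near the chromosome start the interval is clipped at zero
  anch2 <- anchor_row("M1", "chr05", 1e6 - 50, 1e6 + 50)
  cand2 <- project_report(rep1, anch2, chr_lens, half_width = 2e6)
  expect_equal(c(cand2$start, cand2$end), c(0, 3e6))
})

test_that("flanking markers bound the interval exactly", {
  anch <- rbind(anchor_row("ML", "chr05", 5e6 - 50, 5e6 + 50),
                anchor_row("MR", "chr05", 9e6 - 50, 9e6 + 50))
  rep1 <- report_df("S1", c("ML", "MR"),
                    c("flanking_left", "flanking_right"), chrom = "chr05")
  cand <- project_report(rep1, anch, chr_lens, half_width = 2e6)
  expect_equal(c(cand$start, cand$end), c(5e6, 9e6))
  # inverted flank order is an error
  rep2 <- report_df("S1", c("MR", "ML"),
                    c("flanking_left", "flanking_right"), chrom = "chr05")
  expect_error(project_report(rep2, anch, chr_lens), "flank_order_conflict")
})

test_that("unanchored evidence drops the report with a reason", {
  anch <- anchor_row("M1", "chr05", 100, 200, status = "unplaced")
  rep1 <- report_df("S1", "M1", "linked", chrom = "chr05")
  out <- project_report(rep1, anch, chr_lens)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "reason"), "no_anchored_evidence")
})

test_that("overlapping study intervals merge by single linkage", {
  cand <- rbind(
    data.frame(study_id = "S1", species = "potato", trait_class = "LBR",
               locus_kind = "quantitative", chrom = "chr05", start = 3e6,
               end = 7e6, locus_name = NA, report_id = "r1"),
    data.frame(study_id = "S2", species = "potato", trait_class = "LBR",
               locus_kind = "quantitative", chrom = "chr05", start = 5e6,
               end = 9e6, locus_name = NA, report_id = "r2"))
  m <- merge_loci(cand)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(3e6, 9e6))   # union, not intersection
  expect_equal(m$support, 2)
  expect_equal(m$star, "*")

  # disjoint intervals stay separate with single-study support
  cand$start <- c(1e6, 10e6); cand$end <- c(2e6, 12e6)
  m2 <- merge_loci(cand)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$star, c("", ""))

  # half-open adjacency ([1,2) and [2,3)) is not an overlap
  cand$start <- c(1e6, 2e6); cand$end <- c(2e6, 3e6)
  expect_equal(nrow(merge_loci(cand)), 2)
})

test_that("star labels follow the support rule on 1-4 study cases", {
  mk <- function(n) do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(study_id = paste0("S", i), species = "potato",
               trait_class = "LBR", locus_kind = "quantitative",
               chrom = "chr05", start = 3e6 + i * 1e5, end = 8e6 + i * 1e5,
               locus_name = NA, report_id = paste0("r", i))))
  stars <- vapply(1:4, function(n) merge_loci(mk(n))$star, character(1))
  expect_equal(stars, c("", "*", "*", "**"))
  expect_equal(merge_loci(mk(2))$support, 2)
  expect_equal(merge_loci(mk(4))$support, 4)
})

test_that("uniform names are serial by position; gene symbols pass through", {
  loci <- rbind(
    data.frame(species = "potato", trait_class = "LBR",
               locus_kind = "quantitative", chrom = "chr05", start = 1e6,
               end = 6e6, support = 5L, star = "**", locus_name = NA,
               study_ids = "", report_ids = ""),
    data.frame(species = "tomato", trait_class = "sugar",
               locus_kind = "quantitative", chrom = "chr09", start = 2e6,
               end = 5e6, support = 1L, star = "", locus_name = NA,
               study_ids = "", report_ids = ""),
    data.frame(species = "tomato", trait_class = "sugar",
               locus_kind = "quantitative", chrom = "chr09", start = 20e6,
               end = 24e6, support = 2L, star = "*", locus_name = NA,
               study_ids = "", report_ids = ""),
    data.frame(species = "potato", trait_class = "sugar",
               locus_kind = "quantitative", chrom = "chr09", start = 3e6,
               end = 6e6, support = 1L, star = "", locus_name = NA,
               study_ids = "", report_ids = ""),
    data.frame(species = "potato", trait_class = "LBR",
               locus_kind = "qualitative", chrom = "chr05", start = 2e6,
               end = 2.01e6, support = 1L, star = "", locus_name = "R1",
               study_ids = "", report_ids = ""))
  nm <- assign_names(loci)
  expect_equal(nm$name[1], "pLBR5.1")
  expect_equal(nm$name[2], "tSS9.1")
  expect_equal(nm$name[3], "tSS9.2")    # second tomato sugar QTL on chr09
  expect_equal(nm$name[4], "pTSC9.1")   # species-specific sugar acronym
  expect_equal(nm$name[5], "R1")        # published symbol kept verbatim
  bad <- loci[1, ]; bad$trait_class <- "XYZ"
  expect_error(assign_names(bad), "unknown trait_class")
})

test_that("the large-interval exclusion is strictly greater-than", {
  loci <- rbind(locus_row("a", "chr01", 0, 16e6),
                locus_row("b", "chr01", 0, 15e6),
                locus_row("c", "chr01", 0, 4.2e6))
  f <- filter_large(loci, 15e6)
  expect_equal(f$excluded_large, c(TRUE, FALSE, FALSE))
})

test_that("cloned genes get point intervals; mapped genes get spans", {
  mk <- data.frame(locus_id = c("G1", "ML", "MR", "M1"),
                   marker_type = c("gene", "genomic_clone",
                                   "genomic_clone", "genomic_clone"),
                   sequence = "x", sequence2 = NA, prior_chrom = NA,
                   stringsAsFactors = FALSE)
  anch <- rbind(anchor_row("G1", "chr05", 2340000, 2346500),
                anchor_row("ML", "chr05", 5e6, 5e6 + 100),
                anchor_row("MR", "chr05", 6.8e6, 6.8e6 + 100),
                anchor_row("M1", "chr05", 10e6 - 50, 10e6 + 50))
  g <- place_gene(report_df("S1", "G1", "cosegregating", chrom = "chr05",
                            locus_kind = "qualitative", locus_name = "R1"),
                  anch, chr_lens, markers = mk)
  expect_equal(c(g$start, g$end), c(2340000, 2346500))
  expect_equal(g$locus_kind, "qualitative")
  fl <- place_gene(report_df("S2", c("ML", "MR"),
                             c("flanking_left", "flanking_right"),
                             chrom = "chr05", locus_kind = "qualitative"),
                   anch, chr_lens, markers = mk)
  expect_equal(fl$end - fl$start, 1.8e6)
  lk <- place_gene(report_df("S3", "M1", "linked", chrom = "chr05",
                             locus_kind = "qualitative"),
                   anch, chr_lens, half_width = 2e6, markers = mk)
  expect_equal(lk$end - lk$start, 4e6)
})

test_that("merging is idempotent, order-invariant, support-conserving", {
  set.seed(51)
  anch <- do.call(rbind, lapply(1:30, function(i)
    anchor_row(paste0("M", i), "chr01", i * 1.5e6, i * 1.5e6 + 100)))
  studies <- do.call(rbind, lapply(1:12, function(s) {
    m <- sample(30, 1)
    report_df(sprintf("S%02d", s), paste0("M", m), "linked")
  }))
  pr <- project_reports(studies, list(potato = anch),
                        list(potato = chr_lens), half_width = 2e6)
  merged <- merge_loci(pr$candidates)
  named <- assign_names(merged)
  # support conservation
  expect_equal(sum(merged$support), length(unique(studies$report_id)))
  # idempotence: merging the merged output changes nothing
  again <- merge_loci(within(merged, {
    study_id <- study_ids; report_id <- report_ids
  }))
  expect_equal(nrow(again), nrow(merged))
  expect_equal(again$start, merged$start)
  expect_equal(again$end, merged$end)
  # order invariance
  pr2 <- project_reports(studies[sample(nrow(studies)), ],
                         list(potato = anch), list(potato = chr_lens),
                         half_width = 2e6)
  named2 <- assign_names(merge_loci(pr2$candidates))
  expect_equal(named2$name, named$name)
  expect_equal(named2$start, named$start)
})
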
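# fixtures and independent oracles, built in code

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

tiny_genome <- function(lens = c(chr01 = 20000, chr02 = 20000), seed = 1) {
  set.seed(seed)
  genome_set("tiny", vapply(lens, rand_dna, character(1)))
}

# exhaustive-enumeration LIS oracle (all subsets; n <= 15)
lis_exhaustive <- function(v) {
  n <- length(v)
  best <- 0L
  for (m in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (all(diff(v[idx]) > 0)) best <- max(best, length(idx))
  }
  best
}

# quadratic-DP LIS oracle (independent of the patience-sorting chain)
lis_dp <- function(v) {
  n <- length(v)
  if (n == 0) return(0L)
  dp <- rep(1L, n)
  for (i in seq_len(n)) {
    prev <- which(v[seq_len(i - 1)] < v[i])
    if (length(prev)) dp[i] <- 1L + max(dp[prev])
  }
  max(dp)
}

# all permutations of 1..n
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ], n, after = pos - 1)
  }
  out
}

# brute-force all-pairs interval overlap oracle
brute_overlap_pairs <- function(loci) {
  res <- NULL
  n <- nrow(loci)
  if (n < 2) return(res)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (loci$chrom[i] != loci$chrom[j]) next
    ov <- min(loci$end[i], loci$end[j]) - max(loci$start[i], loci$start[j])
    if (ov > 0)
      res <- rbind(res, data.frame(
        locus1 = min(loci$name[i], loci$name[j]),
        locus2 = max(loci$name[i], loci$name[j]),
        overlap_bp = ov, stringsAsFactors = FALSE))
  }
  res[order(res$locus1, res$locus2), , drop = FALSE]
}

# brute-force Kendall concordance sign
kendall_sign_brute <- function(a, b) {
  s <- 0
  n <- length(a)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
  sign(s)
}

empty_hits_df <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), identity = numeric(), score = numeric(),
             aln_len = numeric(), stringsAsFactors = FALSE)
}

# an anchor-table row as produced by anchor_markers
anchor_row <- function(locus_id, chrom, start, end, strand = "+",
                       identity = 100, status = "unique", reason = "",
                       genome_id = "g") {
  data.frame(locus_id = locus_id, genome_id = genome_id, chrom = chrom,
             start = start, end = end, strand = strand,
             identity = identity, evalue_class = "normal", status = status,
             reason = reason, stringsAsFactors = FALSE)
}

# one study-report evidence table
report_df <- function(study_id, marker_ids, relations, chrom = "chr01",
                      species = "potato", trait_class = "LBR",
                      locus_kind = "quantitative", locus_name = NA) {
  d <- data.frame(study_id = study_id, species = species,
                  trait_class = trait_class, locus_kind = locus_kind,
                  chrom = chrom, marker_id = marker_ids,
                  relation = relations,
                  locus_name = as.character(locus_name),
                  stringsAsFactors = FALSE)
  d$report_id <- paste(d$study_id, d$species, d$trait_class, d$locus_kind,
                       d$chrom, ifelse(is.na(d$locus_name), "",
                                       d$locus_name), sep = "|")
  d
}

# named-locus table row
locus_row <- function(name, chrom, start, end, species = "potato",
                      trait_class = "LBR", locus_kind = "quantitative",
                      support = 1L) {
  data.frame(species = species, trait_class = trait_class,
             locus_kind = locus_kind, chrom = chrom, start = start,
             end = end, support = support, star = "",
             locus_name = NA_character_, study_ids = "", report_ids = "",
             name = name, excluded_large = FALSE, stringsAsFactors = FALSE)
}

# resistance loci laid out like the published chr05 and chr09 resistance clusters
# (coordinates in Mbp converted to bp); a mixture of cloned genes, mapped
# gene intervals and QRL covering >= 4 pathogen classes
hotspot_fixture <- function() {
  mk <- function(name, start_mbp, end_mbp, species, trait_class, kind)
    locus_row(name, "chr05", start_mbp * 1e6, end_mbp * 1e6,
              species = species, trait_class = trait_class,
              locus_kind = kind)
  potato5 <- rbind(
    mk("R1", 0.2, 0.25, "potato", "LBR", "qualitative"),
    mk("H2", 1.1, 1.15, "potato", "Gpa", "qualitative"),
    mk("Nb", 2.0, 2.05, "potato", "qTy", "qualitative"),
    mk("Rx2", 2.3, 2.35, "potato", "qTy", "qualitative"),
    mk("Gpa", 4.0, 6.0, "potato", "Gpa", "quantitative"),
    mk("Gpa5", 4.5, 5.8, "potato", "Gpa", "quantitative"),
    mk("Grp1", 4.2, 5.5, "potato", "Gpa", "quantitative"),
    mk("RSe-Va", 1.5, 3.0, "potato", "RSe", "quantitative"),
    mk("pLBR5.1", 0.0, 6.0, "potato", "LBR", "quantitative"),
    mk("CBR5.1", 2.5, 4.5, "potato", "CBR", "quantitative"))
  tomato5 <- rbind(
    mk2 <- locus_row("Bs4", "chr05", 1.2e6, 1.25e6, species = "tomato",
                     trait_class = "BWR", locus_kind = "qualitative"),
    locus_row("SlSW-5-1", "chr05", 2.0e6, 4.0e6, species = "tomato",
              trait_class = "qTy", locus_kind = "quantitative"),
    locus_row("EBR5.1", "chr05", 1.0e6, 6.0e6, species = "tomato",
              trait_class = "EBR", locus_kind = "quantitative"))
  list(potato = potato5, tomato = tomato5)
}
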
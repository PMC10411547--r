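#' Score rearrangement calls against planted truth
#'
#' A call matches a truth record when kind and chromosome agree and the
#' genome-A spans overlap reciprocally by at least `min_overlap` (both
#' overlap/width fractions). Matching is greedy one-to-one in descending
#' overlap.
#'
#' @param calls calls from [detect_rearrangements()].
#' @param truth `truth$rearrangements` from [simulate_genome_pair()].
#' @param min_overlap reciprocal overlap fraction (0.5).
#' @return list: precision, recall, n_calls, n_truth, n_matched.
#' @export
evaluate_rearrangements <- function(calls, truth, min_overlap = 0.5) {
  if (!nrow(calls) || !nrow(truth))
    return(list(precision = ifelse(nrow(calls) == 0, NA, 0),
                recall = ifelse(nrow(truth) == 0, NA, 0),
                n_calls = nrow(calls), n_truth = nrow(truth),
                n_matched = 0L))
  cand <- list()
  for (i in seq_len(nrow(calls))) for (j in seq_len(nrow(truth))) {
    if (calls$kind[i] != truth$kind[j] ||
        calls$chrom[i] != truth$chrom[j]) next
    ov <- min(calls$endA[i], truth$endA[j]) -
      max(calls$startA[i], truth$startA[j])
    if (ov <= 0) next
    f1 <- ov / (calls$endA[i] - calls$startA[i])
    f2 <- ov / (truth$endA[j] - truth$startA[j])
    if (f1 >= min_overlap && f2 >= min_overlap)
      cand[[length(cand) + 1]] <- c(i, j, min(f1, f2))
  }
  used_c <- used_t <- integer(); matched <- 0L
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      if (cand[r, 1] %in% used_c || cand[r, 2] %in% used_t) next
      used_c <- c(used_c, cand[r, 1]); used_t <- c(used_t, cand[r, 2])
      matched <- matched + 1L
    }
  }
  list(precision = matched / nrow(calls), recall = matched / nrow(truth),
       n_calls = nrow(calls), n_truth = nrow(truth), n_matched = matched)
}

#' Fraction of merged loci containing their hidden causal position
#'
#' For every non-loose simulated study report, the merged locus that the
#' report contributed to must contain the study's causal position.
#'
#' @param loci merged locus table (with `report_ids`).
#' @param study_truth `truth$studies` from [simulate_all()].
#' @return list: coverage, n_checked, n_contained.
#' @export
evaluate_causal_coverage <- function(loci, study_truth) {
  tr <- study_truth[!study_truth$loose_evidence, , drop = FALSE]
  checked <- contained <- 0L
  rep_lists <- strsplit(loci$report_ids, ",", fixed = TRUE)
  for (i in seq_len(nrow(tr))) {
    hit <- which(vapply(rep_lists, function(r) tr$report_id[i] %in% r,
                        logical(1)))
    if (!length(hit)) next
    checked <- checked + 1L
    l <- loci[hit[1], ]
    if (tr$causal_pos[i] >= l$start && tr$causal_pos[i] < l$end)
      contained <- contained + 1L
  }
  list(coverage = if (checked) contained / checked else NA_real_,
       n_checked = checked, n_contained = contained)
}
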
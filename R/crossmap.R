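#' Join anchors of the same locus across two genomes into matched pairs
#'
#' A pair is emitted for every locus placed (status `unique` or
#' `resolved_by_prior`) in both genomes on the same chromosome number
#' (homeologous pairing). Loci placed on different chromosome numbers are
#' excluded from pairs and counted with reason `chrom_conflict`. Pair
#' position is the anchor midpoint (symmetric under strand flips). The
#' comparison-anchor subset used for rearrangement detection defaults to
#' pairs with both statuses `unique`.
#'
#' @param anchorsA,anchorsB anchor tables from [anchor_markers()], keyed by
#'   locus_id (duplicates are an error).
#' @return list with `pairs` (locus_id, chromA, posA, strandA, chromB,
#'   posB, strandB, is_comparison_anchor) and `classification` (counts
#'   matched_both / matched_one_only / matched_neither summing to the
#'   catalogue size, plus per-locus reason codes).
#' @export
build_pairs <- function(anchorsA, anchorsB) {
  for (nm in c("A", "B")) {
    tab <- if (nm == "A") anchorsA else anchorsB
    if (anyDuplicated(tab$locus_id))
      stop("duplicate locus_id in anchor table ", nm, ": ",
           paste(unique(tab$locus_id[duplicated(tab$locus_id)]),
                 collapse = ", "))
  }
  ids <- sort(unique(c(anchorsA$locus_id, anchorsB$locus_id)))
  a <- anchorsA[match(ids, anchorsA$locus_id), , drop = FALSE]
  b <- anchorsB[match(ids, anchorsB$locus_id), , drop = FALSE]
  placed <- function(x) !is.na(x$status) & x$status %in%
    c("unique", "resolved_by_prior")
  pa <- placed(a); pb <- placed(b)
  same_chr <- pa & pb & chrom_number(a$chrom) == chrom_number(b$chrom)
  conflict <- pa & pb & !same_chr

  reason <- rep("matched_both", length(ids))
  reason[pa & !pb] <- "placed_A_only"
  reason[!pa & pb] <- "placed_B_only"
  reason[!pa & !pb] <- "matched_neither"
  reason[conflict] <- "chrom_conflict"

  sel <- which(same_chr)
  pairs <- data.frame(
    locus_id = ids[sel],
    chromA = a$chrom[sel],
    posA = floor((a$start[sel] + a$end[sel]) / 2),
    strandA = a$strand[sel],
    chromB = b$chrom[sel],
    posB = floor((b$start[sel] + b$end[sel]) / 2),
    strandB = b$strand[sel],
    is_comparison_anchor = a$status[sel] == "unique" &
      b$status[sel] == "unique",
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$chromA, pairs$posA, pairs$locus_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL

  # a chromosome-conflict locus is placed in both genomes (it counts as
  # matched_both) but yields no pair; its reason code records the exclusion
  classification <- list(
    matched_both = sum(pa & pb),
    matched_one_only = sum(xor(pa, pb)),
    matched_neither = sum(!pa & !pb),
    reasons = setNames(reason, ids))
  list(pairs = pairs, classification = classification)
}
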
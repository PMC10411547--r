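#' Hotspot-detection parameters
#'
#' The hotspot criterion is operational rather than statistical: loci are
#' merged into segments by single linkage with a gap tolerance, and a
#' segment qualifies when it is both densely populated and diverse —
#' enough member loci, enough distinct pathogen classes, and at least one
#' qualitative plus one quantitative locus.
#'
#' @param window_merge_gap_bp single-linkage gap tolerance (2e6).
#' @param hotspot_min_members minimum member loci (6).
#' @param hotspot_min_classes minimum distinct pathogen classes (3).
#' @return list of class `hotspot_params`.
#' @export
hotspot_params <- function(window_merge_gap_bp = 2e6,
                           hotspot_min_members = 6L,
                           hotspot_min_classes = 3L) {
  structure(list(window_merge_gap_bp = window_merge_gap_bp,
                 hotspot_min_members = as.integer(hotspot_min_members),
                 hotspot_min_classes = as.integer(hotspot_min_classes)),
            class = "hotspot_params")
}

#' Find colocalized locus pairs within one genome
#'
#' All unordered pairs of loci overlapping by at least 1 bp, across trait
#' classes and locus kinds; loci flagged `excluded_large` are removed
#' first. Implemented via [IRanges::findOverlaps()].
#'
#' @param loci named locus table (after [assign_names()] and
#'   [filter_large()]).
#' @return data frame: locus1, locus2, chrom, overlap_bp, relation
#'   ("colocalized"), sorted by chrom then start.
#' @export
find_colocalized <- function(loci) {
  if (!is.null(loci$excluded_large))
    loci <- loci[!loci$excluded_large, , drop = FALSE]
  empty <- data.frame(locus1 = character(), locus2 = character(),
                      chrom = character(), overlap_bp = numeric(),
                      relation = character(), stringsAsFactors = FALSE)
  if (nrow(loci) < 2) return(empty)
  loci <- loci[order(loci$chrom, loci$start, loci$name), , drop = FALSE]
  ir <- IRanges::IRanges(start = loci$start + 1, end = loci$end)
  hit <- IRanges::findOverlaps(ir, minoverlap = 1L,
                               drop.self = TRUE, drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hit); j <- S4Vectors::subjectHits(hit)
  keep <- loci$chrom[i] == loci$chrom[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(empty)
  ov <- pmin(loci$end[i], loci$end[j]) - pmax(loci$start[i], loci$start[j])
  out <- data.frame(locus1 = loci$name[pmin(i, j)],
                    locus2 = loci$name[pmax(i, j)],
                    chrom = loci$chrom[i], overlap_bp = ov,
                    relation = "colocalized", stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$locus1, out$locus2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find syntenic locus pairs across the two genomes
#'
#' Each genome-A locus is projected into genome B through the block map;
#' a pair is emitted when the projected image overlaps a genome-B locus of
#' an equivalent trait category. By default a category is equivalent to
#' itself (the package uses unified trait-class keys, so e.g. potato and
#' tomato sugar QTL already share the class "sugar"); a custom equivalence
#' map (`list(sugar = c("sugar", "yield"))`-style) can widen it.
#'
#' @param lociA,lociB locus tables on genomes A and B.
#' @param block_map from [detect_rearrangements()].
#' @param equivalence optional named list mapping an A trait class to the
#'   B trait classes it may pair with.
#' @return data frame: locus1 (A), locus2 (B), chrom, overlap_bp,
#'   relation ("syntenic"); skipped projections in attribute `skipped`.
#' @export
find_syntenic <- function(lociA, lociB, block_map, equivalence = NULL) {
  drop_large <- function(x)
    if (!is.null(x$excluded_large)) x[!x$excluded_large, , drop = FALSE]
    else x
  lociA <- drop_large(lociA); lociB <- drop_large(lociB)
  out <- list(); skipped <- character()
  for (i in seq_len(nrow(lociA))) {
    ch <- lociA$chrom[i]
    proj <- project_interval(c(lociA$start[i], lociA$end[i]),
                             block_map[[ch]])
    if (is.null(proj$interval)) {
      skipped <- c(skipped, lociA$name[i])
      next
    }
    eq <- if (is.null(equivalence)) lociA$trait_class[i] else
      equivalence[[lociA$trait_class[i]]]
    if (is.null(eq)) eq <- lociA$trait_class[i]
    cand <- lociB[lociB$chrom == ch & lociB$trait_class %in% eq, ,
                  drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, proj$interval[2]) -
      pmax(cand$start, proj$interval[1])
    hit <- which(ov > 0)
    for (j in hit)
      out[[length(out) + 1]] <- data.frame(
        locus1 = lociA$name[i], locus2 = cand$name[j], chrom = ch,
        overlap_bp = ov[j], relation = "syntenic",
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(locus1 = character(), locus2 = character(),
                  chrom = character(), overlap_bp = numeric(),
                  relation = character(), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$locus1, res$locus2), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Detect resistance hotspots
#'
#' Restricted to pathogen-resistance loci (trait classes with a pathogen
#' class) with `excluded_large` removed. Genome-B loci are projected onto
#' the genome-A axis (identity when no block map is given, i.e. assumed
#' collinear); per chromosome, loci are merged into segments by single
#' linkage with gap at most `window_merge_gap_bp`. A segment is a hotspot
#' iff it has at least `hotspot_min_members` members AND at least
#' `hotspot_min_classes` distinct pathogen classes AND contains at least
#' one qualitative and one quantitative locus. The genome-B segment is
#' obtained by projecting the genome-A segment.
#'
#' @param lociA,lociB locus tables (genome A and, optionally, genome B).
#' @param block_map optional block map from [detect_rearrangements()].
#' @param params [hotspot_params()].
#' @param scheme nomenclature scheme carrying the pathogen-class map.
#' @return data frame: chrom, startA, endA, startB, endB, n_members,
#'   n_pathogen_classes, has_qualitative, has_quantitative, members.
#' @export
detect_hotspots <- function(lociA, lociB = NULL, block_map = NULL,
                            params = hotspot_params(),
                            scheme = default_nomenclature()) {
  prep <- function(x, side) {
    if (is.null(x) || !nrow(x)) return(NULL)
    if (!is.null(x$excluded_large)) x <- x[!x$excluded_large, , drop = FALSE]
    x$pathogen_class <- pathogen_class_of(x$trait_class, scheme)
    x <- x[!is.na(x$pathogen_class), , drop = FALSE]
    x$side <- side
    x
  }
  a <- prep(lociA, "A"); b <- prep(lociB, "B")
  if (!is.null(b) && nrow(b)) {
    # express genome-B loci on the genome-A axis
    for (i in seq_len(nrow(b))) {
      if (!is.null(block_map)) {
        # block maps are A->B; invert by projecting through the swapped map
        proj <- project_interval_b_to_a(c(b$start[i], b$end[i]),
                                        block_map[[b$chrom[i]]])
        if (is.null(proj)) { b$start[i] <- NA; next }
        b$start[i] <- proj[1]; b$end[i] <- proj[2]
      }
    }
    b <- b[!is.na(b$start), , drop = FALSE]
  }
  loci <- rbind(a[c("name", "chrom", "start", "end", "locus_kind",
                    "pathogen_class", "side")],
                if (!is.null(b) && nrow(b))
                  b[c("name", "chrom", "start", "end", "locus_kind",
                      "pathogen_class", "side")])
  empty <- data.frame(chrom = character(), startA = numeric(),
                      endA = numeric(), startB = numeric(),
                      endB = numeric(), n_members = integer(),
                      n_pathogen_classes = integer(),
                      has_qualitative = logical(),
                      has_quantitative = logical(), members = character(),
                      stringsAsFactors = FALSE)
  if (is.null(loci) || !nrow(loci)) return(empty)
  res <- list()
  for (ch in sort(unique(loci$chrom))) {
    g <- loci[loci$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$end, g$name), , drop = FALSE]
    cl <- integer(nrow(g)); cur <- 1L; cl[1] <- 1L; hi <- g$end[1]
    if (nrow(g) > 1) for (i in 2:nrow(g)) {
      if (g$start[i] <= hi + params$window_merge_gap_bp) cl[i] <- cur
      else { cur <- cur + 1L; cl[i] <- cur }
      hi <- max(hi, g$end[i])
    }
    for (cc in unique(cl)) {
      m <- g[cl == cc, , drop = FALSE]
      ok <- nrow(m) >= params$hotspot_min_members &&
        length(unique(m$pathogen_class)) >= params$hotspot_min_classes &&
        any(m$locus_kind == "qualitative") &&
        any(m$locus_kind == "quantitative")
      if (!ok) next
      sA <- min(m$start); eA <- max(m$end)
      segB <- if (!is.null(block_map) && !is.null(block_map[[ch]])) {
        p <- project_interval(c(sA, eA), block_map[[ch]])
        if (is.null(p$interval)) c(NA, NA) else p$interval
      } else c(sA, eA)
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, startA = sA, endA = eA, startB = segB[1],
        endB = segB[2], n_members = nrow(m),
        n_pathogen_classes = length(unique(m$pathogen_class)),
        has_qualitative = TRUE, has_quantitative = TRUE,
        members = paste(sort(m$name), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  do.call(rbind, c(res, make.row.names = FALSE))
}

# invert the A->B block map for one interval: map through each block's
# anchors with the axes swapped
project_interval_b_to_a <- function(interval, block_map_chrom) {
  if (is.null(block_map_chrom) || !length(block_map_chrom$blocks))
    return(NULL)
  lenB <- block_map_chrom$chrom_len_b
  s <- interval[1]; e <- interval[2]
  if (isTRUE(block_map_chrom$flipped)) {
    tmp <- lenB - e; e <- lenB - s; s <- tmp
  }
  swapped <- block_map_chrom
  swapped$flipped <- FALSE
  swapped$blocks <- lapply(block_map_chrom$blocks, function(blk) {
    o <- order(blk$anchorsB)
    list(role = blk$role, orientation = blk$orientation,
         anchorsA = blk$anchorsB[o], anchorsB = blk$anchorsA[o])
  })
  swapped$chrom_len_b <- Inf
  p <- project_interval(c(s, e), swapped)
  if (is.null(p$interval)) NULL else c(max(0, p$interval[1]), p$interval[2])
}
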
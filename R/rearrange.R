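#' Rearrangement-detection parameters
#'
#' @param min_block_anchors minimum matched pairs supporting a call (2);
#'   single-anchor displacements are treated as noise.
#' @param central_zone_fraction fraction of the chromosome around its
#'   midpoint inside which calls are annotated `central_low_resolution`
#'   (pericentromeric regions have low genetic and physical resolution and
#'   may harbour assembly artefacts); default 1/3.
#' @param comparison_only use only the comparison-anchor subset (both
#'   statuses unique) for chaining; default TRUE.
#' @return list of class `rearrange_params`.
#' @export
rearrange_params <- function(min_block_anchors = 2L,
                             central_zone_fraction = 1 / 3,
                             comparison_only = TRUE) {
  structure(list(min_block_anchors = as.integer(min_block_anchors),
                 central_zone_fraction = central_zone_fraction,
                 comparison_only = comparison_only),
            class = "rearrange_params")
}

#' Determine the global orientation of one chromosome
#'
#' A chromosome whose sequence is assembled in opposite orientation in the
#' two genomes (the classic chromosome-12 situation) shows a strongly
#' negative rank correlation of positions. The Kendall rank correlation
#' of posB against posA decides directly when its magnitude is at least
#' `tau_decisive`: `flipped = TRUE` iff it is negative. In the ambiguous
#' zone (a chromosome whose planted or real inversions cover about half
#' its length can push tau marginally negative without any global flip)
#' both orientations are chained and the one yielding the better
#' collinear parsimony chain — more retained blocks, then more anchors,
#' ties resolved toward the unflipped axis — is kept. When flipped, the
#' returned pairs have posB reflected (`len - posB`) so that chaining
#' sees a canonical orientation.
#'
#' @param pairs matched pairs on one chromosome (columns posA, posB).
#' @param chrom_len_b length of the chromosome in genome B.
#' @param tau_decisive magnitude above which tau alone decides (0.8).
#' @return list with `flipped` (logical, NA when fewer than 3 pairs:
#'   orientation undetermined, chromosome skipped with a warning), `tau`,
#'   and `pairs` (posB reflected when flipped).
#' @export
orient_chromosome <- function(pairs, chrom_len_b, tau_decisive = 0.8) {
  if (nrow(pairs) < 3) {
    warning("fewer than 3 matched pairs; orientation undetermined")
    return(list(flipped = NA, tau = NA_real_, pairs = pairs))
  }
  tau <- suppressWarnings(cor(pairs$posA, pairs$posB, method = "kendall"))
  if (abs(tau) >= tau_decisive) {
    flipped <- tau < 0
  } else {
    quality <- function(p) {
      ch <- chain_collinear(p)
      c(ch$n_chain_blocks, length(ch$chain))
    }
    flp <- pairs
    flp$posB <- chrom_len_b - flp$posB
    qs <- quality(pairs); qf <- quality(flp)
    flipped <- qf[1] > qs[1] || (qf[1] == qs[1] && qf[2] > qs[2])
  }
  if (flipped) pairs$posB <- chrom_len_b - pairs$posB
  list(flipped = flipped, tau = tau, pairs = pairs)
}

# strict-increase longest increasing subsequence via patience sorting;
# returns member indices. Deterministic: equal tails keep the earliest
# viable element, which breaks ties toward earlier input (posA) order.
lis_patience <- function(v) {
  n <- length(v)
  if (n == 0) return(integer())
  tails_v <- numeric(n); tails_i <- integer(n); parent <- integer(n)
  L <- 0L
  for (i in seq_len(n)) {
    lo <- 1L; hi <- L + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (tails_v[mid] >= v[i]) hi <- mid else lo <- mid + 1L
    }
    tails_v[lo] <- v[i]; tails_i[lo] <- i
    parent[i] <- if (lo > 1L) tails_i[lo - 1L] else 0L
    if (lo > L) L <- lo
  }
  out <- integer(L); k <- tails_i[L]
  for (j in L:1) { out[j] <- k; k <- parent[k] }
  out
}

#' Decompose matched pairs on one chromosome into collinear structure
#'
#' Two complementary views are computed. The *backbone* is the longest
#' (strictly) increasing subsequence of posB over posA order — ties in
#' posB are broken by a rank-scaled epsilon added in posA order.
#' Structural *runs* are found at block level: the pair sequence is first
#' cut into maximal monotone blocks contiguous in both posA-rank and
#' posB-rank (the atomic units a rearrangement moves), and the collinear
#' chain is the subset of non-decreasing blocks maximizing the number of
#' retained blocks (minimum-event parsimony; total anchors break ties).
#' Off-chain blocks are the runs. A block the anchor-level LIS kept but
#' the parsimony chain displaces is reported via `absorbed`: with several
#' interacting rearrangements the anchor-richest chain can keep a large
#' moved segment and displace its flanks, which block parsimony resolves
#' in favour of the fewest-events reading.
#'
#' @param pairs matched pairs on one (oriented) chromosome, any order;
#'   columns posA, posB.
#' @param min_block_anchors runs below this size are reported but flagged
#'   for discard by the classifier.
#' @return list: `order` (row indices of `pairs` sorted by posA),
#'   `backbone` (positions into `order` of the LIS), `lis_length`,
#'   `chain` (positions forming the parsimony backbone), `runs` (list of
#'   integer vectors, positions into `order`, each run in posA order),
#'   `absorbed` (LIS members sitting inside displaced runs),
#'   `posA`/`posB` (sorted, jittered).
#' @export
chain_collinear <- function(pairs, min_block_anchors = 2L) {
  ord <- order(pairs$posA, pairs$posB)
  posA <- pairs$posA[ord]
  n <- length(posA)
  posB <- pairs$posB[ord] + seq_len(n) * 1e-6  # deterministic tie-break
  bb <- lis_patience(posB)
  rB <- rank(posB)

  # maximal monotone blocks, contiguous in both rank orders
  blocks <- list()
  cur <- 1L; dir <- 0L
  if (n > 1) for (i in 2:n) {
    step <- rB[i] - rB[i - 1]
    ok <- (length(cur) == 1L && abs(step) == 1) ||
      (length(cur) > 1L && step == dir)
    if (ok) {
      cur <- c(cur, i)
      if (length(cur) == 2L) dir <- step
    } else {
      blocks[[length(blocks) + 1]] <- cur
      cur <- i; dir <- 0L
    }
  }
  blocks[[length(blocks) + 1]] <- cur

  m <- length(blocks)
  n_anc <- lengths(blocks)
  minB <- vapply(blocks, function(b) min(posB[b]), numeric(1))
  maxB <- vapply(blocks, function(b) max(posB[b]), numeric(1))
  decreasing <- vapply(blocks, function(b)
    length(b) > 1 && all(diff(posB[b]) < 0), logical(1))

  # parsimony chain: weighted LIS over blocks, weight 1 per block,
  # anchors as tie-break; decreasing blocks cannot join the chain
  cnt <- integer(m); anc <- numeric(m); prev <- integer(m)
  for (j in seq_len(m)) {
    if (decreasing[j]) next
    cnt[j] <- 1L; anc[j] <- n_anc[j]
    if (j > 1) for (i in seq_len(j - 1)) {
      if (cnt[i] == 0L || maxB[i] >= minB[j]) next
      if (cnt[i] + 1L > cnt[j] ||
          (cnt[i] + 1L == cnt[j] && anc[i] + n_anc[j] > anc[j])) {
        cnt[j] <- cnt[i] + 1L
        anc[j] <- anc[i] + n_anc[j]
        prev[j] <- i
      }
    }
  }
  chain_idx <- integer(0)
  if (any(cnt > 0)) {
    ends <- which(cnt == max(cnt))
    end <- ends[order(-anc[ends], ends)][1]
    while (end > 0) { chain_idx <- c(end, chain_idx); end <- prev[end] }
  }
  runs <- blocks[setdiff(seq_len(m), chain_idx)]
  names(runs) <- NULL
  chain <- sort(unlist(blocks[chain_idx]))
  list(order = ord, backbone = bb, lis_length = length(bb),
       chain = chain, n_chain_blocks = length(chain_idx), runs = runs,
       absorbed = sort(intersect(bb, unlist(runs))),
       posA = posA, posB = posB,
       min_block_anchors = as.integer(min_block_anchors))
}

#' Classify off-backbone runs into rearrangement calls
#'
#' A run internally decreasing in posB is an inversion; an internally
#' increasing but displaced run is an intra-chromosomal translocation.
#' Span per genome is the bounding interval of member positions; size is
#' the larger of the two widths. Runs with fewer than `min_block_anchors`
#' members are discarded (recorded in the `notes` attribute). Calls whose
#' spans in both genomes lie wholly inside the central low-resolution zone
#' carry `confidence_note = "central_low_resolution"`.
#'
#' @param chain result of [chain_collinear()].
#' @param chrom chromosome name for the calls.
#' @param params [rearrange_params()].
#' @param chrom_len_a,chrom_len_b chromosome lengths (for the central-zone
#'   annotation; optional).
#' @return data frame of calls: kind, chrom, startA, endA, startB, endB,
#'   size, n_anchors, confidence_note; attribute `notes` lists discarded
#'   runs.
#' @export
classify_blocks <- function(chain, chrom, params = rearrange_params(),
                            chrom_len_a = NA, chrom_len_b = NA) {
  notes <- character()
  calls <- list()
  central <- function(s, e, len) {
    if (is.na(len)) return(FALSE)
    half <- params$central_zone_fraction / 2
    s >= len * (0.5 - half) && e <= len * (0.5 + half)
  }
  for (run in chain$runs) {
    if (length(run) < params$min_block_anchors) {
      notes <- c(notes, sprintf(
        "run of %d anchor(s) at %s:%d below min_block_anchors, discarded",
        length(run), chrom, round(chain$posA[run[1]])))
      next
    }
    dec <- all(diff(chain$posB[run]) < 0)
    sA <- min(chain$posA[run]); eA <- max(chain$posA[run])
    sB <- min(chain$posB[run]); eB <- max(chain$posB[run])
    note <- if (central(sA, eA, chrom_len_a) && central(sB, eB, chrom_len_b))
      "central_low_resolution" else ""
    calls[[length(calls) + 1]] <- data.frame(
      kind = if (dec) "inversion" else "intra_translocation",
      chrom = chrom, startA = sA, endA = eA, startB = floor(sB),
      endB = ceiling(eB), size = max(eA - sA, eB - sB),
      n_anchors = length(run), confidence_note = note,
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(kind = character(), chrom = character(), startA = numeric(),
               endA = numeric(), startB = numeric(), endB = numeric(),
               size = numeric(), n_anchors = integer(),
               confidence_note = character(), stringsAsFactors = FALSE)
  attr(out, "notes") <- notes
  out
}

# build the per-chromosome block map used for interval projection: the
# parsimony chain as one piecewise direct backbone block plus each
# retained run. Anchor positions are kept for piecewise-linear
# interpolation. Coordinates are in oriented-B space; `flipped` and
# `chrom_len_b` allow conversion back.
build_block_map <- function(chain, params, flipped, chrom_len_b) {
  blocks <- list()
  if (length(chain$chain) >= 2) {
    blocks[[1]] <- list(role = "backbone", orientation = "direct",
                        anchorsA = chain$posA[chain$chain],
                        anchorsB = chain$posB[chain$chain])
  }
  for (run in chain$runs) {
    if (length(run) < params$min_block_anchors) next
    dec <- all(diff(chain$posB[run]) < 0)
    blocks[[length(blocks) + 1]] <- list(
      role = "displaced", orientation = if (dec) "inverted" else "direct",
      anchorsA = chain$posA[run], anchorsB = chain$posB[run])
  }
  list(blocks = blocks, flipped = flipped, chrom_len_b = chrom_len_b)
}

#' Detect rearrangements genome-wide
#'
#' Orients every chromosome, chains the matched pairs, classifies
#' off-backbone runs, and assembles the block map used by
#' [project_interval()]. Call coordinates in genome B are reported in the
#' original (unflipped) B coordinate system.
#'
#' @param pairs matched-pair table from [build_pairs()].
#' @param chrom_lengths_a,chrom_lengths_b named chromosome-length vectors.
#' @param params [rearrange_params()].
#' @return list: `calls` (all chromosomes), `orientations` (chrom,
#'   flipped, n_pairs), `block_map` (per chromosome, for projection),
#'   `notes`.
#' @export
detect_rearrangements <- function(pairs, chrom_lengths_a, chrom_lengths_b,
                                  params = rearrange_params()) {
  if (params$comparison_only && "is_comparison_anchor" %in% names(pairs))
    pairs <- pairs[pairs$is_comparison_anchor, , drop = FALSE]
  chroms <- intersect(names(chrom_lengths_a), unique(pairs$chromA))
  calls <- list(); orient <- list(); block_map <- list(); notes <- character()
  for (ch in chroms) {
    p <- pairs[pairs$chromA == ch, , drop = FALSE]
    lenB <- unname(chrom_lengths_b[ch])
    if (nrow(p) < 3) {
      orient[[ch]] <- data.frame(chrom = ch, flipped = NA,
                                 n_pairs = nrow(p))
      notes <- c(notes, sprintf("%s: fewer than 3 pairs, skipped", ch))
      next
    }
    o <- orient_chromosome(p, lenB)
    orient[[ch]] <- data.frame(chrom = ch, flipped = o$flipped,
                               n_pairs = nrow(p))
    chain <- chain_collinear(o$pairs, params$min_block_anchors)
    cl <- classify_blocks(chain, ch, params,
                          unname(chrom_lengths_a[ch]), lenB)
    notes <- c(notes, attr(cl, "notes"))
    if (nrow(cl) && isTRUE(o$flipped)) {
      # report genome-B spans in original coordinates
      sB <- lenB - cl$endB; eB <- lenB - cl$startB
      cl$startB <- sB; cl$endB <- eB
    }
    calls[[ch]] <- cl
    block_map[[ch]] <- build_block_map(chain, params, o$flipped, lenB)
  }
  calls <- if (length(calls)) do.call(rbind, c(calls, make.row.names = FALSE))
  else classify_blocks(list(runs = list()), "none", params)
  orient <- do.call(rbind, c(orient, make.row.names = FALSE))
  list(calls = calls, orientations = orient, block_map = block_map,
       notes = notes)
}

# subtract one interval from a set of disjoint intervals (rows of a
# two-column matrix)
interval_subtract <- function(mat, cut) {
  out <- NULL
  for (i in seq_len(nrow(mat))) {
    s <- mat[i, 1]; e <- mat[i, 2]
    if (cut[2] <= s || cut[1] >= e) { out <- rbind(out, c(s, e)); next }
    if (cut[1] > s) out <- rbind(out, c(s, cut[1]))
    if (cut[2] < e) out <- rbind(out, c(cut[2], e))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

# map positions through one block by piecewise-linear interpolation over
# its anchors (reversed for inverted blocks); positions outside the anchor
# span extrapolate at slope +/-1 from the nearest anchor.
project_points_block <- function(x, block) {
  a <- block$anchorsA; b <- block$anchorsB
  if (length(a) == 1) return(b + (x - a) *
                               ifelse(block$orientation == "inverted", -1, 1))
  sgn <- if (block$orientation == "inverted") -1 else 1
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (x[i] <= a[1]) out[i] <- b[1] + sgn * (x[i] - a[1])
    else if (x[i] >= a[length(a)])
      out[i] <- b[length(b)] + sgn * (x[i] - a[length(a)])
    else {
      j <- findInterval(x[i], a)
      f <- (x[i] - a[j]) / (a[j + 1] - a[j])
      out[i] <- b[j] + f * (b[j + 1] - b[j])
    }
  }
  out
}

#' Project an interval from genome A into genome B through the block map
#'
#' Each block whose genome-A span intersects the interval maps the clipped
#' endpoints by piecewise-linear interpolation over its member anchors
#' (reversed inside inverted blocks); the result is the bounding interval
#' of the per-block images, with `gap_spanning = TRUE` when more than one
#' block contributed. The backbone block extrapolates to the chromosome
#' ends at unit slope so near-terminal intervals remain projectable.
#'
#' @param interval numeric length-2, genome-A bp (half-open).
#' @param block_map_chrom entry of `detect_rearrangements()$block_map` for
#'   the chromosome.
#' @return list with `interval` (genome-B bp, original orientation),
#'   `gap_spanning`, `n_blocks`; or `NULL` with attribute-free `reason =
#'   "unanchored_region"` field when no block is intersected.
#' @export
project_interval <- function(interval, block_map_chrom) {
  if (is.null(block_map_chrom) || !length(block_map_chrom$blocks))
    return(list(interval = NULL, reason = "unanchored_region"))
  s <- interval[1]; e <- interval[2]
  images <- list()
  # displaced blocks claim their spans first; the backbone maps only the
  # remainder (it spans the whole chromosome by unit-slope extrapolation,
  # so an interval wholly inside one displaced block projects through that
  # block alone)
  remaining <- matrix(c(s, e), ncol = 2)
  for (blk in block_map_chrom$blocks) {
    if (blk$role == "backbone") next
    spanA <- range(blk$anchorsA)
    cs <- max(s, spanA[1]); ce <- min(e, spanA[2])
    if (cs >= ce) next
    images[[length(images) + 1]] <-
      sort(project_points_block(c(cs, ce), blk))
    remaining <- interval_subtract(remaining, c(cs, ce))
  }
  bb <- Filter(function(b) b$role == "backbone", block_map_chrom$blocks)
  if (length(bb) && nrow(remaining)) {
    for (i in seq_len(nrow(remaining))) {
      if (remaining[i, 2] - remaining[i, 1] <= 0) next
      images[[length(images) + 1]] <-
        sort(project_points_block(remaining[i, ], bb[[1]]))
    }
  }
  if (!length(images))
    return(list(interval = NULL, reason = "unanchored_region"))
  lo <- min(vapply(images, `[`, numeric(1), 1))
  hi <- max(vapply(images, `[`, numeric(1), 2))
  lenB <- block_map_chrom$chrom_len_b
  lo <- max(0, lo); hi <- min(lenB, hi)
  if (isTRUE(block_map_chrom$flipped)) {
    tmp <- lenB - hi; hi <- lenB - lo; lo <- tmp
  }
  list(interval = c(floor(lo), ceiling(hi)),
       gap_spanning = length(images) > 1, n_blocks = length(images))
}
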
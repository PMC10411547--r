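#' Simulation configuration
#'
#' Defines a desk-scale analogue of a diverged, largely collinear genome
#' pair: Mbp-scale chromosomes rather than the tens of Mbp of real
#' Solanaceae chromosomes, with every size threshold scaled through the
#' config rather than hard-coded. Genome B is derived from genome A by
#' planted non-overlapping inversions and intra-chromosomal cut-and-paste
#' translocations followed by per-base substitution at the divergence
#' rate (no indels, so the built-in ungapped matcher is a faithful
#' aligner for the simulated truth).
#'
#' @param n_chrom chromosomes per genome (4).
#' @param chrom_len_bp chromosome length (3e6).
#' @param divergence per-base substitution probability between the
#'   genomes (0.05).
#' @param n_inversions,n_translocations planted rearrangements per genome
#'   pair (10, 5).
#' @param rearr_size_range rearrangement sizes in bp (2e5-1e6, a scaled
#'   analogue of the 0.2-22 Mbp range seen between real collinear
#'   genomes).
#' @param n_markers marker catalogue size (1500).
#' @param marker_len_range sequence-marker lengths (200-600 bp).
#' @param primer_pair_frac fraction of markers emitted as primer pairs
#'   bounding a 200-1000 bp amplicon (0.1).
#' @param dup_frac fraction of markers planted inside duplicated segments
#'   to create ambiguous anchoring cases (0.01).
#' @param garbage_frac fraction of markers with random (non-genomic)
#'   sequence, emulating loci that match neither genome (0).
#' @param n_studies simulated mapping studies (60).
#' @param n_causal hidden causal positions the studies sample from (24).
#' @param p_flanking probability a study reports flanking markers rather
#'   than a single linked marker (0.7).
#' @param p_mismap probability a marker's prior chromosome from genetic
#'   mapping is wrong (0.02).
#' @param half_width scaled interval half-width used when projecting
#'   single-marker studies (1e5 here; the real-data default is 2 Mbp on
#'   ~10-20x longer chromosomes).
#' @param large_cutoff scaled large-interval exclusion cutoff (7.5e5).
#' @param seed integer driving all stage generators (stage seeds are
#'   derived deterministically).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4L, chrom_len_bp = 3e6, divergence = 0.05,
                       n_inversions = 10L, n_translocations = 5L,
                       rearr_size_range = c(2e5, 1e6), n_markers = 1500L,
                       marker_len_range = c(200L, 600L),
                       primer_pair_frac = 0.1, dup_frac = 0.01,
                       garbage_frac = 0, n_studies = 60L, n_causal = 24L,
                       p_flanking = 0.7, p_mismap = 0.02,
                       half_width = 1e5, large_cutoff = 7.5e5, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1, p_flanking >= 0,
            p_flanking <= 1, p_mismap >= 0, p_mismap <= 1,
            rearr_size_range[1] <= rearr_size_range[2])
  structure(as.list(environment()), class = "sim_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# place `sizes` non-overlapping intervals (with margin) on [0, len) by gap
# allocation: random order, random gaps summing to the free space. Always
# succeeds when the sizes plus margins fit; errors otherwise.
place_intervals <- function(sizes, len, taken = NULL, margin = 2e4) {
  n <- length(sizes)
  if (n == 0) return(NULL)
  if (!is.null(taken)) {
    # place each segment uniformly within the free gaps left by `taken`
    out <- NULL
    for (sz in sizes) {
      busy <- rbind(taken, out)
      busy <- busy[order(busy[, 1]), , drop = FALSE]
      edges <- c(0, as.vector(t(cbind(pmax(0, busy[, 1] - margin),
                                      pmin(len, busy[, 2] + margin)))), len)
      gaps <- matrix(edges, ncol = 2, byrow = TRUE)
      gaps <- gaps[gaps[, 2] - gaps[, 1] >= sz, , drop = FALSE]
      if (!nrow(gaps))
        stop("could not place segment of ", sz, " bp in the free gaps; ",
             "use smaller sizes")
      room <- gaps[, 2] - gaps[, 1] - sz
      g <- if (nrow(gaps) == 1) 1 else
        sample(nrow(gaps), 1, prob = room + 1)
      s <- floor(runif(1, gaps[g, 1], gaps[g, 1] + room[g]))
      out <- rbind(out, c(s, s + sz))
    }
    return(out)
  }
  ord <- sample.int(n)
  free <- len - sum(sizes) - margin * (n + 1)
  if (free < 0)
    stop("could not place ", n, " segments totalling ", sum(sizes),
         " bp on a ", len, " bp chromosome; use smaller sizes")
  w <- runif(n + 1)
  gaps <- free * w / sum(w)
  starts <- numeric(n)
  pos <- 0
  for (i in seq_len(n)) {
    pos <- pos + gaps[i] + margin
    starts[i] <- floor(pos)
    pos <- pos + sizes[ord[i]]
  }
  out <- cbind(starts, starts + sizes[ord])
  out[order(ord), , drop = FALSE]
}

#' Simulate a diverged genome pair with planted rearrangements
#'
#' @param config [sim_config()].
#' @return list: `genomeA`, `genomeB` (genome_set), `truth` with
#'   `rearrangements` (kind, chrom, startA, endA, startB, endB, size),
#'   `duplications`, `piece_map` (the exact A-to-B coordinate map), and
#'   `chrom_lengths` for both genomes.
#' @export
simulate_genome_pair <- function(config = sim_config()) {
  set.seed(config$seed + 101L)
  chroms <- sprintf("chr%02d", seq_len(config$n_chrom))
  len <- config$chrom_len_bp
  seqsA <- setNames(vapply(chroms, function(ch) rand_seq(len),
                           character(1)), chroms)

  # distribute events over chromosomes, re-drawing until every chromosome
  # can host its events (sizes plus margins within the chromosome)
  n_ev <- config$n_inversions + config$n_translocations
  kinds <- c(rep("inversion", config$n_inversions),
             rep("intra_translocation", config$n_translocations))
  ev_chrom <- character(n_ev)
  ev_size <- numeric(n_ev)
  for (attempt in 1:1000) {
    ev_chrom <- sample(chroms, n_ev, replace = TRUE)
    ev_size <- floor(runif(n_ev, config$rearr_size_range[1],
                           config$rearr_size_range[2]))
    load <- vapply(chroms, function(ch) {
      sel <- ev_chrom == ch
      sum(ev_size[sel]) + 2e4 * (sum(sel) + sum(sel & kinds ==
                                                  "intra_translocation") + 2)
    }, numeric(1))
    if (all(load < len)) break
    if (attempt == 1000)
      stop("could not distribute ", n_ev, " rearrangements over ",
           config$n_chrom, " chromosomes of ", len,
           " bp; use smaller sizes or fewer events")
  }
  rearr <- list(); dups <- list(); piece_map <- list()
  seqsB <- seqsA
  for (ch in chroms) {
    sel <- which(ev_chrom == ch)
    k <- kinds[sel]
    sizes <- ev_size[sel]
    # lay out event spans and translocation insertion points together,
    # retrying the whole chromosome layout when no valid insertion point
    # exists. An insertion point must sit outside every event span and
    # farther from its own segment than 1.2x the segment length —
    # a cut-and-paste over a shorter distance is indistinguishable from
    # (and more parsimoniously explained by) moving the in-between
    # segment the other way.
    spans <- NULL; ins <- numeric(0)
    for (layout in 1:100) {
      spans <- place_intervals(sizes, len)
      tr <- which(k == "intra_translocation")
      ins <- numeric(length(tr)); ok <- TRUE
      for (ti in seq_along(tr)) {
        s <- spans[tr[ti], 1]; e <- spans[tr[ti], 2]
        sz <- e - s
        found <- FALSE
        for (attempt in 1:1000) {
          p <- floor(runif(1, 0, len))
          busy <- rbind(spans, if (ti > 1) cbind(ins[seq_len(ti - 1)],
                                                 ins[seq_len(ti - 1)] + 1))
          if (any(p > busy[, 1] - 2e4 & p < busy[, 2] + 2e4)) next
          if (p > s - 1.2 * sz && p < e + 1.2 * sz) next
          ins[ti] <- p; found <- TRUE; break
        }
        if (!found) { ok <- FALSE; break }
      }
      if (ok) break
      if (layout == 100)
        stop("could not place translocation insertion points on ", ch,
             " after repeated layouts; use smaller sizes")
    }
    if (is.null(spans)) spans <- matrix(numeric(0), ncol = 2)
    # duplications: copy a source segment over a target segment (in A, so
    # both genomes carry the repeat); sized ~2 kb
    ndup <- max(0L, round(config$dup_frac * config$n_markers /
                            config$n_chrom / 2))
    dup_src <- dup_tgt <- NULL
    if (ndup > 0) {
      busy <- rbind(spans, if (length(ins)) cbind(ins, ins + 1))
      dup_src <- place_intervals(rep(2000, ndup), len, taken = busy, margin = 2e3)
      dup_tgt <- place_intervals(rep(2000, ndup), len,
                                 taken = rbind(busy, dup_src),
                                 margin = 2e3)
      sq <- seqsA[[ch]]
      for (d in seq_len(ndup)) {
        substr(sq, dup_tgt[d, 1] + 1, dup_tgt[d, 2]) <-
          substr(sq, dup_src[d, 1] + 1, dup_src[d, 2])
        dups[[length(dups) + 1]] <- data.frame(
          chrom = ch, src_start = dup_src[d, 1], src_end = dup_src[d, 2],
          tgt_start = dup_tgt[d, 1], tgt_end = dup_tgt[d, 2],
          stringsAsFactors = FALSE)
      }
      seqsA[[ch]] <- sq
    }

    # cut A into pieces at event boundaries and insertion points
    bps <- sort(unique(c(0, len, as.vector(spans), ins)))
    pieces <- data.frame(start = bps[-length(bps)], end = bps[-1])
    pieces$inverted <- FALSE
    pieces$moved_to <- NA_real_   # insertion point in A coordinates
    inv_spans <- spans[k == "inversion", , drop = FALSE]
    tr_spans <- spans[k == "intra_translocation", , drop = FALSE]
    for (i in seq_len(nrow(inv_spans)))
      pieces$inverted[pieces$start == inv_spans[i, 1]] <- TRUE
    for (i in seq_len(nrow(tr_spans)))
      pieces$moved_to[pieces$start == tr_spans[i, 1]] <- ins[i]

    # genome-B piece order: moved pieces are re-inserted before the piece
    # that begins at their insertion point
    ordb <- which(is.na(pieces$moved_to))
    for (i in which(!is.na(pieces$moved_to))) {
      tgt <- which(pieces$start[ordb] >= pieces$moved_to[i])[1]
      ordb <- append(ordb, i, after = ifelse(is.na(tgt), length(ordb),
                                             tgt - 1))
    }
    pl <- pieces$end - pieces$start
    b_start <- cumsum(c(0, pl[ordb]))[seq_along(ordb)]
    pm <- data.frame(chrom = ch, a_start = pieces$start[ordb],
                     a_end = pieces$end[ordb], b_start = b_start,
                     inverted = pieces$inverted[ordb],
                     stringsAsFactors = FALSE)
    piece_map[[ch]] <- pm

    sq <- seqsA[[ch]]
    parts <- vapply(seq_along(ordb), function(j) {
      p <- ordb[j]
      s <- substr(sq, pieces$start[p] + 1, pieces$end[p])
      if (pieces$inverted[p]) revcomp(s) else s
    }, character(1))
    seqsB[[ch]] <- paste(parts, collapse = "")

    # truth spans in both coordinate systems
    span_b <- function(sA, eA) {
      row <- which(pm$a_start == sA)
      c(pm$b_start[row], pm$b_start[row] + (eA - sA))
    }
    for (i in seq_len(nrow(inv_spans))) {
      sb <- span_b(inv_spans[i, 1], inv_spans[i, 2])
      rearr[[length(rearr) + 1]] <- data.frame(
        kind = "inversion", chrom = ch, startA = inv_spans[i, 1],
        endA = inv_spans[i, 2], startB = sb[1], endB = sb[2],
        size = inv_spans[i, 2] - inv_spans[i, 1], stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(tr_spans))) {
      sb <- span_b(tr_spans[i, 1], tr_spans[i, 2])
      rearr[[length(rearr) + 1]] <- data.frame(
        kind = "intra_translocation", chrom = ch, startA = tr_spans[i, 1],
        endA = tr_spans[i, 2], startB = sb[1], endB = sb[2],
        size = tr_spans[i, 2] - tr_spans[i, 1], stringsAsFactors = FALSE)
    }
  }

  # divergence: per-base substitution on genome B
  if (config$divergence > 0) {
    bases <- c("A", "C", "G", "T")
    for (ch in chroms) {
      v <- strsplit(seqsB[[ch]], "")[[1]]
      hit <- which(runif(length(v)) < config$divergence)
      if (length(hit)) {
        shift <- sample(1:3, length(hit), replace = TRUE)
        v[hit] <- bases[(match(v[hit], bases) - 1 + shift) %% 4 + 1]
        seqsB[[ch]] <- paste(v, collapse = "")
      }
    }
  }

  rearr <- if (length(rearr)) do.call(rbind, c(rearr,
                                               make.row.names = FALSE))
  else data.frame(kind = character(), chrom = character(),
                  startA = numeric(), endA = numeric(), startB = numeric(),
                  endB = numeric(), size = numeric(),
                  stringsAsFactors = FALSE)
  dups <- if (length(dups)) do.call(rbind, c(dups, make.row.names = FALSE))
  else NULL
  gA <- genome_set("simA", seqsA)
  gB <- genome_set("simB", seqsB)
  list(genomeA = gA, genomeB = gB,
       truth = list(rearrangements = rearr, duplications = dups,
                    piece_map = piece_map,
                    chrom_lengths = list(A = gA$chrom_lengths,
                                         B = gB$chrom_lengths)))
}

#' Map genome-A positions to genome-B through the exact piece map
#' @param chrom chromosome name.
#' @param pos numeric positions (bp, genome A).
#' @param piece_map `truth$piece_map` from [simulate_genome_pair()].
#' @return numeric positions in genome B.
#' @export
map_a_to_b <- function(chrom, pos, piece_map) {
  pm <- piece_map[[chrom]]
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    r <- which(pm$a_start <= pos[i] & pos[i] < pm$a_end)[1]
    out[i] <- if (pm$inverted[r])
      pm$b_start[r] + (pm$a_end[r] - 1 - pos[i])
    else pm$b_start[r] + (pos[i] - pm$a_start[r])
  }
  out
}

#' Simulate a marker catalogue with known positions in both genomes
#'
#' Sequence markers are copied from genome A at uniform positions; a
#' fraction are emitted as primer pairs bounding a short amplicon, a
#' fraction are placed inside planted duplications (ambiguous cases), and
#' a fraction get random non-genomic sequence. The prior chromosome from
#' "genetic mapping" is the true one, corrupted with probability
#' `p_mismap`.
#'
#' @param sim result of [simulate_genome_pair()].
#' @param config [sim_config()].
#' @return list: `markers` (catalogue in the [read_marker_table()]
#'   schema), `truth` (locus_id, chrom, posA, posB, ambiguous, garbage).
#' @export
simulate_markers <- function(sim, config = sim_config()) {
  set.seed(config$seed + 202L)
  chroms <- names(sim$genomeA$seqs)
  n <- config$n_markers
  n_pp <- round(config$primer_pair_frac * n)
  n_amb <- round(config$dup_frac * n)
  n_garbage <- round(config$garbage_frac * n)
  kind <- rep("seq", n)
  if (n_pp) kind[seq_len(n_pp)] <- "primer"
  if (n_amb) kind[n_pp + seq_len(n_amb)] <- "ambiguous"
  if (n_garbage) kind[n_pp + n_amb + seq_len(n_garbage)] <- "garbage"
  kind <- sample(kind)   # shuffle so kinds mix across the catalogue

  dup <- sim$truth$duplications
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("MK%04d", i)
    ch <- sample(chroms, 1)
    sq <- sim$genomeA$seqs[[ch]]
    len_ch <- length(sq)
    if (kind[i] == "garbage") {
      mlen <- floor(runif(1, config$marker_len_range[1],
                          config$marker_len_range[2]))
      rows[[i]] <- data.frame(locus_id = id, marker_type = "genomic_clone",
                              sequence = rand_seq(mlen),
                              sequence2 = NA_character_,
                              prior_chrom = sample(seq_along(chroms), 1),
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(locus_id = id, chrom = NA_character_,
                               posA = NA_real_, posB = NA_real_,
                               ambiguous = FALSE, garbage = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    if (kind[i] == "ambiguous" && !is.null(dup)) {
      d <- dup[sample(nrow(dup), 1), ]
      ch <- d$chrom
      mlen <- 300
      s <- floor(runif(1, d$src_start + 50, d$src_end - mlen - 50))
    } else if (kind[i] == "primer") {
      alen <- floor(runif(1, 200, 1000))
      s <- floor(runif(1, 0, len_ch - alen))
      seqr <- as.character(Biostrings::subseq(sim$genomeA$seqs[[ch]],
                                              s + 1, s + alen))
      fwd <- substr(seqr, 1, 20)
      rev <- revcomp(substr(seqr, alen - 19, alen))
      pc <- chrom_number(ch)
      if (runif(1) < config$p_mismap)
        pc <- safe_pick(setdiff(seq_along(chroms), pc), pc)
      mid <- s + floor(alen / 2)
      rows[[i]] <- data.frame(locus_id = id, marker_type = "primer_pair",
                              sequence = fwd, sequence2 = rev,
                              prior_chrom = pc, stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        locus_id = id, chrom = ch, posA = mid,
        posB = map_a_to_b(ch, mid, sim$truth$piece_map),
        ambiguous = FALSE, garbage = FALSE, stringsAsFactors = FALSE)
      next
    } else {
      mlen <- floor(runif(1, config$marker_len_range[1],
                          config$marker_len_range[2]))
      s <- floor(runif(1, 0, len_ch - mlen))
    }
    seqr <- as.character(Biostrings::subseq(sim$genomeA$seqs[[ch]],
                                            s + 1, s + mlen))
    pc <- chrom_number(ch)
    if (runif(1) < config$p_mismap)
      pc <- safe_pick(setdiff(seq_along(chroms), pc), pc)
    mid <- s + floor(mlen / 2)
    rows[[i]] <- data.frame(locus_id = id, marker_type = "genomic_clone",
                            sequence = seqr, sequence2 = NA_character_,
                            prior_chrom = pc, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      locus_id = id, chrom = ch, posA = mid,
      posB = map_a_to_b(ch, mid, sim$truth$piece_map),
      ambiguous = kind[i] == "ambiguous", garbage = FALSE,
      stringsAsFactors = FALSE)
  }
  list(markers = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Simulate mapping studies around hidden causal positions
#'
#' Causal positions are drawn uniformly per species (species "potato"
#' lives on genome A, "tomato" on genome B); each study samples one and
#' reports, with probability `p_flanking`, the nearest marker on each
#' side as flanking evidence, otherwise the single nearest marker as
#' linked. When no marker lies within `half_width` of the causal position
#' the nearest marker is still reported and the study is truth-flagged
#' `loose_evidence`. When the exact genome coordinate map (`piece_map`)
#' is supplied, half of the tomato causal positions are planted as
#' orthologs of a potato causal position (same trait class, position
#' mapped through the genome correspondence), so cross-genome syntenic
#' trait pairs exist in truth.
#'
#' @param marker_truth `truth` element of [simulate_markers()].
#' @param config [sim_config()].
#' @param piece_map optional `truth$piece_map` from
#'   [simulate_genome_pair()] for planting orthologous causal pairs.
#' @return list: `studies` (evidence table in the [read_study_table()]
#'   schema), `truth` (study_id, report_id, species, trait_class, chrom,
#'   causal_pos, ortholog_of, loose_evidence).
#' @export
simulate_studies <- function(marker_truth, config = sim_config(),
                             piece_map = NULL) {
  set.seed(config$seed + 303L)
  classes <- c("LBR", "EBR", "BWR", "qTy", "Gpa", "CBR")
  mk <- marker_truth[!marker_truth$garbage & !marker_truth$ambiguous, ,
                     drop = FALSE]
  chroms <- sort(unique(mk$chrom))
  causal <- data.frame(
    id = seq_len(config$n_causal),
    species = rep(c("potato", "tomato"), length.out = config$n_causal),
    trait_class = rep(classes, length.out = config$n_causal),
    chrom = sample(chroms, config$n_causal, replace = TRUE),
    stringsAsFactors = FALSE)
  causal$pos <- floor(runif(config$n_causal, 0, config$chrom_len_bp))
  causal$ortholog_of <- NA_integer_
  if (!is.null(piece_map)) {
    # every second tomato causal mirrors the preceding potato causal
    tom <- which(causal$species == "tomato")
    orth <- tom[seq_along(tom) %% 2 == 1]
    src <- orth - 1L
    ok <- src >= 1 & causal$species[pmax(src, 1L)] == "potato"
    orth <- orth[ok]; src <- src[ok]
    causal$trait_class[orth] <- causal$trait_class[src]
    causal$chrom[orth] <- causal$chrom[src]
    causal$pos[orth] <- vapply(seq_along(orth), function(i)
      map_a_to_b(causal$chrom[src[i]], causal$pos[src[i]], piece_map),
      numeric(1))
    causal$ortholog_of[orth] <- src
  }

  ev <- list(); truth <- list()
  for (s in seq_len(config$n_studies)) {
    cz <- causal[sample(config$n_causal, 1), ]
    sid <- sprintf("ST%03d", s)
    poscol <- if (cz$species == "potato") "posA" else "posB"
    m <- mk[mk$chrom == cz$chrom, , drop = FALSE]
    pos <- m[[poscol]]
    d <- pos - cz$pos
    loose <- min(abs(d)) > config$half_width
    use_flank <- runif(1) < config$p_flanking &&
      any(d <= 0) && any(d > 0)
    mkrow <- function(mid, rel) data.frame(
      study_id = sid, species = cz$species, trait_class = cz$trait_class,
      locus_kind = "quantitative", chrom = cz$chrom, marker_id = mid,
      relation = rel, locus_name = NA_character_, stringsAsFactors = FALSE)
    if (use_flank) {
      left <- m$locus_id[d <= 0][which.max(d[d <= 0])]
      right <- m$locus_id[d > 0][which.min(d[d > 0])]
      ev[[length(ev) + 1]] <- rbind(mkrow(left, "flanking_left"),
                                    mkrow(right, "flanking_right"))
    } else {
      nearest <- m$locus_id[which.min(abs(d))]
      ev[[length(ev) + 1]] <- mkrow(nearest, "linked")
    }
    truth[[length(truth) + 1]] <- data.frame(
      study_id = sid, species = cz$species, trait_class = cz$trait_class,
      chrom = cz$chrom, causal_pos = cz$pos,
      ortholog_of = cz$ortholog_of, flanking = use_flank,
      loose_evidence = loose, stringsAsFactors = FALSE)
  }
  studies <- do.call(rbind, c(ev, make.row.names = FALSE))
  studies$report_id <- paste(studies$study_id, studies$species,
                             studies$trait_class, studies$locus_kind,
                             studies$chrom, "", sep = "|")
  tr <- do.call(rbind, c(truth, make.row.names = FALSE))
  tr$report_id <- paste(tr$study_id, tr$species, tr$trait_class,
                        "quantitative", tr$chrom, "", sep = "|")
  list(studies = studies, truth = tr)
}

#' Run the full simulator
#' @param config [sim_config()].
#' @return list: genomeA, genomeB, markers, studies, truth (rearrangements,
#'   piece_map, markers, studies, chrom_lengths, config echo).
#' @export
simulate_all <- function(config = sim_config()) {
  sim <- simulate_genome_pair(config)
  mk <- simulate_markers(sim, config)
  st <- simulate_studies(mk$truth, config, sim$truth$piece_map)
  list(genomeA = sim$genomeA, genomeB = sim$genomeB,
       markers = mk$markers, studies = st$studies,
       truth = c(sim$truth, list(markers = mk$truth, studies = st$truth,
                                 config = unclass(config))))
}

# pick one element of x (sample() would misread a length-1 numeric as 1:n);
# returns `fallback` when x is empty (a one-chromosome genome cannot mismap)
safe_pick <- function(x, fallback) {
  if (!length(x)) return(fallback)
  x[sample.int(length(x), 1)]
}
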
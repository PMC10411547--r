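#' Anchoring parameters
#'
#' Defaults follow the conventions of web-BLAST placement of marker
#' sequences on a reference genome: hits are accepted at strictly more than
#' `min_identity` percent identity, the E-value class is relaxed for queries
#' shorter than `short_query_len` (recorded, since the built-in matcher is
#' seed-based rather than E-value based), and a best hit is called unique
#' when the runner-up scores below `best_hit_margin` times the best score.
#'
#' @param min_identity percent identity a hit must strictly exceed (70).
#' @param min_aln_len minimum aligned length in bp (30).
#' @param short_query_len queries shorter than this get the relaxed
#'   E-value class (30).
#' @param evalue_normal,evalue_short nominal expect thresholds recorded for
#'   the two classes (10 and 1).
#' @param max_amplicon maximum in-silico PCR product length in bp (5000).
#' @param best_hit_margin score ratio under which the runner-up does not
#'   challenge uniqueness (0.95).
#' @param seed_k,seed_step k-mer size and spacing of seeds for the built-in
#'   matcher.
#' @param primer_seed3 number of 3'-terminal primer bases that must match
#'   exactly (8; mimics PCR extension chemistry).
#' @param cluster_window bp window within which several near-equal hits on
#'   one chromosome are collapsed to their midpoint (clustered gene
#'   families; 2e6).
#' @param max_n_frac queries with more than this fraction of N are rejected
#'   as low complexity (0.5).
#' @return list of class `anchor_params`.
#' @export
anchor_params <- function(min_identity = 70, min_aln_len = 30,
                          short_query_len = 30, evalue_normal = 10,
                          evalue_short = 1, max_amplicon = 5000,
                          best_hit_margin = 0.95, seed_k = 12L,
                          seed_step = 10L, primer_seed3 = 8L,
                          cluster_window = 2e6, max_n_frac = 0.5) {
  stopifnot(min_identity > 0, min_identity <= 100, best_hit_margin > 0,
            best_hit_margin <= 1)
  structure(list(min_identity = min_identity, min_aln_len = min_aln_len,
                 short_query_len = short_query_len,
                 evalue_normal = evalue_normal, evalue_short = evalue_short,
                 max_amplicon = max_amplicon,
                 best_hit_margin = best_hit_margin, seed_k = as.integer(seed_k),
                 seed_step = as.integer(seed_step),
                 primer_seed3 = as.integer(primer_seed3),
                 cluster_window = cluster_window, max_n_frac = max_n_frac),
            class = "anchor_params")
}

empty_hits <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), identity = numeric(), score = numeric(),
             aln_len = numeric(), stringsAsFactors = FALSE)
}

#' Align one query sequence against a genome
#'
#' Built-in backend: k-mer seeds (every `seed_step` bp plus the terminal
#' window, both strands) followed by ungapped diagonal evaluation of the
#' full query. Hits below `min_identity` (strict) or shorter than
#' `min_aln_len` are removed; the rest are returned sorted by descending
#' score (match count), ties by chrom/start. Queries with more than
#' `max_n_frac` N content return zero hits with reason
#' `"low_complexity_query"` in the `reason` attribute.
#'
#' @param query nucleotide string (>= 15 bp).
#' @param genome a `genome_set`.
#' @param params [anchor_params()].
#' @return data frame of hits: chrom, start, end (0-based half-open),
#'   strand, identity, score, aln_len; attribute `evalue_class` is
#'   `"normal"` or `"relaxed_short_query"`.
#' @export
align_candidates <- function(query, genome, params = anchor_params()) {
  stopifnot(nchar(query) >= 15)
  query <- toupper(query)
  ecl <- if (nchar(query) < params$short_query_len) "relaxed_short_query"
         else "normal"
  n_frac <- lengths(regmatches(query, gregexpr("N", query))) / nchar(query)
  if (n_frac > params$max_n_frac) {
    h <- empty_hits()
    attr(h, "reason") <- "low_complexity_query"
    attr(h, "evalue_class") <- ecl
    return(h)
  }
  k <- min(params$seed_k, nchar(query))
  raw <- cpp_seed_hits(query, as.character(genome$seqs), k,
                       params$seed_step, params$min_identity,
                       min(params$min_aln_len, nchar(query)), 5000L)
  h <- data.frame(chrom = names(genome$seqs)[raw$chrom_idx],
                  start = raw$start, end = raw$end, strand = raw$strand,
                  identity = 100 * raw$matches / raw$aln_len,
                  score = as.numeric(raw$matches), aln_len = raw$aln_len,
                  stringsAsFactors = FALSE)
  h <- h[order(-h$score, h$chrom, h$start), , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "evalue_class") <- ecl
  h
}

#' In-silico PCR for a primer pair
#'
#' Finds binding sites of both primers (exact 3'-terminal
#' `primer_seed3`-mer, total mismatches bounded by the identity gate),
#' pairs a plus-strand site of one primer with a minus-strand site of the
#' other facing inward, and reports the amplicon span (outer primer ends)
#' when the product length is at most `max_amplicon`.
#'
#' @param fwd,rev primer sequences (>= 15 bp each).
#' @param genome a `genome_set`.
#' @param params [anchor_params()].
#' @return data frame of amplicon hits: chrom, start, end, strand,
#'   identity (mean site identity), score, aln_len (product length). When
#'   primer sites exist only on the same strand the result is empty with
#'   attribute `reason = "no_opposed_sites"`.
#' @export
epcr_primer_pair <- function(fwd, rev, genome, params = anchor_params()) {
  stopifnot(nchar(fwd) >= 15, nchar(rev) >= 15)
  fwd <- toupper(fwd); rev <- toupper(rev)
  sites <- cpp_primer_sites(c(fwd, rev), as.character(genome$seqs),
                            params$primer_seed3,
                            c(primer_max_mm(fwd, params),
                              primer_max_mm(rev, params)))
  sites$chrom <- names(genome$seqs)[sites$chrom_idx]
  sites$len <- ifelse(sites$primer == 1, nchar(fwd), nchar(rev))
  sites$end <- sites$start + sites$len
  pair_amplicons(sites[sites$primer == 1, , drop = FALSE],
                 sites[sites$primer == 2, , drop = FALSE], params)
}

# mismatch budget keeping site identity strictly above the gate
primer_max_mm <- function(p, params) {
  len <- nchar(p)
  m <- floor(len * (1 - params$min_identity / 100))
  if ((len - m) / len * 100 <= params$min_identity) m <- m - 1
  max(0L, as.integer(m))
}

pair_amplicons <- function(f, r, params) {
  out <- empty_hits()
  pair_up <- function(left, right, strand) {
    # left site on plus strand, right site on minus strand, facing inward
    if (!nrow(left) || !nrow(right)) return(NULL)
    res <- NULL
    for (i in seq_len(nrow(left))) {
      cand <- right[right$chrom == left$chrom[i] &
                      right$start >= left$start[i] &
                      right$end - left$start[i] <= params$max_amplicon &
                      right$start >= left$end[i], , drop = FALSE]
      if (!nrow(cand)) next
      res <- rbind(res, data.frame(
        chrom = cand$chrom, start = left$start[i], end = cand$end,
        strand = strand,
        identity = 100 * (1 - (left$mismatches[i] + cand$mismatches) /
                            (left$len[i] + cand$len)),
        score = (left$len[i] - left$mismatches[i]) +
          (cand$len - cand$mismatches),
        aln_len = cand$end - left$start[i], stringsAsFactors = FALSE))
    }
    res
  }
  hits <- rbind(
    pair_up(f[f$strand == "+", , drop = FALSE],
            r[r$strand == "-", , drop = FALSE], "+"),
    pair_up(r[r$strand == "+", , drop = FALSE],
            f[f$strand == "-", , drop = FALSE], "-"))
  if (is.null(hits) || !nrow(hits)) {
    if (nrow(f) || nrow(r)) attr(out, "reason") <- "no_opposed_sites"
    return(out)
  }
  hits <- hits[order(-hits$score, hits$chrom, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Resolve scored hits into one anchor
#'
#' Decision rules, in order: no passing hit is `unplaced`; a single hit or a
#' best hit whose runner-up scores below `best_hit_margin * best` is
#' `unique`; several near-equal hits all within one `cluster_window` on one
#' chromosome collapse to the window midpoint (clustered gene family,
#' status `resolved_by_prior`, reason `clustered_family`); several
#' near-equal hits with exactly one on the prior chromosome from genetic
#' mapping resolve there (`resolved_by_prior`); anything else is
#' `ambiguous` and gets no coordinates.
#'
#' @param hits data frame from [align_candidates()] or
#'   [epcr_primer_pair()], sorted by descending score.
#' @param prior_chrom optional chromosome number (1-12) from genetic
#'   mapping.
#' @param params [anchor_params()].
#' @return one-row data frame: chrom, start, end, strand, identity, status,
#'   reason.
#' @export
resolve_anchor <- function(hits, prior_chrom = NA, params = anchor_params()) {
  out <- function(chrom = NA_character_, start = NA_real_, end = NA_real_,
                  strand = NA_character_, identity = NA_real_,
                  status, reason = "") {
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               identity = identity, status = status, reason = reason,
               stringsAsFactors = FALSE)
  }
  rsn <- attr(hits, "reason")
  if (!nrow(hits))
    return(out(status = "unplaced",
               reason = if (is.null(rsn)) "no_passing_hit" else rsn))
  best <- hits$score[1]
  near <- hits[hits$score >= params$best_hit_margin * best, , drop = FALSE]
  take <- function(i, status, reason = "")
    out(hits$chrom[i], hits$start[i], hits$end[i], hits$strand[i],
        hits$identity[i], status, reason)
  if (nrow(near) == 1) return(take(1, "unique"))
  # clustered gene family: near-equal hits confined to one small window
  if (length(unique(near$chrom)) == 1 &&
      max(near$end) - min(near$start) <= params$cluster_window) {
    mid <- floor((min(near$start) + max(near$end)) / 2)
    return(out(near$chrom[1], mid, mid + 1, near$strand[1],
               max(near$identity), "resolved_by_prior", "clustered_family"))
  }
  if (!is.na(prior_chrom)) {
    pc <- sprintf("chr%02d", as.integer(prior_chrom))
    on_prior <- which(near$chrom == pc)
    if (length(on_prior) == 1)
      return(take(on_prior, "resolved_by_prior", "prior_chrom"))
    if (length(on_prior) > 1)
      return(out(status = "ambiguous", reason = "multiple_on_prior_chrom"))
    return(out(status = "ambiguous", reason = "no_hit_on_prior_chrom"))
  }
  out(status = "ambiguous", reason = "multiple_near_equal_hits")
}

#' Anchor a full marker catalogue on one genome
#'
#' Runs [align_candidates()] (or [epcr_primer_pair()] for primer pairs)
#' followed by [resolve_anchor()] for every marker.
#'
#' @param markers marker data frame from [read_marker_table()].
#' @param genome a `genome_set`.
#' @param params [anchor_params()].
#' @return anchor table: locus_id, genome_id, chrom, start, end, strand,
#'   identity, evalue_class, status, reason.
#' @export
anchor_markers <- function(markers, genome, params = anchor_params()) {
  is_pp <- markers$marker_type == "primer_pair"
  res <- vector("list", nrow(markers))
  # sequence markers go through the matcher in one batched call per genome
  seq_idx <- which(!is_pp)
  if (length(seq_idx)) {
    qs <- toupper(markers$sequence[seq_idx])
    n_frac <- vapply(qs, function(q)
      lengths(regmatches(q, gregexpr("N", q))) / nchar(q), numeric(1))
    ok <- n_frac <= params$max_n_frac
    raw <- if (any(ok))
      cpp_seed_hits(qs[ok], as.character(genome$seqs), params$seed_k,
                    params$seed_step, params$min_identity,
                    params$min_aln_len, 5000L)
    else NULL
    ok_pos <- which(ok)
    for (j in seq_along(seq_idx)) {
      i <- seq_idx[j]
      ecl <- if (nchar(qs[j]) < params$short_query_len)
        "relaxed_short_query" else "normal"
      if (!ok[j]) {
        h <- empty_hits()
        attr(h, "reason") <- "low_complexity_query"
      } else {
        qn <- match(j, ok_pos)
        sel <- raw[raw$query == qn, , drop = FALSE]
        h <- data.frame(chrom = names(genome$seqs)[sel$chrom_idx],
                        start = sel$start, end = sel$end,
                        strand = sel$strand,
                        identity = 100 * sel$matches / sel$aln_len,
                        score = as.numeric(sel$matches),
                        aln_len = sel$aln_len, stringsAsFactors = FALSE)
        h <- h[order(-h$score, h$chrom, h$start), , drop = FALSE]
      }
      a <- resolve_anchor(h, markers$prior_chrom[i], params)
      a$evalue_class <- ecl
      res[[i]] <- a
    }
  }
  pp_idx <- which(is_pp)
  if (length(pp_idx)) {
    # one batched site scan per genome: the k-mer index is built once
    primers <- toupper(as.vector(rbind(markers$sequence[pp_idx],
                                       markers$sequence2[pp_idx])))
    sites <- cpp_primer_sites(primers, as.character(genome$seqs),
                              params$primer_seed3,
                              vapply(primers, primer_max_mm,
                                     integer(1), params))
    sites$chrom <- names(genome$seqs)[sites$chrom_idx]
    sites$len <- nchar(primers)[sites$primer]
    sites$end <- sites$start + sites$len
    for (j in seq_along(pp_idx)) {
      i <- pp_idx[j]
      f <- sites[sites$primer == 2 * j - 1, , drop = FALSE]
      r <- sites[sites$primer == 2 * j, , drop = FALSE]
      h <- pair_amplicons(f, r, params)
      a <- resolve_anchor(h, markers$prior_chrom[i], params)
      a$evalue_class <- "relaxed_short_query"
      res[[i]] <- a
    }
  }
  tab <- do.call(rbind, res)
  tab <- cbind(data.frame(locus_id = markers$locus_id,
                          genome_id = genome$genome_id,
                          stringsAsFactors = FALSE),
               tab[c("chrom", "start", "end", "strand", "identity",
                     "evalue_class", "status", "reason")])
  rownames(tab) <- NULL
  tab
}

#' Reverse-complement a nucleotide string
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
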
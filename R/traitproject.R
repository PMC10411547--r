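#' Default uniform nomenclature scheme
#'
#' Species prefixes (`p` potato, `t` tomato, `pe` pepper, `e` eggplant) and
#' trait-class acronyms for quantitative loci. Resistance classes use one
#' acronym across species; the agronomic classes sugar / yield / weight /
#' maturity have species-specific acronyms (tSS vs pTSC, tFY vs pTY, tFW vs
#' pTW, tM vs pM). Each resistance class also carries its pathogen class,
#' used by hotspot detection.
#'
#' @return list with `species_prefix`, `acronym` (per trait class: either a
#'   single string or a per-species map), `pathogen_class`.
#' @export
default_nomenclature <- function() {
  list(
    species_prefix = c(potato = "p", tomato = "t", pepper = "pe",
                       eggplant = "e", tobacco = "n"),
    acronym = list(
      LBR = "LBR", EBR = "EBR", RSe = "RSe", BWR = "BWR", CSR = "CSR",
      rx = "rx", qTy = "qTy", CMV = "CMV", Gpa = "Gpa", Gro = "Gro",
      WR = "WR", CBR = "CBR", Ts = "Ts", Rtu = "Rtu", `Ol-qtl` = "Ol-qtl",
      Cm = "Cm", Eca = "Eca", PLRV = "PLRV", qPvr = "qPvr",
      sugar = c(tomato = "SS", potato = "TSC"),
      yield = c(tomato = "FY", potato = "TY"),
      weight = c(tomato = "FW", potato = "TW"),
      maturity = c(tomato = "M", potato = "M")),
    pathogen_class = c(
      LBR = "oomycete", qPvr = "virus",
      EBR = "fungus", RSe = "fungus", `Ol-qtl` = "fungus",
      BWR = "bacterium", CSR = "bacterium", rx = "bacterium",
      Cm = "bacterium", Eca = "bacterium",
      qTy = "virus", CMV = "virus", PLRV = "virus",
      Gpa = "nematode", Gro = "nematode",
      WR = "insect", CBR = "insect", Ts = "insect", Rtu = "insect"))
}

#' Pathogen class of a trait class
#' @param trait_class character vector.
#' @param scheme nomenclature scheme.
#' @return character vector (`NA` for non-resistance classes).
#' @export
pathogen_class_of <- function(trait_class, scheme = default_nomenclature()) {
  unname(scheme$pathogen_class[trait_class])
}

empty_candidates <- function() {
  data.frame(study_id = character(), species = character(),
             trait_class = character(), locus_kind = character(),
             chrom = character(), start = numeric(), end = numeric(),
             locus_name = character(), stringsAsFactors = FALSE)
}

#' Project one study report into a candidate physical interval
#'
#' When both flanking markers are placed, the interval runs from the left
#' flank's anchor midpoint to the right flank's. Otherwise the bounding
#' span of all placed linked/associated/cosegregating markers is extended
#' by `half_width` on each side that lacks a flanking bound (the
#' single-linked-marker case yields marker +/- `half_width`), then clipped
#' to the chromosome. Association evidence is treated like linkage;
#' cosegregation is zero-distance linkage.
#'
#' For a qualitative report whose evidence includes a sequence-anchored
#' `gene` marker, the interval is that anchor's span (point-like
#' placement of a cloned gene).
#'
#' @param report data frame of evidence rows (one study report; see
#'   [read_study_table()]).
#' @param anchors anchor table for the species' genome.
#' @param chrom_lengths named chromosome lengths.
#' @param half_width interval half-width for unbounded sides (bp; 2e6).
#' @param markers optional marker table (to recognise `gene` markers).
#' @return one-row candidate data frame; a zero-row frame with attribute
#'   `reason` when no evidence marker is placed on the reported
#'   chromosome.
#' @export
project_report <- function(report, anchors, chrom_lengths,
                           half_width = 2e6, markers = NULL) {
  ch <- normalize_chrom(report$chrom[1])
  len <- unname(chrom_lengths[ch])
  if (is.na(len)) stop("unknown chromosome in study report: ", ch)
  a <- anchors[match(report$marker_id, anchors$locus_id), , drop = FALSE]
  placed <- !is.na(a$status) & a$status %in% c("unique", "resolved_by_prior") &
    a$chrom == ch
  if (!any(placed))
    return(structure(empty_candidates(), reason = "no_anchored_evidence"))
  mid <- floor((a$start + a$end) / 2)
  row <- function(s, e) data.frame(
    study_id = report$study_id[1], species = report$species[1],
    trait_class = report$trait_class[1], locus_kind = report$locus_kind[1],
    chrom = ch, start = max(0, s), end = min(len, e),
    locus_name = report$locus_name[1], stringsAsFactors = FALSE)
  # cloned gene: point-like interval equal to the anchor span
  if (!is.null(markers) && report$locus_kind[1] == "qualitative") {
    mt <- markers$marker_type[match(report$marker_id, markers$locus_id)]
    g <- which(placed & mt == "gene")
    if (length(g))
      return(row(a$start[g[1]], a$end[g[1]]))
  }
  fl <- which(placed & report$relation == "flanking_left")
  fr <- which(placed & report$relation == "flanking_right")
  lk <- which(placed & report$relation %in%
                c("linked", "associated", "cosegregating"))
  if (length(fl) && length(fr)) {
    s <- min(mid[fl]); e <- max(mid[fr])
    if (s > e) stop("flank_order_conflict in report '",
                    report$report_id[1], "'")
    if (s == e) e <- e + 1
    return(row(s, e))
  }
  pts <- mid[c(fl, fr, lk)]
  s <- min(pts); e <- max(pts)
  if (!length(fl)) s <- s - half_width
  if (!length(fr)) e <- e + half_width
  if (e <= max(0, s)) e <- max(0, s) + 1  # degenerate (half_width 0) point
  row(s, e)
}

#' Project all study reports into candidate intervals
#'
#' Batch wrapper around [project_report()]; reports with no anchored
#' evidence or with conflicting flank order are dropped and returned in
#' the `dropped` element with their reason.
#'
#' @param studies study table ([read_study_table()]).
#' @param anchors_by_species named list of anchor tables (one per species'
#'   reference genome; a species absent from the list is skipped).
#' @param chrom_lengths_by_species named list of chromosome-length vectors.
#' @param half_width see [project_report()].
#' @param markers optional marker table.
#' @return list: `candidates` data frame, `dropped` data frame
#'   (report_id, reason).
#' @export
project_reports <- function(studies, anchors_by_species,
                            chrom_lengths_by_species, half_width = 2e6,
                            markers = NULL) {
  cands <- list(); dropped <- list()
  for (rid in unique(studies$report_id)) {
    rep_i <- studies[studies$report_id == rid, , drop = FALSE]
    sp <- rep_i$species[1]
    if (!sp %in% names(anchors_by_species)) {
      dropped[[rid]] <- "no_reference_genome"
      next
    }
    res <- tryCatch(
      project_report(rep_i, anchors_by_species[[sp]],
                     chrom_lengths_by_species[[sp]], half_width, markers),
      error = function(e)
        structure(empty_candidates(), reason = conditionMessage(e)))
    if (is.null(res) || !nrow(res)) {
      rsn <- attr(res, "reason")
      dropped[[rid]] <- if (is.null(rsn)) "no_anchored_evidence" else rsn
    } else {
      res$report_id <- rid
      cands[[rid]] <- res
    }
  }
  list(candidates = if (length(cands))
    do.call(rbind, c(cands, make.row.names = FALSE)) else empty_candidates(),
    dropped = data.frame(report_id = names(dropped),
                         reason = unlist(dropped, use.names = FALSE),
                         stringsAsFactors = FALSE))
}

star_label <- function(support) {
  ifelse(support > 3, "**", ifelse(support >= 2, "*", ""))
}

#' Merge candidate intervals into trait loci
#'
#' Within each species + trait class + locus kind + chromosome group,
#' intervals overlapping by at least 1 bp are merged by single linkage;
#' the merged interval is the union, support is the number of distinct
#' contributing studies, and the star label follows the support rule
#' ("" = 1 study, "*" = 2-3, "**" = >3). Qualitative candidates merge only
#' within the same published gene symbol; quantitative and qualitative
#' loci are never merged with each other (their colocalization is reported
#' downstream instead).
#'
#' @param candidates data frame from [project_reports()].
#' @return locus table: species, trait_class, locus_kind, chrom, start,
#'   end, support, star, locus_name, study_ids, report_ids.
#' @export
merge_loci <- function(candidates) {
  if (!nrow(candidates)) {
    out <- candidates
    out$support <- integer(); out$star <- character()
    out$study_ids <- character(); out$report_ids <- character()
    return(out)
  }
  if (is.null(candidates$report_id))
    candidates$report_id <- candidates$study_id
  key <- paste(candidates$species, candidates$trait_class,
               candidates$locus_kind, candidates$chrom,
               ifelse(candidates$locus_kind == "qualitative" &
                        !is.na(candidates$locus_name),
                      candidates$locus_name, ""),
               sep = "|")
  res <- list()
  for (k in sort(unique(key))) {
    g <- candidates[key == k, , drop = FALSE]
    g <- g[order(g$start, g$end, g$report_id), , drop = FALSE]
    cl <- integer(nrow(g)); cur <- 1L; cl[1] <- 1L
    hi <- g$end[1]
    if (nrow(g) > 1) for (i in 2:nrow(g)) {
      if (g$start[i] < hi) cl[i] <- cur   # >= 1 bp overlap (half-open)
      else { cur <- cur + 1L; cl[i] <- cur }
      hi <- max(hi, g$end[i])
    }
    for (cc in unique(cl)) {
      m <- g[cl == cc, , drop = FALSE]
      support <- length(unique(m$study_id))
      res[[length(res) + 1]] <- data.frame(
        species = m$species[1], trait_class = m$trait_class[1],
        locus_kind = m$locus_kind[1], chrom = m$chrom[1],
        start = min(m$start), end = max(m$end), support = support,
        star = star_label(support),
        locus_name = m$locus_name[1],
        study_ids = paste(sort(unique(m$study_id)), collapse = ","),
        report_ids = paste(sort(unique(m$report_id)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out[order(out$species, out$trait_class, out$chrom, out$start), ,
      drop = FALSE]
}

#' Assign uniform locus names
#'
#' Quantitative loci get `prefix + acronym + chromosome number + "." +
#' serial`, with serials assigned per species/trait/chromosome in
#' ascending interval-start order (e.g. the first potato late-blight QRL
#' on chromosome 5 is `pLBR5.1`). Qualitative loci keep their published
#' gene symbol verbatim.
#'
#' @param loci merged locus table ([merge_loci()]).
#' @param scheme [default_nomenclature()].
#' @return `loci` with a `name` column (unique within the run).
#' @export
assign_names <- function(loci, scheme = default_nomenclature()) {
  if (!nrow(loci)) { loci$name <- character(); return(loci) }
  nm <- character(nrow(loci))
  qual <- loci$locus_kind == "qualitative"
  nm[qual] <- ifelse(is.na(loci$locus_name[qual]),
                     paste0("gene", seq_len(sum(qual))),
                     loci$locus_name[qual])
  qt <- which(!qual)
  if (length(qt)) {
    grp <- paste(loci$species[qt], loci$trait_class[qt], loci$chrom[qt],
                 sep = "|")
    for (g in unique(grp)) {
      sel <- qt[grp == g]
      sel <- sel[order(loci$start[sel], loci$end[sel])]
      sp <- loci$species[sel[1]]
      tc <- loci$trait_class[sel[1]]
      acr <- scheme$acronym[[tc]]
      if (is.null(acr))
        stop("unknown trait_class '", tc, "' (valid: ",
             paste(names(scheme$acronym), collapse = ", "), ")")
      if (length(acr) > 1) acr <- unname(acr[sp])
      pref <- unname(scheme$species_prefix[sp])
      nm[sel] <- paste0(pref, acr, chrom_number(loci$chrom[sel[1]]), ".",
                        seq_along(sel))
    }
  }
  loci$name <- nm
  if (anyDuplicated(nm[nm != ""]))
    warning("duplicate locus names after assignment: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  loci
}

#' Flag loci wider than the large-interval cutoff
#'
#' Loci with width strictly greater than `large_cutoff` are flagged
#' `excluded_large`; width exactly at the cutoff is kept. Flagged loci are
#' retained in outputs but skipped by colocalization and hotspot
#' detection.
#'
#' @param loci locus table.
#' @param large_cutoff bp (15e6).
#' @return `loci` with logical `excluded_large` column.
#' @export
filter_large <- function(loci, large_cutoff = 15e6) {
  loci$excluded_large <- (loci$end - loci$start) > large_cutoff
  loci
}

#' Place a qualitative (gene) report on the physical map
#'
#' Same interval logic as [project_report()], for a report describing a
#' single qualitative resistance gene: a sequence-characterized gene
#' (marker_type `gene`, anchored) gets a point-like interval equal to its
#' anchor span; otherwise linked/flanking-marker logic applies.
#'
#' @inheritParams project_report
#' @return one-row candidate with `locus_kind = "qualitative"`.
#' @export
place_gene <- function(report, anchors, chrom_lengths, half_width = 2e6,
                       markers = NULL) {
  report$locus_kind <- "qualitative"
  project_report(report, anchors, chrom_lengths, half_width, markers)
}
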
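#' Normalize a chromosome name to zero-padded "chrNN"
#'
#' The mapping literature writes "chromosome 5", "chr5", "ch05" or plain "5"
#' interchangeably; all collapse to "chr05". Names without a trailing number
#' are kept verbatim (already-canonical labels pass through).
#'
#' @param x character vector of chromosome labels (or integers).
#' @return character vector of canonical names.
#' @examples
#' normalize_chrom(c("chromosome 5", "chr12", "7"))
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  num <- suppressWarnings(as.integer(sub("^\\s*(chromosome|chrom|chr|ch)?\\s*0*([0-9]+)\\s*$",
                                         "\\2", x, ignore.case = TRUE)))
  out <- ifelse(is.na(num), x, sprintf("chr%02d", num))
  out
}

#' Chromosome number of a canonical chromosome name
#' @param x character vector of "chrNN" names.
#' @return integer vector.
#' @export
chrom_number <- function(x) {
  suppressWarnings(as.integer(sub("^chr0*", "", normalize_chrom(x))))
}

#' Read a genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]; record order is preserved,
#' lowercase bases are normalized to uppercase, and record names are
#' normalized to canonical "chrNN" labels (the original header is retained).
#'
#' @param path FASTA file.
#' @param genome_id short label for the assembly (defaults to the file stem).
#' @return a `genome_set`: list with `genome_id`, `seqs`
#'   (a [Biostrings::DNAStringSet] named by canonical chromosome),
#'   `chrom_lengths` (named numeric) and `original_names`.
#' @export
read_genome <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  # drop description after first whitespace
  orig <- sub("\\s.*$", "", names(seqs))
  canon <- normalize_chrom(orig)
  dup <- unique(canon[duplicated(canon)])
  if (length(dup))
    stop("duplicate chromosome record(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- canon
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  genome_set(genome_id, seqs, original_names = orig)
}

#' Construct a genome_set from sequences in memory
#' @param genome_id short assembly label.
#' @param seqs named [Biostrings::DNAStringSet] or named character vector.
#' @param original_names optional pre-normalization names.
#' @return a `genome_set` list.
#' @export
genome_set <- function(genome_id, seqs, original_names = names(seqs)) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- normalize_chrom(names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in genome '", genome_id, "'")
  structure(list(genome_id = genome_id,
                 seqs = seqs,
                 chrom_lengths = setNames(as.numeric(Biostrings::width(seqs)),
                                          names(seqs)),
                 original_names = original_names),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set '", x$genome_id, "': ", length(x$seqs),
      " chromosome(s), ", format(sum(x$chrom_lengths), big.mark = ","),
      " bp total\n", sep = "")
  invisible(x)
}

MARKER_TYPES <- c("genomic_clone", "cDNA_clone", "primer_pair", "snp_flank",
                  "gene")
RELATIONS <- c("linked", "flanking_left", "flanking_right", "associated",
               "cosegregating")
SPECIES <- c("potato", "tomato", "pepper", "eggplant", "tobacco")

#' Read marker and study tables
#'
#' Markers: TSV with columns `locus_id, marker_type, sequence, sequence2,
#' prior_chrom`. Studies: TSV with columns `study_id, species, trait_class,
#' locus_kind, chrom, marker_id, relation` and optionally `locus_name` (the
#' published gene symbol for qualitative loci). Evidence rows sharing
#' `study_id`, species, trait and chromosome form one study report; the
#' `report_id` column added on read identifies it.
#'
#' The relation vocabulary is closed (`linked`, `flanking_left`,
#' `flanking_right`, `associated`, `cosegregating`); `cosegregating` is
#' zero-distance linkage and is treated as `linked` downstream.
#'
#' @param marker_path,study_path TSV file paths.
#' @return list with `markers` and `studies` data frames.
#' @export
read_tables <- function(marker_path, study_path) {
  list(markers = read_marker_table(marker_path),
       studies = read_study_table(study_path))
}

#' @rdname read_tables
#' @export
read_marker_table <- function(marker_path) {
  m <- read.delim(marker_path, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = c("NA", ""))
  need <- c("locus_id", "marker_type", "sequence")
  if (!all(need %in% names(m)))
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  if (is.null(m$sequence2)) m$sequence2 <- NA_character_
  if (is.null(m$prior_chrom)) m$prior_chrom <- NA_character_
  m$prior_chrom <- suppressWarnings(as.integer(m$prior_chrom))
  validate_markers(m)
  m
}

validate_markers <- function(m) {
  bad <- which(!m$marker_type %in% MARKER_TYPES)
  if (length(bad))
    stop("unknown marker_type at row ", bad[1], ": '", m$marker_type[bad[1]],
         "' (valid: ", paste(MARKER_TYPES, collapse = ", "), ")")
  if (anyDuplicated(m$locus_id))
    stop("duplicate locus_id in marker table: ",
         paste(unique(m$locus_id[duplicated(m$locus_id)]), collapse = ", "))
  pp <- m$marker_type == "primer_pair"
  one_seq <- pp & (is.na(m$sequence2) | nchar(m$sequence2) < 15 |
                     nchar(m$sequence) < 15)
  if (any(one_seq))
    stop("primer_pair marker at row ", which(one_seq)[1],
         " needs two sequences of >= 15 bp each")
  short <- !pp & nchar(m$sequence) < 30
  if (any(short))
    stop("marker at row ", which(short)[1], " ('",
         m$locus_id[which(short)[1]], "'): sequence shorter than 30 bp")
  invisible(m)
}

#' @rdname read_tables
#' @export
read_study_table <- function(study_path) {
  s <- read.delim(study_path, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = c("NA", ""))
  need <- c("study_id", "species", "trait_class", "locus_kind", "chrom",
            "marker_id", "relation")
  if (!all(need %in% names(s)))
    stop("study table must have columns: ", paste(need, collapse = ", "))
  if (is.null(s$locus_name)) s$locus_name <- NA_character_
  bad <- which(!s$relation %in% RELATIONS)
  if (length(bad))
    stop("unknown relation at row ", bad[1], ": '", s$relation[bad[1]],
         "' (valid: ", paste(RELATIONS, collapse = ", "), ")")
  bad <- which(!s$species %in% SPECIES)
  if (length(bad))
    stop("unknown species at row ", bad[1], ": '", s$species[bad[1]], "'")
  bad <- which(!s$locus_kind %in% c("qualitative", "quantitative"))
  if (length(bad))
    stop("unknown locus_kind at row ", bad[1], ": '", s$locus_kind[bad[1]], "'")
  s$chrom <- normalize_chrom(s$chrom)
  s$report_id <- paste(s$study_id, s$species, s$trait_class, s$locus_kind,
                       s$chrom,
                       ifelse(is.na(s$locus_name), "", s$locus_name),
                       sep = "|")
  # both flanks present must name distinct markers
  for (rid in unique(s$report_id)) {
    e <- s[s$report_id == rid, ]
    fl <- e$marker_id[e$relation == "flanking_left"]
    fr <- e$marker_id[e$relation == "flanking_right"]
    if (length(fl) && length(fr) && any(fl %in% fr))
      stop("report '", rid, "': flanking_left and flanking_right name the ",
           "same marker")
  }
  s
}

#' Split a study table into per-report data frames
#' @param studies data frame from [read_study_table()].
#' @return named list of data frames (one per report).
#' @export
study_reports <- function(studies) {
  split(studies, studies$report_id)
}

#' Write intervals as BED6 or GFF3
#'
#' Accepts any data frame with columns `chrom`, `start`, `end` (0-based
#' half-open) and optionally `name`/`locus_id`, `score`/`support`, `strand`.
#' BED is written 0-based half-open; GFF3 1-based inclusive (conversion at
#' this boundary only), through `rtracklayer::export`. Intervals exceeding
#' the chromosome length are a hard error — never silently clipped here.
#'
#' @param intervals data frame of intervals.
#' @param path output file.
#' @param format "bed" or "gff3".
#' @param chrom_lengths named vector of chromosome lengths used for bounds
#'   checking (optional but recommended).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, format = c("bed", "gff3"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(intervals)
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("intervals need columns chrom, start, end")
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("invalid interval: start must be >= 0 and < end")
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[df$chrom]
    over <- which(is.na(lim) | df$end > lim)
    if (length(over))
      stop("interval exceeds chromosome bounds at row ", over[1], " (",
           df$chrom[over[1]], ":", df$start[over[1]], "-", df$end[over[1]], ")")
  }
  nm <- if (!is.null(df$name)) df$name else if (!is.null(df$locus_id))
    df$locus_id else paste0("ivl", seq_len(nrow(df)))
  sc <- if (!is.null(df$score)) df$score else if (!is.null(df$support))
    df$support else 0
  st <- if (!is.null(df$strand)) df$strand else "*"
  st[is.na(st) | !st %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = st)
  S4Vectors::mcols(gr)$name <- as.character(nm)
  S4Vectors::mcols(gr)$score <- as.numeric(sc)
  if (format == "bed") {
    rtracklayer::export(gr, path, format = "BED")
  } else {
    S4Vectors::mcols(gr)$type <- "region"
    S4Vectors::mcols(gr)$source <- "traitanchor"
    S4Vectors::mcols(gr)$ID <- as.character(nm)
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read intervals back from BED or GFF3 into the internal convention
#'
#' Inverse of [write_intervals()]: returns 0-based half-open coordinates.
#' @param path BED or GFF3 file.
#' @param format "bed" or "gff3".
#' @return data frame with chrom, start, end, name, score, strand.
#' @export
read_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = ifelse(format == "bed", "BED",
                                                  "GFF3"))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  df$name <- if (!is.null(mc$name)) as.character(mc$name) else
    if (!is.null(mc$ID)) as.character(mc$ID) else NA_character_
  df$score <- if (!is.null(mc$score)) as.numeric(mc$score) else NA_real_
  df$strand <- as.character(GenomicRanges::strand(gr))
  df
}

#' Write a FASTA file from a genome_set
#' @param genome a `genome_set`.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' Write a data frame as a TSV file (the package's exchange format)
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
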
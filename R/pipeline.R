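#' Run configuration for the end-to-end pipeline
#'
#' Every parameter defaults to the value used for real Solanaceae-scale
#' maps (interval half-width 2 Mbp for single-marker studies, 15 Mbp
#' large-interval cutoff) and is overridable — scaled-down synthetic runs
#' pass the scaled values from their [sim_config()].
#'
#' @param anchor [anchor_params()].
#' @param rearrange [rearrange_params()].
#' @param hotspot [hotspot_params()].
#' @param half_width bp (2e6).
#' @param large_cutoff bp (15e6).
#' @param scheme [default_nomenclature()].
#' @param style [map_style()].
#' @param species_a,species_b species mapped on genome A / genome B
#'   ("potato", "tomato").
#' @return list of class `run_config`.
#' @export
run_config <- function(anchor = anchor_params(),
                       rearrange = rearrange_params(),
                       hotspot = hotspot_params(),
                       half_width = 2e6, large_cutoff = 15e6,
                       scheme = default_nomenclature(),
                       style = map_style(),
                       species_a = "potato", species_b = "tomato") {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline on in-memory inputs
#'
#' Stages in order: anchor both genomes, cross-map into matched pairs,
#' detect rearrangements, project and merge trait loci, colocalization /
#' synteny / hotspots, summary. Analysis stages are deterministic; all
#' randomness lives in the synthetic-data generator.
#'
#' @param genomeA,genomeB `genome_set` objects.
#' @param markers marker table ([read_marker_table()] schema).
#' @param studies study table ([read_study_table()] schema).
#' @param config [run_config()].
#' @return list with per-stage outputs (`anchorsA`, `anchorsB`, `pairs`,
#'   `classification`, `rearrangements`, `loci`, `dropped_reports`,
#'   `coloc`, `syntenic`, `hotspots`, `summary`) and `manifest` (record
#'   counts and parameter echo).
#' @export
run_pipeline <- function(genomeA, genomeB, markers, studies,
                         config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  anchorsA <- stage("anchor",
                    anchor_markers(markers, genomeA, config$anchor))
  anchorsB <- stage("anchor",
                    anchor_markers(markers, genomeB, config$anchor))
  cm <- stage("crossmap", build_pairs(anchorsA, anchorsB))
  re <- stage("rearrange",
              detect_rearrangements(cm$pairs, genomeA$chrom_lengths,
                                    genomeB$chrom_lengths,
                                    config$rearrange))
  anchors_by_species <- setNames(list(anchorsA, anchorsB),
                                 c(config$species_a, config$species_b))
  lengths_by_species <- setNames(list(genomeA$chrom_lengths,
                                      genomeB$chrom_lengths),
                                 c(config$species_a, config$species_b))
  pr <- stage("traitproject",
              project_reports(studies, anchors_by_species,
                              lengths_by_species, config$half_width,
                              markers))
  loci <- stage("traitproject", {
    l <- merge_loci(pr$candidates)
    l <- assign_names(l, config$scheme)
    filter_large(l, config$large_cutoff)
  })
  lociA <- loci[loci$species == config$species_a, , drop = FALSE]
  lociB <- loci[loci$species == config$species_b, , drop = FALSE]
  col <- stage("coloc", rbind(find_colocalized(lociA),
                              find_colocalized(lociB)))
  syn <- stage("coloc", find_syntenic(lociA, lociB, re$block_map))
  hs <- stage("coloc", detect_hotspots(lociA, lociB, re$block_map,
                                       config$hotspot, config$scheme))
  summ <- stage("reporting", summarize_loci(loci))

  placed <- function(a) sum(a$status %in% c("unique", "resolved_by_prior"))
  manifest <- list(
    n_markers = nrow(markers),
    n_placed_A = placed(anchorsA), n_placed_B = placed(anchorsB),
    n_matched_pairs = nrow(cm$pairs),
    classification = cm$classification[c("matched_both",
                                         "matched_one_only",
                                         "matched_neither")],
    n_inversions = sum(re$calls$kind == "inversion"),
    n_translocations = sum(re$calls$kind == "intra_translocation"),
    n_study_reports = length(unique(studies$report_id)),
    n_dropped_reports = nrow(pr$dropped),
    n_loci = nrow(loci), n_excluded_large = sum(loci$excluded_large),
    n_coloc_pairs = nrow(col), n_syntenic_pairs = nrow(syn),
    n_hotspots = nrow(hs),
    params = list(half_width = config$half_width,
                  large_cutoff = config$large_cutoff,
                  min_identity = config$anchor$min_identity,
                  min_block_anchors = config$rearrange$min_block_anchors))
  list(anchorsA = anchorsA, anchorsB = anchorsB, pairs = cm$pairs,
       classification = cm$classification, rearrangements = re,
       loci = loci, dropped_reports = pr$dropped, coloc = col,
       syntenic = syn, hotspots = hs, summary = summ,
       manifest = manifest)
}

#' Run the pipeline from files on disk
#'
#' Thin wrapper: reads two genome FASTAs and the marker/study TSVs, runs
#' [run_pipeline()], and writes stage outputs (TSV + BED) and a JSON run
#' manifest into `outdir`.
#'
#' @param genome_a_path,genome_b_path FASTA files.
#' @param marker_path,study_path TSV files.
#' @param outdir output directory (created).
#' @param config [run_config()].
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_pipeline_files <- function(genome_a_path, genome_b_path, marker_path,
                               study_path, outdir,
                               config = run_config()) {
  for (p in c(genome_a_path, genome_b_path, marker_path, study_path))
    if (!file.exists(p)) stop("missing input path: ", p)
  gA <- read_genome(genome_a_path, "genomeA")
  gB <- read_genome(genome_b_path, "genomeB")
  tabs <- read_tables(marker_path, study_path)
  res <- run_pipeline(gA, gB, tabs$markers, tabs$studies, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$anchorsA, file.path(outdir, "anchors_A.tsv"))
  write_tsv(res$anchorsB, file.path(outdir, "anchors_B.tsv"))
  write_tsv(res$pairs, file.path(outdir, "pairs.tsv"))
  write_tsv(res$rearrangements$calls,
            file.path(outdir, "rearrangements.tsv"))
  write_tsv(res$loci, file.path(outdir, "loci.tsv"))
  write_tsv(res$coloc, file.path(outdir, "coloc.tsv"))
  write_tsv(res$syntenic, file.path(outdir, "syntenic.tsv"))
  write_tsv(res$hotspots, file.path(outdir, "hotspots.tsv"))
  write_tsv(res$summary, file.path(outdir, "summary.tsv"))
  keep <- res$loci[!res$loci$excluded_large & res$loci$species ==
                     config$species_a, , drop = FALSE]
  if (nrow(keep))
    write_intervals(keep, file.path(outdir, "loci_A.bed"), "bed",
                    gA$chrom_lengths)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
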
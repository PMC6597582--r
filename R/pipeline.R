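#' Run the full blacklist pipeline
#'
#' End-to-end driver: mappability, per-sample binning, cross-sample quantile
#' normalization with median reduction, region calling, and BED output.
#' Writes `blacklist.bed` and a machine-readable `manifest.json` (full
#' configuration, per-sample retained/excluded read counts, package version)
#' next to each other; identical inputs and configuration reproduce
#' byte-identical BED output.
#'
#' @param fasta Path to the reference FASTA, or a `DNAStringSet`.
#' @param alignments Character vector of alignment file paths (TSV/SAM/BAM;
#'   at least two), or an equivalent named list of alignment tibbles.
#' @param out_dir Output directory (created if needed).
#' @param config A [blacklist_config()].
#' @param track Optional precomputed [compute_mappability()] result reused
#'   across runs (mappability is the slow stage).
#' @return The `blacklist_regions` tibble, invisibly.
#' @export
run_pipeline <- function(fasta, alignments, out_dir,
                         config = blacklist_config(), track = NULL) {
  genome <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    read_fasta(fasta)
  } else fasta
  lens <- genome_lengths(genome)

  if (is.character(alignments)) {
    paths <- alignments
    alignments <- lapply(paths, read_alignments, genome_lengths = lens,
                         multimap_mapq_max = config$multimap_mapq_max)
    names(alignments) <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(alignments) < 2) {
    abort("run_pipeline requires >= 2 input samples; single-sample mode is unsupported")
  }

  inform(sprintf("mappability: k = %d over %d chromosome(s)", config$k, length(lens)))
  if (is.null(track)) track <- compute_mappability(genome, config$k)

  # excluded chromosomes are pre-filtered from the analysed grid entirely;
  # they re-enter as whole-chromosome records at call time
  grid_lens <- lens[!names(lens) %in% config$exclude_chroms]
  if (length(grid_lens) == 0) abort("every chromosome is excluded")
  grid <- make_grid(grid_lens, config$bin_size, config$step)
  inform(sprintf("binning: %d bins x %d sample(s)", nrow(grid), length(alignments)))
  signal <- bin_signal(grid, alignments, track, config$exclude_chroms)

  norm <- normalize_signal(signal)
  regions <- call_blacklist(norm, lens, config)
  summ <- attr(regions, "stage_summary")
  inform(sprintf("caller: %d seed bin(s) [depth], %d seed bin(s) [multi/zero-map], %d region(s)",
                 summ$n_flagged_depth, summ$n_flagged_multi, nrow(regions)))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bed_path <- file.path(out_dir, "blacklist.bed")
  write_bed(regions, bed_path)
  manifest <- list(
    config = unclass(config),
    chromosomes = as.list(lens),
    samples = list(
      ids = attr(signal, "sample_ids"),
      retained_reads = as.list(attr(signal, "total_reads")),
      excluded_reads = as.list(attr(signal, "excluded_reads"))
    ),
    stages = list(n_bins = nrow(grid),
                  n_flagged_depth = summ$n_flagged_depth,
                  n_flagged_multi = summ$n_flagged_multi,
                  n_regions = nrow(regions)),
    package_version = as.character(utils::packageVersion("blacklistr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, manifest_path)  # atomic next to outputs
  invisible(regions)
}
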
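#' Lay an overlapping-window grid over the genome
#'
#' Windows of `bin_size` bases start every `step` bases on each chromosome
#' (defaults: 1 kb windows sharing 100 bp with their neighbour, i.e. step
#' 900).  The final window is clipped to the chromosome end; every base is
#' covered by at least one window.
#'
#' @param genome_lengths Named vector of chromosome lengths (or a genome as a
#'   `DNAStringSet` / named character vector).
#' @param bin_size Window width in bases.
#' @param step Distance between consecutive window starts; `0 < step <=
#'   bin_size`.
#' @return A tibble (`chrom`, `start`, `end`, `bin`) sorted by chromosome
#'   order of appearance then start; `bin` is the global row index.
#' @export
#' @examples
#' make_grid(c(chr1 = 2000), bin_size = 1000, step = 900)
make_grid <- function(genome_lengths, bin_size = 1000, step = 900) {
  lens <- genome_lengths(genome_lengths)
  if (!is_scalar_number(bin_size) || bin_size <= 0) abort("`bin_size` must be > 0")
  if (!is_scalar_number(step) || step <= 0 || step > bin_size) {
    abort("`step` must satisfy 0 < step <= bin_size")
  }
  bin_size <- as.integer(bin_size); step <- as.integer(step)
  per <- purrr::imap(as.list(lens), function(len, nm) {
    len <- as.integer(len)
    starts <- seq.int(0L, len - 1L, by = step)
    tibble(chrom = nm, start = starts, end = pmin(starts + bin_size, len))
  })
  grid <- bind_rows(per)
  grid$bin <- seq_len(nrow(grid))
  attr(grid, "bin_size") <- bin_size
  attr(grid, "step") <- step
  attr(grid, "chrom_order") <- names(lens)
  grid
}

# per-chromosome count of read starts in each (possibly overlapping) bin.
# A read is assigned to every bin whose interval contains its start.
count_starts_in_bins <- function(starts, n_bins, bin_size, step, chrom_len) {
  counts <- numeric(n_bins)
  if (length(starts) == 0) return(counts)
  n_over <- ceiling(bin_size / step)
  base_idx <- starts %/% step            # index of rightmost candidate bin
  for (off in seq_len(n_over) - 1L) {
    i <- base_idx - off
    ok <- i >= 0L & i < n_bins & starts < i * step + bin_size
    if (any(ok)) counts <- counts + tabulate(i[ok] + 1L, nbins = n_bins)
  }
  counts
}

#' Score one sample's alignments over a bin grid
#'
#' Computes, per bin, the two input-signal metrics: reads per uniquely
#' mappable base (`depth`) and multimapping reads per million mapped reads
#' (`multi`).  Reads on excluded chromosomes (mitochondrial contigs by
#' default) are discarded before any counting, including the per-million
#' denominator.  A read whose start falls inside several overlapping bins is
#' counted in all of them.  Bins with no uniquely mappable base get
#' `depth = 0` and are flagged `zero_map` for the caller's
#' no-signal-due-to-no-mappability merge rule.
#'
#' @param alignments Tibble of alignment records (`chrom`, `start`,
#'   `read_length`, `is_multimapping`), e.g. from [read_alignments()].
#' @param grid Bin grid from [make_grid()].
#' @param track Mappability track from [compute_mappability()].
#' @param exclude_chroms Chromosomes pre-filtered from analysis.
#' @param include_multimapping Count multimapping reads in the depth
#'   numerator as well (default `TRUE`).
#' @return A tibble aligned with `grid`: `bin`, `reads`, `multi_reads`,
#'   `depth`, `multi`, plus attributes `total_reads` and `excluded_reads`.
#'   Returns `NULL` (with a warning) when no reads remain after exclusion.
#' @export
bin_sample <- function(alignments, grid, track,
                       exclude_chroms = c("chrM", "MT"),
                       include_multimapping = TRUE) {
  stopifnot(is.data.frame(alignments))
  excl <- alignments$chrom %in% exclude_chroms
  aln <- alignments[!excl, , drop = FALSE]
  total <- nrow(aln)
  if (total == 0) {
    warn("sample has no mapped reads after chromosome exclusion; sample rejected")
    return(NULL)
  }
  bin_size <- attr(grid, "bin_size")
  step <- attr(grid, "step")
  mappable <- grid_mappable(grid, track)

  reads <- numeric(nrow(grid))
  multi_reads <- numeric(nrow(grid))
  for (nm in unique(grid$chrom)) {
    rows <- which(grid$chrom == nm)
    sel <- aln$chrom == nm
    if (!any(sel)) next
    s <- aln$start[sel]
    reads[rows] <- count_starts_in_bins(s, length(rows), bin_size, step, NA)
    mm <- s[aln$is_multimapping[sel]]
    multi_reads[rows] <- count_starts_in_bins(mm, length(rows), bin_size, step, NA)
  }
  depth_reads <- if (include_multimapping) reads else reads - multi_reads
  out <- tibble(
    bin = grid$bin,
    reads = reads,
    multi_reads = multi_reads,
    depth = ifelse(mappable > 0, depth_reads / mappable, 0),
    multi = multi_reads * 1e6 / total
  )
  attr(out, "total_reads") <- total
  attr(out, "excluded_reads") <- sum(excl)
  out
}

# per-bin uniquely-mappable position counts, via cumulative sums
grid_mappable <- function(grid, track) {
  mappable <- integer(nrow(grid))
  for (nm in unique(grid$chrom)) {
    rows <- which(grid$chrom == nm)
    if (!nm %in% names(track$tracks)) {
      abort(sprintf("grid chromosome '%s' missing from mappability track", nm))
    }
    cs <- c(0L, cumsum(track$tracks[[nm]]))
    mappable[rows] <- cs[grid$end[rows] + 1L] - cs[grid$start[rows] + 1L]
  }
  mappable
}

#' Build the bins-by-samples signal table for a panel of input samples
#'
#' Runs [bin_sample()] for every sample and assembles a `bin_signal` tibble:
#' the grid columns, per-bin mappable-base counts, a `zero_map` flag, and two
#' matrix columns `depth` and `multi` (bins x samples).  Samples rejected for
#' having no reads are dropped with a warning.
#'
#' @param grid Bin grid from [make_grid()].
#' @param samples Named list of alignment tibbles (names become sample ids).
#' @param track Mappability track from [compute_mappability()].
#' @inheritParams bin_sample
#' @return A `bin_signal` tibble.
#' @export
bin_signal <- function(grid, samples, track,
                       exclude_chroms = c("chrM", "MT"),
                       include_multimapping = TRUE) {
  if (!is.list(samples) || length(samples) == 0) {
    abort("`samples` must be a non-empty named list of alignment tables")
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  cols <- purrr::imap(samples, function(aln, nm) {
    bin_sample(aln, grid, track, exclude_chroms, include_multimapping)
  })
  kept <- !vapply(cols, is.null, logical(1))
  if (!any(kept)) abort("every sample was rejected (no reads)")
  cols <- cols[kept]

  depth <- vapply(cols, `[[`, numeric(nrow(grid)), "depth")
  multi <- vapply(cols, `[[`, numeric(nrow(grid)), "multi")
  raw <- vapply(cols, `[[`, numeric(nrow(grid)), "reads")
  mappable <- grid_mappable(grid, track)

  out <- grid
  out$mappable <- mappable
  out$zero_map <- mappable == 0L
  out$depth <- depth
  out$multi <- multi
  attr(out, "raw_reads") <- raw
  attr(out, "sample_ids") <- names(cols)
  attr(out, "total_reads") <- vapply(cols, attr, numeric(1), "total_reads")
  attr(out, "excluded_reads") <- vapply(cols, attr, numeric(1), "excluded_reads")
  class(out) <- c("bin_signal", class(out))
  out
}

#' @method tidy bin_signal
#' @export
tidy.bin_signal <- function(x, ...) {
  ids <- attr(x, "sample_ids")
  long <- purrr::map(seq_along(ids), function(j) {
    tibble(chrom = x$chrom, start = x$start, end = x$end,
           sample = ids[j], depth = x$depth[, j], multi = x$multi[, j])
  })
  bind_rows(long)
}

#' Write / read a bin-signal table as TSV
#'
#' Wide format for inspection and resume: `chrom`, `start`, `end`,
#' `mappable`, then one `depth.<id>` and one `multi.<id>` column per sample.
#'
#' @param x A `bin_signal` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_signal <- function(x, path) {
  ids <- attr(x, "sample_ids")
  flat <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                     mappable = x$mappable, check.names = FALSE)
  for (j in seq_along(ids)) flat[[paste0("depth.", ids[j])]] <- x$depth[, j]
  for (j in seq_along(ids)) flat[[paste0("multi.", ids[j])]] <- x$multi[, j]
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
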
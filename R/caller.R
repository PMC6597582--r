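#' Default region-calling configuration
#'
#' Collects every tunable parameter of the pipeline with its default: 1 kb
#' windows sharing 100 bp with their neighbour (step 900), flagging at the
#' top 0.1% of signal, extension through neighbours in the top 1%, joining
#' of flagged regions within 20 kb, mitochondrial pre-filtering, and read
#' length 36 for mappability.
#'
#' @param bin_size,step Window geometry in bases.
#' @param flag_quantile Quantile of the nonzero-signal distribution above
#'   which a bin seeds a region (0.999 = top 0.1%).
#' @param extend_quantile Quantile above which neighbouring bins extend a
#'   region (0.99 = top 1%); must not exceed `flag_quantile`.
#' @param join_distance Regions on one chromosome closer than this many bases
#'   are unioned (gap included).
#' @param exclude_chroms Chromosomes pre-filtered from analysis and emitted
#'   whole as blacklist records.
#' @param k Read length for the mappability computation.
#' @param multimap_mapq_max Maximum MAPQ marking a read multimapping.
#' @param collapse Union overlapping High Signal / Low Mappability records
#'   into label-free records.
#' @return A named list of class `blacklist_config`.
#' @export
blacklist_config <- function(bin_size = 1000, step = 900,
                             flag_quantile = 0.999, extend_quantile = 0.99,
                             join_distance = 20000,
                             exclude_chroms = c("chrM", "MT"),
                             k = 36, multimap_mapq_max = 0,
                             collapse = FALSE) {
  if (flag_quantile < extend_quantile) {
    abort("`flag_quantile` must be >= `extend_quantile`")
  }
  if (join_distance < 0) abort("`join_distance` must be >= 0")
  structure(list(bin_size = bin_size, step = step,
                 flag_quantile = flag_quantile, extend_quantile = extend_quantile,
                 join_distance = join_distance, exclude_chroms = exclude_chroms,
                 k = k, multimap_mapq_max = multimap_mapq_max,
                 collapse = collapse),
            class = "blacklist_config")
}

# threshold of the nonzero-signal empirical distribution; NA when no signal.
# Zero bins are excluded so that sparse genomes with a zero-inflated signal
# distribution do not collapse the high quantiles to 0.
nonzero_quantile <- function(values, q) {
  nz <- values[values > 0]
  if (length(nz) == 0) return(NA_real_)
  quantile(nz, q, names = FALSE, type = 7)
}

#' Flag bins in the extreme tail of the signal distribution
#'
#' Returns the bins whose value is at or above the `flag_quantile` empirical
#' quantile of the nonzero-signal distribution (ties at the threshold
#' included).  An all-zero vector flags nothing.
#'
#' @param values Per-bin standard values (finite, `>= 0`).
#' @param flag_quantile Quantile defining the tail (default 0.999).
#' @return Integer vector of flagged bin indices.
#' @export
flag_bins <- function(values, flag_quantile = 0.999) {
  if (anyNA(values) || any(!is.finite(values))) abort("`values` must be finite")
  thr <- nonzero_quantile(values, flag_quantile)
  if (is.na(thr)) return(integer())
  flagged <- which(values >= thr)
  if (length(flagged) == length(values)) {
    warn("flag_bins: all bins share one value; every bin flagged")
  }
  flagged
}

#' Grow flagged bins through extendable neighbours and join nearby regions
#'
#' Each flagged bin seeds a region.  Regions extend across adjacent grid
#' bins whose value is at or above the `extend_quantile` threshold of the
#' nonzero-signal distribution, or which have no signal because no position
#' in them is uniquely mappable, iterating to a fixed point.  Overlapping
#' bins are collapsed to maximal intervals, and intervals on one chromosome
#' separated by at most `join_distance` bases are unioned, gap included.
#'
#' @param flagged Integer indices of seed bins (subset of grid rows).
#' @param values Per-bin standard values used for the extension threshold.
#' @param zero_map Per-bin logical: no uniquely mappable position in the bin.
#' @param grid Bin grid from [make_grid()].
#' @param extend_quantile Extension quantile (default 0.99).
#' @param join_distance Maximum gap joined, bases (default 20000).
#' @return Tibble of merged intervals (`chrom`, `start`, `end`), sorted.
#' @export
grow_and_join <- function(flagged, values, zero_map, grid,
                          extend_quantile = 0.99, join_distance = 20000) {
  n <- nrow(grid)
  if (length(flagged) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (any(flagged < 1 | flagged > n)) abort("`flagged` indices outside the grid")
  thr <- nonzero_quantile(values, extend_quantile)
  extendable <- (if (is.na(thr)) rep(FALSE, n) else values >= thr) | zero_map
  extendable[flagged] <- TRUE

  # extension to a fixed point over grid adjacency = maximal runs of
  # extendable bins (per chromosome) that contain at least one seed
  seed <- logical(n)
  seed[flagged] <- TRUE
  out <- purrr::map(unique(grid$chrom), function(nm) {
    rows <- which(grid$chrom == nm)
    r <- rle(extendable[rows])
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- which(r$values)
    ivs <- purrr::map(keep, function(i) {
      idx <- rows[run_start[i]:run_end[i]]
      if (!any(seed[idx])) return(NULL)
      c(min(grid$start[idx]), max(grid$end[idx]))
    })
    ivs <- do.call(rbind, ivs[!vapply(ivs, is.null, logical(1))])
    if (is.null(ivs)) return(NULL)
    merged <- merge_gaps(ivs[, 1], ivs[, 2], join_distance)
    tibble(chrom = nm, start = merged$start, end = merged$end)
  })
  bind_rows(out)
}

# union sorted intervals whose gap is <= join_distance (overlap counts too)
merge_gaps <- function(starts, ends, join_distance) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me <= join_distance) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Call blacklist regions from normalized panel signal
#'
#' Runs [flag_bins()] and [grow_and_join()] independently on the read-depth
#' standard values (label `"High Signal Region"`) and on the multimapping
#' standard values together with zero-mappability bins (label
#' `"Low Mappability"`).  Every excluded chromosome present in the genome is
#' emitted whole as a High Signal Region (its reads were pre-filtered and
#' the chromosome is considered part of the blacklist).  Where a locus
#' qualifies under both tracks, both labelled records are kept by default;
#' `collapse = TRUE` unions them label-free.
#'
#' @param norm A `normalized_signal` tibble from [normalize_signal()].
#' @param genome_lengths Named chromosome lengths (used for the excluded
#'   whole-chromosome records).
#' @param config A [blacklist_config()] list; individual arguments below
#'   override it.
#' @param flag_quantile,extend_quantile,join_distance,exclude_chroms,collapse
#'   See [blacklist_config()].
#' @return A `blacklist_regions` tibble (`chrom`, `start`, `end`, `name`),
#'   sorted by chromosome order then start.
#' @export
call_blacklist <- function(norm, genome_lengths, config = blacklist_config(),
                           flag_quantile = config$flag_quantile,
                           extend_quantile = config$extend_quantile,
                           join_distance = config$join_distance,
                           exclude_chroms = config$exclude_chroms,
                           collapse = config$collapse) {
  if (!inherits(norm, "normalized_signal")) {
    abort("`norm` must be a `normalized_signal` object")
  }
  if (length(attr(norm, "sample_ids")) < 2) {
    abort("call_blacklist requires >= 2 input samples; single-sample mode is unsupported")
  }
  lens <- genome_lengths(genome_lengths)
  grid <- norm[, c("chrom", "start", "end", "bin")]
  for (a in c("bin_size", "step")) attr(grid, a) <- attr(norm, a)

  high <- grow_and_join(flag_bins(norm$depth_std, flag_quantile),
                        norm$depth_std, norm$zero_map, grid,
                        extend_quantile, join_distance)
  low_seeds <- sort(union(flag_bins(norm$multi_std, flag_quantile),
                          which(norm$zero_map)))
  low <- grow_and_join(low_seeds, norm$multi_std, norm$zero_map, grid,
                       extend_quantile, join_distance)

  regions <- bind_rows(
    if (nrow(high)) mutate(high, name = "High Signal Region"),
    if (nrow(low)) mutate(low, name = "Low Mappability")
  )
  # excluded chromosomes present in the genome are blacklisted whole
  mito <- intersect(exclude_chroms, names(lens))
  if (length(mito)) {
    regions <- bind_rows(regions,
      tibble(chrom = mito, start = 0L, end = as.integer(lens[mito]),
             name = "High Signal Region"))
  }
  if (is.null(regions) || nrow(regions) == 0) {
    regions <- tibble(chrom = character(), start = integer(), end = integer(),
                      name = character())
  }
  chrom_order <- attr(norm, "chrom_order") %||% names(lens)
  regions <- sort_intervals(regions, chrom_order)
  if (collapse) {
    regions <- collapse_labels(regions, chrom_order)
  }
  flags <- list(
    n_flagged_depth = length(flag_bins(norm$depth_std, flag_quantile)),
    n_flagged_multi = length(low_seeds)
  )
  structure(regions,
            class = c("blacklist_regions", class(tibble())),
            chrom_order = chrom_order, stage_summary = flags)
}

# label-free union of possibly overlapping labelled records
collapse_labels <- function(regions, chrom_order) {
  out <- purrr::map(unique(regions$chrom), function(nm) {
    r <- regions[regions$chrom == nm, ]
    m <- merge_gaps(r$start, r$end, 0L)
    tibble(chrom = nm, start = m$start, end = m$end, name = "Blacklist")
  })
  sort_intervals(bind_rows(out), chrom_order)
}

#' @method glance blacklist_regions
#' @export
glance.blacklist_regions <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_high_signal = sum(x$name == "High Signal Region"),
    n_low_mappability = sum(x$name == "Low Mappability"),
    bases = sum(covered_bases(x)),
    mean_width = if (nrow(x)) mean(x$end - x$start) else NA_real_
  )
}

# total bases covered per chromosome after collapsing overlaps
covered_bases <- function(regions) {
  if (nrow(regions) == 0) return(0)
  vapply(unique(regions$chrom), function(nm) {
    r <- regions[regions$chrom == nm, ]
    m <- merge_gaps(r$start, r$end, 0L)
    sum(m$end - m$start)
  }, numeric(1))
}

#' Remove peaks that overlap a blacklist
#'
#' Drops every peak overlapping any blacklist region by at least one base and
#' reports how many were removed.
#'
#' @param peaks Tibble of intervals (`chrom`, `start`, `end`, ...).
#' @param blacklist Tibble of blacklist intervals.
#' @return The surviving peaks, in input order, with attribute `removed`.
#' @export
filter_peaks <- function(peaks, blacklist) {
  assert_intervals(peaks, "peaks")
  if (nrow(blacklist) > 0) assert_intervals(blacklist, "blacklist")
  if (nrow(peaks) == 0 || nrow(blacklist) == 0) {
    attr(peaks, "removed") <- 0L
    return(peaks)
  }
  hit <- logical(nrow(peaks))
  for (nm in unique(peaks$chrom)) {
    p <- which(peaks$chrom == nm)
    b <- blacklist[blacklist$chrom == nm, ]
    if (nrow(b) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = peaks$start[p] + 1L, end = peaks$end[p]),
      IRanges::IRanges(start = b$start + 1L, end = b$end),
      minoverlap = 1L)
    hit[p[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  inform(sprintf("filter_peaks: removed %d of %d peak(s)", sum(hit), length(hit)))
  out <- peaks[!hit, , drop = FALSE]
  attr(out, "removed") <- sum(hit)
  out
}
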
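#' Specification of a synthetic input-panel experiment
#'
#' Describes a toy genome and a multi-sample panel of control ("input")
#' sequencing reads with planted artifact mechanisms, so the whole pipeline
#' can be exercised against known ground truth:
#'
#' * **collapsed repeats** — the reference holds one copy of a segment
#'   present in `copies` copies in the sampled genome, so read starts inside
#'   the locus arrive at `copies` times the background rate;
#' * a **NUMT-like locus** — a nuclear insertion of mitochondrial-origin
#'   sequence whose effective copy number (many mitochondrial genomes per
#'   nucleus) inflates read depth the same way, at a higher copy number;
#' * **duplicated segments** — the same sequence placed at two reference
#'   loci; reads sampled from either copy are multimapping and are assigned
#'   to one copy uniformly at random, and the loci are genuinely
#'   non-uniquely-mappable on the reference;
#' * **Poisson background** everywhere else;
#' * optionally a single-sample **CNV** — one locus amplified in one sample
#'   only, a non-artifact confounder that the cross-sample median summary
#'   should ignore.
#'
#' Defaults describe a 1 Mb single-chromosome genome sampled by 20 input
#' samples at 0.05 read starts per base, with five 5 kb collapsed repeats at
#' copy number 50, one 3 kb NUMT-like locus at copy number 100, and one
#' duplicated 4 kb segment pair.
#'
#' @param genome_length Reference length in bases.
#' @param n_samples Number of input samples in the panel.
#' @param background_depth Mean read starts per base per sample (Poisson).
#' @param collapsed_repeats List of `c(length, copies)` pairs.
#' @param numt `c(length, copies)` for the NUMT-like locus, or `NULL`.
#' @param duplicated_segments Vector of segment lengths; each is planted at
#'   two reference loci.
#' @param cnv `NULL`, or `list(length =, fold =, sample =)`: one locus
#'   amplified `fold`-fold in sample number `sample` only.
#' @param read_length Read length in bases.
#' @param chrom_name Name of the single chromosome.
#' @param min_gap Minimum distance between planted loci and from chromosome
#'   ends; keeps distinct artifacts farther apart than the caller's default
#'   20 kb join distance so they are separable events.
#' @param seed Master seed; per-sample streams are derived from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 1e6,
                           n_samples = 20,
                           background_depth = 0.05,
                           collapsed_repeats = rep(list(c(5000, 50)), 5),
                           numt = c(3000, 100),
                           duplicated_segments = 4000,
                           cnv = NULL,
                           read_length = 36,
                           chrom_name = "chr1",
                           min_gap = 30000,
                           seed = 1) {
  spec <- list(genome_length = as.integer(genome_length),
               n_samples = as.integer(n_samples),
               background_depth = background_depth,
               collapsed_repeats = collapsed_repeats,
               numt = numt,
               duplicated_segments = duplicated_segments,
               cnv = cnv, read_length = as.integer(read_length),
               chrom_name = chrom_name, min_gap = as.integer(min_gap),
               seed = as.integer(seed))
  lens <- c(vapply(spec$collapsed_repeats, `[`, numeric(1), 1),
            if (!is.null(spec$numt)) spec$numt[1],
            rep(spec$duplicated_segments, each = 2),
            if (!is.null(spec$cnv)) spec$cnv$length)
  need <- sum(lens) + (length(lens) + 1) * spec$min_gap
  if (need > spec$genome_length) {
    abort(sprintf("planted loci (%d bases incl. gaps) exceed the genome (%d)",
                  need, spec$genome_length))
  }
  if (any(vapply(spec$collapsed_repeats, `[`, numeric(1), 2) < 2)) {
    abort("collapsed-repeat copy numbers must be >= 2")
  }
  structure(spec, class = "synthetic_spec")
}

# non-overlapping left-to-right placement: mandatory min_gap between loci and
# from the ends, with the leftover slack split randomly across the gaps
place_loci <- function(lengths, genome_length, min_gap) {
  n <- length(lengths)
  if (n == 0) return(integer())
  free <- genome_length - sum(lengths) - (n + 1L) * min_gap
  if (free < 0) abort("cannot place planted loci with the requested min_gap")
  cuts <- sort(runif(n))
  slack <- floor(c(cuts, 1) * free) - floor(c(0, cuts) * free)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    starts[i] <- pos + min_gap + slack[i]
    pos <- starts[i] + lengths[i]
  }
  starts
}

#' Generate a synthetic genome, read panel, and ground truth
#'
#' Builds an i.i.d. uniform A/C/G/T reference, plants the artifact loci of
#' the spec, and draws per-sample read tables.  Read starts arrive as
#' Poisson processes: at `background_depth` per base outside planted loci,
#' at `copies * background_depth` inside collapsed repeats and the NUMT
#' locus, and at background rate per copy inside duplicated segments, whose
#' reads are flagged multimapping and assigned to one of the two copies
#' uniformly at random.  All draws derive from `spec$seed` with one
#' substream per sample, so output is reproducible.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_panel`: `genome` (DNAStringSet),
#'   `truth` (tibble `chrom`, `start`, `end`, `mechanism`), `alignments`
#'   (named list of per-sample tibbles in the [read_alignments()] layout),
#'   `cnv_locus` (tibble or `NULL`), and `spec`.
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a `synthetic_spec`")
  set.seed(spec$seed)
  L <- spec$genome_length
  rl <- spec$read_length
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  rep_lens <- vapply(spec$collapsed_repeats, `[`, numeric(1), 1)
  rep_copies <- vapply(spec$collapsed_repeats, `[`, numeric(1), 2)
  dup_lens <- rep(spec$duplicated_segments, each = 2)
  lens <- c(rep_lens,
            if (!is.null(spec$numt)) spec$numt[1],
            dup_lens,
            if (!is.null(spec$cnv)) spec$cnv$length)
  mech <- c(rep("collapsed_repeat", length(rep_lens)),
            if (!is.null(spec$numt)) "numt",
            rep("duplicated", length(dup_lens)),
            if (!is.null(spec$cnv)) "cnv")
  starts <- place_loci(as.integer(lens), L, spec$min_gap)
  loci <- tibble(chrom = spec$chrom_name, start = starts,
                 end = starts + as.integer(lens), mechanism = mech)

  # duplicated pairs share one sequence: overwrite copy 2 with copy 1
  dup_rows <- which(loci$mechanism == "duplicated")
  for (p in seq_len(length(dup_rows) %/% 2)) {
    a <- loci[dup_rows[2 * p - 1], ]; b <- loci[dup_rows[2 * p], ]
    bases[(b$start + 1):b$end] <- bases[(a$start + 1):a$end]
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""),
                                              spec$chrom_name))

  truth <- loci[loci$mechanism != "cnv", ]
  cnv_locus <- if (any(loci$mechanism == "cnv")) loci[loci$mechanism == "cnv", ] else NULL

  rates <- list()  # high-rate loci for unique reads: repeats, numt, (cnv per sample)
  hot <- loci[loci$mechanism %in% c("collapsed_repeat", "numt"), ]
  hot$copies <- c(rep_copies, if (!is.null(spec$numt)) spec$numt[2])

  max_start <- L - rl  # read must fit on the chromosome
  draw_uniform_starts <- function(n, lo, hi) {
    if (n == 0) return(integer())
    lo + floor(runif(n) * (min(hi, max_start) - lo + 1L))
  }

  alignments <- vector("list", spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    set.seed((spec$seed %% 100000L) * 20011L + s)  # per-sample substream
    # background over the whole chromosome at base rate, then excess on
    # planted high-copy loci (total in-locus rate = copies * background)
    n_bg <- rpois(1, spec$background_depth * (max_start + 1))
    st_bg <- floor(runif(n_bg) * (max_start + 1))
    st_hot <- purrr::map(seq_len(nrow(hot)), function(i) {
      extra <- (hot$copies[i] - 1) * spec$background_depth *
        (hot$end[i] - hot$start[i])
      draw_uniform_starts(rpois(1, extra), hot$start[i], hot$end[i] - 1L)
    })
    # single-sample CNV: (fold - 1) x excess in the designated sample only
    st_cnv <- integer()
    if (!is.null(cnv_locus) && s == spec$cnv$sample) {
      extra <- (spec$cnv$fold - 1) * spec$background_depth *
        (cnv_locus$end - cnv_locus$start)
      st_cnv <- draw_uniform_starts(rpois(1, extra), cnv_locus$start,
                                    cnv_locus$end - 1L)
    }
    uni <- c(st_bg, unlist(st_hot), st_cnv)
    # duplicated segments: each copy sampled at background rate; every read
    # multimapping, reported position on a uniformly random copy
    st_dup <- integer()
    for (p in seq_len(length(dup_rows) %/% 2)) {
      a <- loci[dup_rows[2 * p - 1], ]; b <- loci[dup_rows[2 * p], ]
      seg <- a$end - a$start
      n_mm <- rpois(1, 2 * spec$background_depth * seg)
      offs <- floor(runif(n_mm) * seg)
      copy_start <- ifelse(runif(n_mm) < 0.5, a$start, b$start)
      st_dup <- c(st_dup, pmin(copy_start + offs, max_start))
    }
    aln <- tibble(
      chrom = spec$chrom_name,
      start = as.integer(c(uni, st_dup)),
      read_length = rl,
      is_multimapping = rep(c(FALSE, TRUE), c(length(uni), length(st_dup)))
    )
    alignments[[s]] <- aln[order(aln$start), ]
  }
  names(alignments) <- sprintf("input%02d", seq_len(spec$n_samples))

  structure(list(genome = genome, truth = truth, alignments = alignments,
                 cnv_locus = cnv_locus, spec = spec),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d bp genome, %d sample(s), %d truth region(s)\n",
              sum(Biostrings::width(x$genome)), length(x$alignments), nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic panel to disk
#'
#' Writes the reference FASTA, one alignment TSV per sample, and the truth
#' regions as BED (mechanism in the name field).
#'
#' @param panel A `synthetic_panel` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(panel$genome, file.path(dir, "genome.fa"))
  for (nm in names(panel$alignments)) {
    readr::write_tsv(panel$alignments[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     col_names = FALSE, progress = FALSE)
  }
  truth <- panel$truth
  names(truth)[names(truth) == "mechanism"] <- "name"
  write_bed(sort_intervals(truth), file.path(dir, "truth.bed"))
  invisible(dir)
}

#' Compare called regions against ground truth
#'
#' For every truth region reports the best base-level Jaccard index
#' (intersection over union) against any called region; a truth region is
#' *recovered* when its best Jaccard is at least 0.5, and a call is
#' *spurious* when it overlaps no truth region extended by `join_distance`
#' on both sides.
#'
#' @param called Tibble of called intervals (`chrom`, `start`, `end`, ...).
#' @param truth Tibble of truth intervals.
#' @param join_distance Slack around truth regions when scoring spurious
#'   calls (default 20000, the caller's gap-joining distance).
#' @return A list of class `region_comparison`: `per_truth` (truth rows plus
#'   `best_jaccard`, `recovered`, and the label of the best-matching call),
#'   `n_truth`, `n_recovered`, `n_called`, `n_spurious`, `spurious`.
#' @export
compare_region_sets <- function(called, truth, join_distance = 20000) {
  if (nrow(truth)) assert_intervals(truth, "truth")
  if (nrow(called)) assert_intervals(called, "called")
  jac <- function(a_start, a_end, b_start, b_end) {
    inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
    inter / ((a_end - a_start) + (b_end - b_start) - inter)
  }
  per_truth <- truth
  per_truth$best_jaccard <- 0
  per_truth$best_call <- NA_character_
  for (i in seq_len(nrow(truth))) {
    same <- called[called$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) next
    j <- jac(same$start, same$end, truth$start[i], truth$end[i])
    per_truth$best_jaccard[i] <- max(j)
    if (max(j) > 0 && "name" %in% names(same)) {
      per_truth$best_call[i] <- same$name[which.max(j)]
    }
  }
  per_truth$recovered <- per_truth$best_jaccard >= 0.5

  spurious <- logical(nrow(called))
  for (i in seq_len(nrow(called))) {
    same <- truth[truth$chrom == called$chrom[i], , drop = FALSE]
    ov <- nrow(same) > 0 &&
      any(pmin(called$end[i], same$end + join_distance) >
          pmax(called$start[i], same$start - join_distance))
    spurious[i] <- !ov
  }
  structure(list(per_truth = as_tibble(per_truth),
                 n_truth = nrow(truth),
                 n_recovered = sum(per_truth$recovered),
                 n_called = nrow(called),
                 n_spurious = sum(spurious),
                 spurious = as_tibble(called[spurious, , drop = FALSE])),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("<region_comparison> %d/%d truth region(s) recovered, %d spurious call(s)\n",
              x$n_recovered, x$n_truth, x$n_spurious))
  print(x$per_truth)
  invisible(x)
}

#' @method tidy region_comparison
#' @export
tidy.region_comparison <- function(x, ...) x$per_truth

#' @method glance region_comparison
#' @export
glance.region_comparison <- function(x, ...) {
  tibble(n_truth = x$n_truth, n_recovered = x$n_recovered,
         n_called = x$n_called, n_spurious = x$n_spurious,
         min_best_jaccard = if (x$n_truth) min(x$per_truth$best_jaccard) else NA_real_)
}
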
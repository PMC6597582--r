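#' Compute unique-mappability of every genome position at read length k
#'
#' A position is uniquely mappable when a read of length `k` starting there
#' matches exactly one genomic locus, considering both strands: the k-mer
#' must occur once in total, counting forward occurrences of the k-mer plus
#' forward occurrences of its reverse complement (a palindromic k-mer with a
#' single forward occurrence counts as unique — the read has one locus even
#' though its strand is ambiguous).  Any window containing an `N` is
#' unmappable.  Implemented by exact hashing of canonical k-mers (the
#' lexicographic minimum of a k-mer and its reverse complement), which is
#' exact and memory-linear for desk-scale genomes.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector of
#'   uppercase chromosome sequences.
#' @param k Read length in bases (default 36, a common short-read length).
#' @return A `mappability_track`: list with elements `k` and `tracks`, the
#'   latter one logical vector per chromosome of length equal to the
#'   chromosome (positions past `length - k` are padded `FALSE` so vectors
#'   align with chromosome coordinates).
#' @export
#' @examples
#' compute_mappability(c(chr1 = "ACGGT"), k = 3)
compute_mappability <- function(genome, k = 36) {
  seqs <- genome_as_character(genome)
  if (!is_scalar_number(k) || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer read length")
  }
  k <- as.integer(k)
  lens <- nchar(seqs)
  if (all(lens < k)) abort(sprintf("k = %d exceeds the length of every chromosome", k))

  # pool k-mers across chromosomes so cross-chromosome repeats are seen
  per_chrom <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  kmers <- unlist(per_chrom, use.names = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  first <- match(canon, canon)
  counts <- tabulate(first, nbins = length(canon))
  unique_hit <- counts[first] == 1L & !grepl("N", kmers, fixed = TRUE)

  tracks <- vector("list", length(seqs))
  names(tracks) <- names(seqs)
  off <- 0L
  for (i in seq_along(seqs)) {
    n <- max(lens[i] - k + 1L, 0L)
    v <- logical(lens[i])                       # pads the trailing k-1 FALSE
    if (n > 0L) v[seq_len(n)] <- unique_hit[off + seq_len(n)]
    tracks[[i]] <- v
    off <- off + n
  }
  structure(list(k = k, tracks = tracks), class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat(sprintf("<mappability_track> k = %d, %d chromosome(s)\n", x$k, length(x$tracks)))
  for (nm in names(x$tracks)) {
    v <- x$tracks[[nm]]
    cat(sprintf("  %s: %d bp, %.1f%% uniquely mappable\n",
                nm, length(v), 100 * mean(v)))
  }
  invisible(x)
}

#' Count uniquely mappable positions inside an interval
#'
#' @param track A `mappability_track` from [compute_mappability()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return Number of uniquely mappable read start positions in
#'   `[start, end)`.
#' @export
mappable_bases_in <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$tracks)) {
    abort(sprintf("unknown chromosome '%s' in mappability track", chrom))
  }
  v <- track$tracks[[chrom]]
  if (start < 0 || end > length(v) || start >= end) {
    abort("interval out of chromosome bounds")
  }
  sum(v[(start + 1L):end])
}

#' Export a mappability track as maximal runs of uniquely mappable positions
#'
#' @param track A `mappability_track`.
#' @return A tibble (`chrom`, `start`, `end`) of maximal runs of `TRUE`, BED
#'   coordinates.
#' @export
mappability_runs <- function(track) {
  out <- purrr::imap(track$tracks, function(v, nm) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    tibble(chrom = nm, start = starts[keep], end = ends[keep])
  })
  bind_rows(out)
}

#' @method tidy mappability_track
#' @export
tidy.mappability_track <- function(x, ...) mappability_runs(x)
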
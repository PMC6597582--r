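#' Read a genome FASTA file
#'
#' Loads a (multi-line) FASTA file into a `DNAStringSet`.  Sequences are
#' uppercased on load; the header token before the first whitespace is used as
#' the chromosome name.  Chromosome order is the order of appearance in the
#' file and is preserved by every downstream step.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one entry per chromosome.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt", "AC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(seqs) == 0) abort(sprintf("FASTA file '%s' contains no sequences", path))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    abort(sprintf("duplicate chromosome name in FASTA: '%s'", dup))
  }
  # normalise case; masked/soft-masked input is common
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Read a two-column chromosome-sizes table
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return A named integer vector of chromosome lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "ci", progress = FALSE)
  if (nrow(tab) == 0) abort(sprintf("empty chromosome-sizes file: %s", path))
  if (anyDuplicated(tab$chrom)) abort("duplicate chromosome name in sizes file")
  setNames(as.integer(tab$length), tab$chrom)
}

#' Read alignment records
#'
#' Reads mapped alignment records from SAM/BAM or from a 4-column TSV
#' (`chrom`, `start`, `read_length`, `is_multimapping`).  Only the leftmost
#' position, read length and a multimapping indicator are retained; unmapped
#' records are skipped.  For SAM/BAM a read is considered multimapping when
#' its mapping quality is `<= multimap_mapq_max` (aligner-reported MAPQ 0 is
#' the conventional multi-hit signal).
#'
#' @param path Path to a `.sam`, `.bam`, `.tsv` or `.txt` file.
#' @param format One of `"auto"`, `"sam"`, `"bam"`, `"tsv"`.  `"auto"` picks
#'   by file extension.
#' @param genome_lengths Optional named vector of chromosome lengths.  When
#'   given, records on chromosomes absent from it are skipped (the skipped
#'   count is reported) and out-of-bounds records raise an error.
#' @param multimap_mapq_max Maximum MAPQ that marks a read multimapping
#'   (SAM/BAM only; default 0).
#' @return A tibble with columns `chrom`, `start` (0-based leftmost),
#'   `read_length`, `is_multimapping`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "tsv"),
                            genome_lengths = NULL, multimap_mapq_max = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", tsv = "tsv", txt = "tsv",
                     abort(sprintf("cannot infer alignment format from extension '.%s'", ext)))
  }
  aln <- switch(format,
    tsv = read_alignments_tsv(path),
    sam = ,
    bam = read_alignments_bam(path, format, multimap_mapq_max)
  )
  if (!is.null(genome_lengths)) {
    known <- aln$chrom %in% names(genome_lengths)
    if (any(!known)) {
      inform(sprintf("read_alignments: skipped %d record(s) on chromosomes absent from the genome",
                     sum(!known)))
      aln <- aln[known, , drop = FALSE]
    }
    ends <- aln$start + aln$read_length
    over <- ends > unname(genome_lengths[aln$chrom]) | aln$start < 0
    if (any(over)) {
      abort(sprintf("%d alignment record(s) extend beyond the chromosome end", sum(over)))
    }
  }
  as_tibble(aln)
}

read_alignments_tsv <- function(path) {
  tab <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "read_length", "is_multimapping"),
                         col_types = "ciil", comment = "#", progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("unparseable alignment TSV '%s' at line %d: %s",
                  path, probs$row[1], probs$expected[1]))
  }
  if (any(is.na(tab$start)) || any(is.na(tab$chrom))) {
    abort(sprintf("missing values in alignment TSV '%s'", path))
  }
  tab$is_multimapping <- as.logical(tab$is_multimapping)
  tab
}

read_alignments_bam <- function(path, format, multimap_mapq_max) {
  bam <- path
  if (format == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE, indexDestination = FALSE))
  }
  what <- c("rname", "pos", "qwidth", "mapq")
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what, flag = flags))[[1]]
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 255L
  tibble(
    chrom = as.character(res$rname),
    start = as.integer(res$pos) - 1L,          # SAM POS is 1-based
    read_length = as.integer(res$qwidth),
    is_multimapping = mapq <= multimap_mapq_max
  )
}

#' Write intervals to a BED file
#'
#' Writes 0-based half-open intervals as headerless, tab-separated BED.  A
#' `name` column, if present, is written as the 4th field (BED4).  Input must
#' be sorted by (chromosome, start) and must not contain degenerate intervals.
#'
#' @param regions A data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  assert_intervals(regions, "regions")
  if (nrow(regions) > 1) {
    ord <- order(match(regions$chrom, unique(regions$chrom)), regions$start)
    if (!identical(ord, seq_len(nrow(regions)))) {
      abort("`regions` must be sorted by (chromosome, start) before writing BED")
    }
  }
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  out <- as.data.frame(regions[, cols, drop = FALSE])
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path Path to a headerless BED3/BED4 file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  names4 <- c("chrom", "start", "end", "name")
  tab <- readr::read_tsv(path, col_names = names4[seq_len(min(nfield, 4))],
                         col_types = substr("ciic", 1, min(nfield, 4)),
                         progress = FALSE)
  assert_intervals(tab, "BED file")
  as_tibble(tab)
}
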
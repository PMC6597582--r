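# shared validation helpers

chrom_levels <- function(x) {
  if (is.factor(x)) levels(x) else unique(as.character(x))
}

# order an interval tibble by (chromosome order, start); chrom_order gives the
# canonical chromosome ordering (order of appearance in the genome file)
sort_intervals <- function(x, chrom_order = NULL) {
  chrom_order <- chrom_order %||% unique(x$chrom)
  extra <- setdiff(unique(x$chrom), chrom_order)
  x$.c <- match(x$chrom, c(chrom_order, extra))
  out <- dplyr::arrange(x, .data$.c, .data$start, .data$end)
  out$.c <- NULL
  out
}

assert_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end", arg))
  }
  if (nrow(x) > 0 && any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(sprintf("`%s` row %d has start >= end (%d >= %d)",
                  arg, bad, x$start[bad], x$end[bad]))
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# lengths of a genome given as DNAStringSet or named character vector
genome_lengths <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    setNames(nchar(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    abort("`genome` must be a named DNAStringSet, named character vector, or named lengths")
  }
}

genome_as_character <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    toupper(genome)
  } else {
    abort("`genome` must be a named DNAStringSet or named character vector")
  }
}
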
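# Independent brute-force oracles used to check the fast implementations.
# These deliberately take a different route than the package code.

random_genome <- function(len, seed, chrom = "chr1", n_frac = 0) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  bases <- sample(alphabet, len, replace = TRUE)
  if (n_frac > 0) {
    bases[sample(len, max(1, round(n_frac * len)))] <- "N"
  }
  setNames(paste(bases, collapse = ""), chrom)
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# position-by-position uniqueness by counting forward occurrences of the
# k-mer and of its reverse complement over the whole genome (palindromes:
# forward occurrences only)
naive_mappability_oracle <- function(seqs, k) {
  fwd <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) character() else substring(s, 1:n, k:(n + k - 1))
  }), use.names = FALSE)
  lapply(seqs, function(s) {
    L <- nchar(s)
    n <- L - k + 1
    v <- logical(L)
    for (p in seq_len(max(n, 0))) {
      km <- substr(s, p, p + k - 1)
      if (grepl("N", km, fixed = TRUE)) next
      rc <- revcomp_chr(km)
      cnt <- if (km == rc) sum(fwd == km) else sum(fwd == km) + sum(fwd == rc)
      v[p] <- cnt == 1
    }
    v
  })
}

# O(reads x bins) interval-stabbing: count read starts falling in each bin
stab_count_oracle <- function(starts, grid_chrom) {
  vapply(seq_len(nrow(grid_chrom)), function(i) {
    sum(starts >= grid_chrom$start[i] & starts < grid_chrom$end[i])
  }, numeric(1))
}

# brute-force region growing: BFS from each seed over adjacent extendable
# bins, then pairwise gap-union to closure
bfs_grow_oracle <- function(flagged, extendable, grid, join_distance) {
  extendable[flagged] <- TRUE
  regions <- list()
  for (seed in flagged) {
    members <- seed
    frontier <- seed
    while (length(frontier) > 0) {
      nxt <- integer()
      for (b in frontier) {
        for (nb in c(b - 1, b + 1)) {
          if (nb < 1 || nb > nrow(grid)) next
          if (grid$chrom[nb] != grid$chrom[b]) next
          if (!extendable[nb] || nb %in% members) next
          nxt <- c(nxt, nb)
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
    }
    regions[[length(regions) + 1]] <-
      list(chrom = grid$chrom[seed],
           start = min(grid$start[members]), end = max(grid$end[members]))
  }
  if (length(regions) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  df <- unique(dplyr::bind_rows(lapply(regions, tibble::as_tibble)))
  # pairwise union to closure: merge any two regions on one chromosome whose
  # gap (or overlap) is within join_distance
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(nrow(df))) {
        if (i >= j || df$chrom[i] != df$chrom[j]) next
        gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
        if (gap <= join_distance) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, ]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  dplyr::arrange(df, chrom, start)
}

# sort-and-slice flagging: the top ceiling(n * (1 - q)) nonzero values, with
# every value tied at the cutoff included
sort_slice_flag_oracle <- function(values, q) {
  nz <- values[values > 0]
  if (length(nz) == 0) return(integer())
  # round before ceiling: (1 - q) is inexact in binary floating point
  m <- ceiling(round(length(nz) * (1 - q), 6))
  cutoff <- sort(nz, decreasing = TRUE)[m]
  which(values >= cutoff)
}

# base-by-base Jaccard between one interval and an interval set, on a toy
# coordinate span
per_base_jaccard_oracle <- function(a, b, span) {
  va <- logical(span); vb <- logical(span)
  va[(a$start + 1):a$end] <- TRUE
  for (i in seq_len(nrow(b))) vb[(b$start[i] + 1):b$end[i]] <- TRUE
  sum(va & vb) / sum(va | vb)
}

# small ready-made grid + track fixtures
all_true_track <- function(lens, k = 36) {
  structure(list(k = k, tracks = lapply(as.list(lens), function(L) rep(TRUE, L))),
            class = "mappability_track")
}

manual_track <- function(tracks, k = 36) {
  structure(list(k = k, tracks = tracks), class = "mappability_track")
}
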
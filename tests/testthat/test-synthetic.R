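background_only_spec <- function(len = 1e5, n = 1, bg = 0.05, seed = 3) {
  synthetic_spec(genome_length = len, n_samples = n, background_depth = bg,
                 collapsed_repeats = list(), numt = NULL,
                 duplicated_segments = numeric(), min_gap = 1000, seed = seed)
}

test_that("a background-only panel is Poisson at the requested rate", {
  spec <- background_only_spec()
  panel <- simulate_panel(spec)
  expect_equal(nrow(panel$truth), 0)
  n_reads <- nrow(panel$alignments[[1]])
  lambda <- 0.05 * (1e5 - 36 + 1)
  expect_lt(abs(n_reads - lambda), 4 * sqrt(lambda))
  expect_false(any(panel$alignments[[1]]$is_multimapping))
  # reads lie within the chromosome
  expect_true(all(panel$alignments[[1]]$start + 36 <= 1e5))
})

test_that("read counts over disjoint windows have Poisson dispersion", {
  panel <- simulate_panel(background_only_spec(len = 3e5, seed = 9))
  starts <- panel$alignments[[1]]$start
  expect_gt(length(starts), 1e4)
  counts <- table(cut(starts, breaks = seq(0, 3e5, by = 1000)))
  disp <- var(as.numeric(counts)) / mean(as.numeric(counts))
  expect_gt(disp, 0.8); expect_lt(disp, 1.2)
})

test_that("collapsed repeats pile reads at copy-number times background", {
  spec <- synthetic_spec(genome_length = 2e5, n_samples = 1,
                         collapsed_repeats = list(c(5000, 50)), numt = NULL,
                         duplicated_segments = numeric(), min_gap = 10000, seed = 2)
  panel <- simulate_panel(spec)
  locus <- panel$truth[panel$truth$mechanism == "collapsed_repeat", ]
  aln <- panel$alignments[[1]]
  inside <- sum(aln$start >= locus$start & aln$start < locus$end)
  lambda <- 50 * 0.05 * 5000
  expect_lt(abs(inside - lambda), 4 * sqrt(lambda))
})

test_that("duplicated segments are the only multimapping source and share sequence", {
  spec <- synthetic_spec(genome_length = 2e5, n_samples = 2,
                         collapsed_repeats = list(c(5000, 50)), numt = c(3000, 100),
                         duplicated_segments = 4000, min_gap = 15000, seed = 4)
  panel <- simulate_panel(spec)
  dup <- panel$truth[panel$truth$mechanism == "duplicated", ]
  expect_equal(nrow(dup), 2)
  g <- as.character(panel$genome[[1]])
  expect_identical(substr(g, dup$start[1] + 1, dup$end[1]),
                   substr(g, dup$start[2] + 1, dup$end[2]))
  for (aln in panel$alignments) {
    mm <- aln[aln$is_multimapping, ]
    in_dup <- (mm$start >= dup$start[1] & mm$start < dup$end[1]) |
      (mm$start >= dup$start[2] & mm$start < dup$end[2])
    expect_true(all(in_dup))
  }
  # the planted duplication really is non-uniquely-mappable on the reference
  track <- compute_mappability(panel$genome, 36)
  mid <- dup$start[1] + 2000
  expect_false(any(track$tracks$chr1[(mid - 100):(mid + 100)]))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(genome_length = 1e5, n_samples = 3,
                         collapsed_repeats = list(c(5000, 10)), numt = NULL,
                         duplicated_segments = numeric(), min_gap = 10000, seed = 11)
  p1 <- simulate_panel(spec)
  p2 <- simulate_panel(spec)
  expect_identical(as.character(p1$genome), as.character(p2$genome))
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$alignments, p2$alignments)
})

test_that("infeasible placements are rejected", {
  expect_error(
    synthetic_spec(genome_length = 3e4,
                   collapsed_repeats = rep(list(c(5000, 50)), 5)),
    "exceed"
  )
  expect_error(
    synthetic_spec(collapsed_repeats = list(c(5000, 1))),
    "copy numbers"
  )
})

test_that("write_panel emits formats the readers round-trip", {
  spec <- synthetic_spec(genome_length = 5e4, n_samples = 2,
                         collapsed_repeats = list(c(3000, 5)), numt = NULL,
                         duplicated_segments = numeric(), min_gap = 5000, seed = 6)
  panel <- simulate_panel(spec)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  g <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(panel$genome))
  a1 <- read_alignments(file.path(dir, "input01.tsv"))
  expect_equal(as.data.frame(a1), as.data.frame(panel$alignments[[1]]))
  truth <- read_bed(file.path(dir, "truth.bed"))
  expect_equal(truth$start, panel$truth$start)
  expect_identical(truth$name, panel$truth$mechanism)
})

test_that("compare_region_sets scores identity, partial overlap, and symmetry", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 5000L), end = c(1000L, 6000L))
  self <- compare_region_sets(a, a)
  expect_true(all(self$per_truth$best_jaccard == 1))
  expect_equal(self$n_spurious, 0)

  called <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  truth <- tibble::tibble(chrom = "chr1", start = 500L, end = 1500L)
  cmp <- compare_region_sets(called, truth)
  expect_equal(cmp$per_truth$best_jaccard, 1 / 3)
  expect_false(cmp$per_truth$recovered)

  # Jaccard values are symmetric under swapping called and truth
  set.seed(15)
  mk <- function(n) {
    s <- sort(sample(0:9000, n))
    tibble::tibble(chrom = "chr1", start = s, end = s + sample(100:800, n, TRUE))
  }
  x <- mk(5); y <- mk(4)
  # pairwise: Jaccard(A, B) == Jaccard(B, A), and best-vs-set matches the
  # per-base counting oracle
  for (i in seq_len(nrow(y))) {
    oracle_best <- max(vapply(seq_len(nrow(x)), function(j) {
      per_base_jaccard_oracle(y[i, ], x[j, , drop = FALSE], 12000)
    }, numeric(1)))
    expect_equal(compare_region_sets(x, y[i, ])$per_truth$best_jaccard, oracle_best)
  }
  for (j in seq_len(nrow(x))) {
    oracle_best <- max(vapply(seq_len(nrow(y)), function(i) {
      per_base_jaccard_oracle(x[j, ], y[i, , drop = FALSE], 12000)
    }, numeric(1)))
    expect_equal(compare_region_sets(y, x[j, ])$per_truth$best_jaccard, oracle_best)
  }
})

test_that("spurious calls are those outside truth extended by the join distance", {
  truth <- tibble::tibble(chrom = "chr1", start = 50000L, end = 55000L)
  called <- tibble::tibble(chrom = "chr1",
                           start = c(52000L, 68000L, 90000L),
                           end = c(54000L, 69000L, 91000L))
  cmp <- compare_region_sets(called, truth, join_distance = 20000)
  # 68-69 kb is within 20 kb of the truth end; 90-91 kb is not
  expect_equal(cmp$n_spurious, 1)
  expect_equal(cmp$spurious$start, 90000L)
  gl <- glance(cmp)
  expect_equal(gl$n_called, 3)
  expect_equal(gl$n_truth, 1)
})
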
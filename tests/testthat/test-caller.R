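test_that("flag_bins picks the extreme tail of the nonzero distribution", {
  set.seed(1)
  v <- sample(seq(0.001, 1, length.out = 1000))   # 1000 distinct values
  expect_identical(flag_bins(v, 0.999), which.max(v))

  expect_identical(flag_bins(rep(0, 50)), integer())
  expect_warning(f <- flag_bins(rep(3, 20), 0.999), "every bin")
  expect_identical(f, 1:20)                        # tie closure, degenerate

  expect_error(flag_bins(c(1, NA)), "finite")
})

test_that("flag_bins equals the sort-and-slice oracle on random values", {
  for (seed in 1:4) {
    set.seed(seed)
    v <- runif(10000)
    v[sample(10000, 500)] <- 0                     # zero bins excluded from the tail
    for (q in c(0.999, 0.99, 0.95)) {
      expect_identical(flag_bins(v, q), sort_slice_flag_oracle(v, q),
                       info = sprintf("seed %d q %s", seed, q))
    }
  }
})

test_that("grow_and_join honours the worked gap-joining examples", {
  grid <- make_grid(c(chr1 = 40000), bin_size = 1000, step = 1000)
  vals <- rep(0, nrow(grid))
  zero <- rep(FALSE, nrow(grid))
  # seeds covering [0,1000) and [15000,16000): 14 kb gap <= 20 kb -> one region
  seeds <- c(1L, 16L)
  vals[seeds] <- 100
  out <- grow_and_join(seeds, vals, zero, grid, 0.99, 20000)
  expect_identical(out, tibble::tibble(chrom = "chr1", start = 0L, end = 16000L))

  # seeds at [0,1000) and [30000,31000): 29 kb gap -> two regions
  grid2 <- make_grid(c(chr1 = 31000), bin_size = 1000, step = 1000)
  vals2 <- rep(0, nrow(grid2)); vals2[c(1, 31)] <- 100
  out2 <- grow_and_join(c(1L, 31L), vals2, rep(FALSE, nrow(grid2)), grid2, 0.99, 20000)
  expect_equal(nrow(out2), 2)
  expect_identical(out2$start, c(0L, 30000L))
})

test_that("zero-mappability bins extend regions even without signal", {
  grid <- make_grid(c(chr1 = 10000), bin_size = 1000, step = 1000)
  vals <- c(100, rep(0, 9))
  zero <- c(FALSE, TRUE, TRUE, rep(FALSE, 7))
  out <- grow_and_join(1L, vals, zero, grid, 0.99, 0)
  expect_identical(out$end, 3000L)                 # grew through the unmappable run
})

test_that("grow_and_join equals the BFS + gap-union oracle on random configurations", {
  grid <- make_grid(c(chr1 = 300000, chr2 = 200000), bin_size = 1000, step = 1000)
  n <- nrow(grid)
  for (seed in 1:25) {
    set.seed(seed)
    vals <- rexp(n)
    vals[sample(n, n %/% 3)] <- 0
    zero <- runif(n) < 0.05
    flagged <- flag_bins(vals, 0.98)
    jd <- sample(c(0, 5000, 20000), 1)
    got <- grow_and_join(flagged, vals, zero, grid, 0.9, jd)
    thr <- quantile(vals[vals > 0], 0.9, names = FALSE)
    want <- bfs_grow_oracle(flagged, vals >= thr | zero, grid, jd)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 info = sprintf("seed %d jd %d", seed, jd))
  }
})

test_that("region growth is monotone in flag quantile and join distance", {
  grid <- make_grid(c(chr1 = 500000), bin_size = 1000, step = 1000)
  set.seed(33)
  vals <- rexp(nrow(grid))^3
  zero <- runif(nrow(grid)) < 0.02
  covered <- function(q, jd) {
    r <- grow_and_join(flag_bins(vals, q), vals, zero, grid, min(q, 0.99), jd)
    sum(r$end - r$start)
  }
  expect_true(covered(0.995, 20000) >= covered(0.999, 20000))
  expect_true(covered(0.99, 20000) >= covered(0.995, 20000))
  expect_true(covered(0.999, 30000) >= covered(0.999, 10000))
  expect_true(covered(0.999, 10000) >= covered(0.999, 0))
})

make_norm_fixture <- function(lens = c(chr1 = 50000), n_samples = 4,
                              hot = NULL, seed = 5, with_m = FALSE) {
  set.seed(seed)
  grid <- make_grid(lens, bin_size = 1000, step = 900)
  track <- all_true_track(lens)
  mk <- function() {
    starts <- unlist(lapply(names(lens), function(nm) {
      s <- sample(0:(lens[[nm]] - 100), round(lens[[nm]] * 0.05), TRUE)
      if (!is.null(hot) && nm == "chr1") {
        s <- c(s, sample(hot[1]:hot[2], 30 * n_samples, TRUE))
      }
      s
    }))
    chroms <- rep(names(lens), times = vapply(names(lens), function(nm) {
      round(lens[[nm]] * 0.05) + if (!is.null(hot) && nm == "chr1") 30 * n_samples else 0
    }, numeric(1)))
    tibble::tibble(chrom = chroms, start = as.integer(starts),
                   read_length = 36L, is_multimapping = FALSE)
  }
  samples <- setNames(replicate(n_samples, mk(), simplify = FALSE),
                      paste0("s", seq_len(n_samples)))
  sig <- bin_signal(grid, samples, track)
  normalize_signal(sig)
}

test_that("call_blacklist refuses single-sample panels", {
  norm <- make_norm_fixture(n_samples = 2)
  attr(norm, "sample_ids") <- "s1"
  expect_error(call_blacklist(norm, c(chr1 = 50000)), "single-sample")
})

test_that("excluded chromosomes are emitted whole as High Signal Regions", {
  norm <- make_norm_fixture()
  lens <- c(chr1 = 50000, chrM = 16569)
  bl <- call_blacklist(norm, lens, exclude_chroms = "chrM")
  m <- bl[bl$chrom == "chrM", ]
  expect_equal(nrow(m), 1)
  expect_identical(m$start, 0L)
  expect_identical(m$end, 16569L)
  expect_identical(m$name, "High Signal Region")
})

test_that("a hot locus is called under High Signal and collapse unions labels", {
  norm <- make_norm_fixture(hot = c(20000, 24000), seed = 8)
  bl <- call_blacklist(norm, c(chr1 = 50000))
  high <- bl[bl$name == "High Signal Region", ]
  expect_true(nrow(high) >= 1)
  expect_true(any(high$start < 24000 & high$end > 20000))

  blc <- call_blacklist(norm, c(chr1 = 50000), collapse = TRUE)
  expect_true(all(blc$name == "Blacklist"))
  # collapsed set is non-overlapping
  if (nrow(blc) > 1) expect_true(all(blc$start[-1] >= utils::head(blc$end, -1)))
})

test_that("calling is deterministic for identical inputs", {
  n1 <- make_norm_fixture(hot = c(10000, 13000), seed = 17)
  n2 <- make_norm_fixture(hot = c(10000, 13000), seed = 17)
  b1 <- call_blacklist(n1, c(chr1 = 50000))
  b2 <- call_blacklist(n2, c(chr1 = 50000))
  expect_identical(as.data.frame(b1), as.data.frame(b2))
})

test_that("filter_peaks drops exactly the >= 1 bp overlappers, keeping input order", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(0L, 200L), end = c(100L, 300L))
  bl <- tibble::tibble(chrom = "chr1", start = 250L, end = 400L,
                       name = "High Signal Region")
  kept <- suppressMessages(filter_peaks(peaks, bl))
  expect_identical(kept$start, 0L)
  expect_equal(attr(kept, "removed"), 1)

  none <- suppressMessages(filter_peaks(peaks, bl[0, ]))
  expect_identical(none$start, peaks$start)
  expect_equal(attr(none, "removed"), 0)

  # single-base touch counts; adjacency does not
  p2 <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(100L, 200L))
  b2 <- tibble::tibble(chrom = "chr1", start = 99L, end = 100L)
  k2 <- suppressMessages(filter_peaks(p2, b2))
  expect_identical(k2$start, 100L)
})

test_that("filter_peaks agrees with the all-pairs overlap oracle", {
  set.seed(23)
  peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                          start = sample(0:99000, 1000, TRUE))
  peaks$end <- peaks$start + sample(100:500, 1000, TRUE)
  bl <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                       start = sample(0:99000, 50, TRUE))
  bl$end <- bl$start + sample(500:3000, 50, TRUE)
  bl <- dplyr::arrange(bl, chrom, start)
  kept <- suppressMessages(filter_peaks(peaks, bl))
  overlap <- vapply(seq_len(nrow(peaks)), function(i) {
    any(bl$chrom == peaks$chrom[i] &
          pmax(bl$start, peaks$start[i]) < pmin(bl$end, peaks$end[i]))
  }, logical(1))
  expect_equal(tibble::as_tibble(kept), peaks[!overlap, ], ignore_attr = TRUE)
  expect_equal(attr(kept, "removed"), sum(overlap))
})
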
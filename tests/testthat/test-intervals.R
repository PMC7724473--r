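test_that("read_bed maps fields, sorts, and round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  ps <- read_bed(f)
  expect_equal(as.data.frame(ps),
               data.frame(chrom = "chr1", start = 100L, end = 200L))

  writeLines(character(), f)
  expect_length(read_bed(f), 0)

  # 50 shuffled lines give the same set as the pre-sorted file
  set.seed(42)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                   start = sample.int(1e5, 50))
  df$end <- df$start + sample.int(500, 50)
  shuffled <- df[sample.int(50), ]
  write.table(shuffled, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  got <- as.data.frame(read_bed(f))
  want <- df[order(df$chrom, df$start, df$end), ]
  rownames(want) <- NULL
  expect_equal(got, want)

  # write/read round-trip is the identity, including name and score
  ps2 <- peak_set(df$chrom, df$start, df$end,
                  name = sprintf("p%02d", 1:50), score = runif(50))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps2, f2)
  expect_equal(as.data.frame(read_bed(f2)), as.data.frame(ps2))
})

test_that("malformed BED lines raise instead of being skipped", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30"), f)
  expect_error(read_bed(f), "field")
  writeLines("chr1\tten\t20", f)
  expect_error(read_bed(f), "non-integer")
  writeLines("chr1\t50\t40", f)
  expect_error(read_bed(f), "start >= end")
  expect_error(read_bed(file.path(tempdir(), "does-not-exist.bed")),
               "no such file")
  expect_error(peak_set("chr1", 100, 200, genome = c(chr1 = 150)),
               "exceeds")
})

test_that("merge_union merges, respects gap, and matches a sweep-line oracle", {
  g <- c(chr1 = 1e6)
  a <- peak_set("chr1", 100, 200, genome = g)
  b <- peak_set("chr1", 150, 250, genome = g)
  expect_equal(as.data.frame(merge_union(list(a, b)))[, c("start", "end")],
               data.frame(start = 100L, end = 250L))

  far <- peak_set(c("chr1", "chr1"), c(1000, 11000), c(1500, 11500),
                  genome = g)
  expect_equal(nrow(as.data.frame(merge_union(list(far)))), 2L)

  set.seed(7)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                   start = sample.int(5e4, 200, replace = TRUE))
  df$end <- df$start + sample.int(400, 200, replace = TRUE)
  ps <- peak_set(df$chrom, df$start, df$end)
  got <- as.data.frame(merge_union(list(ps), gap = 100))
  want <- oracle_merge(df, gap = 100)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)

  # idempotent, and invariant to how the input is split across sets
  again <- merge_union(list(merge_union(list(ps), gap = 100)), gap = 100)
  expect_equal(as.data.frame(again), got)
  halves <- list(ps[1:100], ps[101:200])
  expect_equal(as.data.frame(merge_union(rev(halves), gap = 100)), got)
})

test_that("merge_union refuses inconsistent genomes", {
  a <- peak_set("chr1", 1, 10, genome = c(chr1 = 100))
  b <- peak_set("chr1", 1, 10, genome = c(chr1 = 200))
  expect_error(merge_union(list(a, b)), "inconsistent")
})

test_that("signal extraction windows, padding, and background contract", {
  # uniform depth 1 everywhere -> all entries 1
  tr <- make_track(list(chrA = rep(1, 200)))
  ps <- peak_set("chrA", 4000, 6000, genome = c(chrA = 1e4))
  sm <- extract_signal_matrix(tr, ps, 1000, 50)
  expect_true(all(sm$values == 1))
  expect_equal(dim(sm$values), c(1L, 40L))

  # peak centered at bp 0 -> left half zero-padded
  ps0 <- peak_set("chrA", 0, 2, genome = c(chrA = 1e4))
  sm0 <- extract_signal_matrix(tr, ps0, 1000, 50)
  # center = 1, so 999 of the 1000 left-half bp are padding
  expect_true(all(sm0$values[1, 1:19] == 0))
  expect_equal(unname(sm0$values[1, 20]), 1 / 50)
  expect_true(all(sm0$values[1, 21:40] == 1))

  # single nonzero bin at the center -> exactly one nonzero column
  bins <- rep(0, 200); bins[101] <- 7  # bp 5000..5049
  tr2 <- make_track(list(chrA = bins))
  ps2 <- peak_set("chrA", 4975, 5025, genome = c(chrA = 1e4))  # center 5000
  sm2 <- extract_signal_matrix(tr2, ps2, 1000, 50)
  expect_equal(sum(sm2$values != 0), 1L)
  expect_equal(max(sm2$values), 7)

  # peak on an absent chromosome is a hard error
  psx <- peak_set("chrB", 0, 100, genome = c(chrA = 1e4, chrB = 1e4))
  expect_error(extract_signal_matrix(tr, psx, 1000, 50), "absent")
  expect_error(extract_signal_matrix(tr, ps, 1030, 50), "multiple")
})

test_that("extraction commutes with scalar track scaling and bounds row sums", {
  set.seed(1)
  bins <- rpois(400, 3)
  tr1 <- make_track(list(chrA = bins))
  tr3 <- make_track(list(chrA = 3 * bins))
  ps <- peak_set(c("chrA", "chrA"), c(2000, 9000), c(4000, 12000),
                 genome = c(chrA = 2e4))
  m1 <- extract_signal_matrix(tr1, ps, 1000, 50)
  m3 <- extract_signal_matrix(tr3, ps, 1000, 50)
  expect_equal(m3$values, 3 * m1$values)
  total_depth <- sum(bins) # reads; bins are 50 bp so T / bin_size in bp units
  expect_true(all(rowSums(m1$values) <= total_depth))
})

test_that("occupancy_fraction counts enriched rows over background", {
  v <- matrix(1, nrow = 100, ncol = 10)
  v[1:37, ] <- 5
  sm <- signal_matrix(v, half_window = 250, bin_size = 50,
                      track_background = 1)
  ps <- peak_set(rep("c", 100), seq(0, 990, by = 10), seq(5, 995, by = 10))
  expect_equal(occupancy_fraction(ps, sm, 2), 0.37)

  # a matrix that is all zero scores zero occupancy
  sm0 <- signal_matrix(matrix(0, 100, 10), 250, 50, track_background = 1)
  expect_equal(occupancy_fraction(ps, sm0, 2), 0)

  # zero background is an explicit error
  smz <- signal_matrix(v, 250, 50, track_background = 0)
  expect_error(occupancy_fraction(ps, smz, 2), "background")

  # the reference signal against itself clears any modest threshold
  tr <- make_track(list(chrA = c(rep(1, 100), rep(50, 20), rep(1, 280))))
  psr <- peak_set("chrA", 5000, 6000, genome = c(chrA = 2e4))
  smr <- extract_signal_matrix(tr, psr, 500, 50)
  expect_equal(occupancy_fraction(psr, smr, 2), 1)
})

test_that("bedGraph and SignalMatrix archives round-trip", {
  set.seed(9)
  bins <- list(chrA = rpois(100, 2), chrB = rpois(60, 2))
  tr <- make_track(bins, library_size = 5e6, spike = 1234, id = "x.y.z")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  tr2 <- read_bedgraph(f, genome = tr$genome, bin_size = 50,
                       library_size = 5e6, spike_in_reads = 1234,
                       sample_id = "x.y.z")
  expect_identical(lapply(tr2$cov, as.numeric), lapply(tr$cov, as.numeric))
  expect_equal(track_mean(tr2), track_mean(tr))
  expect_equal(track_background(tr2), track_background(tr))

  ps <- peak_set("chrA", 2000, 2400, genome = tr$genome)
  sm <- extract_signal_matrix(tr, ps, 500, 50)
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_signal_matrix(sm, fa)
  sm2 <- read_signal_matrix(fa)
  expect_equal(sm2$values, sm$values)
  expect_equal(sm2[c("half_window", "bin_size", "sample_id",
                     "normalization", "track_background", "library_size")],
               sm[c("half_window", "bin_size", "sample_id",
                    "normalization", "track_background", "library_size")])
})
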
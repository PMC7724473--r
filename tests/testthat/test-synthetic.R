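mini_design <- function() {
  cn <- c("nar", "brd")
  structure(list(
    genome = c(chr1 = 4e5, chr2 = 3e5), bin_size = 50L,
    class_specs = list(
      peak_class_spec("nar", "narrow", 12, c(800, 1400), c(15, 25), 8),
      peak_class_spec("brd", "broad", 6, c(1800, 2100), c(8, 12), 2)),
    conditions = list(
      condition_spec("ezh2", "WT", "none", setNames(c(1, 1), cn),
                     library_size = 1e7),
      condition_spec("ezh2", "mut", "none", setNames(c(0.2, 0.6), cn),
                     library_size = 1e7)),
    background_rate = 1, eed226_as_reduction = FALSE),
    class = "study_design")
}

test_that("generated widths respect class ranges and labels survive BED", {
  uni <- generate_universe(
    list(peak_class_spec("nar", "narrow", 20, c(1000, 2000), c(10, 20), 5)),
    c(chrA = 3e5), seed = 41)
  df <- as.data.frame(uni$peaks)
  expect_true(all(df$end - df$start >= 1000 & df$end - df$start <= 2000))
  expect_true(all(df$start >= 0 & df$end <= 3e5))
  # disjoint placement
  expect_true(all(diff(df$start) > 0))
  expect_true(all(utils::head(df$end, -1) < utils::tail(df$start, -1)))

  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(uni$peaks, f)
  back <- read_bed(f, genome = c(chrA = 3e5))
  expect_equal(peak_names(back), peak_names(uni$peaks))
  expect_equal(as.data.frame(back)$score, df$score)
})

test_that("the same seed reproduces the universe byte for byte", {
  specs <- list(peak_class_spec("a", "narrow", 10, c(800, 1200),
                                c(10, 20), 6))
  u1 <- generate_universe(specs, c(chrA = 2e5), seed = 77)
  u2 <- generate_universe(specs, c(chrA = 2e5), seed = 77)
  expect_identical(as.data.frame(u1$peaks), as.data.frame(u2$peaks))
  expect_identical(as.character(u1$sequences), as.character(u2$sequences))
  u3 <- generate_universe(specs, c(chrA = 2e5), seed = 78)
  expect_false(identical(as.data.frame(u1$peaks), as.data.frame(u3$peaks)))

  expect_error(generate_universe(
    list(peak_class_spec("a", "narrow", 500, c(5000, 6000), c(1, 2), 1)),
    c(chrA = 1e5), seed = 1), "too small")
})

test_that("planted GCG density is recovered by the shape counter", {
  uni <- generate_universe(
    list(peak_class_spec("nar", "narrow", 100, c(2000, 2000), c(10, 20), 10)),
    c(chrA = 2.5e6, chrB = 2.5e6), seed = 43)
  rc <- region_shape_counts(uni$sequences, uni$peaks,
                            synthetic_shape_table(),
                            twist_threshold = uni$twist_threshold)
  # 3-SE band around the requested 10 per kb
  se <- sd(rc$density) / sqrt(nrow(rc))
  expect_lt(abs(mean(rc$density) - 10), 3 * max(se, 0.05))
  # decoy GCGs exist but never count as shape-matching
  expect_true(all(rc$total_gcg > rc$shape_matching_gcg))
})

test_that("coverage simulation follows the planted rates", {
  uni <- generate_universe(
    list(peak_class_spec("brd", "broad", 50, c(4000, 4000), c(20, 20), 0)),
    c(chrA = 2.5e6), seed = 44)
  cond <- condition_spec("ezh2", "mut", "none", c(brd = 0.5),
                         background_rate = 1)
  tr <- simulate_coverage(uni, cond, seed = 45)
  df <- as.data.frame(uni$peaks)
  centers <- peak_centers(uni$peaks)
  # flat plateau inner region: |offset| <= 0.4 * width -> rate 1 + 0.5*20
  vals <- as.numeric(tr$chip$cov$chrA)
  plateau <- unlist(lapply(seq_len(nrow(df)), function(i)
    vals[seq(centers[i] - 1400, centers[i] + 1400, by = 50) + 1]))
  expect_lt(abs(mean(plateau) - 11), 3 * sd(plateau) / sqrt(length(plateau)))

  # residual fraction 0 makes chip and input distributionally identical
  cond0 <- condition_spec("ezh2", "mut0", "none", c(brd = 0),
                          background_rate = 1)
  tr0 <- simulate_coverage(uni, cond0, seed = 46)
  m_chip <- track_mean(tr0$chip)
  m_input <- track_mean(tr0$input)
  expect_lt(abs(m_chip - m_input), 0.02)

  expect_error(simulate_coverage(uni,
    condition_spec("x", "mut", "none", c(other = 1)), seed = 1),
    "lacks fractions")
})

test_that("library size metadata does not alter depths but rescales RPKM", {
  uni <- generate_universe(
    list(peak_class_spec("nar", "narrow", 10, c(1000, 1500), c(15, 20), 4)),
    c(chrA = 3e5), seed = 47)
  c1 <- condition_spec("ezh2", "mut", "none", c(nar = 0.5),
                       library_size = 1e7)
  c2 <- condition_spec("ezh2", "mut", "none", c(nar = 0.5),
                       library_size = 2e7)
  t1 <- simulate_coverage(uni, c1, seed = 48)$chip
  t2 <- simulate_coverage(uni, c2, seed = 48)$chip
  expect_identical(as.numeric(t1$cov$chrA), as.numeric(t2$cov$chrA))
  q1 <- quantify_peaks(extract_signal_matrix(t1, uni$peaks, 1000, 50))
  q2 <- quantify_peaks(extract_signal_matrix(t2, uni$peaks, 1000, 50))
  expect_equal(q2$value, q1$value / 2)
})

test_that("spike-in counts fall as efficiency rises", {
  lo <- condition_spec("e", "g", "t", c(a = 1), efficiency = 0.5)
  hi <- condition_spec("e", "g", "t", c(a = 1), efficiency = 2)
  expect_equal(lo$spike_in_reads, 6e5)
  expect_equal(hi$spike_in_reads, 1.5e5)
  expect_error(condition_spec("e", "WT", "none", c(a = 0.5)), "wild type")
})

test_that("a study directory is reproducible and internally consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st <- default_study(d1, seed = 7, design = mini_design())
  default_study(d2, seed = 7, design = mini_design())

  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  sums1 <- tools::md5sum(file.path(d1, files))
  sums2 <- tools::md5sum(file.path(d2, files))
  expect_identical(unname(sums1), unname(sums2))

  samples <- read.table(file.path(d1, "samples.tsv"), header = TRUE,
                        sep = "\t")
  expect_equal(nrow(samples), length(mini_design()$conditions))
  expect_equal(colnames(samples),
               c("sample_id", "antibody", "genotype", "treatment",
                 "chip_track", "input_track", "library_size",
                 "spike_in_reads"))
  expect_true(all(file.exists(file.path(d1, samples$chip_track))))

  # the loader reconstructs what the generator wrote
  study <- load_study(d1)
  expect_equal(length(study$peaks), 18L)
  expect_equal(sort(unique(peak_names(study$peaks))), c("brd", "nar"))
  tm <- vapply(study$tracks, function(tr) track_mean(tr$chip), 0)
  expect_true(all(tm > 0.9))
})
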
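test_that("peak-to-gene assignment matches an all-pairs nearest search", {
  ann <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                    tss = c(5000L, 5000L), strand = "+")
  ps <- peak_set("chr1", 4900, 5100)  # center exactly on both TSS
  got <- assign_peaks_to_genes(ps, ann, max_distance = 1e4)
  expect_equal(unname(got), "gA")  # tie broken to smaller gene id

  far <- peak_set("chr1", 50000, 50200)
  expect_true(is.na(assign_peaks_to_genes(far, ann, max_distance = 1e4)))
  expect_error(assign_peaks_to_genes(ps, ann[0, ], 1e4), "empty")

  set.seed(21)
  peaks_df <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                         start = sample.int(2e5, 100))
  peaks_df$end <- peaks_df$start + 500
  ps2 <- peak_set(peaks_df$chrom, peaks_df$start, peaks_df$end)
  ann2 <- data.frame(gene_id = sprintf("g%02d", 1:50),
                     chrom = sample(c("chr1", "chr2"), 50, TRUE),
                     tss = sample.int(2e5, 50), strand = "-")
  got2 <- assign_peaks_to_genes(ps2, ann2, max_distance = 2e4)
  df2 <- as.data.frame(ps2)
  want2 <- oracle_nearest(df2, (df2$start + df2$end) %/% 2, ann2, 2e4)
  expect_equal(unname(got2), want2)
})

test_that("hypergeometric tail and fold match closed form and enumeration", {
  bg <- sprintf("g%02d", 1:20)
  res <- hypergeometric_enrichment(bg[1:5], bg[1:5], bg)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$fold, (5 / 5) / (5 / 20))

  disjoint <- hypergeometric_enrichment(bg[1:5], bg[6:10], bg[1:10])
  expect_equal(disjoint$overlap, 0L)
  expect_equal(disjoint$p, 1)

  expect_error(hypergeometric_enrichment(c(bg, "zz"), bg[1:3], bg),
               "outside the background")
  expect_error(hypergeometric_enrichment(bg[1:2], bg[1:3], character()),
               "empty background")

  # against exhaustive enumeration of every draw, bg <= 12
  for (cfg in list(c(10, 4, 3), c(12, 6, 5), c(9, 3, 4))) {
    bgN <- cfg[1]; termN <- cfg[2]; fgN <- cfg[3]
    genes <- sprintf("x%02d", seq_len(bgN))
    set.seed(sum(cfg))
    fg <- sample(genes, fgN)
    ov <- length(intersect(fg, genes[seq_len(termN)]))
    p_pkg <- hypergeometric_enrichment(fg, genes[seq_len(termN)], genes)$p
    expect_equal(p_pkg, oracle_hyper_tail(bgN, termN, fgN, ov),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("background choice separates global from cluster-specific terms", {
  set.seed(22)
  n_peak <- 120
  peak_genes <- sprintf("pg%03d", 1:n_peak)
  bg_genes <- sprintf("bg%03d", 1:800)
  ann <- data.frame(gene_id = c(peak_genes, bg_genes), chrom = "chr1",
                    tss = seq_len(n_peak + 800) * 100L, strand = "+")
  labels <- setNames(rep(c(1L, 2L), c(70, 50)), paste0("peak", 1:n_peak))
  p2g <- setNames(peak_genes, names(labels))
  terms <- rbind(
    data.frame(term = "broad_program",
               gene = c(peak_genes[71:120], sample(bg_genes, 25))),
    data.frame(term = "polycomb_program",
               gene = c(peak_genes, sample(bg_genes, 40))),
    data.frame(term = "tiny", gene = bg_genes[1:2]))

  all_bg <- enrich_clusters(labels, p2g, terms, ann, background = "all")
  tgt_bg <- enrich_clusters(labels, p2g, terms, ann,
                            background = "targets")

  pick <- function(df, tm, cl) df[df$term == tm & df$cluster == cl, ]
  # the cluster-2 term is enriched under both backgrounds
  expect_lt(pick(all_bg, "broad_program", 2)$q, 1e-6)
  expect_lt(pick(tgt_bg, "broad_program", 2)$q, 1e-6)
  # the everywhere-term is enriched only against the all-genes background
  expect_lt(pick(all_bg, "polycomb_program", 1)$q, 1e-6)
  expect_gt(pick(tgt_bg, "polycomb_program", 1)$p, 0.5)
  # fold moves in the documented direction when the background narrows
  expect_gt(pick(all_bg, "polycomb_program", 1)$fold,
            pick(tgt_bg, "polycomb_program", 1)$fold)
  # undersized terms are skipped and reported
  expect_true("tiny" %in% attr(all_bg, "skipped_terms"))
  expect_false("tiny" %in% all_bg$term)
  # q respects p elementwise
  expect_true(all(all_bg$q >= all_bg$p - 1e-12))
})
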
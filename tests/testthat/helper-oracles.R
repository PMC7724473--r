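# Independent oracles and small fixture builders shared across the suite.
# Every oracle re-derives its answer by a different route than the
# implementation it checks (brute force, exhaustive enumeration, direct
# definitions), so agreement is evidence, not tautology.

# sweep-line interval merge: sort, then walk, merging intervals whose gap
# to the growing interval is <= gap
oracle_merge <- function(df, gap = 0) {
  df <- df[order(df$chrom, df$start), ]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.null(cur) || row$chrom != cur$chrom ||
        row$start - cur$end > gap) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- row[, c("chrom", "start", "end")]
    } else {
      cur$end <- max(cur$end, row$end)
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# direct Lloyd iterations under Pearson distance on the raw rows:
# centroids are plain means, distance is 1 - cor
oracle_pearson_lloyd <- function(x, k, seed, n_init = 20, max_iter = 100) {
  set.seed(seed)
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    labels <- integer(n)
    obj <- Inf
    for (it in seq_len(max_iter)) {
      d <- sapply(seq_len(k), function(j)
        apply(x, 1, function(row) 1 - cor(row, centers[j, ])))
      new_labels <- apply(d, 1, which.min)
      if (any(tabulate(new_labels, k) == 0)) break
      obj <- sum(d[cbind(seq_len(n), new_labels)])
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (j in seq_len(k))
        centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    if (all(tabulate(labels, k) > 0) &&
        (is.null(best) || obj < best$obj))
      best <- list(labels = labels, obj = obj)
  }
  best$labels
}

# exhaustive search over all bipartitions of n rows minimizing total
# within-cluster Pearson distance to the cluster mean
oracle_best_bipartition <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2L) next
    obj <- 0
    for (j in 1:2) {
      rows <- x[lab == j, , drop = FALSE]
      cen <- colMeans(rows)
      obj <- obj + sum(apply(rows, 1, function(r) 1 - cor(r, cen)))
    }
    if (is.null(best) || obj < best$obj) best <- list(lab = lab, obj = obj)
  }
  best$lab
}

same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# brute-force GCG scan by sliding a 3-bp window
oracle_scan <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  hits <- data.frame(start = integer(), strand = character())
  if (n < 3) return(hits)
  for (p in 0:(n - 3)) {
    w <- substr(s, p + 1, p + 3)
    if (w == "GCG") hits <- rbind(hits, data.frame(start = p, strand = "+"))
    if (w == "CGC") hits <- rbind(hits, data.frame(start = p, strand = "-"))
  }
  hits
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

# brute-force shape-matching count: enumerate every hit on both strands,
# recompute the two context pentamers and their mean twist from scratch
oracle_shape_count <- function(s, tab, thr) {
  count_strand <- function(seqc) {
    n <- nchar(seqc)
    total <- 0L; matching <- 0L; edge <- 0L
    if (n >= 3) for (p in 0:(n - 3)) {
      if (substr(seqc, p + 1, p + 3) != "GCG") next
      total <- total + 1L
      if (p < 1 || p + 4 > n - 1) { edge <- edge + 1L; next }
      mt <- (tab[substr(seqc, p, p + 4)] +
               tab[substr(seqc, p + 1, p + 5)]) / 2
      if (mt < thr) matching <- matching + 1L
    }
    c(total, matching, edge)
  }
  f <- count_strand(toupper(s))
  r <- count_strand(revcomp(s))
  list(total = f[1] + r[1], matching = f[2] + r[2], edge = f[3] + r[3])
}

# all-pairs nearest-TSS search
oracle_nearest <- function(peaks_df, centers, ann, max_distance) {
  out <- rep(NA_character_, nrow(peaks_df))
  for (i in seq_len(nrow(peaks_df))) {
    cand <- ann[ann$chrom == peaks_df$chrom[i], ]
    if (!nrow(cand)) next
    d <- abs(cand$tss - centers[i])
    if (min(d) > max_distance) next
    out[i] <- min(cand$gene_id[d == min(d)])
  }
  out
}

# exhaustive hypergeometric tail: enumerate every possible foreground draw
oracle_hyper_tail <- function(bg_n, term_n, fg_n, overlap) {
  draws <- utils::combn(bg_n, fg_n)
  hit <- colSums(draws <= term_n)  # genes 1..term_n carry the term
  mean(hit >= overlap)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# build a CoverageTrack directly from bin vectors
make_track <- function(bins, bin_size = 50, library_size = 1e6,
                       spike = NA_real_, id = "s") {
  genome <- vapply(bins, function(v) length(v) * bin_size, 0)
  coverage_track(bins, bin_size, genome, library_size, spike, id)
}

# two-sample Kolmogorov-Smirnov distance without ks.test's tie warnings
ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

# the default synthetic study and its pipeline run are expensive; build
# them once per test session and share
.fixture_env <- new.env(parent = emptyenv())

default_pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    dir <- file.path(tempdir(), "prc2strat-default-study")
    default_study(dir, seed = 101)
    .fixture_env$pipeline <- run_study_pipeline(dir, seed = 101)
  }
  .fixture_env$pipeline
}
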
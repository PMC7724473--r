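# Fully synthetic study generator: genome sequence, a peak universe with
# planted signal classes, per-condition ChIP and input coverage with
# class-specific residual fractions, spike-in read counts, a TSS
# annotation and a term-to-gene map.  One base seed governs every draw via
# the sub_seed() stream-splitting scheme (universe = stream 1, condition i
# = stream 10 + i, gene annotation = stream 100), so a whole study is
# byte-reproducible from a single integer.

#' Describe a planted peak class
#'
#' @param name class label written to the BED name field (e.g.
#'   \code{"narrow1"}).
#' @param shape \code{"narrow"} (sharp Gaussian bump, sd = width/4) or
#'   \code{"broad"} (flat plateau with a linear taper over the outer 10
#'   percent of the width on each side).
#' @param n_peaks number of peaks (> 0).
#' @param width_range length-2 vector, widths drawn uniformly (bp).
#' @param amplitude_range length-2 vector, per-peak wild-type amplitude
#'   drawn uniformly (reads per bin).
#' @param gcg_density planted shape-matching GCG trinucleotides per kb.
#' @param cpg_like logical flag (bivalent, CpG-island-like class).
#' @param antibodies antibodies that show this class at all in wild type
#'   (\code{NULL} = all); used to plant classes bound by a single subunit.
#' @return list of class \code{peak_class_spec}.
#' @export
peak_class_spec <- function(name, shape = c("narrow", "broad"), n_peaks,
                            width_range, amplitude_range, gcg_density,
                            cpg_like = shape == "narrow",
                            antibodies = NULL) {
  shape <- match.arg(shape)
  stopifnot(n_peaks > 0, length(width_range) == 2L,
            width_range[1L] > 0, diff(width_range) >= 0,
            length(amplitude_range) == 2L, gcg_density >= 0)
  structure(list(name = name, shape = shape, n_peaks = as.integer(n_peaks),
                 width_range = width_range,
                 amplitude_range = amplitude_range,
                 gcg_density = gcg_density, cpg_like = isTRUE(cpg_like),
                 antibodies = antibodies),
            class = "peak_class_spec")
}

#' Describe one ChIP condition (antibody x genotype x treatment)
#'
#' @param antibody,genotype,treatment condition labels; the sample id is
#'   their dot-separated concatenation.
#' @param fractions named vector: residual fraction of the wild-type peak
#'   amplitude per class (>= 0). The untreated wild type must have all
#'   fractions equal to 1.
#' @param background_rate background reads per bin (>= 0).
#' @param library_size total mapped reads.
#' @param efficiency global ChIP efficiency multiplier; scales simulated
#'   ChIP depth and, inversely, the spike-in read count.
#' @param spike_in_reads explicit spike-in read count; by default
#'   \code{round(spike_in_base / efficiency)}.
#' @param spike_in_base baseline spike-in reads at efficiency 1.
#' @return list of class \code{condition_spec}.
#' @export
condition_spec <- function(antibody, genotype, treatment, fractions,
                           background_rate = 1, library_size = 2e7,
                           efficiency = 1, spike_in_reads = NULL,
                           spike_in_base = 3e5) {
  if (any(fractions < 0)) stopf("residual fractions must be >= 0")
  if (is.null(names(fractions))) stopf("fractions must be named by class")
  if (genotype == "WT" && treatment == "none" && any(fractions != 1))
    stopf("untreated wild type must have all residual fractions = 1")
  if (background_rate < 0) stopf("background_rate must be >= 0")
  structure(list(antibody = antibody, genotype = genotype,
                 treatment = treatment,
                 sample_id = paste(antibody, genotype, treatment, sep = "."),
                 fractions = fractions, background_rate = background_rate,
                 library_size = library_size, efficiency = efficiency,
                 spike_in_reads = spike_in_reads %||%
                   round(spike_in_base / efficiency)),
            class = "condition_spec")
}

# profile weight at signed bp offsets from the peak center
profile_weight <- function(shape, width, offset) {
  half <- width / 2
  if (shape == "narrow") {
    s <- width / 4
    w <- exp(-offset^2 / (2 * s^2))
    w[abs(offset) > half] <- 0
    w
  } else {
    taper <- 0.1 * width
    a <- abs(offset)
    w <- numeric(length(offset))
    inside <- a <= half
    w[inside] <- pmin(1, (half - a[inside]) / taper)
    w
  }
}

# --- sequence construction -------------------------------------------------

# random ACGT vector with every GCG/CGC occurrence destroyed (middle base
# set to T; T never occurs in either motif, so no new occurrence can arise)
cleansed_random_seq <- function(len) {
  v <- sample(DNA_BASES, len, replace = TRUE)
  s <- Biostrings::DNAString(paste(v, collapse = ""))
  for (motif in c("GCG", "CGC")) {
    hit <- Biostrings::start(Biostrings::matchPattern(motif, s))
    if (length(hit)) v[hit + 1L] <- "T"
    s <- Biostrings::DNAString(paste(v, collapse = ""))
  }
  v
}

# flank triples (a, b, c) for the planted block "T a GCG b c T"; a and b
# exclude C so the block contains exactly one GCG and no CGC.  Returns the
# 8-mers whose mean twist over the two internal steps is below / at-or-above
# the threshold.
motif_blocks <- function(table, twist_threshold) {
  tab <- as_shape_vector(table)
  grid <- expand.grid(a = c("A", "G", "T"), b = c("A", "G", "T"),
                      c = DNA_BASES, stringsAsFactors = FALSE)
  tw <- (tab[paste0(grid$a, "GCG", grid$b)] +
           tab[paste0("GCG", grid$b, grid$c)]) / 2
  blocks <- paste0("T", grid$a, "GCG", grid$b, grid$c, "T")
  list(matching = blocks[tw < twist_threshold],
       decoy = blocks[tw >= twist_threshold])
}

#' Generate the synthetic peak universe and genome sequence
#'
#' Peaks of each class are placed disjointly (separated by at least
#' \code{min_gap} bp, away from chromosome edges), interleaved at random
#' along the genome; each peak draws its width and wild-type amplitude
#' uniformly from its class ranges. Chromosome sequences are random ACGT
#' purged of GCG/CGC, and each peak gets shape-matching GCG motifs planted
#' at its class density (plus half as many non-matching decoy GCGs), so
#' the shape-conditioned counter sees exactly the planted contrast.
#'
#' @param class_specs list of \code{\link{peak_class_spec}}.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param seed integer seed (mandatory; same seed, same bytes out).
#' @param min_gap minimum bp between adjacent peaks (default 2500).
#' @param edge_margin bp kept peak-free at chromosome ends (default 6000).
#' @param shape_table pentamer twist table used to select planted motifs
#'   (default \code{\link{synthetic_shape_table}()}).
#' @param twist_threshold threshold for "shape-matching" (default table
#'   median).
#' @return list of class \code{peak_universe}: \code{peaks} (a
#'   \code{PeakSet}; BED name = class, score = wild-type amplitude),
#'   \code{sequences} (\code{DNAStringSet}), \code{class_specs},
#'   \code{genome}, \code{twist_threshold}.
#' @export
generate_universe <- function(class_specs, genome, seed, min_gap = 2500,
                              edge_margin = 6000,
                              shape_table = synthetic_shape_table(),
                              twist_threshold = NULL) {
  if (missing(seed)) stopf("seed is mandatory")
  tab <- as_shape_vector(shape_table)
  twist_threshold <- twist_threshold %||% stats::median(tab)
  set.seed(seed)
  cls <- unlist(lapply(class_specs, function(cs) rep(cs$name, cs$n_peaks)))
  widths <- unlist(lapply(class_specs, function(cs)
    round(stats::runif(cs$n_peaks, cs$width_range[1L], cs$width_range[2L]))))
  amps <- unlist(lapply(class_specs, function(cs)
    stats::runif(cs$n_peaks, cs$amplitude_range[1L], cs$amplitude_range[2L])))
  n <- length(cls)
  perm <- sample.int(n)
  cls <- cls[perm]; widths <- widths[perm]; amps <- amps[perm]
  avail <- genome - 2 * edge_margin
  if (sum(widths) + n * min_gap > sum(avail))
    stopf("genome too small to place %d peaks disjointly", n)
  # split peaks over chromosomes in proportion to available length
  cum_w <- cumsum(widths + min_gap)
  breaks <- cumsum(avail) / sum(avail) * cum_w[n]
  chrom_of <- as.integer(cut(cum_w, c(0, breaks), labels = FALSE))
  chrom_names <- names(genome)
  out_chrom <- character(n); out_start <- integer(n)
  for (ci in seq_along(chrom_names)) {
    idx <- which(chrom_of == ci)
    if (!length(idx)) next
    w <- widths[idx]
    slack <- avail[ci] - sum(w) - min_gap * (length(idx) - 1L)
    if (slack < 0) stopf("genome too small to place peaks disjointly")
    g <- stats::rexp(length(idx) + 1L)
    g <- g / sum(g) * slack
    pos <- edge_margin + cumsum(g[seq_along(idx)]) +
      c(0, cumsum(w[-length(w)] + min_gap))
    out_chrom[idx] <- chrom_names[ci]
    out_start[idx] <- as.integer(round(pos))
  }
  # sequences with planted motifs
  blocks <- motif_blocks(tab, twist_threshold)
  if (!length(blocks$matching))
    stopf("no flank triple satisfies the twist threshold")
  seqs <- lapply(chrom_names, function(ch) cleansed_random_seq(genome[[ch]]))
  names(seqs) <- chrom_names
  for (ch in chrom_names) {
    sv <- seqs[[ch]]
    for (i in which(out_chrom == ch)) {
      w <- widths[i]
      n_match <- round(gcg_density_of(class_specs, cls[i]) * w / 1000)
      n_decoy <- round(n_match / 2)
      total <- n_match + n_decoy
      if (total == 0) next
      nslot <- w %/% 8L
      if (total > nslot) stopf("peak too small for requested GCG density")
      slots <- sample.int(nslot, total)
      picks <- c(sample(blocks$matching, n_match, replace = TRUE),
                 if (n_decoy > 0)
                   sample(blocks$decoy, n_decoy, replace = TRUE))
      starts <- out_start[i] + (slots - 1L) * 8L  # 0-based
      chars <- strsplit(picks, "", fixed = TRUE)
      for (j in seq_len(total))
        sv[(starts[j] + 1L):(starts[j] + 8L)] <- chars[[j]]
    }
    seqs[[ch]] <- sv
  }
  sequences <- Biostrings::DNAStringSet(vapply(seqs, paste, "",
                                               collapse = ""))
  peaks <- peak_set(out_chrom, out_start, out_start + widths,
                    name = cls, score = amps, genome = genome,
                    source = "synthetic")
  structure(list(peaks = peaks, sequences = sequences,
                 class_specs = class_specs, genome = genome,
                 twist_threshold = twist_threshold, seed = seed),
            class = "peak_universe")
}

gcg_density_of <- function(class_specs, name) {
  for (cs in class_specs) if (cs$name == name) return(cs$gcg_density)
  stopf("unknown class '%s'", name)
}

class_spec_of <- function(class_specs, name) {
  for (cs in class_specs) if (cs$name == name) return(cs)
  stopf("unknown class '%s'", name)
}

#' Simulate ChIP and input coverage for one condition
#'
#' Per-bin ChIP depth is Poisson with rate
#' \code{efficiency * (background_rate + fraction * amplitude * profile)};
#' the matched input is Poisson at the background rate alone. The
#' condition's library size and spike-in reads are copied onto the tracks
#' as metadata (simulated depths do not depend on them).
#'
#' @param universe a \code{peak_universe} from
#'   \code{\link{generate_universe}}.
#' @param condition a \code{\link{condition_spec}}; it must define a
#'   residual fraction for every class present.
#' @param seed integer seed.
#' @param bin_size bin width in bp (default 50).
#' @return list with elements \code{chip} and \code{input}, both
#'   \code{CoverageTrack}s.
#' @export
simulate_coverage <- function(universe, condition, seed, bin_size = 50L) {
  stopifnot(inherits(universe, "peak_universe"),
            inherits(condition, "condition_spec"))
  df <- as.data.frame(universe$peaks)
  centers <- peak_centers(universe$peaks)
  miss <- setdiff(unique(df$name), names(condition$fractions))
  if (length(miss))
    stopf("condition '%s' lacks fractions for class(es): %s",
          condition$sample_id, paste(miss, collapse = ", "))
  set.seed(seed)
  chip_bins <- list(); input_bins <- list()
  for (ch in names(universe$genome)) {
    nb <- as.integer(ceiling(universe$genome[[ch]] / bin_size))
    rate <- rep(condition$background_rate, nb)
    for (i in which(df$chrom == ch)) {
      cs <- class_spec_of(universe$class_specs, df$name[i])
      bound <- is.null(cs$antibodies) ||
        condition$antibody %in% cs$antibodies
      f <- condition$fractions[[df$name[i]]] * as.numeric(bound)
      if (f == 0) next
      b1 <- df$start[i] %/% bin_size + 1L
      b2 <- min((df$end[i] - 1L) %/% bin_size + 1L, nb)
      mid <- (seq(b1, b2) - 0.5) * bin_size
      w <- profile_weight(cs$shape, df$end[i] - df$start[i],
                          mid - centers[i])
      rate[b1:b2] <- rate[b1:b2] + f * df$score[i] * w
    }
    chip_bins[[ch]] <- stats::rpois(nb, condition$efficiency * rate)
    input_bins[[ch]] <- stats::rpois(nb, condition$background_rate)
  }
  list(chip = coverage_track(chip_bins, bin_size, universe$genome,
                             condition$library_size,
                             condition$spike_in_reads,
                             condition$sample_id),
       input = coverage_track(input_bins, bin_size, universe$genome,
                              condition$library_size, NA_real_,
                              paste0(condition$sample_id, ".input")))
}

#' The default synthetic study design
#'
#' A desk-scale emulation of a multi-condition PRC2 ChIP-seq study: a
#' 2 x 5 Mb genome; six planted condition-profile classes -- four
#' narrow-shaped, CpG-island-like classes with sharply localized binding
#' and two broad, low-CpG domain classes -- plus a decoy class bound by
#' JARID2 alone (excluded by the solo-peak filter, as in the analysis the
#' package implements); and 15 ChIP conditions spanning the antibody x
#' genotype x treatment grid (the peak-count-weighted EED226 residuals
#' match the printed overall levels near 77, 85 and 41 percent). Class sizes are the study's printed cluster
#' sizes scaled down by four. Residual fractions for the perturbed
#' conditions follow the published per-cluster ranges where printed
#' (H3K27me3 in the Mtf2 mutant 6 to 27 percent for narrow classes versus
#' 48 to 56 percent for broad; EZH2 9 to 12 versus 23 to 26; JARID2 11 to
#' 19 versus 30 to 34; EED226-treated wild-type residuals near 77, 85 and
#' 41 percent for EZH2, MTF2 and JARID2) and are design choices elsewhere;
#' see the package vignette.
#'
#' @param eed226_as_reduction if TRUE, interpret the EED226 percentages as
#'   the amount of reduction instead of the residual level (fractions
#'   become 1 - f for treated conditions). Default FALSE (residual
#'   levels).
#' @return list of class \code{study_design}: genome, bin_size,
#'   class_specs, conditions, background_rate.
#' @export
default_design <- function(eed226_as_reduction = FALSE) {
  genome <- c(chr1 = 5e6, chr2 = 5e6)
  classes <- list(
    peak_class_spec("narrow1", "narrow", 300, c(800, 1600), c(25, 40), 12),
    peak_class_spec("narrow2", "narrow", 300, c(800, 1600), c(20, 32), 10),
    peak_class_spec("narrow3", "narrow", 300, c(800, 1600), c(16, 26), 8),
    peak_class_spec("narrow4", "narrow", 250, c(800, 1600), c(22, 35), 10),
    peak_class_spec("broad1", "broad", 270, c(1800, 2100), c(10, 16), 2),
    peak_class_spec("broad2", "broad", 90, c(4000, 6000), c(8, 14), 1.5),
    peak_class_spec("jarid2only", "narrow", 100, c(800, 1400), c(15, 25), 5,
                    cpg_like = FALSE, antibodies = "jarid2"))
  cn <- c("narrow1", "narrow2", "narrow3", "narrow4", "broad1", "broad2",
          "jarid2only")
  fr <- function(...) stats::setNames(c(...), cn)
  # equally sequenced libraries within each antibody; depth differences
  # between antibodies exercise the RPKM library-size term without biasing
  # within-antibody WT-normalized percentages
  libs <- c(ezh2 = 2.0e7, h3k27me3 = 2.4e7, mtf2 = 1.8e7, jarid2 = 2.2e7)
  lib <- function(i) unname(libs[c(rep("ezh2", 4), rep("h3k27me3", 4),
                                   rep("mtf2", 4), rep("jarid2", 3))[i]])
  conds <- list(
    condition_spec("ezh2", "WT", "none",
                   fr(1, 1, 1, 1, 1, 1, 1), library_size = lib(1)),
    condition_spec("ezh2", "Mtf2GT", "none",
                   fr(.09, .10, .11, .12, .23, .26, 1), library_size = lib(2)),
    condition_spec("ezh2", "Jarid2KO", "none",
                   fr(.90, 0, .90, 0, .70, .60, 1), library_size = lib(3)),
    condition_spec("ezh2", "WT", "EED226",
                   fr(.87, .84, .81, .79, .71, .22, 1), library_size = lib(4)),
    condition_spec("h3k27me3", "WT", "none",
                   fr(1, 1, 1, 1, 1, 1, 1), library_size = lib(5)),
    condition_spec("h3k27me3", "Mtf2GT", "none",
                   fr(.06, .13, .20, .27, .48, .56, 1), library_size = lib(6)),
    condition_spec("h3k27me3", "Jarid2KO", "none",
                   fr(.90, .90, 0, 0, .60, .50, 1), library_size = lib(7)),
    condition_spec("h3k27me3", "WT", "EED226",
                   fr(.02, .02, .02, .02, .02, .02, 1), library_size = lib(8)),
    condition_spec("mtf2", "WT", "none",
                   fr(1, 1, 1, 1, 1, 1, 1), library_size = lib(9)),
    condition_spec("mtf2", "Jarid2KO", "none",
                   fr(0, .90, .90, 0, .35, .20, 1), library_size = lib(10)),
    condition_spec("mtf2", "WT", "EED226",
                   fr(.96, .93, .90, .87, .72, .45, 1), library_size = lib(11)),
    condition_spec("mtf2", "EedKO", "none",
                   fr(.90, .45, 0, 0, .05, .02, 1), library_size = lib(12)),
    condition_spec("jarid2", "WT", "none",
                   fr(1, 1, 1, 1, 1, 1, 1), library_size = lib(13)),
    condition_spec("jarid2", "Mtf2GT", "none",
                   fr(.11, .14, .16, .19, .30, .34, 1), library_size = lib(14)),
    condition_spec("jarid2", "WT", "EED226",
                   fr(.50, .45, .42, .40, .35, .10, 1), library_size = lib(15)))
  if (eed226_as_reduction) {
    for (i in seq_along(conds)) {
      if (conds[[i]]$treatment == "EED226")
        conds[[i]]$fractions[cn != "jarid2only"] <-
          1 - conds[[i]]$fractions[cn != "jarid2only"]
    }
  }
  structure(list(genome = genome, bin_size = 50L, class_specs = classes,
                 conditions = conds, background_rate = 1,
                 eed226_as_reduction = eed226_as_reduction),
            class = "study_design")
}

# synthetic TSS annotation and term map: one gene per peak plus background
# genes; one term planted in the broad classes (the Hox-like program), one
# planted across all PRC2-bound peaks, and random terms as chaff
make_annotation <- function(universe, seed, n_background = 2000) {
  set.seed(seed)
  df <- as.data.frame(universe$peaks)
  centers <- peak_centers(universe$peaks)
  n <- nrow(df)
  off <- round(stats::runif(n, -2000, 2000))
  tss <- pmin(pmax(centers + off, 0), universe$genome[df$chrom] - 1)
  peak_genes <- sprintf("pg%04d", seq_len(n))
  bg_chrom <- sample(names(universe$genome), n_background, replace = TRUE)
  bg_tss <- vapply(bg_chrom, function(ch)
    sample.int(universe$genome[[ch]] - 1L, 1L), 0L)
  ann <- data.frame(
    gene_id = c(peak_genes, sprintf("bg%04d", seq_len(n_background))),
    chrom = c(df$chrom, bg_chrom),
    tss = as.integer(c(tss, bg_tss)),
    strand = sample(c("+", "-"), n + n_background, replace = TRUE),
    stringsAsFactors = FALSE)
  is_broad <- grepl("^broad", df$name)
  is_target <- df$name != "jarid2only"
  broad_genes <- peak_genes[is_broad]
  target_genes <- peak_genes[is_target]
  all_genes <- ann$gene_id
  terms <- rbind(
    data.frame(term = "broad_domain_program",
               gene = c(sample(broad_genes, round(0.9 * length(broad_genes))),
                        sample(all_genes[grepl("^bg", all_genes)], 30))),
    data.frame(term = "polycomb_program",
               gene = c(sample(target_genes, round(0.8 * length(target_genes))),
                        sample(all_genes[grepl("^bg", all_genes)], 50))),
    do.call(rbind, lapply(1:20, function(i)
      data.frame(term = sprintf("random_term_%02d", i),
                 gene = sample(all_genes, 40)))))
  list(annotation = ann, terms = terms, peak_genes = peak_genes)
}

#' Write a complete synthetic study to disk
#'
#' Generates the universe, simulates every condition, and writes: the peak
#' BED (class label in the name field, wild-type amplitude in the score
#' field), the genome FASTA, one bedGraph pair (ChIP and input) per
#' condition, the sample sheet TSV, the TSS BED, the term-to-gene TSV, the
#' pentamer twist table, and a JSON manifest recording the seed and all
#' parameters. Re-running with the same seed reproduces every file
#' byte-identically.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer base seed.
#' @param design a \code{study_design} (default \code{default_design()}).
#' @return invisibly, a list: \code{dir}, \code{universe}, \code{design},
#'   \code{samples} (the sample sheet), \code{annotation}, \code{terms},
#'   \code{manifest} path.
#' @export
default_study <- function(out_dir, seed, design = default_design()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  universe <- generate_universe(design$class_specs, design$genome,
                                seed = sub_seed(seed, 1L))
  write_bed(universe$peaks, file.path(out_dir, "peaks.bed"))
  Biostrings::writeXStringSet(universe$sequences,
                              file.path(out_dir, "genome.fa"))
  write_shape_table(synthetic_shape_table(),
                    file.path(out_dir, "twist_table.tsv"))
  rows <- list()
  for (i in seq_along(design$conditions)) {
    cond <- design$conditions[[i]]
    cond$background_rate <- design$background_rate
    tr <- simulate_coverage(universe, cond, seed = sub_seed(seed, 10L + i),
                            bin_size = design$bin_size)
    chip_f <- sprintf("%s.chip.bedgraph", cond$sample_id)
    input_f <- sprintf("%s.input.bedgraph", cond$sample_id)
    write_bedgraph(tr$chip, file.path(out_dir, chip_f))
    write_bedgraph(tr$input, file.path(out_dir, input_f))
    rows[[i]] <- data.frame(
      sample_id = cond$sample_id, antibody = cond$antibody,
      genotype = cond$genotype, treatment = cond$treatment,
      chip_track = chip_f, input_track = input_f,
      library_size = cond$library_size,
      spike_in_reads = cond$spike_in_reads, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  utils::write.table(samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- make_annotation(universe, seed = sub_seed(seed, 100L))
  tss_bed <- data.frame(ann$annotation$chrom, ann$annotation$tss,
                        ann$annotation$tss + 1L, ann$annotation$gene_id,
                        0L, ann$annotation$strand)
  utils::write.table(tss_bed, file.path(out_dir, "tss.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(ann$terms, file.path(out_dir, "terms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- list(
    seed = seed, bin_size = design$bin_size,
    genome = as.list(design$genome),
    background_rate = design$background_rate,
    eed226_as_reduction = isTRUE(design$eed226_as_reduction),
    twist_threshold = universe$twist_threshold,
    classes = lapply(design$class_specs, function(cs)
      cs[c("name", "shape", "n_peaks", "width_range", "amplitude_range",
           "gcg_density", "cpg_like")]),
    conditions = lapply(design$conditions, function(cd)
      list(sample_id = cd$sample_id, fractions = as.list(cd$fractions),
           library_size = cd$library_size,
           spike_in_reads = cd$spike_in_reads,
           efficiency = cd$efficiency)),
    files = c("peaks.bed", "genome.fa", "twist_table.tsv", "samples.tsv",
              "tss.bed", "terms.tsv", samples$chip_track,
              samples$input_track))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = out_dir, universe = universe, design = design,
                 samples = samples, annotation = ann$annotation,
                 terms = ann$terms,
                 manifest = file.path(out_dir, "manifest.json")))
}
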
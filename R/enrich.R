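# Peak-to-gene association and hypergeometric term enrichment.  Each peak
# is assigned to the gene with the nearest TSS within a distance cap
# (Polycomb targets are predominantly promoter-proximal bivalent elements,
# hence the 10 kb default); term enrichment is an upper-tail hypergeometric
# test with Benjamini-Hochberg correction, run against either all genes or
# the PRC2-target genes as background.

#' Read a TSS annotation from a 6-column BED file
#'
#' One 1-bp interval per gene; the name column carries the gene id and the
#' strand column is kept for reporting only.
#'
#' @param path BED file path.
#' @param genome optional named vector of chromosome lengths.
#' @return data.frame with columns gene_id, chrom, tss (0-based position),
#'   strand; gene ids must be unique.
#' @export
read_tss_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stopf("TSS BED needs >= 4 columns (chrom,start,end,name)")
  out <- data.frame(gene_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    tss = as.integer(df[[2L]]),
                    strand = if (ncol(df) >= 6L) as.character(df[[6L]])
                             else "*",
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stopf("duplicate gene ids in %s", path)
  if (!is.null(genome)) {
    if (any(!out$chrom %in% names(genome)))
      stopf("TSS on chromosome absent from genome")
    if (any(out$tss < 0 | out$tss >= genome[out$chrom]))
      stopf("TSS outside chromosome bounds")
  }
  out
}

#' Read a term-to-gene mapping from a two-column TSV
#'
#' @param path TSV with columns term, gene (no header).
#' @return data.frame with columns term, gene.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("term", "gene"),
                          stringsAsFactors = FALSE)
  df
}

#' Assign peaks to the gene with the nearest TSS
#'
#' Distance is measured from the peak center to the TSS; peaks with no TSS
#' within \code{max_distance} stay unassigned (NA). Exact distance ties go
#' to the lexicographically smaller gene id.
#'
#' @param peaks a \code{PeakSet}.
#' @param annotation TSS table from \code{\link{read_tss_bed}} (non-empty).
#' @param max_distance maximum center-to-TSS distance in bp (default
#'   10,000).
#' @return character vector of gene ids (NA = unassigned), named by
#'   \code{peak_ids(peaks)}.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, max_distance = 10000) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (nrow(annotation) == 0L) stopf("empty gene annotation")
  df <- as.data.frame(peaks)
  centers <- peak_centers(peaks)
  out <- rep(NA_character_, length(peaks))
  for (ch in unique(df$chrom)) {
    pi <- which(df$chrom == ch)
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (!nrow(ann)) next
    ann <- ann[order(ann$tss, ann$gene_id), , drop = FALSE]
    for (i in pi) {
      d <- abs(ann$tss - centers[i])
      dmin <- min(d)
      if (dmin > max_distance) next
      cand <- ann$gene_id[d == dmin]
      out[i] <- sort(cand)[1L]
    }
  }
  names(out) <- peak_ids(peaks)
  out
}

#' Upper-tail hypergeometric enrichment of one term in one gene set
#'
#' Probability of observing at least the seen overlap when drawing
#' \code{|fg|} genes from the background without replacement; fold change
#' is \code{(overlap/fg_size) / (term_size/bg_size)}.
#'
#' @param fg_genes foreground gene set (must be a subset of
#'   \code{bg_genes}).
#' @param term_genes genes annotated with the term; only its intersection
#'   with the background enters the test.
#' @param bg_genes background gene universe (non-empty).
#' @param term,cluster optional labels copied into the result.
#' @return one-row data.frame: term, cluster, overlap, fg_size, term_size,
#'   bg_size, fold, p.
#' @export
hypergeometric_enrichment <- function(fg_genes, term_genes, bg_genes,
                                      term = NA_character_,
                                      cluster = NA_integer_) {
  bg <- unique(bg_genes)
  if (!length(bg)) stopf("empty background")
  fg <- unique(fg_genes)
  if (length(setdiff(fg, bg)))
    stopf("foreground contains genes outside the background")
  tg <- intersect(unique(term_genes), bg)
  overlap <- length(intersect(fg, tg))
  p <- if (length(tg) == 0L || length(fg) == 0L) 1 else
    stats::phyper(overlap - 1L, length(tg), length(bg) - length(tg),
                  length(fg), lower.tail = FALSE)
  fold <- if (length(tg) == 0L || length(fg) == 0L) NA_real_ else
    (overlap / length(fg)) / (length(tg) / length(bg))
  data.frame(term = term, cluster = cluster, overlap = overlap,
             fg_size = length(fg), term_size = length(tg),
             bg_size = length(bg), fold = fold, p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted values (monotone, capped at 1), with input range
#' validation.
#'
#' @param p_values numeric vector of p values in (0, 1].
#' @return numeric vector of q values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stopf("p values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment per cluster against a chosen background
#'
#' Builds per-cluster foreground gene sets from the peak-to-gene map
#' (deduplicated; one gene per peak but a gene may own several peaks) and
#' tests every term. Background \code{"all"} uses every annotated gene;
#' \code{"targets"} uses only genes associated with any peak (the
#' PRC2-target universe), which is what separates globally Polycomb-like
#' terms from cluster-specific ones. Terms with fewer than
#' \code{min_term_size} background genes are skipped and reported in the
#' \code{"skipped_terms"} attribute.
#'
#' @param assignment a \code{pkmeans} fit or named integer vector of
#'   cluster labels (names = peak ids).
#' @param peak2gene named character vector from
#'   \code{\link{assign_peaks_to_genes}}.
#' @param terms term-to-gene table from \code{\link{read_term_map}}.
#' @param annotation TSS table (defines the all-genes universe).
#' @param background \code{"all"} or \code{"targets"}.
#' @param min_term_size minimum term size in the background (default 3).
#' @return data.frame of \code{\link{hypergeometric_enrichment}} rows with
#'   a BH-adjusted \code{q} column (adjusted over the whole table).
#' @export
enrich_clusters <- function(assignment, peak2gene, terms, annotation,
                            background = c("all", "targets"),
                            min_term_size = 3L) {
  background <- match.arg(background)
  labels <- if (inherits(assignment, "pkmeans")) assignment$labels
            else assignment
  target_genes <- unique(stats::na.omit(peak2gene[names(labels)]))
  bg <- if (background == "all") unique(annotation$gene_id) else target_genes
  term_sets <- split(terms$gene, terms$term)
  term_sizes <- vapply(term_sets, function(g)
    length(intersect(unique(g), bg)), 0L)
  skipped <- names(term_sets)[term_sizes < min_term_size]
  term_sets <- term_sets[term_sizes >= min_term_size]
  rows <- list()
  for (cl in sort(unique(labels))) {
    fg <- unique(stats::na.omit(peak2gene[names(labels)[labels == cl]]))
    fg <- intersect(fg, bg)
    for (tm in names(term_sets))
      rows[[length(rows) + 1L]] <-
        hypergeometric_enrichment(fg, term_sets[[tm]], bg,
                                  term = tm, cluster = cl)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  attr(out, "skipped_terms") <- skipped
  attr(out, "background") <- background
  out
}
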
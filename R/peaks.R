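# Peak intervals are stored as a GRanges internally (1-based, closed, the
# Bioconductor convention); every user-facing coordinate in this package --
# constructors, accessors, files -- follows the BED convention instead:
# 0-based, half-open.  Conversion happens in exactly one place (here).

#' Construct a PeakSet
#'
#' A PeakSet is the region universe all downstream quantification runs on:
#' a sorted collection of genomic intervals with an optional name and score
#' per interval, a source label (the antibody the peaks were called for, or
#' \code{"common"} for a merged set) and an optional genome
#' (chromosome-name to length map) used for bounds checking.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open interval bounds.
#' @param name optional character vector of labels.
#' @param score optional numeric vector.
#' @param genome optional named numeric vector of chromosome lengths (bp).
#' @param source label for the peak set (default \code{"common"}).
#' @return An object of class \code{PeakSet}.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL,
                     genome = NULL, source = "common") {
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stopf("chrom, start, end must have equal length")
  if (n > 0L) {
    if (any(!nzchar(chrom)) || any(is.na(chrom)))
      stopf("chromosome names must be non-empty")
    if (any(start != floor(start)) || any(end != floor(end)))
      stopf("coordinates must be integers")
    if (any(start < 0)) stopf("start coordinates must be >= 0")
    bad <- which(start >= end)
    if (length(bad))
      stopf("invalid interval (start >= end) at row %d: %s:%d-%d",
            bad[1L], chrom[bad[1L]], start[bad[1L]], end[bad[1L]])
  }
  if (!is.null(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome))))
      stopf("genome must be a named vector of chromosome lengths")
    miss <- setdiff(unique(chrom), names(genome))
    if (length(miss))
      stopf("chromosome(s) absent from genome: %s",
            paste(miss, collapse = ", "))
    if (n > 0L && any(end > genome[chrom]))
      stopf("interval exceeds chromosome length")
  }
  if (!is.null(name) && length(name) != n) stopf("name has wrong length")
  if (!is.null(score) && length(score) != n) stopf("score has wrong length")
  ord <- order(chrom, start, end)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[ord],
    ranges = IRanges::IRanges(start = start[ord] + 1L, end = end[ord]))
  if (!is.null(name)) gr$name <- name[ord]
  if (!is.null(score)) gr$score <- score[ord]
  structure(list(gr = gr, genome = genome, source = source),
            class = "PeakSet")
}

#' @export
length.PeakSet <- function(x) length(x$gr)

#' Coerce a PeakSet to a BED-convention data.frame
#'
#' @param x a \code{PeakSet}.
#' @param ... unused.
#' @return data.frame with columns chrom, start, end (0-based half-open)
#'   and, when present, name and score.
#' @export
as.data.frame.PeakSet <- function(x, ...) {
  gr <- x$gr
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df
}

#' @export
`[.PeakSet` <- function(x, i) {
  out <- x
  out$gr <- x$gr[i]
  out
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d intervals on %d chromosome(s)\n",
              x$source, length(x),
              length(unique(as.character(GenomicRanges::seqnames(x$gr))))))
  if (length(x)) {
    df <- as.data.frame(x)
    print(utils::head(df, 5L))
    if (nrow(df) > 5L) cat(sprintf("... and %d more\n", nrow(df) - 5L))
  }
  invisible(x)
}

#' Peak names
#'
#' Canonical per-peak identifiers: the BED name field when present and
#' unique, otherwise \code{chrom:start-end} in BED coordinates.
#' @param x a \code{PeakSet}.
#' @return character vector.
#' @export
peak_ids <- function(x) {
  df <- as.data.frame(x)
  sprintf("%s:%d-%d", df$chrom, df$start, df$end)
}

#' Peak class labels (BED name field), if present
#' @param x a \code{PeakSet}.
#' @return character vector or NULL.
#' @export
peak_names <- function(x) x$gr$name

#' Peak centers
#'
#' The center of a peak with 0-based half-open bounds \code{[start, end)} is
#' \code{floor((start + end) / 2)}, a 0-based position.
#'
#' @param x a \code{PeakSet}.
#' @return integer vector of 0-based center positions.
#' @export
peak_centers <- function(x) {
  df <- as.data.frame(x)
  (df$start + df$end) %/% 2L
}

#' Read a BED file into a PeakSet
#'
#' Accepts 3- to 6-column BED. Malformed lines (fewer than three fields,
#' non-integer coordinates, start >= end) raise an error naming the
#' offending line; they are never skipped silently. An empty file yields an
#' empty PeakSet.
#'
#' @param path file path.
#' @param genome optional named vector of chromosome lengths.
#' @param source label for the returned set (default: file base name).
#' @return A \code{PeakSet}, sorted by (chrom, start).
#' @export
read_bed <- function(path, genome = NULL, source = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  source <- source %||% sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(peak_set(character(), integer(), integer(),
                    genome = genome, source = source))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("%s: line %d has %d field(s); BED needs >= 3",
          path, which(nf < 3L)[1L], min(nf))
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  if (any(!grepl("^-?[0-9]+$", s_chr)) || any(!grepl("^-?[0-9]+$", e_chr))) {
    bad <- which(!grepl("^-?[0-9]+$", s_chr) | !grepl("^-?[0-9]+$", e_chr))[1L]
    stopf("%s: non-integer coordinate on line %d", path, bad)
  }
  start <- as.integer(s_chr); end <- as.integer(e_chr)
  name <- if (any(nf >= 4L))
    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  score <- if (any(nf >= 5L))
    suppressWarnings(as.numeric(vapply(
      fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
  peak_set(chrom, start, end, name = name, score = score,
           genome = genome, source = source)
}

#' Write a PeakSet to a BED file
#'
#' Coordinates are written in BED convention, bit-exact with what
#' \code{read_bed} returns, so write/read round-trips are the identity.
#'
#' @param x a \code{PeakSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Union-merge peak sets into a common region set
#'
#' Builds the common region universe from several peak sets: the union of
#' all intervals, with intervals closer than or exactly \code{gap} bp merged
#' into one. Output intervals are pairwise disjoint and separated by more
#' than \code{gap} bp, and every input base pair is covered by exactly one
#' output interval.
#'
#' @param peak_sets list of \code{PeakSet} objects sharing one genome.
#' @param gap non-negative integer: merge intervals separated by <= gap bp.
#' @return A \code{PeakSet} with source \code{"common"}.
#' @export
merge_union <- function(peak_sets, gap = 0L) {
  stopifnot(length(peak_sets) >= 1L, gap >= 0)
  genomes <- lapply(peak_sets, `[[`, "genome")
  genome <- genomes[[1L]]
  for (g in genomes[-1L]) {
    if (!identical(is.null(g), is.null(genome)) ||
        (!is.null(g) && !identical(sort(names(g)), sort(names(genome))) ) ||
        (!is.null(g) && !identical(g[sort(names(g))], genome[sort(names(genome))])))
      stopf("peak sets have inconsistent genomes")
  }
  grl <- lapply(peak_sets, `[[`, "gr")
  all_gr <- suppressWarnings(do.call(c, lapply(grl, function(g) {
    GenomicRanges::granges(g)
  })))
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = gap + 1L)
  merged <- GenomicRanges::sort(merged)
  peak_set(as.character(GenomicRanges::seqnames(merged)),
           GenomicRanges::start(merged) - 1L,
           GenomicRanges::end(merged),
           genome = genome, source = "common")
}
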
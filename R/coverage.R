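# Coverage is held per chromosome as a run-length-encoded step function at
# base-pair resolution (an IRanges::RleList).  The depth unit throughout is
# "reads per bin at the track's bin size": a bedGraph produced by binned
# counting stores one value per bin, and that value is replicated across the
# bin's base pairs, so window means read off mean reads-per-bin directly.

#' Construct a CoverageTrack from per-chromosome bin vectors
#'
#' @param bins named list of numeric vectors, one per chromosome, each
#'   holding the read count per consecutive bin of \code{bin_size} bp.
#' @param bin_size bin width in bp.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param library_size total mapped reads in the library (> 0).
#' @param spike_in_reads optional count of reads mapping to the exogenous
#'   spike-in genome.
#' @param sample_id sample identifier, conventionally
#'   "antibody.genotype.treatment".
#' @return An object of class \code{CoverageTrack}.
#' @export
coverage_track <- function(bins, bin_size, genome, library_size,
                           spike_in_reads = NA_real_, sample_id = "sample") {
  stopifnot(is.list(bins), !is.null(names(bins)))
  if (!all(names(bins) %in% names(genome)))
    stopf("bins contain chromosomes absent from genome")
  if (library_size <= 0) stopf("library_size must be > 0")
  cov <- IRanges::RleList(lapply(names(bins), function(ch) {
    v <- bins[[ch]]
    if (any(v < 0)) stopf("negative depth on %s", ch)
    len <- as.integer(genome[[ch]])
    need <- ceiling(len / bin_size)
    if (length(v) < need)
      stopf("bin vector for %s too short (%d bins, need %d)",
            ch, length(v), need)
    widths <- rep.int(bin_size, length(v))
    widths[length(v)] <- len - bin_size * (length(v) - 1L)
    S4Vectors::Rle(values = v, lengths = widths)
  }), compress = FALSE)
  names(cov) <- names(bins)
  new_coverage_track(cov, bin_size, genome, library_size, spike_in_reads,
                     sample_id)
}

new_coverage_track <- function(cov, bin_size, genome, library_size,
                               spike_in_reads, sample_id,
                               normalization = "raw", scale_factor = 1) {
  structure(list(cov = cov, bin_size = bin_size, genome = genome,
                 library_size = library_size,
                 spike_in_reads = spike_in_reads,
                 sample_id = sample_id, normalization = normalization,
                 scale_factor = scale_factor),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf(
    "CoverageTrack '%s' (%s): %d chromosome(s), bin %d bp, library %.3g reads%s\n",
    x$sample_id, x$normalization, length(x$cov), x$bin_size, x$library_size,
    if (is.finite(x$spike_in_reads))
      sprintf(", spike-in %.3g reads", x$spike_in_reads) else ""))
  invisible(x)
}

#' Genome-wide mean depth of a track
#'
#' Mean depth (reads per bin) over all covered base pairs. For the robust
#' background estimate used by enrichment criteria see
#' \code{\link{track_background}}.
#' @param track a \code{CoverageTrack}.
#' @return numeric scalar.
#' @export
track_mean <- function(track) {
  tot <- sum(vapply(track$cov, function(r)
    sum(as.double(S4Vectors::runValue(r)) * S4Vectors::runLength(r)), 0))
  tot / sum(vapply(track$cov, length, 0L))
}

#' Genome-wide background depth of a track
#'
#' The background level is estimated as the weighted median of the per-bp
#' depth: unlike the mean it is not inflated by the enriched regions
#' themselves, which matters when peaks cover a non-negligible fraction of
#' the genome.
#' @param track a \code{CoverageTrack}.
#' @return numeric scalar.
#' @export
track_background <- function(track) {
  vals <- unlist(lapply(track$cov, function(r)
    as.double(S4Vectors::runValue(r))), use.names = FALSE)
  lens <- unlist(lapply(track$cov, function(r)
    S4Vectors::runLength(r)), use.names = FALSE)
  ord <- order(vals)
  cum <- cumsum(as.double(lens[ord]))
  vals[ord][which(cum >= sum(as.double(lens)) / 2)[1L]]
}

#' Read a bedGraph coverage file
#'
#' The file is parsed with \code{rtracklayer}; values are interpreted as
#' reads per bin at \code{bin_size} resolution. Regions absent from the file
#' have depth 0.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param genome named numeric vector of chromosome lengths.
#' @param bin_size bin width the values were computed at (bp).
#' @inheritParams coverage_track
#' @return A \code{CoverageTrack}.
#' @export
read_bedgraph <- function(path, genome, bin_size = 50L, library_size = 1e6,
                          spike_in_reads = NA_real_, sample_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sample_id <- sample_id %||% sub("\\.(bedgraph|bg)$", "", basename(path),
                                  ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  bad <- setdiff(as.character(GenomeInfoDb::seqlevels(gr)), names(genome))
  if (length(bad))
    stopf("%s covers chromosome(s) absent from genome: %s", path,
          paste(bad, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- unname(genome)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  new_coverage_track(cov, bin_size, genome, library_size, spike_in_reads,
                     sample_id)
}

#' Read a coverage file (bedGraph or bigWig)
#'
#' Dispatches on file extension: \code{.bedgraph}/\code{.bg} via
#' \code{\link{read_bedgraph}}, \code{.bw}/\code{.bigwig} via
#' \code{rtracklayer}'s bigWig reader.
#'
#' @inheritParams read_bedgraph
#' @return A \code{CoverageTrack}.
#' @export
read_coverage <- function(path, genome, bin_size = 50L, library_size = 1e6,
                          spike_in_reads = NA_real_, sample_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bedgraph", "bg"))
    return(read_bedgraph(path, genome, bin_size, library_size,
                         spike_in_reads, sample_id))
  if (ext %in% c("bw", "bigwig")) {
    sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
    cov <- rtracklayer::import(path, as = "RleList")
    cov <- cov[intersect(names(cov), names(genome))]
    return(new_coverage_track(cov, bin_size, genome, library_size,
                              spike_in_reads, sample_id))
  }
  stopf("unsupported coverage format: .%s", ext)
}

#' Write a CoverageTrack as bedGraph
#'
#' Runs of equal depth are collapsed; zero-depth runs are written too, so a
#' write/read round-trip reproduces the track exactly.
#'
#' @param track a \code{CoverageTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- as(track$cov, "GRanges")
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# ---------------------------------------------------------------------------
# SignalMatrix

#' Construct a SignalMatrix from its parts
#'
#' Mostly used by \code{\link{extract_signal_matrix}}; exposed so matrices
#' can be assembled directly (e.g. from external quantifications).
#'
#' @param values peaks x bins numeric matrix (row names = peak ids).
#' @param half_window,bin_size window geometry in bp; the column count
#'   must equal \code{2 * half_window / bin_size}.
#' @param sample_id sample identifier.
#' @param normalization tag: raw, rpkm, input_subtracted, wt_normalized or
#'   spikein_scaled.
#' @param track_mean,track_background genome-wide mean and background
#'   depth of the source track.
#' @param library_size,spike_in_reads library metadata.
#' @return A \code{SignalMatrix}.
#' @export
signal_matrix <- function(values, half_window, bin_size,
                          sample_id = "sample", normalization = "raw",
                          track_mean = NA_real_,
                          track_background = NA_real_,
                          library_size = NA_real_,
                          spike_in_reads = NA_real_) {
  new_signal_matrix(values, half_window, bin_size, sample_id,
                    normalization, track_mean, track_background,
                    library_size, spike_in_reads)
}

new_signal_matrix <- function(values, half_window, bin_size, sample_id,
                              normalization = "raw", track_mean = NA_real_,
                              track_background = NA_real_,
                              library_size = NA_real_,
                              spike_in_reads = NA_real_) {
  stopifnot(is.matrix(values))
  if (ncol(values) != 2 * half_window / bin_size)
    stopf("column count must equal 2*half_window/bin_size")
  structure(list(values = values, half_window = half_window,
                 bin_size = bin_size, sample_id = sample_id,
                 normalization = normalization, track_mean = track_mean,
                 track_background = track_background,
                 library_size = library_size,
                 spike_in_reads = spike_in_reads),
            class = "SignalMatrix")
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf(
    "SignalMatrix '%s' (%s): %d peaks x %d bins (+/-%d bp at %d bp)\n",
    x$sample_id, x$normalization, nrow(x$values), ncol(x$values),
    x$half_window, x$bin_size))
  invisible(x)
}

#' @export
dim.SignalMatrix <- function(x) dim(x$values)

#' Extract a peak-centered binned signal matrix from a coverage track
#'
#' Row i holds the mean depth per bin over the window
#' \code{[center - half_window, center + half_window)} of peak i, where the
#' center is \code{floor((start + end)/2)} in BED coordinates. Windows
#' running past a chromosome edge are zero-padded. A peak on a chromosome
#' absent from the track is a hard error (silent zeros would corrupt
#' WT-normalized percentages downstream).
#'
#' @param track a \code{CoverageTrack}.
#' @param peaks a \code{PeakSet} (non-empty).
#' @param half_window half window width in bp (multiple of \code{bin_size}).
#' @param bin_size bin width in bp.
#' @return A \code{SignalMatrix} with rows in \code{peaks} order, row names
#'   \code{peak_ids(peaks)}, and the track's genome-wide mean depth and
#'   library metadata attached for downstream normalization.
#' @export
extract_signal_matrix <- function(track, peaks, half_window = 1000L,
                                  bin_size = 50L) {
  stopifnot(inherits(track, "CoverageTrack"), inherits(peaks, "PeakSet"))
  if (length(peaks) == 0L) stopf("peaks must be non-empty")
  if (half_window %% bin_size != 0)
    stopf("half_window must be a multiple of bin_size")
  df <- as.data.frame(peaks)
  miss <- setdiff(unique(df$chrom), names(track$cov))
  if (length(miss))
    stopf("peak chromosome(s) absent from track: %s",
          paste(miss, collapse = ", "))
  centers <- peak_centers(peaks)
  nbin <- as.integer(2 * half_window / bin_size)
  values <- matrix(0, nrow = nrow(df), ncol = nbin)
  for (i in seq_len(nrow(df))) {
    r <- track$cov[[df$chrom[i]]]
    L <- length(r)
    w1 <- centers[i] - half_window + 1L   # 1-based inclusive
    w2 <- centers[i] + half_window
    v <- numeric(2L * half_window)
    s <- max(w1, 1L); e <- min(w2, L)
    if (s <= e)
      v[(s - w1 + 1L):(e - w1 + 1L)] <- as.numeric(S4Vectors::window(r, s, e))
    values[i, ] <- colMeans(matrix(v, nrow = bin_size))
  }
  rownames(values) <- peak_ids(peaks)
  new_signal_matrix(values, half_window, bin_size, track$sample_id,
                    normalization = track$normalization,
                    track_mean = track_mean(track),
                    track_background = track_background(track),
                    library_size = track$library_size,
                    spike_in_reads = track$spike_in_reads)
}

#' Per-row enrichment over track background
#'
#' A row (peak window) counts as enriched when its mean signal exceeds
#' \code{enrichment_threshold} times the genome-wide background depth (the
#' weighted median bin depth, see \code{\link{track_background}}) of the
#' track the matrix was extracted from.
#'
#' @param query a \code{SignalMatrix}.
#' @param enrichment_threshold fold over background (default 2).
#' @return logical vector, one element per row.
#' @export
row_enriched <- function(query, enrichment_threshold = 2) {
  stopifnot(inherits(query, "SignalMatrix"))
  bg <- query$track_background
  if (!is.finite(bg) || bg <= 0)
    stopf("track background is zero or unknown")
  rowMeans(query$values) > enrichment_threshold * bg
}

#' Fraction of reference peaks occupied by a second mark
#'
#' Quantifies co-occupancy: the fraction of reference peaks whose window
#' signal in \code{query} exceeds \code{enrichment_threshold} times the
#' query track's genome-wide background mean.
#'
#' @param ref_peaks the \code{PeakSet} whose rows \code{query} was
#'   extracted over.
#' @param query a \code{SignalMatrix} of the companion mark over the same
#'   peaks.
#' @param enrichment_threshold fold over background (default 2).
#' @return fraction in \code{[0, 1]}.
#' @export
occupancy_fraction <- function(ref_peaks, query, enrichment_threshold = 2) {
  stopifnot(inherits(ref_peaks, "PeakSet"))
  if (nrow(query$values) != length(ref_peaks))
    stopf("query rows (%d) do not match ref_peaks (%d)",
          nrow(query$values), length(ref_peaks))
  mean(row_enriched(query, enrichment_threshold))
}

#' Write a SignalMatrix to a plain-text archive
#'
#' Tab-separated matrix preceded by '#key value' header lines carrying
#' every SignalMatrix field, so \code{\link{read_signal_matrix}} restores
#' the object exactly.
#'
#' @param x a \code{SignalMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(half_window = x$half_window, bin_size = x$bin_size,
            sample_id = x$sample_id, normalization = x$normalization,
            track_mean = x$track_mean,
            track_background = x$track_background,
            library_size = x$library_size,
            spike_in_reads = x$spike_in_reads)
  writeLines(sprintf("#%s\t%s", names(meta), as.character(meta)), con)
  utils::write.table(x$values, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a SignalMatrix archive written by \code{write_signal_matrix}
#' @param path archive path.
#' @return A \code{SignalMatrix}.
#' @export
read_signal_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, `[[`, "", 2L),
                        vapply(meta, `[[`, "", 1L))
  body <- utils::read.table(text = lines[-hdr], sep = "\t",
                            row.names = 1L, header = FALSE)
  values <- as.matrix(body)
  colnames(values) <- NULL
  new_signal_matrix(values,
                    half_window = as.numeric(kv[["half_window"]]),
                    bin_size = as.numeric(kv[["bin_size"]]),
                    sample_id = kv[["sample_id"]],
                    normalization = kv[["normalization"]],
                    track_mean = as.numeric(kv[["track_mean"]]),
                    track_background = as.numeric(kv[["track_background"]]),
                    library_size = as.numeric(kv[["library_size"]]),
                    spike_in_reads = as.numeric(kv[["spike_in_reads"]]))
}
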
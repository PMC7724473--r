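# Signal normalizations.  The normalization tag on a value moves along
#   raw -> rpkm -> input_subtracted -> (wt_normalized | spikein_scaled)
# and the per-region value tables produced here carry that tag so misuse
# (e.g. subtracting input from an already-subtracted value) errors early.

#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = read_count / ((region_length/1000) * (library_size/1e6))}.
#' Vectorized over \code{read_count} and \code{region_length}.
#'
#' @param read_count reads in the region (>= 0).
#' @param region_length region length in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(read_count, region_length, library_size) {
  if (any(region_length <= 0)) stopf("region_length must be > 0")
  if (any(library_size <= 0)) stopf("library_size must be > 0")
  read_count / ((region_length / 1000) * (library_size / 1e6))
}

#' Per-peak RPKM quantification of a signal matrix
#'
#' The per-peak read count is taken from the coverage itself (mean binned
#' depth times the number of bins in the window); no read-level recounting
#' is done. The region length is the full window (2 x half_window).
#'
#' @param sm a \code{SignalMatrix} with \code{normalization = "raw"}.
#' @param library_size total mapped reads; defaults to the library size
#'   recorded on the matrix.
#' @return data.frame with columns region_id, value, normalization
#'   (\code{"rpkm"}), sample_id.
#' @export
quantify_peaks <- function(sm, library_size = NULL) {
  stopifnot(inherits(sm, "SignalMatrix"))
  if (sm$normalization != "raw")
    stopf("quantify_peaks expects a raw matrix, got '%s'", sm$normalization)
  library_size <- library_size %||% sm$library_size
  if (!is.finite(library_size)) stopf("library_size unknown")
  counts <- rowMeans(sm$values) * ncol(sm$values)
  data.frame(region_id = rownames(sm$values),
             value = rpkm(counts, 2 * sm$half_window, library_size),
             normalization = "rpkm", sample_id = sm$sample_id,
             stringsAsFactors = FALSE)
}

#' Subtract input signal from ChIP signal
#'
#' Values must both be RPKM-normalized and cover the same regions in the
#' same order. Negative differences are retained, not clamped: clamping
#' before medians would bias cluster-level quantification.
#'
#' @param chip,input per-region value tables as returned by
#'   \code{\link{quantify_peaks}}.
#' @return table like \code{chip} with \code{value = chip - input} and
#'   normalization tag \code{"input_subtracted"}.
#' @export
input_subtract <- function(chip, input) {
  if (!all(chip$normalization == "rpkm") ||
      !all(input$normalization == "rpkm"))
    stopf("input_subtract requires rpkm-normalized values")
  if (!identical(chip$region_id, input$region_id))
    stopf("chip and input cover different regions")
  out <- chip
  out$value <- chip$value - input$value
  out$normalization <- "input_subtracted"
  out
}

#' Express a condition-level statistic as a percentage of wild type
#'
#' @param condition_stat statistic (e.g. cluster median input-subtracted
#'   RPKM) in the perturbed condition.
#' @param wt_stat the same statistic in wild type (non-zero).
#' @return \code{100 * condition_stat / wt_stat} (percent).
#' @export
wt_percent <- function(condition_stat, wt_stat) {
  if (any(wt_stat == 0, na.rm = TRUE))
    stopf("WT statistic is zero; percentage undefined")
  100 * condition_stat / wt_stat
}

#' Scale a coverage track by its spike-in factor
#'
#' Depths are multiplied by \code{reference_spike_reads / spike_in_reads},
#' putting samples with different ChIP efficiencies on the exogenous
#' spike-in scale.
#'
#' @param track a \code{CoverageTrack} with known \code{spike_in_reads}.
#' @param reference_spike_reads spike-in reads of the reference sample.
#' @return A new \code{CoverageTrack} tagged \code{"spikein_scaled"}.
#' @export
spike_in_scale <- function(track, reference_spike_reads) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (!is.finite(track$spike_in_reads) || track$spike_in_reads <= 0)
    stopf("track has no spike-in read count")
  if (reference_spike_reads <= 0) stopf("reference spike-in must be > 0")
  f <- reference_spike_reads / track$spike_in_reads
  cov <- IRanges::RleList(lapply(track$cov, function(r) r * f),
                          compress = FALSE)
  names(cov) <- names(track$cov)
  new_coverage_track(cov, track$bin_size, track$genome, track$library_size,
                     track$spike_in_reads, track$sample_id,
                     normalization = "spikein_scaled",
                     scale_factor = track$scale_factor * f)
}

#' Concordance between two per-region quantifications
#'
#' Pearson correlation of paired per-region values, the diagnostic used to
#' compare spike-in scaling with per-million (RPKM) scaling.
#'
#' @param values_a,values_b equal-length numeric vectors (length >= 3) with
#'   non-zero variance.
#' @return correlation in \code{[-1, 1]}.
#' @export
normalization_concordance <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stopf("unequal lengths")
  if (length(values_a) < 3L) stopf("need at least 3 paired values")
  if (stats::var(values_a) == 0 || stats::var(values_b) == 0)
    stopf("zero variance")
  stats::cor(values_a, values_b)
}
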
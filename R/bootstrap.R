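# Cluster-level bootstrap quantification.  The exchangeable unit is the
# peak: each bootstrap round draws peaks within a (condition x cluster)
# cell with replacement and records the median (the plotted dots) and the
# mean of the resample; the confidence interval is the central percentile
# interval of the bootstrapped means (a switch offers CI-of-medians).
# Resampling uses integer indices only, so results are reproducible across
# platforms for a fixed seed.

#' Bootstrap medians of a value vector
#'
#' Each entry is the median of a with-replacement resample of size
#' \code{length(values)}; deterministic for a fixed seed.
#'
#' @param values non-empty numeric vector (per-peak normalized signal).
#' @param n_boot number of bootstrap rounds (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length \code{n_boot}.
#' @export
bootstrap_medians <- function(values, n_boot, seed) {
  boot_stats(values, n_boot, seed)$medians
}

boot_stats <- function(values, n_boot, seed) {
  n <- length(values)
  if (n == 0L) stopf("values must be non-empty")
  if (n_boot < 1L) stopf("n_boot must be >= 1")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  res <- matrix(values[idx], nrow = n)
  list(medians = apply(res, 2L, stats::median), means = colMeans(res))
}

#' Central percentile interval
#'
#' The \code{[(100 - level)/2, 100 - (100 - level)/2]} percentiles of the
#' bootstrap distribution, with linear interpolation between order
#' statistics (\code{quantile} type 7).
#'
#' @param samples numeric vector of bootstrap statistics (length >= 2).
#' @param level confidence level in percent, in (0, 100).
#' @return numeric vector \code{c(low, high)}.
#' @export
ci_percentile <- function(samples, level) {
  if (length(samples) < 2L) stopf("need at least 2 samples")
  if (level <= 0 || level >= 100) stopf("level must be in (0, 100)")
  a <- (100 - level) / 200
  unname(stats::quantile(samples, c(a, 1 - a), type = 7, names = FALSE))
}

#' Bootstrap summary per condition and cluster
#'
#' For every (condition x cluster) cell, resamples the member peaks'
#' values, records \code{n_boot} bootstrap medians and means, the
#' percentile confidence interval, a point estimate (the median of the
#' bootstrapped medians) and, when a wild-type condition is named, the
#' WT-normalized percentage of the point estimate.
#'
#' Peaks are sorted by id before resampling, so the result is invariant to
#' the order the values arrive in; each cell resamples from its own
#' deterministic sub-seed of \code{seed}.
#'
#' @param values named list (one element per condition) of numeric vectors
#'   named by peak id: per-peak normalized signal, typically
#'   input-subtracted RPKM from \code{\link{input_subtract}}.
#' @param assignment a \code{pkmeans} fit (or any named integer vector of
#'   cluster labels) covering the peaks.
#' @param n_boot bootstrap rounds per cell (default 1000).
#' @param level confidence level in percent (default 99.9).
#' @param seed integer seed.
#' @param wt optional name of the wild-type condition in \code{values};
#'   when given, a \code{wt_percent} column is added.
#' @param ci_of \code{"mean"} (default: CI of the bootstrapped means) or
#'   \code{"median"}.
#' @return An object of class \code{bootstrap_summary}: \code{$table}
#'   (condition, cluster, n_peaks, point_estimate, ci_low, ci_high,
#'   optional wt_percent, flag) and \code{$draws}, the per-cell bootstrap
#'   medians and means. Cells with fewer than 2 peaks are flagged and get
#'   an undefined (NA) interval.
#' @export
summarize_bootstrap <- function(values, assignment, n_boot = 1000L,
                                level = 99.9, seed, wt = NULL,
                                ci_of = c("mean", "median")) {
  ci_of <- match.arg(ci_of)
  if (missing(seed)) stopf("seed is mandatory")
  labels <- if (inherits(assignment, "pkmeans")) assignment$labels
            else assignment
  if (is.null(names(labels))) stopf("assignment must carry peak ids")
  if (!is.list(values) || is.null(names(values)))
    stopf("values must be a named list of per-condition vectors")
  conditions <- names(values)
  clusters <- sort(unique(labels))
  rows <- list(); draws <- list()
  for (ci in seq_along(conditions)) {
    v <- values[[ci]]
    if (is.null(names(v))) stopf("per-condition values must be named by peak id")
    miss <- setdiff(names(labels), names(v))
    if (length(miss))
      stopf("condition '%s' lacks values for %d assigned peak(s)",
            conditions[ci], length(miss))
    for (cl in clusters) {
      ids <- sort(names(labels)[labels == cl])
      x <- v[ids]
      cell_seed <- sub_seed(seed, 1000L * ci + cl)
      if (length(x) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = conditions[ci], cluster = cl, n_peaks = length(x),
          point_estimate = if (length(x)) stats::median(x) else NA_real_,
          ci_low = NA_real_, ci_high = NA_real_,
          flag = "too_few_peaks", stringsAsFactors = FALSE)
        draws[[paste(conditions[ci], cl, sep = ".")]] <-
          list(medians = numeric(), means = numeric())
        next
      }
      bs <- boot_stats(x, n_boot, cell_seed)
      ci_int <- ci_percentile(if (ci_of == "mean") bs$means else bs$medians,
                              level)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = conditions[ci], cluster = cl, n_peaks = length(x),
        point_estimate = stats::median(bs$medians),
        ci_low = ci_int[1L], ci_high = ci_int[2L], flag = "",
        stringsAsFactors = FALSE)
      draws[[paste(conditions[ci], cl, sep = ".")]] <- bs
    }
  }
  table <- do.call(rbind, rows)
  if (!is.null(wt)) {
    if (!wt %in% conditions) stopf("wt condition '%s' not in values", wt)
    wt_pt <- table$point_estimate[table$condition == wt]
    names(wt_pt) <- table$cluster[table$condition == wt]
    table$wt_percent <- wt_percent(table$point_estimate,
                                   wt_pt[as.character(table$cluster)])
  }
  structure(list(table = table, draws = draws, level = level,
                 n_boot = n_boot, seed = seed, ci_of = ci_of, wt = wt),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "Bootstrap summary: %d cells, %d rounds each, %.4g%% percentile CI of the %s\n",
    nrow(x$table), x$n_boot, x$level, x$ci_of))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
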
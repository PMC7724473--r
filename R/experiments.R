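# Self-contained simulation experiments that measure how well the
# pipeline recovers known truths.  These are the package's calibration
# harness: parameter recovery of planted residual fractions, spike-in
# versus per-million normalization behaviour under efficiency and global
# signal shifts, and empirical coverage of the bootstrap interval.

recovery_classes <- function(n_per_class) list(
  peak_class_spec("narrow", "narrow", n_per_class, c(800, 1600),
                  c(20, 35), 8),
  peak_class_spec("broad", "broad", n_per_class, c(1800, 2100),
                  c(10, 16), 2))

#' Recovery of planted residual fractions by the bootstrap point estimate
#'
#' Simulates one wild-type condition and one perturbed condition per
#' requested fraction (the same residual fraction for both planted
#' classes), runs the quantification path (peak-centered matrices, RPKM,
#' input subtraction, bootstrap medians per class, WT-normalization) with
#' the planted class labels as the cluster assignment, and reports the
#' estimated WT-normalized percentage next to the simulated truth.
#'
#' @param fractions residual fractions to plant (default
#'   \code{c(0.10, 0.25, 0.50, 0.85)}).
#' @param n_per_class peaks per class (default 300).
#' @param seed integer seed.
#' @param n_boot bootstrap rounds (default 500).
#' @return data.frame: condition, class, fraction_true,
#'   estimated_percent, error_pp (estimated minus true, percentage
#'   points).
#' @export
fraction_recovery_experiment <- function(fractions = c(.10, .25, .50, .85),
                                         n_per_class = 300, seed,
                                         n_boot = 500L) {
  if (missing(seed)) stopf("seed is mandatory")
  genome <- c(chrA = 2.5e6, chrB = 2.5e6)
  uni <- generate_universe(recovery_classes(n_per_class), genome,
                           seed = sub_seed(seed, 1L))
  cls <- c(narrow = 1, broad = 1)
  conds <- c(list(condition_spec("ezh2", "WT", "none", cls,
                                 library_size = 2e7)),
             lapply(seq_along(fractions), function(i)
               condition_spec("ezh2", sprintf("mut%d", i), "none",
                              cls * fractions[i], library_size = 2e7)))
  labels <- stats::setNames(match(peak_names(uni$peaks),
                                  c("narrow", "broad")),
                            peak_ids(uni$peaks))
  vals <- list()
  for (i in seq_along(conds)) {
    tr <- simulate_coverage(uni, conds[[i]], seed = sub_seed(seed, 10L + i))
    chip <- extract_signal_matrix(tr$chip, uni$peaks, 1000L, 50L)
    input <- extract_signal_matrix(tr$input, uni$peaks, 1000L, 50L)
    q <- input_subtract(quantify_peaks(chip), quantify_peaks(input))
    vals[[conds[[i]]$sample_id]] <- stats::setNames(q$value, q$region_id)
  }
  bs <- summarize_bootstrap(vals, labels, n_boot = n_boot, level = 99,
                            seed = sub_seed(seed, 2L),
                            wt = "ezh2.WT.none")
  tab <- bs$table[bs$table$condition != "ezh2.WT.none", ]
  idx <- as.integer(sub("^ezh2\\.mut(\\d+)\\..*$", "\\1", tab$condition))
  data.frame(condition = tab$condition,
             class = c("narrow", "broad")[tab$cluster],
             fraction_true = fractions[idx],
             estimated_percent = tab$wt_percent,
             error_pp = tab$wt_percent - 100 * fractions[idx],
             row.names = NULL)
}

#' Spike-in versus per-million normalization under a global signal shift
#'
#' Simulates a series of samples over one peak universe whose true
#' genome-wide occupancy varies, under a fixed-sequencing-depth model:
#' every library is sequenced to the same total, so when global occupancy
#' drops the remaining reads are redistributed (observed depths are
#' compressed or inflated by the composition factor), and the constant
#' exogenous spike-in chromatin claims a correspondingly larger read share
#' -- spike-in reads end up inversely proportional to the global occupancy
#' level. Per-million (RPKM) scaling therefore mis-estimates the
#' between-sample ratio while spike-in scaling recovers it.
#'
#' @param signal_levels true per-sample occupancy multipliers (first
#'   sample is the reference; default \code{c(1, .8, .6, .4, .25)}).
#' @param n_peaks peaks in the universe (default 300).
#' @param spike_share spike-in chromatin mass as a fraction of the
#'   reference sample's genome mass (default 0.05).
#' @param seed integer seed.
#' @return data.frame: sample, signal_true, spike_in_reads, mean_rpkm,
#'   mean_spike_scaled, plus attribute \code{"ratios"} with the
#'   last-vs-first sample ratio under truth, RPKM and spike-in scaling.
#' @export
spikein_experiment <- function(signal_levels = c(1, .8, .6, .4, .25),
                               n_peaks = 300, spike_share = 0.05, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  genome <- c(chrA = 2.5e6, chrB = 2.5e6)
  uni <- generate_universe(
    list(peak_class_spec("narrow", "narrow", n_peaks, c(800, 1600),
                         c(20, 35), 8)),
    genome, seed = sub_seed(seed, 1L))
  df <- as.data.frame(uni$peaks)
  # expected signal mass (reads) at occupancy 1, from the planted profiles
  mass <- sum(vapply(seq_len(nrow(df)), function(i) {
    w <- df$end[i] - df$start[i]
    mids <- seq(25, w, by = 50) - w / 2
    df$score[i] * sum(profile_weight("narrow", w, mids))
  }, 0))
  nbins <- sum(ceiling(genome / 50))
  bg_mass <- nbins  # background rate 1 read per bin
  M1 <- bg_mass + mass
  Fmass <- spike_share * M1
  spike_base <- 3e5
  rows <- list()
  for (i in seq_along(signal_levels)) {
    g <- signal_levels[i]
    Ms <- bg_mass + g * mass
    Cs <- (M1 + Fmass) / (Ms + Fmass)   # fixed-total-sequencing compression
    geno <- if (i == 1L) "WT" else sprintf("cond%d", i)
    cond <- condition_spec("ezh2", geno, "none", c(narrow = g),
                           efficiency = Cs, library_size = M1 + Fmass,
                           spike_in_reads = round(spike_base * Cs))
    tr <- simulate_coverage(uni, cond, seed = sub_seed(seed, 10L + i))
    sm_raw <- extract_signal_matrix(tr$chip, uni$peaks, 1000L, 50L)
    sm_in <- extract_signal_matrix(tr$input, uni$peaks, 1000L, 50L)
    scaled <- spike_in_scale(tr$chip, reference_spike_reads = spike_base)
    sm_sc <- extract_signal_matrix(scaled, uni$peaks, 1000L, 50L)
    q <- input_subtract(quantify_peaks(sm_raw), quantify_peaks(sm_in))
    rows[[i]] <- data.frame(sample = cond$sample_id, signal_true = g,
                            spike_in_reads = cond$spike_in_reads,
                            mean_rpkm = mean(q$value),
                            mean_spike_scaled =
                              mean(sm_sc$values) - mean(sm_in$values))
  }
  out <- do.call(rbind, rows)
  n <- nrow(out)
  attr(out, "ratios") <- c(
    true = signal_levels[n] / signal_levels[1L],
    rpkm = out$mean_rpkm[n] / out$mean_rpkm[1L],
    spike = out$mean_spike_scaled[n] / out$mean_spike_scaled[1L])
  out
}

#' Empirical coverage of the percentile bootstrap interval for the mean
#'
#' Replicates a Gaussian sample many times, builds the level-\code{level}
#' percentile interval of the bootstrapped means each time, and reports
#' the fraction of replications whose interval covers the true mean.
#'
#' @param n sample size per replication (default 200).
#' @param n_rep replications (default 500).
#' @param level confidence level in percent (default 99).
#' @param n_boot bootstrap rounds per replication (default 500).
#' @param mean_true,sd_true Gaussian parameters (default 10, 3).
#' @param seed integer seed.
#' @return fraction of replications covering \code{mean_true}.
#' @export
boot_ci_coverage <- function(n = 200L, n_rep = 500L, level = 99,
                             n_boot = 500L, mean_true = 10, sd_true = 3,
                             seed) {
  if (missing(seed)) stopf("seed is mandatory")
  set.seed(seed)
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- stats::rnorm(n, mean_true, sd_true)
    means <- colMeans(matrix(x[sample.int(n, n * n_boot, replace = TRUE)],
                             nrow = n))
    ci <- ci_percentile(means, level)
    covered[r] <- ci[1L] <= mean_true && mean_true <= ci[2L]
  }
  mean(covered)
}
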
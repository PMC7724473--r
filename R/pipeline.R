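# End-to-end orchestration: read a study from disk (sample sheet +
# tracks + peaks), build the common peak set, extract matrices, cluster,
# and produce cluster-level bootstrap quantification -- the same sequence
# of steps the individual modules expose, wired together.

#' Load a study directory written by \code{\link{default_study}}
#'
#' @param dir study directory containing manifest.json, samples.tsv,
#'   peaks.bed and the coverage files.
#' @return list: \code{genome}, \code{bin_size}, \code{peaks},
#'   \code{samples}, \code{tracks} (named list with \code{$chip} and
#'   \code{$input} per sample), \code{manifest}.
#' @export
load_study <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  genome <- unlist(mf$genome)
  samples <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  peaks <- read_bed(file.path(dir, "peaks.bed"), genome = genome)
  tracks <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    list(chip = read_coverage(file.path(dir, s$chip_track), genome,
                              bin_size = mf$bin_size,
                              library_size = s$library_size,
                              spike_in_reads = s$spike_in_reads,
                              sample_id = s$sample_id),
         input = read_coverage(file.path(dir, s$input_track), genome,
                               bin_size = mf$bin_size,
                               library_size = s$library_size,
                               sample_id = paste0(s$sample_id, ".input")))
  })
  names(tracks) <- samples$sample_id
  list(genome = genome, bin_size = mf$bin_size, peaks = peaks,
       samples = samples, tracks = tracks, manifest = mf)
}

subset_signal_matrix <- function(sm, keep) {
  sm$values <- sm$values[keep, , drop = FALSE]
  sm
}

#' Run the full stratification pipeline on a study directory
#'
#' Reads the study, drops peaks bound by a single mark only (enrichment in
#' fewer than \code{min_marks} of the untreated wild-type EZH2, H3K27me3
#' and MTF2 tracks), extracts peak-centered matrices for every condition,
#' clusters the common set by Pearson-distance k-means (k chosen by the
#' elbow method when \code{k = "auto"}), renumbers clusters by wild-type
#' signal sharpness, quantifies input-subtracted RPKM per peak and
#' condition, and bootstraps cluster medians with WT-normalized
#' percentages per antibody.
#'
#' @param dir study directory.
#' @param seed integer seed driving clustering restarts and bootstrap
#'   resampling.
#' @param k \code{"auto"} (elbow over \code{k_range}) or a fixed integer.
#' @param k_range candidate k values for the elbow scan (default 2:10).
#' @param half_window clustering window half-width in bp (default 1000).
#' @param n_init,max_iter k-means restart/iteration settings.
#' @param min_marks,enrichment_threshold solo-peak exclusion settings.
#' @param n_boot,level bootstrap settings (default 1000 rounds, 99.9
#'   percent interval).
#' @return list: \code{study}, \code{common} (filtered \code{PeakSet}),
#'   \code{kept} (logical over the input peaks), \code{matrices} (raw,
#'   common-set rows), \code{elbow} (\code{elbow_fit} or NULL), \code{fit}
#'   (relabeled \code{pkmeans}), \code{quant} (per-condition
#'   input-subtracted RPKM tables), \code{boot} (per-antibody
#'   \code{bootstrap_summary}), \code{table} (combined bootstrap table).
#' @export
run_study_pipeline <- function(dir, seed, k = "auto", k_range = 2:10,
                               half_window = 1000L, n_init = 10L,
                               max_iter = 300L, min_marks = 2L,
                               enrichment_threshold = 2, n_boot = 1000L,
                               level = 99.9) {
  study <- load_study(dir)
  bin_size <- study$bin_size
  mats_all <- lapply(study$tracks, function(tr)
    extract_signal_matrix(tr$chip, study$peaks, half_window, bin_size))
  wt_marks <- study$samples$sample_id[
    study$samples$genotype == "WT" & study$samples$treatment == "none" &
      study$samples$antibody %in% c("ezh2", "h3k27me3", "mtf2")]
  common <- exclude_solo_peaks(study$peaks, mats_all[wt_marks],
                               min_marks = min_marks,
                               enrichment_threshold = enrichment_threshold)
  kept <- attr(common, "kept")
  mats <- lapply(mats_all, subset_signal_matrix, keep = kept)
  elbow <- NULL
  if (identical(k, "auto")) {
    elbow <- select_k_elbow(mats, k_range = k_range,
                            seed = sub_seed(seed, 1L), n_init = n_init,
                            max_iter = max_iter)
    fit <- elbow$fits[[match(elbow$k, elbow$k_range)]]
  } else {
    fit <- kmeans_correlation(mats, k = k, seed = sub_seed(seed, 1L),
                              n_init = n_init, max_iter = max_iter)
  }
  wt_ezh2 <- study$samples$sample_id[
    study$samples$antibody == "ezh2" & study$samples$genotype == "WT" &
      study$samples$treatment == "none"][1L]
  fit <- relabel_clusters(fit, cluster_sharpness(fit, mats[[wt_ezh2]]))
  quant <- lapply(study$samples$sample_id, function(sid) {
    chip_sm <- mats[[sid]]
    input_sm <- extract_signal_matrix(study$tracks[[sid]]$input, common,
                                      half_window, bin_size)
    input_subtract(quantify_peaks(chip_sm), quantify_peaks(input_sm))
  })
  names(quant) <- study$samples$sample_id
  boot <- list()
  tables <- list()
  for (ab in unique(study$samples$antibody)) {
    sids <- study$samples$sample_id[study$samples$antibody == ab]
    wt_sid <- study$samples$sample_id[
      study$samples$antibody == ab & study$samples$genotype == "WT" &
        study$samples$treatment == "none"][1L]
    vals <- lapply(quant[sids], function(q)
      stats::setNames(q$value, q$region_id))
    bs <- summarize_bootstrap(vals, fit, n_boot = n_boot, level = level,
                              seed = sub_seed(seed, 2L), wt = wt_sid)
    boot[[ab]] <- bs
    tables[[ab]] <- bs$table
  }
  list(study = study, common = common, kept = kept, matrices = mats,
       elbow = elbow, fit = fit, quant = quant, boot = boot,
       table = do.call(rbind, tables))
}
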
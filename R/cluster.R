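# Stratification of the common peak set by multi-condition signal shape.
#
# The distance is 1 - Pearson correlation.  Lloyd iterations are run on
# row-wise z-scored data under squared Euclidean distance: for rows scaled
# to mean 0 and unit (sample) standard deviation,
#   ||z(x) - z(y)||^2 = 2 (p - 1) (1 - r(x, y)),
# so squared Euclidean distance on z-scores is an affine, strictly
# increasing transform of the Pearson distance and both objectives rank
# partitions identically.  This equivalence is asserted by the test suite
# against a direct Pearson-distance Lloyd implementation.

#' Pearson correlation distance
#'
#' \code{1 - r(x, y)}, in \code{[0, 2]}.
#'
#' @param x,y equal-length numeric vectors (length >= 3) with non-zero
#'   variance.
#' @return numeric distance.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y)) stopf("unequal lengths")
  if (length(x) < 3L) stopf("need vectors of length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("Pearson distance undefined for zero-variance vector")
  1 - stats::cor(x, y)
}

row_zscore <- function(x) {
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  flat <- sdv == 0 | !is.finite(sdv)
  z <- (x - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  list(z = z, flat = flat)
}

#' Build a clustering feature matrix from per-condition signal matrices
#'
#' Each condition's peak-window matrix is z-scored row-wise independently
#' (so only the signal *shape* within the window enters, per condition) and
#' the blocks are concatenated column-wise in the order given. Rows that
#' are flat (zero variance) within a block contribute zeros for that block
#' and are flagged.
#'
#' @param matrices list of \code{SignalMatrix} objects over the same peaks
#'   in the same order.
#' @return numeric matrix with attributes \code{block_sizes},
#'   \code{block_ids} (sample ids) and \code{flat} (peaks x blocks logical
#'   matrix of zero-variance flags).
#' @export
build_cluster_features <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ids <- rownames(matrices[[1L]]$values)
  for (m in matrices)
    if (!identical(rownames(m$values), ids))
      stopf("signal matrices are not row-aligned")
  zs <- lapply(matrices, function(m) row_zscore(m$values))
  feats <- do.call(cbind, lapply(zs, `[[`, "z"))
  rownames(feats) <- ids
  attr(feats, "block_sizes") <- vapply(matrices, function(m)
    ncol(m$values), 0L)
  attr(feats, "block_ids") <- vapply(matrices, function(m)
    m$sample_id, "")
  attr(feats, "flat") <- do.call(cbind, lapply(zs, `[[`, "flat"))
  feats
}

lloyd_once <- function(z, k, init_idx, max_iter) {
  n <- nrow(z)
  centers <- z[init_idx, , drop = FALSE]
  labels <- integer(n)
  zsq <- rowSums(z^2)
  converged <- FALSE
  inertia <- Inf
  for (iter in seq_len(max_iter)) {
    d2 <- outer(zsq, rowSums(centers^2), "+") - 2 * z %*% t(centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: re-seed at the point farthest from its centroid
    repeat {
      sizes <- tabulate(new_labels, nbins = k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      dmin <- d2[cbind(seq_len(n), new_labels)]
      far <- which.max(dmin)
      centers[empty[1L], ] <- z[far, ]
      d2[, empty[1L]] <- zsq + sum(z[far, ]^2) - 2 * drop(z %*% z[far, ])
      new_labels <- max.col(-d2, ties.method = "first")
    }
    inertia <- sum(pmax(d2[cbind(seq_len(n), new_labels)], 0))
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(z[labels == j, , drop = FALSE])
  }
  list(labels = labels, centers = centers, inertia = inertia,
       iterations = iter, converged = converged)
}

#' k-means clustering under Pearson correlation distance
#'
#' Stratifies peaks by signal shape: rows are z-scored (per condition block
#' when a list of \code{SignalMatrix} objects is supplied, as a single
#' block for a plain matrix) and Lloyd's algorithm is run under squared
#' Euclidean distance, which is an increasing transform of the Pearson
#' distance (see Details in the package vignette). The best of
#' \code{n_init} random restarts by within-cluster inertia is returned.
#' Rows flat across all features are excluded from fitting and afterwards
#' assigned to the cluster with the nearest raw-space centroid; they are
#' flagged in the result.
#'
#' @param x list of row-aligned \code{SignalMatrix} objects, or a plain
#'   numeric matrix (rows = peaks).
#' @param k number of clusters (>= 2).
#' @param seed integer seed; mandatory for reproducibility.
#' @param n_init number of random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300). If no
#'   restart converges, the best solution so far is returned with
#'   \code{converged = FALSE} and a warning.
#' @return An object of class \code{pkmeans}: labels (named, contiguous
#'   1..k, no empty cluster), centroids (k x features, z-score space),
#'   sizes, inertia, k, seed, n_init, iterations, converged, flat_rows.
#' @export
kmeans_correlation <- function(x, k, seed, n_init = 10L, max_iter = 300L) {
  if (missing(seed)) stopf("seed is mandatory")
  if (k < 2L) stopf("k must be >= 2")
  if (is.list(x) && !is.matrix(x)) {
    feats <- build_cluster_features(x)
  } else {
    zx <- row_zscore(as.matrix(x))
    feats <- zx$z
    attr(feats, "flat") <- matrix(zx$flat, ncol = 1L)
    attr(feats, "block_sizes") <- ncol(feats)
    attr(feats, "block_ids") <- "x"
  }
  raw <- if (is.list(x) && !is.matrix(x))
    do.call(cbind, lapply(x, function(m) m$values)) else as.matrix(x)
  flat_all <- rowSums(abs(feats)) == 0
  fit_idx <- which(!flat_all)
  z <- feats[fit_idx, , drop = FALSE]
  n <- nrow(z)
  if (n < k) stopf("fewer non-degenerate rows (%d) than clusters (%d)", n, k)
  if (nrow(unique(z)) < k)
    stopf("k exceeds the number of distinct rows")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    init_idx <- sample.int(n, k)
    # avoid coincident starting centroids
    tries <- 0L
    while (anyDuplicated(z[init_idx, , drop = FALSE]) && tries < 50L) {
      init_idx <- sample.int(n, k)
      tries <- tries + 1L
    }
    fit <- lloyd_once(z, k, init_idx, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  if (!best$converged)
    warnf("k-means did not converge within %d iterations; returning best solution found",
          max_iter)
  labels <- integer(nrow(feats))
  labels[fit_idx] <- best$labels
  if (any(flat_all)) {
    raw_centers <- t(vapply(seq_len(k), function(j)
      colMeans(raw[fit_idx[best$labels == j], , drop = FALSE]),
      numeric(ncol(raw))))
    for (i in which(flat_all)) {
      d2 <- rowSums((raw_centers - matrix(raw[i, ], k, ncol(raw),
                                          byrow = TRUE))^2)
      labels[i] <- which.min(d2)
    }
  }
  names(labels) <- rownames(feats)
  structure(list(labels = labels, centroids = best$centers,
                 sizes = tabulate(labels, nbins = k), k = k,
                 inertia = best$inertia, seed = seed, n_init = n_init,
                 iterations = best$iterations, converged = best$converged,
                 flat_rows = which(flat_all),
                 block_sizes = attr(feats, "block_sizes"),
                 block_ids = attr(feats, "block_ids")),
            class = "pkmeans")
}

#' @export
print.pkmeans <- function(x, ...) {
  cat(sprintf(
    "Pearson-distance k-means: k = %d over %d peaks (inertia %.4g, %s)\n",
    x$k, length(x$labels), x$inertia,
    if (x$converged) "converged" else "NOT converged"))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (length(x$flat_rows))
    cat(sprintf("%d flat (zero-variance) row(s) assigned post hoc\n",
                length(x$flat_rows)))
  invisible(x)
}

#' @export
summary.pkmeans <- function(object, ...) {
  data.frame(cluster = seq_len(object$k), n_peaks = object$sizes,
             within_share = vapply(seq_len(object$k), function(j) {
               idx <- object$labels == j
               sum(idx) / length(object$labels)
             }, 0))
}

#' Assign new peak rows to fitted clusters
#'
#' @param object a \code{pkmeans} fit.
#' @param newdata list of \code{SignalMatrix} objects (same condition
#'   blocks as the fit) or a plain matrix with the same feature layout.
#' @param ... unused.
#' @return integer cluster labels.
#' @export
predict.pkmeans <- function(object, newdata, ...) {
  feats <- if (is.list(newdata) && !is.matrix(newdata))
    build_cluster_features(newdata) else row_zscore(as.matrix(newdata))$z
  if (ncol(feats) != ncol(object$centroids))
    stopf("newdata has %d features; fit has %d", ncol(feats),
          ncol(object$centroids))
  d2 <- outer(rowSums(feats^2), rowSums(object$centroids^2), "+") -
    2 * feats %*% t(object$centroids)
  max.col(-d2, ties.method = "first")
}

#' Plot cluster centroid profiles
#'
#' One panel line per cluster, condition blocks separated by vertical
#' dashed lines.
#'
#' @param x a \code{pkmeans} fit.
#' @param ... passed to \code{matplot}.
#' @export
plot.pkmeans <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "l", lty = 1,
                    xlab = "feature (condition blocks)",
                    ylab = "centroid (z-score)", ...)
  if (length(x$block_sizes) > 1L)
    graphics::abline(v = cumsum(x$block_sizes)[-length(x$block_sizes)] + 0.5,
                     lty = 2, col = "grey60")
  graphics::legend("topright", legend = paste("cluster", seq_len(x$k)),
                   col = seq_len(x$k), lty = 1, cex = 0.7)
  invisible(x)
}

#' Choose the number of clusters by the elbow method
#'
#' Runs \code{\link{kmeans_correlation}} for each k in \code{k_range} and
#' places the elbow at the maximum discrete second difference of the
#' inertia-vs-k curve, \code{I(k-1) - 2 I(k) + I(k+1)}. When the maximum
#' curvature is below 5 percent of the initial inertia drop
#' (\code{I(k_min) - I(k_min + 1)}) the curve has no pronounced knee and
#' the result is flagged.
#'
#' @param x input as in \code{\link{kmeans_correlation}}.
#' @param k_range integer range of k to scan (default 2:10); must span at
#'   least three values.
#' @param seed integer seed.
#' @param n_init,max_iter passed to \code{\link{kmeans_correlation}}.
#' @param curvature_tol fraction of the initial inertia drop below which
#'   the knee is flagged as not pronounced (default 0.05).
#' @return An object of class \code{elbow_fit}: \code{k} (chosen),
#'   \code{k_range}, \code{inertia}, \code{second_diff}, \code{no_knee}
#'   flag, and \code{fits} (the per-k \code{pkmeans} objects).
#' @export
select_k_elbow <- function(x, k_range = 2:10, seed, n_init = 10L,
                           max_iter = 300L, curvature_tol = 0.05) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L)
    stopf("k_range must span at least three values of k")
  fits <- lapply(seq_along(k_range), function(i)
    kmeans_correlation(x, k_range[i], seed = sub_seed(seed, i),
                       n_init = n_init, max_iter = max_iter))
  inertia <- vapply(fits, `[[`, 0, "inertia")
  kk <- k_range
  interior <- seq(2L, length(kk) - 1L)
  d2 <- inertia[interior - 1L] - 2 * inertia[interior] + inertia[interior + 1L]
  names(d2) <- kk[interior]
  tol <- curvature_tol * (inertia[1L] - inertia[2L])
  no_knee <- max(d2) < tol
  k <- kk[interior][which.max(d2)]
  if (no_knee)
    warnf("no pronounced knee in the inertia curve (max curvature %.3g < tol %.3g)",
          max(d2), tol)
  structure(list(k = k, k_range = kk, inertia = inertia, second_diff = d2,
                 no_knee = no_knee, fits = fits, seed = seed),
            class = "elbow_fit")
}

#' @export
print.elbow_fit <- function(x, ...) {
  cat(sprintf("Elbow scan over k = %d..%d: chosen k = %d%s\n",
              min(x$k_range), max(x$k_range), x$k,
              if (x$no_knee) " (no pronounced knee)" else ""))
  print(data.frame(k = x$k_range, inertia = x$inertia))
  invisible(x)
}

#' @export
plot.elbow_fit <- function(x, ...) {
  plot(x$k_range, x$inertia, type = "b", xlab = "k",
       ylab = "within-cluster inertia", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Exclude peaks bound by a single mark only
#'
#' Retains peaks that are enriched (per the \code{\link{row_enriched}}
#' criterion) in at least \code{min_marks} companion marks; used to drop
#' solo peaks of one subunit that lack occupancy of the rest of the
#' complex before building the common region set.
#'
#' @param ref_peaks the candidate \code{PeakSet}.
#' @param companion_matrices list of \code{SignalMatrix} objects
#'   row-aligned to \code{ref_peaks}, one per companion mark.
#' @param min_marks minimum number of enriched companion marks (default 1).
#' @param enrichment_threshold fold over background (default 2).
#' @return The retained \code{PeakSet}, with a logical attribute
#'   \code{"kept"} aligned to the input.
#' @export
exclude_solo_peaks <- function(ref_peaks, companion_matrices, min_marks = 1L,
                               enrichment_threshold = 2) {
  stopifnot(inherits(ref_peaks, "PeakSet"))
  for (m in companion_matrices)
    if (nrow(m$values) != length(ref_peaks))
      stopf("companion matrix not row-aligned to ref_peaks")
  if (min_marks == 0L) {
    out <- ref_peaks
    attr(out, "kept") <- rep(TRUE, length(ref_peaks))
    return(out)
  }
  n_enriched <- Reduce(`+`, lapply(companion_matrices, function(m)
    as.integer(row_enriched(m, enrichment_threshold))))
  kept <- n_enriched >= min_marks
  out <- ref_peaks[kept]
  attr(out, "kept") <- kept
  out
}

#' Sharpness statistic per cluster for deterministic relabeling
#'
#' Mean over cluster members of center-bin signal over window-mean signal
#' in the supplied (typically wild-type) matrix; high values mean sharply
#' localized binding.
#'
#' @param fit a \code{pkmeans} fit.
#' @param wt_matrix a \code{SignalMatrix} row-aligned to the fit.
#' @return numeric vector of length k.
#' @export
cluster_sharpness <- function(fit, wt_matrix) {
  v <- wt_matrix$values
  ctr <- ncol(v) / 2
  center_sig <- rowMeans(v[, c(floor(ctr), ceiling(ctr + 1)), drop = FALSE])
  ratio <- center_sig / pmax(rowMeans(v), .Machine$double.eps)
  vapply(seq_len(fit$k), function(j) mean(ratio[fit$labels == j]), 0)
}

#' Renumber clusters by a per-cluster statistic
#'
#' The k-means cluster numbering is arbitrary; this renumbers clusters 1..k
#' by descending \code{ordering_stat} (ties broken by descending cluster
#' size, then original id), so that e.g. cluster 1 is always the sharpest.
#'
#' @param fit a \code{pkmeans} fit.
#' @param ordering_stat numeric vector, one value per cluster.
#' @return A relabeled \code{pkmeans} fit; the permutation applied is in
#'   attribute \code{"relabeling"} (new id for each original id).
#' @export
relabel_clusters <- function(fit, ordering_stat) {
  stopifnot(inherits(fit, "pkmeans"))
  if (length(ordering_stat) != fit$k)
    stopf("need exactly one statistic per cluster")
  ord <- order(-ordering_stat, -fit$sizes, seq_len(fit$k))
  new_id <- integer(fit$k)
  new_id[ord] <- seq_len(fit$k)
  out <- fit
  out$labels <- stats::setNames(new_id[fit$labels], names(fit$labels))
  out$centroids <- fit$centroids[ord, , drop = FALSE]
  out$sizes <- fit$sizes[ord]
  attr(out, "relabeling") <- new_id
  out
}
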
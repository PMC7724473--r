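planted_rows <- function(n_per, shapes, noise = 0.2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(shapes), function(j)
    matrix(rep(shapes[[j]], n_per), nrow = n_per, byrow = TRUE)))
  x + matrix(rnorm(length(x), sd = noise), nrow = nrow(x))
}

test_that("pearson_distance definition and guards", {
  x <- c(0, 1, 2); y <- c(0, 2, 3)
  expect_equal(pearson_distance(x, x), 0)
  expect_equal(pearson_distance(x, -x), 2)
  expect_equal(pearson_distance(x, y), 1 - cor(x, y))
  expect_equal(pearson_distance(x, y), 0.0180195, tolerance = 1e-6)
  expect_error(pearson_distance(c(1, 1, 1), x), "zero-variance")
  expect_error(pearson_distance(1:3, 1:4), "unequal")
})

test_that("k-means recovers exact groups and is affine-invariant per row", {
  t <- seq(0, 2 * pi, length.out = 24)
  x <- planted_rows(10, list(sin(t), cos(t)), noise = 0)
  fit <- kmeans_correlation(x, k = 2, seed = 5)
  expect_true(same_partition(fit$labels, rep(1:2, each = 10)))
  expect_lt(fit$inertia, 1e-10)
  expect_equal(sum(fit$sizes), 20L)

  # correlation distance ignores per-row affine transforms
  x2 <- x
  x2[3, ] <- 3 * x2[3, ] + 7
  fit2 <- kmeans_correlation(x2, k = 2, seed = 5)
  expect_true(same_partition(fit2$labels, fit$labels))

  expect_error(kmeans_correlation(x, k = 2), "seed")
  expect_error(kmeans_correlation(x[1:3, ], k = 5, seed = 1), "fewer")
})

test_that("n = 6 partition matches exhaustive bipartition search", {
  t <- seq(0, 2 * pi, length.out = 20)
  for (s in 1:5) {
    set.seed(s)
    base <- rbind(matrix(rep(sin(t), 3), 3, byrow = TRUE),
                  matrix(rep(cos(t), 3), 3, byrow = TRUE))
    x <- base + matrix(rnorm(120, sd = 0.3), 6)
    fit <- kmeans_correlation(x, k = 2, seed = s, n_init = 20)
    expect_true(same_partition(fit$labels, oracle_best_bipartition(x)))
  }
})

test_that("z-score Euclidean solution equals direct Pearson-distance Lloyd", {
  t <- seq(0, 2 * pi, length.out = 16)
  shapes <- list(sin(t), cos(t), sin(2 * t))
  for (s in 1:20) {
    x <- planted_rows(4, shapes, noise = 0.35, seed = 100 + s)
    a <- kmeans_correlation(x, k = 3, seed = s, n_init = 10)$labels
    b <- oracle_pearson_lloyd(x, k = 3, seed = s)
    expect_true(same_partition(a, b))
  }
})

test_that("zero-variance rows are assigned without crashing and flagged", {
  t <- seq(0, 2 * pi, length.out = 20)
  x <- planted_rows(8, list(sin(t), cos(t)), noise = 0.1, seed = 2)
  x <- rbind(x, matrix(5, nrow = 2, ncol = 20))
  fit <- kmeans_correlation(x, k = 2, seed = 9)
  expect_equal(fit$flat_rows, c(17L, 18L))
  expect_true(all(fit$labels[17:18] %in% 1:2))
  expect_equal(sum(fit$sizes), 18L)
})

test_that("inertia is non-increasing in k and elbow finds planted structure", {
  t <- seq(0, 2 * pi, length.out = 30)
  # three mutually negatively correlated profiles (r = -0.5 pairwise)
  shapes <- lapply(0:2, function(j) cos(t + 2 * pi * j / 3))
  x <- planted_rows(25, shapes, noise = 0.4, seed = 3)
  eb <- select_k_elbow(x, k_range = 2:8, seed = 11, n_init = 5)
  expect_equal(eb$k, 3L)
  expect_false(eb$no_knee)
  expect_true(all(diff(eb$inertia) <= 1e-8))

  # pure noise: curvature below the tolerance is flagged and warned about
  set.seed(8)
  noise <- matrix(rnorm(100 * 40), 100)
  expect_warning(ebn <- select_k_elbow(noise, k_range = 2:8, seed = 12,
                                       n_init = 3, curvature_tol = 2),
                 "no pronounced knee")
  expect_true(ebn$no_knee)
  expect_error(select_k_elbow(x, k_range = 2:3, seed = 1), "three values")
})

test_that("relabel_clusters renumbers by statistic with documented tie-breaks", {
  t <- seq(0, 2 * pi, length.out = 20)
  x <- planted_rows(6, list(sin(t), cos(t), -sin(t)), noise = 0.1, seed = 4)
  fit <- kmeans_correlation(x, k = 3, seed = 6)
  # already-ordered statistic: identity
  id <- relabel_clusters(fit, c(3, 2, 1))
  expect_identical(id$labels, fit$labels)
  # reversed statistic: reversed labels
  rev_fit <- relabel_clusters(fit, c(1, 2, 3))
  expect_identical(unname(rev_fit$labels), 4L - unname(fit$labels))
  # random stats: labels equal ranks from an independent sort
  stats <- c(0.2, 1.5, 0.7)
  rl <- relabel_clusters(fit, stats)
  want_new <- match(seq_len(3), order(-stats))
  expect_identical(unname(rl$labels), want_new[unname(fit$labels)])
  expect_error(relabel_clusters(fit, c(1, 2)), "one statistic per cluster")
})

test_that("exclude_solo_peaks retains exactly the multi-mark peaks", {
  ps <- peak_set(rep("c", 100), seq(0, 990, 10), seq(5, 995, 10))
  v1 <- matrix(1, 100, 10); v1[1:40, ] <- 6
  v2 <- matrix(1, 100, 10); v2[1:55, ] <- 6
  m1 <- signal_matrix(v1, 250, 50, track_background = 1)
  m2 <- signal_matrix(v2, 250, 50, track_background = 1)

  expect_length(exclude_solo_peaks(ps, list(m1, m2), min_marks = 0), 100)
  # rows 1:40 pass both marks, 41:55 pass one, rest none
  expect_length(exclude_solo_peaks(ps, list(m1, m2), min_marks = 2), 40)
  kept1 <- exclude_solo_peaks(ps, list(m1, m2), min_marks = 1)
  expect_length(kept1, 55)
  # a peak with all-zero companion signal is excluded at min_marks = 1
  expect_false(attr(kept1, "kept")[99])
})

test_that("predict assigns training rows to their own clusters", {
  t <- seq(0, 2 * pi, length.out = 24)
  x <- planted_rows(10, list(sin(t), cos(t)), noise = 0.2, seed = 13)
  fit <- kmeans_correlation(x, k = 2, seed = 14)
  expect_identical(unname(predict(fit, x)), unname(fit$labels))
})
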
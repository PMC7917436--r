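test_that("in/out/intermediate states follow the 4/5 A thresholds", {
  tab <- data.frame(frame = 1:4, d1 = c(3.5, 6.0, 4.5, 3.0),
                    d2 = c(3.0, 3.0, 3.0, 4.2))
  st <- classify_states(tab, c(Q489 = "d1", N468 = "d2"))
  expect_equal(as.character(st$states$Q489),
               c("in", "out", "intermediate", "in"))
  # frame class: OUT needs one out residue; IN needs all in;
  # an intermediate residue with no out residue -> unassigned
  expect_equal(as.character(st$class),
               c("IN", "OUT", "unassigned", "unassigned"))
})

test_that("state classification is monotone in distance", {
  set.seed(1)
  d <- sort(runif(200, 2, 8))
  st <- classify_states(data.frame(frame = seq_along(d), d1 = d),
                        c(Q = "d1"))
  codes <- as.integer(st$states$Q)  # in < intermediate < out
  expect_true(all(diff(codes) >= 0))
})

test_that("unknown distance columns are reported", {
  tab <- data.frame(frame = 1, d1 = 3)
  expect_error(classify_states(tab, c(Q = "d99")), "d99")
})

test_that("PCA reproduces an analytic eigendecomposition", {
  # build data whose sample covariance is exactly [[2,1],[1,2]]:
  # eigenvalues 3 and 1, explained fractions 0.75 / 0.25
  set.seed(2)
  n <- 400
  Z <- matrix(rnorm(2 * n), n, 2)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z)))      # whiten exactly
  C <- matrix(c(2, 1, 1, 2), 2)
  X <- Z %*% chol(C)
  tab <- data.frame(frame = 1:n, a = X[, 1], b = X[, 2])
  p <- fit_pca(tab, variance_target = 0.9)
  expect_equal(p$explained, c(0.75, 0.25), tolerance = 1e-10)
  expect_equal(p$n_retained, 2)              # 0.75 < 0.9 needs both
  # components orthonormal
  expect_equal(crossprod(p$rotation), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("variance on a single feature yields that axis", {
  tab <- data.frame(frame = 1:50, a = rnorm(50), b = rep(2.9, 50))
  p <- fit_pca(tab, variance_target = 0.9)
  expect_equal(p$n_retained, 1)
  expect_equal(abs(p$rotation[, 1]), c(1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(p$explained[1], 1.0)
})

test_that("full back-projection reproduces centered data", {
  cfg <- synthetic_config(n_frames = 100, seed = 13)
  tr <- generate_pocket_trajectory(cfg)
  p <- fit_pca(tr$distances, variance_target = 1.0)
  scores <- project_pca(p, tr$distances, n_components = ncol(p$rotation))
  back <- scores %*% t(p$rotation)
  centered <- sweep(as.matrix(tr$distances[-1]), 2, p$center)
  expect_lt(max(abs(back - centered)), 1e-8)
})

test_that("zero-variance feature sets are a degenerate-input error", {
  tab <- data.frame(frame = 1:10, a = rep(1, 10), b = rep(2, 10))
  expect_error(fit_pca(tab), "zero variance")
})

test_that("two well-separated blobs are recovered almost perfectly", {
  set.seed(10)
  n <- 500
  X <- rbind(matrix(rnorm(2 * n, 0, 1), ncol = 2),
             matrix(rnorm(2 * n, 10, 1), ncol = 2))  # 10 sigma apart
  truth <- rep(0:1, each = n)
  cl <- cluster_density(X, min_cluster_size = 25)
  expect_equal(nrow(cl$summary), 2)
  assigned <- !is.na(cl$assignment)
  agree <- max(mean(cl$assignment[assigned] == truth[assigned]),
               mean(cl$assignment[assigned] != truth[assigned]))
  expect_gte(agree, 0.99)
  expect_gte(mean(assigned), 0.98)
})

test_that("identical points form a single cluster", {
  X <- matrix(1, 40, 2)
  cl <- cluster_density(X, min_cluster_size = 5)
  expect_equal(nrow(cl$summary), 1)
  expect_true(all(cl$assignment == 0))
})

test_that("population bookkeeping sums to one", {
  set.seed(4)
  X <- rbind(matrix(rnorm(400), ncol = 2),
             matrix(rnorm(400, 8), ncol = 2),
             matrix(runif(60, -20, 28), ncol = 2))   # sprinkle of noise
  cl <- cluster_density(X, min_cluster_size = 20)
  tot <- sum(cl$summary$population) +
    attr(cl$summary, "noise_fraction") +
    attr(cl$summary, "excluded_fraction")
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("a sub-1% blob is removed by the population filter", {
  set.seed(6)
  n <- 5000
  n_small <- 25  # 0.5% of frames
  X <- rbind(matrix(rnorm(2 * (n - n_small), 0, 1), ncol = 2),
             matrix(rnorm(2 * n_small, 15, 0.2), ncol = 2))
  cl_nofilter <- cluster_density(X, min_cluster_size = 8, min_population = 0)
  # the blob is dense enough to be found when no filter is applied...
  small_found <- any(cl_nofilter$summary$n <= 30 & cl_nofilter$summary$n >= 15)
  expect_true(small_found)
  # ...and the 1% filter dissolves it into noise
  cl <- cluster_density(X, min_cluster_size = 8, min_population = 0.01)
  expect_false(any(cl$summary$n <= 30))
  expect_gte(attr(cl$summary, "excluded_fraction"), n_small / n - 1e-12)
})

test_that("majority vote labels clusters IN/OUT with tie -> unassigned", {
  assignment <- c(rep(0L, 20), rep(1L, 10), rep(2L, 10))
  class <- factor(c(rep("IN", 19), "OUT",             # 95% IN
                    rep("OUT", 10),                   # 100% OUT
                    rep(c("IN", "OUT"), 5)),          # 50/50
                  levels = c("IN", "OUT", "unassigned"))
  clustering <- list(assignment = assignment,
                     summary = data.frame(cluster = 0:2, n = c(20, 10, 10),
                                          population = c(0.5, 0.25, 0.25)))
  lab <- label_clusters(clustering, list(class = class))
  expect_equal(lab$label, c("IN", "OUT", "unassigned"))
})

test_that("representative sampling clamps, reproduces, and is uniform", {
  clustering <- list(assignment = c(rep(0L, 7), rep(1L, 100)))
  r1 <- sample_representatives(clustering, n_per_cluster = 10, seed = 5)
  expect_equal(r1[["0"]], 1:7)                   # clamp: all 7 returned
  expect_length(r1[["1"]], 10)
  expect_identical(r1,
                   sample_representatives(clustering, n_per_cluster = 10,
                                          seed = 5))
  counts <- integer(100)
  big <- list(assignment = rep(0L, 100))
  for (i in 1:10000) {
    s <- sample_representatives(big, n_per_cluster = 10, seed = i)[["0"]]
    counts[s] <- counts[s] + 1L
  }
  # frequency of each frame across resamples: 10% +/- 1 percentage point
  expect_true(all(abs(counts / 10000 - 0.10) <= 0.01))
})

test_that("clustering recovers three planted conformations", {
  cfg <- planted_three_class_config(5000, seed = 21)
  tr <- generate_pocket_trajectory(cfg)
  p <- fit_pca(tr$distances, variance_target = 0.9)
  cl <- cluster_density(p$scores, min_cluster_size = 50)
  expect_equal(nrow(cl$summary), 3)
  truth_pop <- sort(tr$truth$populations, decreasing = TRUE)
  expect_true(all(abs(sort(cl$summary$population, decreasing = TRUE) -
                      truth_pop) < 0.05))
})
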
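test_that("amplitude normalization centres, scales and is affine-invariant", {
  x <- c(0, 1, 0, -1)
  nx <- normalize_profile(x)
  expect_equal(mean(nx), 0)
  expect_equal(sqrt(sum(nx^2)), 1)
  expect_equal(nx, x / sqrt(2))
  # c*x + d (c > 0) maps to the same normalized vector
  expect_equal(normalize_profile(3.7 * x + 2), nx)
  expect_error(normalize_profile(rep(4, 5)), "constant")
})

test_that("min-max normalization maps to [0, 1]; constant maps to zeros", {
  expect_equal(normalize_profile(c(3, 5, 4), "minmax"), c(0, 1, 0.5))
  expect_equal(normalize_profile(rep(2, 4), "minmax"), rep(0, 4))
})

test_that("cosine distance satisfies its axioms and known values", {
  t <- seq(0, 44, by = 4)
  cx <- cos(2 * pi * t / 24)
  sx <- sin(2 * pi * t / 24)
  expect_equal(cosine_distance(cx, cx), 0)
  expect_equal(cosine_distance(cx, -cx), 2)
  # orthogonal over full cycles
  expect_equal(cosine_distance(cx, sx), 1, tolerance = 1e-10)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    d <- cosine_distance(a, b)
    expect_equal(d, cosine_distance(b, a))
    expect_gte(d, 0); expect_lte(d, 2)
  }
  expect_error(cosine_distance(rep(0, 4), 1:4), "zero")
  expect_error(cosine_distance(1:3, 1:4), "equal length")
})

test_that("two anti-phase waveform groups separate perfectly", {
  skip_if_not_installed("mclust")
  set.seed(42)
  t <- seq(0, 44, by = 4)
  n <- 30
  truth <- rep(1:2, each = n)
  prof <- t(sapply(truth, function(g)
    cos(2 * pi * t / 24 - if (g == 1) 0 else pi) + rnorm(12, 0, 0.2)))
  rownames(prof) <- sprintf("g%02d", seq_len(2 * n))
  cl <- hierarchical_cluster(prof, 2)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
})

test_that("clustering edge cases and order invariance", {
  set.seed(5)
  prof <- matrix(rnorm(60), 10, 6,
                 dimnames = list(letters[1:10], NULL))
  one <- hierarchical_cluster(prof, 1)
  expect_true(all(one$labels == 1))
  expect_error(hierarchical_cluster(prof, 11), "fewer genes")
  expect_error(hierarchical_cluster(prof, 0), "n_clusters")

  cl <- hierarchical_cluster(prof, 3)
  perm <- sample(10)
  cl_perm <- hierarchical_cluster(prof[perm, ], 3)
  # same partition up to label names
  part1 <- split(names(cl$labels), cl$labels)
  part2 <- split(names(cl_perm$labels), cl_perm$labels)
  key <- function(p) sort(vapply(p, function(g)
    paste(sort(g), collapse = ","), ""))
  expect_equal(key(part1), key(part2))
})

test_that("phase-peak genes co-cluster in a 3-peak synthetic set", {
  set.seed(31)
  t <- seq(0, 44, by = 4)
  centers <- c(pi / 3, 2 * pi / 3, 3 * pi / 2)
  truth <- rep(1:3, each = 40)
  prof <- t(sapply(truth, function(g)
    cos(2 * pi * t / 24 - rnorm(1, centers[g], 0.15)) +
      rnorm(12, 0, 0.25)))
  rownames(prof) <- sprintf("g%03d", seq_along(truth))
  cl <- hierarchical_cluster(prof, 4)
  # the "magenta"-phase genes should land overwhelmingly in one cluster
  mag <- cl$labels[truth == 1]
  top <- max(table(mag))
  expect_gte(top / length(mag), 0.9)
})

test_that("phase bins follow the half-open convention with 'other' fallback", {
  bins <- phase_bins()
  expect_equal(assign_phase_bin(pi / 3, bins), "magenta")
  expect_equal(assign_phase_bin(pi, bins), "other")
  # boundary pi/2: exclusive upper of magenta, inclusive lower of navy
  expect_equal(assign_phase_bin(pi / 2, bins), "navy")
  expect_equal(assign_phase_bin(c(pi / 6, 5 * pi / 6, 4 * pi / 3), bins),
               c("magenta", "other", "gray"))
  expect_error(phase_bins(c("a", "b"), c(0, 1), c(1.5, 2)), "overlap")
  expect_error(phase_bins("a", 3, 2), "lower < upper")
})

test_that("phase histogram conserves counts and finds planted modes", {
  expect_equal(sum(phase_histogram(numeric(0), 12)), 0)
  h <- phase_histogram(rep(pi / 4, 100), 12)
  expect_equal(sum(h), 100)
  expect_equal(max(h), 100)

  set.seed(77)
  centers <- c(pi / 3, 2 * pi / 3, 3 * pi / 2)
  ph <- (rnorm(600, centers[sample(3, 600, TRUE)], 0.12)) %% (2 * pi)
  # 7 bins: no planted center falls on a bin edge
  h3 <- phase_histogram(ph, 7)
  expect_equal(sum(h3), 600)
  # each of the top-3 modes sits at a distinct planted component
  mids <- as.numeric(names(h3))
  top3 <- order(h3, decreasing = TRUE)[1:3]
  nearest <- vapply(mids[top3], function(m)
    which.min(circ_error(rep(m, 3), centers)), 0L)
  expect_true(all(vapply(mids[top3], function(m)
    min(circ_error(rep(m, 3), centers)), 0) < 0.45))
  expect_setequal(nearest, 1:3)
  expect_error(phase_histogram(ph, 1), "n_bins")
})

test_that("mean_profiles averages replicates per timepoint", {
  sim <- simulate_expression(design_circadian(seed = 3), 5, 0)
  prof <- mean_profiles(sim$expr, sim$samples)
  expect_equal(dim(prof), c(5, 12))
  tt <- sim$samples$time_h == 0
  expect_equal(prof[, 1], rowMeans(sim$expr[, tt]))
})
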
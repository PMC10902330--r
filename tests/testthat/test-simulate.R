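test_that("same design and seed give bitwise-identical simulations", {
  d <- design_circadian(seed = 5)
  s1 <- simulate_expression(d, 30, frac_rhythmic = 0.3)
  s2 <- simulate_expression(d, 30, frac_rhythmic = 0.3)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth, s2$truth)
})

test_that("frac_rhythmic = 0 plants no rhythms and all amplitudes are 0", {
  s <- simulate_expression(design_circadian(seed = 2), 25,
                           frac_rhythmic = 0)
  expect_false(any(s$truth$is_rhythmic))
  expect_true(all(s$truth$amplitude == 0))
  expect_true(all(s$truth$component == "none"))
})

test_that("planted amplitudes follow the requested distribution", {
  s <- simulate_expression(design_circadian(seed = 1), 1000,
                           frac_rhythmic = 0.2,
                           amplitude_dist = dist_normal(1.5, 0.5))
  amps <- s$truth$amplitude[s$truth$is_rhythmic]
  expect_equal(length(amps), 200)
  # truncation at 0 barely moves the N(1.5, 0.5) mean; 3 SE band
  expect_lt(abs(mean(amps) - 1.5), 3 * 0.5 / sqrt(length(amps)))
  expect_true(all(amps >= 0))
})

test_that("truth invariants hold", {
  s <- simulate_expression(design_circadian(seed = 9), 200,
                           frac_rhythmic = 0.4)
  r <- s$truth[s$truth$is_rhythmic, ]
  expect_true(all(r$phase >= 0 & r$phase < 2 * pi))
  expect_true(all(r$amplitude >= 0))
  expect_true(all(s$truth$amplitude[!s$truth$is_rhythmic] == 0))
  expect_true(all(r$component %in% c("magenta", "navy", "gray")))
  validate <- rhythmscan:::validate_expression(s$expr, s$samples)
  expect_true(validate)
})

test_that("non-rhythmic genes are flat: per-gene ANOVA rejects at ~alpha", {
  s <- simulate_expression(design_circadian(seed = 13), 400,
                           frac_rhythmic = 0)
  tp <- factor(s$samples$time_h)
  pvals <- apply(s$expr, 1, function(y)
    stats::anova(stats::lm(y ~ tp))[["Pr(>F)"]][1])
  alpha <- 0.05
  frac <- mean(pvals < alpha)
  expect_lt(frac, alpha + 2 * sqrt(alpha * (1 - alpha) / length(pvals)))
})

test_that("knockdown with scale 1 is the identity; scale 0 zeroes the target", {
  base <- simulate_expression(design_knockdown(seed = 7), 40,
                              frac_rhythmic = 0.5)
  kd1 <- simulate_knockdown(base, "auxin", 1)
  expect_identical(kd1$expr, base$expr)

  kd0 <- simulate_knockdown(base, "auxin", 0)
  expect_true(all(kd0$truth_conditions[, "auxin"] == 0))
  # mock condition untouched
  mock_cols <- base$samples$sample_id[base$samples$condition == "mock"]
  expect_identical(kd0$expr[, mock_cols], base$expr[, mock_cols])
  # auxin columns of non-rhythmic genes untouched (only signal changed)
  flat <- base$truth$gene_id[!base$truth$is_rhythmic]
  aux_cols <- setdiff(colnames(base$expr), mock_cols)
  expect_identical(kd0$expr[flat, aux_cols], base$expr[flat, aux_cols])

  expect_error(simulate_knockdown(base, "nope", 0.5), "unknown condition")
  expect_error(simulate_knockdown(base, "auxin", 2), "amplitude_scale")
})

test_that("dual-period generator links second-period rhythms to components", {
  circ <- simulate_expression(design_circadian(seed = 21), 600,
                              frac_rhythmic = 0.5)
  dev <- simulate_dual_period(circ, design_developmental(seed = 22),
                              overlap_probs = c(magenta = 1, navy = 0,
                                                gray = 0, none = 0))
  expect_identical(dev$truth$gene_id, circ$truth$gene_id)
  mag <- circ$truth$component == "magenta"
  expect_true(all(dev$truth$is_rhythmic[mag]))
  expect_false(any(dev$truth$is_rhythmic[!mag]))
  expect_true(all(is.na(dev$truth$period) |
                    dev$truth$period == 8.5))
})

test_that("design constructors validate their invariants", {
  expect_error(sim_design(c(4, 0, 8)), "strictly increasing")
  expect_error(sim_design(numeric(0)), "non-empty")
  expect_error(sim_design(0:10, replicates = 0), "replicates")
  expect_error(sim_design(0:10, noise_sd = -1), "noise_sd")
  d <- design_knockdown()
  expect_equal(d$conditions, c("mock", "auxin"))
  expect_equal(length(d$timepoints), 12)
})
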
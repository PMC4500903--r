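test_that("sinusoid trajectories match their closed form and stay in [-1, 1]", {
  # default S2-style trajectory spans exactly 0.4 (from -0.2 to 0.2)
  s2 <- generate_sinusoid(sinusoid_spec(mean = 0, amplitude = 0.2, period = 80,
                                        n_samples = 240))
  expect_equal(max(s2) - min(s2), 0.4)
  expect_true(all(abs(s2) <= 1))

  # zero amplitude: constant vector, zero variance
  const <- generate_sinusoid(sinusoid_spec(mean = 0.5, amplitude = 0,
                                           n_samples = 50))
  expect_equal(const, rep(0.5, 50))
  expect_equal(var(const), 0)

  # sample variance against an independently summed oracle over one period
  spec <- sinusoid_spec(mean = 0, amplitude = 0.2, period = 64, phase = 0,
                        n_samples = 64)
  v <- generate_sinusoid(spec)
  v_oracle <- numeric(64)
  for (t in 0:63) v_oracle[t + 1] <- 0 + 0.2 * sin(2 * pi * t / 64)
  var_oracle <- sum((v_oracle - sum(v_oracle) / 64)^2) / 63
  expect_equal(var(v), var_oracle, tolerance = 1e-14)
})

test_that("sinusoid specs reject out-of-range correlations and bad periods", {
  expect_error(sinusoid_spec(mean = 0.9, amplitude = 0.2), "\\[-1, 1\\]")
  expect_error(sinusoid_spec(period = 0), "period")
  expect_error(sinusoid_spec(period = -3), "period")
  expect_error(sinusoid_spec(n_samples = 0), "n_samples")
})

test_that("perfect coupling makes within-block windowed correlations exactly 1", {
  co <- tiny_cohort(n_subjects = 1, n_nodes = 6, n_blocks = 2, n_timepoints = 80,
                    within_coupling = coupling_trajectory("constant", value = 1),
                    global_coupling = coupling_trajectory("constant", value = 0))
  es <- sliding_window_correlation(co$subjects[[1]], 20, method = "pearson")
  cls <- classify_edges(es, co$partition)
  expect_equal(max(abs(es$values[cls == "within", ] - 1)), 0, tolerance = 1e-10)
})

test_that("uncoupled nodes have near-zero mean windowed correlation", {
  co <- generate_cohort(block_cohort_spec(
    n_subjects = 4, n_nodes = 16, n_blocks = 2, n_timepoints = 240, seed = 5,
    within_coupling = coupling_trajectory("constant", value = 0),
    global_coupling = coupling_trajectory("constant", value = 0)))
  m <- mean(vapply(co$subjects, function(s)
    mean(sliding_window_correlation(s, 45, method = "pearson")$values),
    numeric(1)))
  expect_lt(abs(m), 0.03)  # Monte-Carlo tolerance over 4 x 120 edges
})

test_that("cohort generation is seed-reproducible with prefix-stable subjects", {
  spec <- block_cohort_spec(n_subjects = 2, n_nodes = 8, n_blocks = 2,
                            n_timepoints = 100, seed = 9)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$subjects[[2]]$values, co2$subjects[[2]]$values)
  # growing the cohort must not change earlier subjects
  spec3 <- block_cohort_spec(n_subjects = 3, n_nodes = 8, n_blocks = 2,
                             n_timepoints = 100, seed = 9)
  co3 <- generate_cohort(spec3)
  expect_identical(co1$subjects[[1]]$values, co3$subjects[[1]]$values)
})

test_that("generated node series honour the unit-variance standardization contract", {
  co <- tiny_cohort(n_subjects = 2, n_timepoints = 240)
  for (s in co$subjects) {
    sds <- apply(s$values, 1, sd)
    expect_equal(unname(sds), rep(1, nrow(s$values)), tolerance = 1e-12)
    expect_equal(unname(rowMeans(s$values)), rep(0, nrow(s$values)),
                 tolerance = 1e-12)
  }
})

test_that("infeasible coupling (negative noise variance) is rejected", {
  expect_error(block_cohort_spec(
    within_coupling = coupling_trajectory("constant", value = 0.9),
    global_coupling = coupling_trajectory("sinusoid", mean = 0.4,
                                          amplitude = 0.2, period = 100)),
    "negative")
  expect_error(block_cohort_spec(latent_bandpass = c(0.01, 0.3), tr = 2),
               "Nyquist")
  expect_error(block_cohort_spec(n_nodes = 4, n_blocks = 4), "at least 2 nodes")
})

test_that("ground truth carries the model-implied correlations in [0, 1]", {
  co <- tiny_cohort(n_subjects = 1)
  gt <- co$ground_truth
  b2 <- eval_trajectory(co$spec$global_coupling, co$spec$n_timepoints)^2
  a2 <- eval_trajectory(co$spec$within_coupling[[1]], co$spec$n_timepoints)^2
  expect_equal(gt$between_corr, b2)
  expect_equal(unname(gt$within_corr[1, ]), a2 + b2)
  expect_true(all(gt$within_corr >= 0 & gt$within_corr <= 1))
  expect_true(all(gt$between_corr >= 0 & gt$between_corr <= 1))
})

test_that("windowed between-block correlations track the coupling trajectory", {
  # slow dynamics (period >> window): the window-averaged ground truth is
  # recovered by edge- and subject-averaged windowed correlations
  co <- generate_cohort(block_cohort_spec(
    n_subjects = 6, n_nodes = 20, n_blocks = 2, n_timepoints = 240, seed = 21,
    within_coupling = coupling_trajectory("constant", value = 0.8),
    global_coupling = coupling_trajectory("sinusoid", mean = 0.3,
                                          amplitude = 0.2, period = 200)))
  w <- 45
  truth <- window_average(co$ground_truth$between_corr, w)
  cls <- classify_edges(edge_index(20), co$partition)
  est <- 0
  for (s in co$subjects)
    est <- est + sliding_window_correlation(s, w, method = "pearson")$values
  traj <- colMeans((est / length(co$subjects))[cls == "between", ])
  expect_lt(mean(abs(traj - truth)), 0.10)
})

test_that("the designed cohort produces the intended mean/variance contrast", {
  co <- tiny_cohort(n_subjects = 4, n_timepoints = 240)
  sums <- lapply(co$subjects, function(s)
    summarize_edges(sliding_window_correlation(s, 45)))
  g <- group_average(sums)
  cls <- classify_edges(g, co$partition)
  expect_gt(mean(g$mean[cls == "within"]), mean(g$mean[cls == "between"]))
  expect_lt(mean(g$variance[cls == "within"]), mean(g$variance[cls == "between"]))
})
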
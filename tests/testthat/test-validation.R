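test_that("bootstrap median test has the stated degenerate behavior", {
  expect_equal(bootstrap_median_test(rep(3, 5), rep(3, 5), n_boot = 500,
                                     seed = 1)$p_value, 1)
  # a clear location shift rejects (pooled resampled medians concentrate
  # near the pooled median, far from the observed distance)
  set.seed(2)
  a <- rnorm(20)
  p <- bootstrap_median_test(a, a + 2, n_boot = 2000, seed = 2)$p_value
  expect_lte(p, 0.01)
  # reproducible under a seed
  a <- rnorm(12); b <- rnorm(12)
  p1 <- bootstrap_median_test(a, b, n_boot = 1000, seed = 3)$p_value
  p2 <- bootstrap_median_test(a, b, n_boot = 1000, seed = 3)$p_value
  expect_identical(p1, p2)
  expect_error(bootstrap_median_test(numeric(0), 1:3), "length")
})

test_that("bootstrap median CI behaves on constants and covers the median", {
  ci <- bootstrap_median_ci(rep(2.5, 10), n_boot = 200, seed = 1)
  expect_equal(unname(ci), c(2.5, 2.5))
  set.seed(4)
  covered <- 0
  for (i in 1:100) {
    x <- rnorm(25)
    ci <- bootstrap_median_ci(x, n_boot = 400)
    if (median(x) >= ci[1] && median(x) <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 99)
})

test_that("coefficient of variation uses the sample sd and is scale invariant", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3 * 100)
  x <- c(1.2, 3.4, 2.2, 5.6)
  expect_equal(coefficient_of_variation(7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("group trend reproduces the closed-form least-squares solution", {
  x <- c(5, 6, 7, 8, 9)
  res <- group_trend(x, 2 * x)
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
  expect_equal(group_trend(x, rep(1, 5))$slope, 0, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    xi <- rnorm(20); yi <- rnorm(20)
    # normal-equation oracle
    X <- cbind(1, xi)
    beta <- solve(t(X) %*% X, t(X) %*% yi)
    res <- group_trend(xi, yi)
    expect_equal(res$slope, beta[2], tolerance = 1e-10)
    expect_equal(res$intercept, beta[1], tolerance = 1e-10)
  }
  expect_error(group_trend(rep(1, 5), rnorm(5)), "distinct")
  expect_error(group_trend(1:2, 1:2), "3")
})

test_that("histogram noise injection is unbiased away from zero and clips at zero", {
  pr <- fixture_protocol_cont()
  ev <- simulate_ddm(fixture_params(), pr,
                     sim_config(seed = 6, duration_per_coherence = 300))
  h <- isi_histograms(ev, pr)
  # zero variance is the identity
  expect_equal(add_histogram_noise(h, 0)$heights, h$heights)
  # small noise is unbiased on a tall bin
  peak_idx <- which.max(h$heights)
  vals <- replicate(3000, {
    hn <- add_histogram_noise(h, variance = (0.05 * max(h$heights))^2)
    hn$heights[peak_idx]
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - h$heights[peak_idx]), 3 * se)
  # large noise clips a reported fraction of bins
  hn <- add_histogram_noise(h, variance = max(h$heights)^2, seed = 7)
  expect_gt(hn$clip_fraction, 0)
  expect_true(all(hn$heights >= 0))
})

test_that("synthetic orientation traces honor schedule, determinism and overlap checks", {
  tr0 <- gen_orientation_trace(3, noise_sd = 0, seed = 1)
  expect_true(all(tr0$orientation_deg == 0))
  expect_equal(nrow(detect_swims(tr0)), 0L)
  t1 <- gen_orientation_trace(10, bout_times = c(1, 3), bout_angles = c(10, -15),
                              noise_sd = 0.1, seed = 2)
  t2 <- gen_orientation_trace(10, bout_times = c(1, 3), bout_angles = c(10, -15),
                              noise_sd = 0.1, seed = 2)
  expect_identical(t1, t2)
  expect_error(gen_orientation_trace(5, bout_times = c(1, 1.05),
                                     bout_angles = c(5, 5),
                                     bout_duration = 0.2), "overlap")
  # ten 20-degree bouts are all recovered
  tr <- gen_orientation_trace(11, bout_times = seq(1, 10, by = 1),
                              bout_angles = rep(20, 10), noise_sd = 0.1,
                              seed = 3)
  expect_equal(nrow(detect_swims(tr)), 10L)
})

test_that("model target datasets match the session arithmetic and seeds", {
  p <- fixture_params()
  tgt <- gen_target_dataset(p, duration_per_coherence = 900, seed = 10)
  # 900 s per coherence -> 3600 s simulated across the four levels
  pr <- tgt$events
  expect_equal(length(unique(pr$session)) * 900, 3600)
  expect_equal(unname(stim_time(tgt$events)), rep(898, 4))
  tgt2 <- gen_target_dataset(p, duration_per_coherence = 900, seed = 10)
  expect_identical(tgt$hists$heights, tgt2$hists$heights)
  empty <- gen_target_dataset(p, duration_per_coherence = 0, seed = 1)
  expect_equal(nrow(empty$events), 0L)
  expect_true(all(empty$hists$heights == 0))
})

test_that("zero perturbation is indistinguishable from the noise floor", {
  lib <- build_library(search_space(), n_models = 8,
                       duration_per_coherence = 300, seed = 61)
  sens <- sensitivity_analysis(lib, search_space(), levels = 0,
                               parameters = "sigma",
                               duration_per_coherence = 300, seed = 62)
  expect_true(all(!sens$losses$skipped))
  expect_gt(sens$tests$p_value[1], 0.05)
})

test_that("perturbations leaving the space are skipped, not imputed", {
  lib <- build_library(search_space(), n_models = 3,
                       duration_per_coherence = 300, seed = 63)
  # force r near the top of its range
  lib$models[[1]]$params$r <- 0.95
  sens <- sensitivity_analysis(lib, search_space(), levels = c(0.25),
                               parameters = "r",
                               duration_per_coherence = 120, seed = 64)
  sub <- sens$losses[sens$losses$model == 1, ]
  expect_true(sub$skipped)
  expect_true(is.na(sub$loss))
})

test_that("a large diffusion perturbation raises the loss above the noise floor", {
  lib <- build_library(search_space(), n_models = 6,
                       duration_per_coherence = 600, seed = 65)
  sens <- sensitivity_analysis(lib, search_space(), levels = 0.5,
                               parameters = "sigma",
                               duration_per_coherence = 600, seed = 66)
  ok <- !sens$losses$skipped
  expect_gt(median(sens$losses$loss[ok]), median(sens$baseline))
})

test_that("an empty duration list yields an empty sweep", {
  sw <- duration_sweep(list(), numeric(0), search_space())
  expect_equal(nrow(sw), 0L)
})

test_that("random-draw baseline error is near the uniform expectation of 1/3", {
  # E|U - p*| for U uniform on [0,1], averaged over p* uniform, is 1/3
  sp <- search_space()
  set.seed(67)
  errs <- replicate(4000, {
    mean(estimation_error(sample_parameters(sp), sample_parameters(sp), sp))
  })
  expect_equal(mean(errs), 1 / 3, tolerance = 0.02)
})
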
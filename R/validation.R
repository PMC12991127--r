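#' Generate a model target dataset
#'
#' Simulates a parameter set and histograms the events in one call: the
#' canonical entry point for parameter-recovery experiments. With the
#' default continuous protocol, 900 s per coherence level reproduces the
#' data volume of a standard session (3,600 s across the four levels).
#'
#' @param params [ddm_params()].
#' @param protocol [stimulus_protocol()].
#' @param duration_per_coherence Stimulation seconds per coherence
#'   (continuous mode).
#' @param n_trials Trials per coherence (trial mode).
#' @param dt Euler step (s).
#' @param seed Simulation seed.
#' @param height_convention Passed to [isi_histograms()].
#' @return List with `events` (`event_series`) and `hists`
#'   (`isi_histograms`).
#' @export
gen_target_dataset <- function(params,
                               protocol = stimulus_protocol(mode = "continuous"),
                               duration_per_coherence = 900, n_trials = NULL,
                               dt = 0.01, seed = 1,
                               height_convention = "per_bin") {
  cfg <- if (protocol$mode == "trial") {
    if (is.null(n_trials)) n_trials <- ceiling(duration_per_coherence / protocol$stim_dur)
    sim_config(dt = dt, seed = seed, n_trials = n_trials)
  } else {
    sim_config(dt = dt, seed = seed,
               duration_per_coherence = duration_per_coherence)
  }
  ev <- simulate_ddm(params, protocol, cfg)
  h <- isi_histograms(ev, protocol, height_convention = height_convention)
  list(events = ev, hists = h)
}

#' Perturbation sensitivity of the histogram loss
#'
#' For each library model and each parameter, simulates reference data,
#' perturbs the parameter by a fraction of its search-range width, simulates
#' again, and scores the perturbed data against the reference with
#' [total_loss()]. The baseline for comparison is the loss between two
#' independent simulations of the unperturbed model (the re-simulation
#' noise floor). Each perturbation level's loss distribution across models
#' is compared with the baseline distribution by a two-sided Mann-Whitney U
#' test. Models whose perturbed value leaves the search space are skipped at
#' that level, not imputed.
#'
#' @param library A `model_library` (or list with `models` of
#'   `params`/`seed`).
#' @param space [search_space()] defining perturbation widths and bounds.
#' @param levels Signed perturbation fractions of the range width, within
#'   `[-0.5, 0.5]`. The default grid is `{+/-5, +/-10, +/-25, +/-50}%`.
#' @param parameters Which parameters to perturb.
#' @param duration_per_coherence Simulation seconds per coherence level.
#' @param protocol,dt,seed,metric,height_convention Simulation and loss
#'   settings.
#' @return A `sensitivity_result`: list with `losses` (data frame: model,
#'   parameter, level, loss, skipped), `baseline` (per-model noise-floor
#'   losses), `tests` (data frame: parameter, level, n, p_value),
#'   `settings`.
#' @export
sensitivity_analysis <- function(library, space,
                                 levels = c(-0.5, -0.25, -0.1, -0.05,
                                            0.05, 0.1, 0.25, 0.5),
                                 parameters = c("sigma", "mu", "lam", "r",
                                                "delta"),
                                 duration_per_coherence = 900,
                                 protocol = stimulus_protocol(mode = "continuous"),
                                 dt = 0.01, seed = 1,
                                 metric = "dkl_star",
                                 height_convention = "per_bin") {
  if (any(abs(levels) > 0.5)) stop("perturbation levels must be within +/-50%")
  models <- library$models
  w <- space_width(space)
  simulate_hists <- function(params, s) {
    cfg <- sim_config(dt = dt, seed = s,
                      duration_per_coherence = duration_per_coherence)
    isi_histograms(simulate_ddm(params, protocol, cfg), protocol,
                   height_convention = height_convention)
  }
  baseline <- numeric(length(models))
  rows <- list()
  for (i in seq_along(models)) {
    p0 <- models[[i]]$params
    href <- simulate_hists(p0, derive_seed(seed, i, 10L))
    hbase <- simulate_hists(p0, derive_seed(seed, i, 11L))
    baseline[i] <- total_loss(href, hbase, metric = metric)
    for (par in parameters) {
      for (li in seq_along(levels)) {
        lv <- levels[li]
        val <- params_vector(p0)[[par]] + lv * w[[par]]
        iv <- space[[par]]
        if (val < iv[1] || val > iv[2]) {
          rows[[length(rows) + 1]] <- data.frame(
            model = i, parameter = par, level = lv, loss = NA_real_,
            skipped = TRUE)
          next
        }
        pv <- as.list(params_vector(p0))
        pv[[par]] <- val
        pp <- ddm_params(pv$sigma, pv$mu, pv$lam, pv$r, pv$delta)
        hp <- simulate_hists(pp, derive_seed(seed, i * 100L + li, 12L +
                                               match(par, parameters)))
        rows[[length(rows) + 1]] <- data.frame(
          model = i, parameter = par, level = lv,
          loss = total_loss(href, hp, metric = metric), skipped = FALSE)
      }
    }
  }
  losses <- do.call(rbind, rows)
  tests <- list()
  for (par in parameters) {
    for (lv in levels) {
      sub <- losses[losses$parameter == par & losses$level == lv &
                      !losses$skipped, ]
      p <- if (nrow(sub) >= 2) {
        suppressWarnings(stats::wilcox.test(sub$loss, baseline,
                                            alternative = "two.sided")$p.value)
      } else NA_real_
      tests[[length(tests) + 1]] <- data.frame(parameter = par, level = lv,
                                               n = nrow(sub), p_value = p)
    }
  }
  structure(list(losses = losses, baseline = baseline,
                 tests = do.call(rbind, tests),
                 settings = list(levels = levels, parameters = parameters,
                                 duration_per_coherence = duration_per_coherence,
                                 dt = dt, seed = seed, metric = metric,
                                 n_models = length(models))),
            class = "sensitivity_result")
}

#' Significance onsets of the perturbation suite
#'
#' For each parameter, the smallest perturbation magnitude (percent of the
#' search-range width) at which the Mann-Whitney comparison against the
#' noise-floor baseline is significant. With `rule = "any"` (default) a
#' magnitude counts as soon as one of its evaluable signed levels (with at
#' least `min_n` unskipped models) rejects at `alpha` — the smallest grid
#' magnitude carrying a significant level; `rule = "all"` requires every
#' evaluable signed level of the magnitude to reject, a stricter convention
#' that guards against one-sided flukes but has less power.
#'
#' @param sens A `sensitivity_result`.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum unskipped models for a signed level to be evaluable.
#' @param rule `"any"` or `"all"` (see above).
#' @return Named numeric vector of onset magnitudes in percent (`NA` when no
#'   magnitude is significant).
#' @export
sensitivity_onsets <- function(sens, alpha = 0.05, min_n = 5,
                               rule = c("any", "all")) {
  rule <- match.arg(rule)
  tests <- sens$tests
  out <- c()
  for (par in unique(tests$parameter)) {
    tp <- tests[tests$parameter == par, ]
    mags <- sort(unique(abs(tp$level)))
    onset <- NA_real_
    for (m in mags) {
      tm <- tp[abs(tp$level) == m & tp$n >= min_n & !is.na(tp$p_value), ]
      if (nrow(tm) == 0) next
      hit <- if (rule == "any") any(tm$p_value < alpha)
             else all(tm$p_value < alpha)
      if (hit) { onset <- 100 * m; break }
    }
    out[par] <- onset
  }
  out
}

#' Dataset-duration sweep for recovery reliability
#'
#' For each total dataset duration, generates targets from the supplied
#' models, fits them, and measures the per-parameter normalized recovery
#' error `e(final)`; errors are compared against the errors of
#' non-optimized uniform random parameter draws (whose expected normalized
#' error is 1/3) with a one-sided Mann-Whitney U test.
#'
#' @param models List of model entries (each with `params`), e.g.
#'   `model_library$models`.
#' @param durations Total dataset durations in seconds (summed over the
#'   coherence levels; each level receives an equal share).
#' @param space [search_space()].
#' @param budget,n_init,trials_per_eval Fit settings (see [fit_ddm()]).
#' @param n_random Random baseline draws per duration.
#' @param protocol,dt,seed,metric,height_convention Simulation settings.
#' @return A `duration_sweep` data-frame result: columns `duration`,
#'   `model`, per-parameter errors, `mean_error`, plus attributes
#'   `baseline` (random-draw mean errors) and `tests` (per-duration
#'   Mann-Whitney p-values, fitted vs random).
#' @export
duration_sweep <- function(models, durations, space, budget = 60,
                           n_init = 20, trials_per_eval = 100,
                           n_random = 20,
                           protocol = stimulus_protocol(mode = "continuous"),
                           dt = 0.01, seed = 1, metric = "dkl_star",
                           height_convention = "per_bin") {
  if (length(durations) == 0)
    return(structure(data.frame(), baseline = numeric(0),
                     tests = data.frame(), class = c("duration_sweep",
                                                     "data.frame")))
  ncoh <- length(protocol$coherence_levels)
  rows <- list()
  tests <- list()
  set.seed(derive_seed(seed, 1L, 20L))
  baseline <- replicate(n_random, {
    mi <- sample(length(models), 1)
    mean(estimation_error(sample_parameters(space),
                          models[[mi]]$params, space))
  })
  for (di in seq_along(durations)) {
    d <- durations[di]
    for (i in seq_along(models)) {
      tgt <- gen_target_dataset(models[[i]]$params, protocol,
                                duration_per_coherence = d / ncoh, dt = dt,
                                seed = derive_seed(seed, di * 100L + i, 21L),
                                height_convention = height_convention)
      f <- fit_ddm(tgt$hists, space, budget = budget, n_init = n_init,
                   trials_per_eval = trials_per_eval,
                   seed = derive_seed(seed, di * 100L + i, 22L),
                   metric = metric)
      e <- estimation_error(f$best_params, models[[i]]$params, space)
      rows[[length(rows) + 1]] <- data.frame(
        duration = d, model = i, t(e), mean_error = mean(e))
    }
    fitted <- vapply(rows[vapply(rows, function(r) r$duration == d,
                                 logical(1))],
                     function(r) r$mean_error, numeric(1))
    p <- suppressWarnings(stats::wilcox.test(fitted, baseline,
                                             alternative = "less")$p.value)
    tests[[length(tests) + 1]] <- data.frame(duration = d, p_value = p)
  }
  structure(do.call(rbind, rows), baseline = baseline,
            tests = do.call(rbind, tests),
            class = c("duration_sweep", "data.frame"))
}

#' Add Gaussian bin noise to histograms
#'
#' Perturbs every bin height with i.i.d. Gaussian noise of the given
#' variance; negative results are clipped to zero (heights are rates). The
#' fraction of clipped bins is recorded in the result's `clip_fraction`
#' element.
#'
#' @param hists An `isi_histograms` object.
#' @param variance Noise variance in squared height units (`>= 0`).
#' @param seed Optional seed.
#' @return A perturbed `isi_histograms` with element `clip_fraction`.
#' @export
add_histogram_noise <- function(hists, variance, seed = NULL) {
  stopifnot(inherits(hists, "isi_histograms"), variance >= 0)
  if (!is.null(seed)) set.seed(seed)
  h <- hists$heights
  if (variance > 0) h <- h + stats::rnorm(length(h), sd = sqrt(variance))
  clipped <- h < 0
  h[clipped] <- 0
  out <- hists
  out$heights <- h
  counts <- sweep(h, 2, hists$total_time, "*")
  if (hists$height_convention == "density") counts <- counts * hists$bin_width
  out$counts <- counts
  out$clip_fraction <- mean(clipped)
  out
}

#' Bootstrap test for a difference in medians
#'
#' The observed statistic is the absolute difference of group medians.
#' Under the null of no difference, both groups are resampled with
#' replacement from the pooled data at the original group sizes `n_boot`
#' times; the p-value is the fraction of resampled statistics that match or
#' exceed the observed one.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param n_boot Number of resamples (default 10,000).
#' @param seed Optional seed.
#' @return List with `p_value`, `observed` (the median distance) and
#'   `n_boot`.
#' @export
bootstrap_median_test <- function(group_a, group_b, n_boot = 10000,
                                  seed = NULL) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  if (!is.null(seed)) set.seed(seed)
  observed <- abs(stats::median(group_a) - stats::median(group_b))
  stats <- boot_median_diff(c(group_a, group_b), length(group_a),
                            length(group_b), as.integer(n_boot))
  list(p_value = mean(stats >= observed), observed = observed,
       n_boot = n_boot)
}

#' Bootstrap percentile interval of the median
#'
#' @param values Nonempty numeric vector.
#' @param n_boot Number of resamples (default 10,000).
#' @param probs Interval probabilities (default 5th and 95th percentiles).
#' @param seed Optional seed.
#' @return Numeric vector of the interval endpoints.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000,
                                probs = c(0.05, 0.95), seed = NULL) {
  stopifnot(length(values) > 0)
  if (!is.null(seed)) set.seed(seed)
  meds <- boot_medians(as.numeric(values), as.integer(n_boot))
  stats::quantile(meds, probs = probs, names = TRUE)
}

#' Coefficient of variation in percent
#'
#' `CV = sd / mean * 100`, with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector with nonzero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(2, 4))  # sqrt(2)/3 * 100
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(values) / m * 100
}

#' Ordinary least-squares trend across ordered groups
#'
#' OLS regression of estimates on an ordinal group value (for example age in
#' days), returning the slope, intercept and the two-sided t-test p-value of
#' the slope.
#'
#' @param x Ordinal group values (at least 2 distinct).
#' @param y Responses (same length as `x`, at least 3 points).
#' @return List with `slope`, `intercept`, `p_value`, `r_squared`.
#' @export
group_trend <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired points")
  if (length(unique(x)) < 2) stop("x must contain at least 2 distinct values")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  pv <- tryCatch(sm$coefficients["x", "Pr(>|t|)"], error = function(e) NA_real_)
  list(slope = unname(coef(fit)[["x"]]), intercept = unname(coef(fit)[[1]]),
       p_value = unname(pv), r_squared = sm$r.squared)
}

#' Generate a synthetic heading-orientation trace
#'
#' Builds a piecewise-constant orientation time series with smooth
#' (raised-cosine) ramps at scheduled turn bouts plus per-frame Gaussian
#' jitter, annotated with stimulus metadata. The jitter default is far below
#' the swim-detection variance threshold, so scheduled bouts are the only
#' detectable events.
#'
#' @param duration Trace duration (s).
#' @param bout_times Bout start times (s); bouts must not overlap.
#' @param bout_angles Signed orientation change per bout (degrees; positive
#'   is leftward/counterclockwise).
#' @param bout_duration Bout lengths (s; scalar or per bout).
#' @param frame_rate Sampling rate (Hz, default 90).
#' @param noise_sd Per-frame jitter standard deviation (degrees).
#' @param coherence,direction,phase,trial_id Per-trace stimulus annotation.
#' @param seed Optional seed for the jitter.
#' @return A data frame with columns `time_s`, `orientation_deg`,
#'   `coherence`, `direction`, `phase`, `trial_id`, `t_stim_s`.
#' @export
gen_orientation_trace <- function(duration, bout_times = numeric(0),
                                  bout_angles = numeric(0),
                                  bout_duration = 0.15, frame_rate = 90,
                                  noise_sd = 0.1, coherence = 1,
                                  direction = "left", phase = "stimulus",
                                  trial_id = 1L, seed = NULL) {
  stopifnot(length(bout_times) == length(bout_angles))
  nb <- length(bout_times)
  bd <- rep_len(bout_duration, nb)
  if (nb > 1) {
    o <- order(bout_times)
    bt <- bout_times[o]; ba <- bout_angles[o]; bdur <- bd[o]
    if (any(bt[-1] < (bt + bdur)[-nb])) stop("bouts overlap")
  } else {
    bt <- bout_times; ba <- bout_angles; bdur <- bd
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / frame_rate)
  orientation <- rep(0, length(t))
  base <- 0
  for (k in seq_len(nb)) {
    ramp <- t >= bt[k] & t < bt[k] + bdur[k]
    u <- (t[ramp] - bt[k]) / bdur[k]
    orientation[ramp] <- base + ba[k] * (1 - cos(pi * u)) / 2
    after <- t >= bt[k] + bdur[k]
    base <- base + ba[k]
    orientation[after] <- base
  }
  orientation <- orientation + stats::rnorm(length(t), sd = noise_sd)
  data.frame(time_s = t, orientation_deg = orientation,
             coherence = coherence, direction = direction, phase = phase,
             trial_id = trial_id, t_stim_s = t)
}
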
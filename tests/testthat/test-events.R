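test_that("rolling variance matches the direct windowed oracle", {
  # constant trace
  tr <- data.frame(time_s = seq(0, 1, by = 1 / 90), orientation_deg = 5)
  expect_true(all(rolling_variance(tr) == 0))
  # alternating +/-1 degree at every frame, against the literal oracle
  x <- rep(c(1, -1), 50)
  k <- max(2, round(0.05 * 90))
  expect_equal(rolling_variance(x, frame_rate = 90), oracle_rolling_var(x, k),
               tolerance = 1e-10)
  # random trace, several windows
  set.seed(1)
  x <- rnorm(500)
  for (w in c(0.03, 0.05, 0.11)) {
    k <- max(2, round(w * 90))
    expect_equal(rolling_variance(x, window = w, frame_rate = 90),
                 oracle_rolling_var(x, k), tolerance = 1e-8)
  }
  # i.i.d. N(0, 4) noise: the population estimator over k-frame windows has
  # mean (k-1)/k * 4 (here k = 4 at 90 Hz)
  set.seed(2)
  x <- rnorm(1e5, sd = 2)
  k <- max(2, round(0.05 * 90))
  expect_equal(mean(rolling_variance(x, frame_rate = 90)), 4 * (k - 1) / k,
               tolerance = 0.05 * 4)
  expect_error(rolling_variance(numeric(0), frame_rate = 90), "empty")
})

test_that("swim detection finds a single smoothed turn and ignores flat traces", {
  # flat trace: no events
  tr <- gen_orientation_trace(5, noise_sd = 0, seed = 1)
  expect_equal(nrow(detect_swims(tr)), 0L)
  # one 20-degree bout amid flat segments
  tr <- gen_orientation_trace(5, bout_times = 2, bout_angles = 20,
                              bout_duration = 0.1, noise_sd = 0.1, seed = 2)
  sw <- detect_swims(tr)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$orientation_change_deg, 20, tolerance = 1)
  expect_lt(abs(sw$start_s - 2), 0.06)
})

test_that("sub-threshold-duration variance excursions produce no events", {
  # hysteresis rule on a constructed variance trace: an excursion above
  # 1 deg^2 lasting ~11 ms (one frame at 90 Hz) is shorter than the 20 ms
  # minimum and opens no event; two frames (22 ms) do
  v <- rep(0, 200)
  v[100] <- 1.5
  short <- ddmfit:::variance_hysteresis(v, fs = 90)
  expect_length(short$start, 0)
  v[101] <- 1.5
  long <- ddmfit:::variance_hysteresis(v, fs = 90)
  expect_length(long$start, 1)
  expect_equal(long$start, 100)
  # the event only closes after 50 ms below 0.5 deg^2
  v2 <- c(rep(0, 10), rep(2, 5), rep(0.4, 3), rep(2, 5), rep(0, 10))
  ev2 <- ddmfit:::variance_hysteresis(v2, fs = 90)
  expect_length(ev2$start, 1)  # the 3-frame dip does not end the event
  expect_equal(ev2$start, 11)
  expect_equal(ev2$end, 24)    # first frame of the sustained quiet run
})

test_that("synthetic bouts are recovered with exact counts and sub-degree angles", {
  set.seed(33)
  for (rep in 1:20) {
    nb <- sample(3:10, 1)
    # bouts separated by > 200 ms
    starts <- cumsum(runif(nb, 0.6, 1.2))
    angles <- runif(nb, -40, 40)
    angles[abs(angles) < 6] <- 12  # keep turns well above the jitter
    tr <- gen_orientation_trace(max(starts) + 1, bout_times = starts,
                                bout_angles = angles, bout_duration = 0.12,
                                noise_sd = 0.1, seed = 100 + rep)
    sw <- detect_swims(tr)
    expect_equal(nrow(sw), nb)
    expect_true(all(abs(sw$orientation_change_deg - angles) < 1))
    expect_true(all(sw$isi_s[-1] > 0))
  }
})

test_that("turn labeling partitions events into the three classes", {
  expect_equal(label_event(c(20, 2, -3.01), "left"),
               c("correct", "forward-excluded", "incorrect"))
  expect_equal(label_event(-20, "right"), "correct")
  expect_equal(label_event(c(3, -3), "left"),
               c("forward-excluded", "forward-excluded"))
  expect_error(label_event(10, NA_character_), "direction")
  # every event gets exactly one label
  set.seed(4)
  lab <- label_event(runif(500, -180, 180),
                     sample(c("left", "right"), 500, replace = TRUE))
  expect_true(all(lab %in% c("correct", "incorrect", "forward-excluded")))
})

test_that("QC flags events, drops bad trials and low-rate animals", {
  ev <- data.frame(
    isi_s = c(NA, 31, rep(1, 8)),
    orientation_change_deg = c(10, 10, 160, rep(10, 7)),
    mean_speed_cmps = c(rep(1, 3), 7, rep(1, 6)),
    area_px = c(rep(500, 4), 2500, rep(500, 5)),
    trial_id = rep(1:2, each = 5))
  qc <- qc_filter(ev, total_time_s = 10)
  # events 2 (isi 31), 3 (turn 160), 4 (speed 7), 5 (area 2500) flagged;
  # they all sit in trial 1 (80% flagged -> dropped); trial 2 is clean
  expect_equal(qc$report$n_flagged, 4L)
  expect_equal(qc$report$dropped_trials, 1L)
  expect_equal(nrow(qc$events), 5L)
  expect_false(qc$report$fish_dropped)  # 10 events / 10 s = 1 swim/s

  # borderline values: 150 degrees and 0.4 swims/s are retained
  ev2 <- data.frame(isi_s = rep(1, 40), orientation_change_deg = rep(150, 40),
                    trial_id = rep(1, 40))
  qc2 <- qc_filter(ev2, total_time_s = 100)
  expect_equal(qc2$report$n_flagged, 0L)
  expect_false(qc2$report$fish_dropped)  # rate 0.4 >= 0.375
  expect_true(all(c("fast_swim", "big_area") %in%
                    qc2$report$skipped_criteria))
  # a fish at 0.37 swims/s is dropped
  qc3 <- qc_filter(ev2, total_time_s = 40 / 0.37)
  expect_true(qc3$report$fish_dropped)
  expect_equal(nrow(qc3$events), 0L)
})

test_that("a trial is dropped only above the 5% flagged fraction", {
  mk <- function(nflag, n = 100) data.frame(
    isi_s = c(rep(31, nflag), rep(1, n - nflag)),
    orientation_change_deg = 10, trial_id = 1)
  expect_equal(qc_filter(mk(5))$report$dropped_trials, integer(0))
  expect_equal(qc_filter(mk(6))$report$dropped_trials, 1L)
})

test_that("tightening any QC threshold never increases retained events", {
  set.seed(7)
  ev <- data.frame(
    isi_s = rexp(300, 1 / 8),
    orientation_change_deg = runif(300, -180, 180),
    mean_speed_cmps = rexp(300, 1 / 3),
    area_px = runif(300, 100, 2600),
    trial_id = sample(1:10, 300, replace = TRUE))
  base <- nrow(qc_filter(ev, total_time_s = 300)$events)
  tighter <- list(list(isi_max = 20), list(speed_max = 4),
                  list(area_max = 1500), list(turn_max = 120),
                  list(trial_flag_frac = 0.02))
  for (tw in tighter) {
    n <- nrow(do.call(qc_filter, c(list(ev, total_time_s = 300), tw))$events)
    expect_lte(n, base)
  }
})

test_that("orientation unwrapping removes wrap-around jumps", {
  raw <- c(170, 179, -178, -170, -100)  # crossing +180
  un <- unwrap_orientation(raw)
  expect_true(all(abs(diff(un)) < 180))
  expect_equal(un[3], 182)
})
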
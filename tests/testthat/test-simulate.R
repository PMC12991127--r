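test_that("stimulus transform is the square root on [0,1] and rejects outside", {
  expect_equal(input_transform(0), 0)
  expect_equal(input_transform(1), 1)
  expect_equal(input_transform(0.25), 0.5)
  expect_true(all(diff(input_transform(seq(0, 1, 0.01))) >= 0))
  expect_error(input_transform(-0.1), "\\[0, 1\\]")
  expect_error(input_transform(1.1), "\\[0, 1\\]")
})

test_that("one Euler step matches drift, leak and self-reinforcement arithmetic", {
  expect_equal(ddm_step(0, ddm_params(0, 2, 0, 0, 0), 1, 0.01, 0), 0.02)
  expect_equal(ddm_step(0.5, ddm_params(0, 0, 1, 0, 0), 0, 0.01, 0), 0.495)
  expect_equal(ddm_step(0.5, ddm_params(0, 0, -1, 0, 0), 0, 0.01, 0), 0.505)
  # noise scaling: increment sd is sigma * sqrt(dt)
  expect_equal(ddm_step(0, ddm_params(2, 0, 0, 0, 0), 0, 0.04, 1), 2 * 0.2)
})

test_that("parameter and protocol constructors enforce their invariants", {
  expect_error(ddm_params(-1, 0, 0, 0, 0), "sigma")
  expect_error(ddm_params(1, 0, 0, 1.5, 0), "r must")
  expect_error(ddm_params(1, 0, 0, 0, -1), "delta")
  expect_error(stimulus_protocol(coherence_levels = c(0, 2)), "\\[0, 1\\]")
  expect_error(stimulus_protocol(exclusion_window = 40), "exclusion_window")
  expect_error(sim_config(dt = 0), "dt")
})

test_that("noise-free simulations match analytic first-passage times", {
  pr <- stimulus_protocol(mode = "continuous", coherence_levels = 1)
  # pure drift: B / (mu * f(I))
  ev <- simulate_ddm(ddm_params(0, 2, 0, 0, 0), pr,
                     sim_config(duration_per_coherence = 5, seed = 1))
  expect_true(all(abs(ev$isi_s - 0.5) <= 0.01 + 1e-12))
  # leaky OU: t = log((x* - x0) / (x* - B)) / lam
  ev <- simulate_ddm(ddm_params(0, 2, 1, 0, 0), pr,
                     sim_config(duration_per_coherence = 5, seed = 1))
  expect_true(all(abs(ev$isi_s - log(2)) <= 0.01 + 1e-12))
  # with partial reset the post-first intervals start from r*B
  ev <- simulate_ddm(ddm_params(0, 2, 1, 0.5, 0), pr,
                     sim_config(duration_per_coherence = 5, seed = 1))
  expect_true(all(abs(ev$isi_s[-1] - log(1.5)) <= 0.01 + 1e-12))
  # self-reinforcing leak from a seeded start: t = log(B/x0)/|lam|
  ev <- simulate_ddm(ddm_params(0, 0, -1, 0.5, 0), pr,
                     sim_config(duration_per_coherence = 5, seed = 1, x0 = 0.5))
  expect_true(all(abs(ev$isi_s[-1] - log(2)) <= 0.01 + 1e-12))
  # no drive, no noise, nonnegative leak: no events at all
  ev <- simulate_ddm(ddm_params(0, 0, 1, 0, 0),
                     stimulus_protocol(mode = "continuous",
                                       coherence_levels = 0),
                     sim_config(duration_per_coherence = 10, seed = 1))
  expect_equal(nrow(ev), 0L)
})

test_that("noise-free intervals match the closed form across a parameter grid", {
  pr <- stimulus_protocol(mode = "continuous", coherence_levels = 1)
  set.seed(42)
  n_checked <- 0
  while (n_checked < 100) {
    mu <- runif(1, 1.2, 6)
    lam <- runif(1, -2, 2)
    r <- runif(1, 0, 0.8)
    delta <- sample(c(0, round(runif(1, 0, 0.5), 2)), 1)
    p <- ddm_params(0, mu, lam, r, delta)
    t1 <- first_passage_deterministic(p, 1, x0 = 0)
    t2 <- first_passage_deterministic(p, 1, x0 = r)
    if (!is.finite(t1) || !is.finite(t2) || t2 > 5) next
    # stay where Euler truncation (~ |lam| t^2 dt / 2 per passage) is below
    # the one-step detection tolerance
    if (abs(lam) * max(t1, t2) > 1.5) next
    ev <- simulate_ddm(p, pr, sim_config(duration_per_coherence = 20, seed = 1))
    if (nrow(ev) < 3) next
    # tolerance: one-step detection rounding plus Euler truncation
    expect_lt(abs(ev$isi_s[1] - t1), 0.01 * (1 + abs(lam) * t1 / 2) + 1e-9)
    expect_true(all(abs(ev$isi_s[-1] - (t2 + delta)) <=
                      0.01 * (1 + abs(lam) * t2 / 2) + 1e-9))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("the post-decision delay adds exactly to noise-free intervals", {
  pr <- stimulus_protocol(mode = "continuous", coherence_levels = 1)
  base <- simulate_ddm(ddm_params(0, 2, 1, 0.3, 0), pr,
                       sim_config(duration_per_coherence = 10, seed = 1))
  for (delta in c(0.1, 0.25, 0.4)) {
    ev <- simulate_ddm(ddm_params(0, 2, 1, 0.3, delta), pr,
                       sim_config(duration_per_coherence = 10, seed = 1))
    expect_true(all(abs(ev$isi_s[2:5] - (base$isi_s[2] + delta)) <=
                      0.01 + 1e-9))
  }
})

test_that("the bound is redundant: B=k with scaled sigma, mu reproduces B=1 events", {
  pr <- stimulus_protocol(mode = "continuous", coherence_levels = c(0.25, 1))
  p1 <- fixture_params()
  k <- 2.5
  pk <- ddm_params(sigma = k * p1$sigma, mu = k * p1$mu, lam = p1$lam,
                   r = p1$r, delta = p1$delta, bound = k)
  e1 <- simulate_ddm(p1, pr, sim_config(duration_per_coherence = 200, seed = 9))
  ek <- simulate_ddm(pk, pr, sim_config(duration_per_coherence = 200, seed = 9))
  expect_equal(e1$time_s, ek$time_s)
  expect_equal(e1$label, ek$label)
})

test_that("matched seeds reproduce simulations exactly", {
  pr <- stimulus_protocol()
  cfg <- sim_config(seed = 77, n_trials = 5)
  a <- simulate_ddm(fixture_params(), pr, cfg)
  b <- simulate_ddm(fixture_params(), pr, cfg)
  expect_identical(a, b)
})

test_that("mean interval is consistent across dt = 0.01 and dt = 0.005", {
  pr <- stimulus_protocol(mode = "continuous", coherence_levels = 1)
  p <- fixture_params()
  m <- vapply(c(0.01, 0.005), function(dt) {
    ev <- simulate_ddm(p, pr, sim_config(dt = dt, seed = 5,
                                         duration_per_coherence = 2000))
    mean(ev$isi_s[-1])
  }, numeric(1))
  # Monte-Carlo tolerance: a few percent at ~2000 events
  expect_lt(abs(m[1] - m[2]) / m[2], 0.05)
})

test_that("without stimulus the two bounds are hit equally often", {
  pr <- stimulus_protocol(mode = "continuous", coherence_levels = 0)
  ev <- simulate_ddm(ddm_params(1.2, 0, 0, 0, 0), pr,
                     sim_config(seed = 3, duration_per_coherence = 9000))
  n <- nrow(ev)
  expect_gte(n, 10000)
  bt <- binom.test(sum(ev$label == "correct"), n, p = 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("rest-phase events are recorded but excluded from histograms", {
  pr <- stimulus_protocol(mode = "trial", coherence_levels = c(0, 1))
  ev <- simulate_ddm(ddm_params(1.5, 1, 0, 0, 0), pr,
                     sim_config(seed = 21, n_trials = 20))
  expect_true(any(ev$phase == "rest"))
  h <- isi_histograms(ev, pr)
  # every binned event sits in the stimulus phase, past the onset window
  expect_equal(sum(h$counts),
               sum(ev$phase == "stimulus" & ev$t_stim_s >= 2 &
                     ev$isi_s < 2 & ev$isi_s >= 0))
})

test_that("pathological leak aborts with a diagnostic naming the parameters", {
  pr <- stimulus_protocol(mode = "continuous", coherence_levels = 0)
  # |lam| dt must be large enough to jump past 10 B within one step (smaller
  # self-reinforcing leaks hit the bound first and are reset)
  expect_error(
    simulate_ddm(ddm_params(0, 0, -2000, 0, 0), pr,
                 sim_config(seed = 1, duration_per_coherence = 50, x0 = 0.5,
                            dt = 0.01)),
    "diverged")
})

test_that("event tables and settings survive a CSV / JSON round trip", {
  pr <- stimulus_protocol()
  ev <- simulate_ddm(fixture_params(), pr, sim_config(seed = 4, n_trials = 3))
  csv <- tempfile(fileext = ".csv")
  write_events(ev, csv)
  back <- read_events(csv)
  expect_equal(back$time_s, ev$time_s)
  expect_equal(back$label, ev$label)
  expect_equal(back$isi_s, ev$isi_s, tolerance = 1e-12)

  js <- tempfile(fileext = ".json")
  write_settings_json(js, params = fixture_params(), protocol = pr,
                      config = sim_config(seed = 4, n_trials = 3))
  st <- read_settings_json(js)
  expect_equal(st$params, fixture_params())
  expect_equal(st$protocol, pr)
  expect_equal(st$config$n_trials, 3)
})
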
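#' Parameter search space
#'
#' Closed intervals for the five free parameters. The defaults admit event
#' rates of roughly 0.1-3 events/s at the tested coherence levels with
#' `B = 1` (the experimentally observed regime of about one swim per second)
#' without saturating the reset or delay ranges.
#'
#' @param sigma,mu,lam,r,delta Length-2 numeric intervals `c(min, max)`.
#' @return A `search_space` object (named list of intervals).
#' @export
search_space <- function(sigma = c(0.05, 3), mu = c(0, 8), lam = c(-8, 8),
                         r = c(0, 1), delta = c(0, 1)) {
  sp <- list(sigma = sigma, mu = mu, lam = lam, r = r, delta = delta)
  for (nm in names(sp)) {
    iv <- sp[[nm]]
    if (!is.numeric(iv) || length(iv) != 2 || any(!is.finite(iv)))
      stop("interval for ", nm, " must be two finite numbers")
    if (iv[1] >= iv[2]) stop("interval for ", nm, " must have min < max")
  }
  if (sp$sigma[1] < 0) stop("sigma interval must be nonnegative")
  if (sp$r[1] < 0 || sp$r[2] > 1) stop("r interval must lie within [0, 1]")
  if (sp$delta[1] < 0) stop("delta interval must be nonnegative")
  structure(sp, class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("Parameter search space:\n")
  for (nm in names(x))
    cat(sprintf("  %-5s [%g, %g]\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

space_width <- function(space) {
  vapply(space, function(iv) iv[2] - iv[1], numeric(1))
}

#' Draw uniform random parameters from a search space
#'
#' Each parameter is drawn independently and uniformly over its interval,
#' using the current RNG state (seed with `set.seed()`).
#'
#' @param space [search_space()].
#' @return A [ddm_params()] object.
#' @export
sample_parameters <- function(space) {
  stopifnot(inherits(space, "search_space"))
  v <- vapply(space, function(iv) stats::runif(1, iv[1], iv[2]), numeric(1))
  ddm_params(v[["sigma"]], v[["mu"]], v[["lam"]], v[["r"]], v[["delta"]])
}

#' Acceptability of a candidate target model
#'
#' Evaluates the seven inequalities a simulated model must satisfy to count
#' as a plausible (biologically realistic) target, on its labeled ISI
#' histograms. With `A_c(c)`/`A_i(c)` the correct/incorrect histogram areas
#' at coherence `c` and `h` the bin heights (per-bin time-normalized
#' convention):
#'
#' 1. minimum correct activity scaling with coherence: `A_c(c) >= 0.005 * c`;
#' 2. minimum incorrect activity scaling against coherence:
#'    `A_i(c) >= 0.005 * (1 - c)`;
#' 3. activity at full coherence: `A_c(1) > 0.01` or `A_i(1) > 0.01`;
#' 4. coherence growth and dominance, in either orientation:
#'    (`A_c(1) > 1.33 * A_c(0)` and `A_c(1) > 3.33 * A_i(1)`) or
#'    (`A_i(1) > 1.33 * A_i(0)` and `A_i(1) > 3.33 * A_c(1)`);
#' 5. no unnaturally regular correct events: all `h_correct <= 0.15`;
#' 6. likewise for incorrect events: all `h_incorrect <= 0.15`.
#'
#' The height cap is stated in the per-bin convention; under the density
#' convention it is applied to `h * bin_width` (the equivalent quantity).
#'
#' @param hists An `isi_histograms` object over coherence levels including
#'   0 and 1.
#' @return A list with `ok` (logical), `failed` (character vector of failed
#'   criteria) and `areas` (the labeled event-rate matrix).
#' @export
check_acceptability <- function(hists) {
  stopifnot(inherits(hists, "isi_histograms"))
  coh <- hists$coherence_levels
  if (!all(c(0, 1) %in% coh))
    stop("acceptability requires coherence levels 0 and 1")
  A <- histogram_areas(hists)  # labels x coherences
  ac <- A["correct", ]; ai <- A["incorrect", ]
  c0 <- as.character(0); c1 <- as.character(1)
  h <- hists$heights
  if (hists$height_convention == "density") h <- h * hists$bin_width
  failed <- character(0)
  if (!all(ac >= 0.005 * coh)) failed <- c(failed, "min_correct_activity")
  if (!all(ai >= 0.005 * (1 - coh))) failed <- c(failed, "min_incorrect_activity")
  if (!(ac[c1] > 0.01 || ai[c1] > 0.01)) failed <- c(failed, "activity_at_full_coherence")
  correct_dominant <- ac[c1] > 1.33 * ac[c0] && ac[c1] > 3.33 * ai[c1]
  incorrect_dominant <- ai[c1] > 1.33 * ai[c0] && ai[c1] > 3.33 * ac[c1]
  if (!(correct_dominant || incorrect_dominant))
    failed <- c(failed, "coherence_growth")
  if (!all(h[, , "correct"] <= 0.15)) failed <- c(failed, "correct_height_cap")
  if (!all(h[, , "incorrect"] <= 0.15)) failed <- c(failed, "incorrect_height_cap")
  list(ok = length(failed) == 0, failed = failed, areas = A)
}

#' Build a library of accepted target models
#'
#' Rejection sampling: draw uniform parameter sets, simulate each candidate
#' continuously per coherence level, histogram the events, and keep
#' candidates passing [check_acceptability()], until `n_models` are
#' accepted. Each stored model records the seed of its simulation so its
#' reference histograms can be reproduced exactly.
#'
#' @param space [search_space()].
#' @param n_models Number of accepted models to collect.
#' @param duration_per_coherence Simulation seconds per coherence level for
#'   each candidate (900 s matches the per-coherence data volume of a
#'   standard session).
#' @param protocol Protocol supplying coherence levels and the onset
#'   exclusion window; continuous mode is used regardless of its `mode`.
#' @param dt Euler step (s).
#' @param seed Master seed; candidate draws and simulations derive from it.
#' @param height_convention Passed to [isi_histograms()].
#' @param max_draws Abort when this many candidates have been drawn with an
#'   acceptance rate below 1e-4 (signals a mis-scaled search space).
#' @return A `model_library`: list with `models` (each `params`, `seed`,
#'   `hists`, `areas`), `n_drawn`, `acceptance_rate`, `space`, simulation
#'   settings.
#' @export
build_library <- function(space, n_models = 100, duration_per_coherence = 900,
                          protocol = stimulus_protocol(mode = "continuous"),
                          dt = 0.01, seed = 1,
                          height_convention = "per_bin",
                          max_draws = 1e5) {
  stopifnot(inherits(space, "search_space"), n_models >= 1)
  protocol <- stimulus_protocol(mode = "continuous",
                                coherence_levels = protocol$coherence_levels,
                                exclusion_window = protocol$exclusion_window)
  models <- vector("list", n_models)
  accepted <- 0L
  drawn <- 0L
  fail_tally <- integer(0)
  while (accepted < n_models) {
    drawn <- drawn + 1L
    if (drawn > max_draws && accepted / drawn < 1e-4)
      stop("acceptance rate below 1e-4 after ", drawn, " draws; failures: ",
           paste(names(fail_tally), fail_tally, sep = "=", collapse = ", "))
    set.seed(derive_seed(seed, drawn, 1L))
    params <- sample_parameters(space)
    sim_seed <- derive_seed(seed, drawn, 2L)
    cfg <- sim_config(dt = dt, seed = sim_seed,
                      duration_per_coherence = duration_per_coherence)
    ev <- simulate_ddm(params, protocol, cfg)
    h <- isi_histograms(ev, protocol, height_convention = height_convention)
    chk <- check_acceptability(h)
    if (chk$ok) {
      accepted <- accepted + 1L
      models[[accepted]] <- list(params = params, seed = sim_seed,
                                 hists = h, areas = chk$areas)
    } else {
      for (f in chk$failed)
        fail_tally[f] <- if (is.na(fail_tally[f])) 1L else fail_tally[f] + 1L
    }
  }
  structure(list(models = models, n_drawn = drawn,
                 acceptance_rate = n_models / drawn, space = space,
                 duration_per_coherence = duration_per_coherence,
                 protocol = protocol, dt = dt, seed = seed,
                 height_convention = height_convention,
                 failure_tally = fail_tally),
            class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat("Model library:", length(x$models), "accepted models from", x$n_drawn,
      sprintf("draws (acceptance rate %.3f)\n", x$acceptance_rate))
  cat("  simulated", x$duration_per_coherence, "s per coherence at dt =",
      x$dt, "\n")
  invisible(x)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(master, i, stream = 0L) {
  as.integer((as.double(master) %% 65011 + 1) * 16369 +
               as.double(i) * 131 + as.double(stream) * 7919) %% 2147483629L
}

#' Write / read a model library as JSON lines
#'
#' One model per line: parameters, simulation seed, areas. Histograms are
#' not stored; they are reproducible from the seed and settings (a header
#' line carries the settings).
#'
#' @param library A `model_library`.
#' @param file Path.
#' @return `write_library_jsonl` returns `file` invisibly;
#'   `read_library_jsonl` a list with `settings` and `models`
#'   (parameters + seeds; histograms must be re-simulated).
#' @export
write_library_jsonl <- function(library, file) {
  header <- jsonlite::toJSON(list(
    type = "model_library_header", n_models = length(library$models),
    n_drawn = library$n_drawn, acceptance_rate = library$acceptance_rate,
    space = lapply(library$space, identity),
    duration_per_coherence = library$duration_per_coherence,
    dt = library$dt, seed = library$seed,
    height_convention = library$height_convention), auto_unbox = TRUE,
    digits = NA)
  lines <- vapply(library$models, function(m) {
    jsonlite::toJSON(list(
      params = m$params[c("sigma", "mu", "lam", "r", "delta")],
      seed = m$seed,
      areas = list(correct = unname(m$areas["correct", ]),
                   incorrect = unname(m$areas["incorrect", ]))),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(c(header, lines), file)
  invisible(file)
}

#' @rdname write_library_jsonl
#' @export
read_library_jsonl <- function(file) {
  lines <- readLines(file)
  settings <- jsonlite::fromJSON(lines[1])
  models <- lapply(lines[-1], function(l) {
    doc <- jsonlite::fromJSON(l)
    list(params = ddm_params(doc$params$sigma, doc$params$mu, doc$params$lam,
                             doc$params$r, doc$params$delta),
         seed = doc$seed, areas = doc$areas)
  })
  list(settings = settings, models = models)
}
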
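#' Drift-diffusion model parameters
#'
#' Bundle the five free parameters of the bounded Ornstein-Uhlenbeck decision
#' model together with the (fixed) decision bound. The decision variable
#' evolves as `dx = (mu * f(I) - lam * x) dt + sigma dW` between absorbing
#' bounds at `+/-bound`; on a bound hit the state is reset to
#' `sign(x) * r * bound` and frozen for `delta` seconds.
#'
#' @param sigma Diffusion coefficient (bound units / sqrt(s)); `sigma >= 0`.
#' @param mu Drift gain converting transformed stimulus strength into
#'   deterministic drift (bound units / s).
#' @param lam Integrator leak (1/s). Positive values decay the state toward
#'   zero; negative values are self-reinforcing.
#' @param r Reset fraction retained after a decision; in `[0, 1]`.
#' @param delta Post-decision delay during which the integrator is frozen (s);
#'   `delta >= 0`.
#' @param bound Absorbing bound `B`. Fixed at 1 in all fitting contexts: the
#'   bound is redundant (it scales with `sigma` and `mu`), so it is not a free
#'   parameter.
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' ddm_params(sigma = 0.5, mu = 2, lam = 0.5, r = 0.3, delta = 0.2)
#' @export
ddm_params <- function(sigma, mu, lam, r, delta, bound = 1) {
  stopifnot(is.numeric(sigma), is.numeric(mu), is.numeric(lam),
            is.numeric(r), is.numeric(delta), is.numeric(bound))
  vals <- c(sigma = sigma, mu = mu, lam = lam, r = r, delta = delta,
            bound = bound)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (sigma < 0) stop("sigma must be >= 0")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  if (delta < 0) stop("delta must be >= 0")
  if (bound <= 0) stop("bound must be > 0")
  structure(list(sigma = sigma, mu = mu, lam = lam, r = r, delta = delta,
                 bound = bound), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Drift-diffusion parameters (bound B =", x$bound, ")\n")
  cat(sprintf("  sigma (diffusion) %8.4f  1/sqrt(s)\n", x$sigma))
  cat(sprintf("  mu    (drift)     %8.4f  1/s\n", x$mu))
  cat(sprintf("  lam   (leak)      %8.4f  1/s\n", x$lam))
  cat(sprintf("  r     (reset)     %8.4f\n", x$r))
  cat(sprintf("  delta (delay)     %8.4f  s\n", x$delta))
  invisible(x)
}

#' Coerce parameters to a named numeric vector of the five free parameters
#' @param x A `ddm_params` object or named numeric vector.
#' @return Named numeric vector `c(sigma, mu, lam, r, delta)`.
#' @export
params_vector <- function(x) {
  nm <- c("sigma", "mu", "lam", "r", "delta")
  if (inherits(x, "ddm_params"))
    return(stats::setNames(as.numeric(unlist(x[nm])), nm))
  if (is.numeric(x) && all(nm %in% names(x)))
    return(stats::setNames(as.numeric(x[nm]), nm))
  stop("cannot interpret 'x' as drift-diffusion parameters")
}

#' Stimulus protocol
#'
#' Describes how stimulation is organised in time: either one continuous
#' segment per coherence level, or the trial structure of a random-dot-motion
#' session (rest / stimulus / rest, with the coherence constant within a
#' trial). The first `exclusion_window` seconds after stimulus onset are
#' excluded from histogram analysis (onset adaptation).
#'
#' @param mode `"continuous"` (one uninterrupted stimulation segment per
#'   coherence) or `"trial"` (rest_pre + stimulus + rest_post repeated).
#' @param coherence_levels Stimulus strengths in `[0, 1]`.
#' @param rest_pre,stim_dur,rest_post Trial phase durations (s).
#' @param exclusion_window Seconds after stimulus onset excluded from
#'   analysis; must be shorter than `stim_dur`.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(mode = c("trial", "continuous"),
                              coherence_levels = c(0, 0.25, 0.5, 1),
                              rest_pre = 10, stim_dur = 30, rest_post = 10,
                              exclusion_window = 2) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(coherence_levels), length(coherence_levels) >= 1)
  if (any(coherence_levels < 0 | coherence_levels > 1))
    stop("coherence levels must lie in [0, 1]")
  if (anyDuplicated(coherence_levels)) stop("duplicated coherence levels")
  if (rest_pre < 0 || stim_dur <= 0 || rest_post < 0 || exclusion_window < 0)
    stop("durations must be nonnegative (stim_dur positive)")
  if (exclusion_window >= stim_dur)
    stop("exclusion_window must be shorter than stim_dur")
  structure(list(mode = mode, coherence_levels = sort(coherence_levels),
                 rest_pre = rest_pre, stim_dur = stim_dur,
                 rest_post = rest_post, exclusion_window = exclusion_window),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol (", x$mode, " mode)\n", sep = "")
  cat("  coherences:", paste(x$coherence_levels, collapse = ", "), "\n")
  if (x$mode == "trial")
    cat(sprintf("  trial: %g s rest / %g s stimulus / %g s rest\n",
                x$rest_pre, x$stim_dur, x$rest_post))
  cat(sprintf("  onset exclusion window: %g s\n", x$exclusion_window))
  invisible(x)
}

#' Simulation configuration
#'
#' @param dt Euler time step (s); 0.01 s is adequate (no accuracy gain below
#'   it, instabilities near 0.1 s).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param n_trials Trials per coherence level (`mode = "trial"`).
#' @param duration_per_coherence Stimulation seconds per coherence
#'   (`mode = "continuous"`).
#' @param x0 Initial decision-variable state at the start of each session.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, seed = NULL, n_trials = NULL,
                       duration_per_coherence = NULL, x0 = 0) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) seed <- as.integer(seed)
  if (!is.null(n_trials) && n_trials < 0) stop("n_trials must be >= 0")
  if (!is.null(duration_per_coherence) && duration_per_coherence < 0)
    stop("duration_per_coherence must be >= 0")
  structure(list(dt = dt, seed = seed, n_trials = n_trials,
                 duration_per_coherence = duration_per_coherence, x0 = x0),
            class = "sim_config")
}

#' Read or write model settings as JSON
#'
#' Parameters, protocol and simulation configuration share one JSON document
#' with keys `sigma, mu, lam, r, delta, bound, dt, seed, x0, mode,
#' coherences, rest_pre, stim_dur, rest_post, exclusion_window, n_trials,
#' duration_per_coherence`. Missing keys take the constructors' defaults.
#'
#' @param params,protocol,config Objects to serialize (any may be `NULL`).
#' @param file Path to a JSON file.
#' @return `write_settings_json` returns `file` invisibly;
#'   `read_settings_json` returns a list with elements `params`, `protocol`,
#'   `config` (elements are `NULL` when their keys are absent).
#' @export
write_settings_json <- function(file, params = NULL, protocol = NULL,
                                config = NULL) {
  doc <- list()
  if (!is.null(params))
    doc <- c(doc, params[c("sigma", "mu", "lam", "r", "delta", "bound")])
  if (!is.null(protocol))
    doc <- c(doc, list(mode = protocol$mode,
                       coherences = protocol$coherence_levels,
                       rest_pre = protocol$rest_pre,
                       stim_dur = protocol$stim_dur,
                       rest_post = protocol$rest_post,
                       exclusion_window = protocol$exclusion_window))
  if (!is.null(config))
    doc <- c(doc, Filter(Negate(is.null),
                         config[c("dt", "seed", "n_trials",
                                  "duration_per_coherence", "x0")]))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_settings_json
#' @export
read_settings_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  params <- NULL
  if (all(c("sigma", "mu", "lam", "r", "delta") %in% names(doc)))
    params <- ddm_params(doc$sigma, doc$mu, doc$lam, doc$r, doc$delta,
                         bound = if (is.null(doc$bound)) 1 else doc$bound)
  protocol <- NULL
  if (!is.null(doc$coherences) || !is.null(doc$mode)) {
    args <- list()
    if (!is.null(doc$mode)) args$mode <- doc$mode
    if (!is.null(doc$coherences)) args$coherence_levels <- doc$coherences
    for (k in c("rest_pre", "stim_dur", "rest_post", "exclusion_window"))
      if (!is.null(doc[[k]])) args[[k]] <- doc[[k]]
    protocol <- do.call(stimulus_protocol, args)
  }
  config <- NULL
  if (any(c("dt", "seed", "n_trials", "duration_per_coherence", "x0") %in%
          names(doc))) {
    args <- list()
    for (k in c("dt", "seed", "n_trials", "duration_per_coherence", "x0"))
      if (!is.null(doc[[k]])) args[[k]] <- doc[[k]]
    config <- do.call(sim_config, args)
  }
  list(params = params, protocol = protocol, config = config)
}
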
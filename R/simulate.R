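#' Sublinear stimulus transform
#'
#' Maps stimulus strength (motion coherence) to integrator input following a
#' Weber-law-style power transform with fixed exponent 0.5, `f(I) = sqrt(I)`.
#'
#' @param I Stimulus strength in `[0, 1]` (vectorized).
#' @return `sqrt(I)`, in `[0, 1]`.
#' @examples
#' input_transform(c(0, 0.25, 1))  # 0, 0.5, 1
#' @export
input_transform <- function(I) {
  if (!is.numeric(I) || any(!is.finite(I)) || any(I < 0 | I > 1))
    stop("stimulus strength must lie in [0, 1]")
  sqrt(I)
}

#' One Euler step of the decision variable
#'
#' Pure-arithmetic reference update used for testing and documentation; the
#' simulator applies the same update in compiled code. The stochastic
#' increment has standard deviation `sigma * sqrt(dt)`, which makes event
#' statistics comparable across choices of `dt`.
#'
#' @param x Current state (bound units).
#' @param params [ddm_params()].
#' @param I Stimulus strength in `[0, 1]`.
#' @param dt Time step (s).
#' @param noise_draw Standard-normal deviate.
#' @return Updated state.
#' @examples
#' p <- ddm_params(0, 2, 0, 0, 0)
#' ddm_step(0, p, I = 1, dt = 0.01, noise_draw = 0)  # 0.02
#' @export
ddm_step <- function(x, params, I, dt, noise_draw = 0) {
  x + (params$mu * input_transform(I) - params$lam * x) * dt +
    params$sigma * sqrt(dt) * noise_draw
}

# Build the segment table (one row per constant-stimulus stretch) that the
# compiled simulator consumes. Sessions are continuous processes: one session
# per coherence level.
protocol_segments <- function(protocol, config) {
  coh <- protocol$coherence_levels
  if (protocol$mode == "continuous") {
    dur <- config$duration_per_coherence
    if (is.null(dur)) stop("continuous mode needs config$duration_per_coherence")
    data.frame(coherence = coh, duration = dur, phase = 1L,
               trial_id = 1L, session = seq_along(coh))
  } else {
    n <- config$n_trials
    if (is.null(n)) stop("trial mode needs config$n_trials")
    segs <- vector("list", length(coh))
    for (i in seq_along(coh)) {
      per_trial <- data.frame(
        coherence = c(0, coh[i], 0),
        duration = c(protocol$rest_pre, protocol$stim_dur, protocol$rest_post),
        phase = c(0L, 1L, 0L))
      per_trial <- per_trial[per_trial$duration > 0, , drop = FALSE]
      tr <- per_trial[rep(seq_len(nrow(per_trial)), n), , drop = FALSE]
      tr$trial_id <- rep(seq_len(n), each = nrow(per_trial))
      tr$session <- i
      # stimulus identity of the session (needed because rest phases show 0%)
      tr$session_coherence <- coh[i]
      segs[[i]] <- tr
    }
    do.call(rbind, segs)
  }
}

#' Simulate the decision process
#'
#' Runs the forward-Euler simulation of the bounded Ornstein-Uhlenbeck
#' process for every coherence level of the protocol and returns the decision
#' events. A decision event is recorded whenever `|x| >= B` at the end of a
#' step; the state is then partially reset to `sign(x) * r * B` and frozen
#' for `delta` seconds (the inter-event clock keeps running). Events at the
#' upper bound are `"correct"`, at the lower bound `"incorrect"`. Each
#' coherence level forms one continuous session: the state carries over
#' across trial boundaries within a session (including rest phases, where
#' `I = 0`), and is reset to `x0` only at session start.
#'
#' @param params [ddm_params()].
#' @param protocol [stimulus_protocol()].
#' @param config [sim_config()]; `seed` (when non-`NULL`) makes the output
#'   reproducible.
#' @return An `event_series`: a data frame with columns `time_s` (within
#'   session), `isi_s` (time since the previous event in the session; for a
#'   session's first event, time since session start), `label`, `coherence`
#'   (the session's stimulus level), `trial_id`, `phase`, `t_stim_s` (time
#'   since stimulus onset, `NA` in rest), `session`; with attributes
#'   `protocol` and `stim_time` (analysed stimulation seconds per coherence,
#'   i.e. excluding the onset window).
#' @examples
#' p <- ddm_params(sigma = 0, mu = 2, lam = 0, r = 0, delta = 0)
#' pr <- stimulus_protocol(mode = "continuous", coherence_levels = 1)
#' ev <- simulate_ddm(p, pr, sim_config(duration_per_coherence = 5, seed = 1))
#' ev$isi_s  # every interval 0.5 s: drift 2 reaches the bound in B/mu s
#' @export
simulate_ddm <- function(params, protocol, config) {
  stopifnot(inherits(params, "ddm_params"),
            inherits(protocol, "stimulus_protocol"),
            inherits(config, "sim_config"))
  segs <- protocol_segments(protocol, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  ev <- sim_ou_events(params$sigma, params$mu, params$lam, params$r,
                      params$delta, config$dt, params$bound, config$x0,
                      segs$coherence, segs$duration, segs$phase,
                      segs$trial_id, segs$session)
  coh_levels <- protocol$coherence_levels
  out <- data.frame(
    time_s = ev$time_s,
    isi_s = ev$isi_s,
    label = ifelse(ev$label_sign > 0, "correct", "incorrect"),
    coherence = coh_levels[ev$session],
    trial_id = ev$trial_id,
    phase = ifelse(ev$phase_code == 1L, "stimulus", "rest"),
    session = ev$session,
    stringsAsFactors = FALSE)
  # time since stimulus onset (for the steady-state onset exclusion)
  if (protocol$mode == "continuous") {
    out$t_stim_s <- ifelse(out$phase == "stimulus", out$time_s, NA_real_)
    stim_time <- rep(max(config$duration_per_coherence -
                           protocol$exclusion_window, 0), length(coh_levels))
  } else {
    cycle <- protocol$rest_pre + protocol$stim_dur + protocol$rest_post
    onset <- (out$trial_id - 1) * cycle + protocol$rest_pre
    out$t_stim_s <- ifelse(out$phase == "stimulus", out$time_s - onset,
                           NA_real_)
    stim_time <- rep(config$n_trials *
                       (protocol$stim_dur - protocol$exclusion_window),
                     length(coh_levels))
  }
  names(stim_time) <- as.character(coh_levels)
  structure(out, protocol = protocol, stim_time = stim_time, dt = config$dt,
            class = c("event_series", "data.frame"))
}

#' Total analysed stimulation time per coherence
#' @param events An `event_series` (or a data frame carrying the attribute).
#' @return Named numeric vector, seconds per coherence level.
#' @export
stim_time <- function(events) {
  st <- attr(events, "stim_time")
  if (is.null(st)) stop("object carries no stimulation-time attribute")
  st
}

#' Write / read decision events as CSV
#'
#' One header line, '.' decimal separator; columns `time_s, isi_s, label,
#' coherence, trial_id, phase` (extra columns such as `t_stim_s` are kept).
#'
#' @param events Event table.
#' @param file Path.
#' @return `write_events` returns `file` invisibly; `read_events` a data
#'   frame.
#' @export
write_events <- function(events, file) {
  utils::write.csv(as.data.frame(events), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Analytic noise-free first-passage time
#'
#' Deterministic-limit crossing time of the leaky integrator starting at
#' `x0` under constant drive `mu * sqrt(I)`: with `lam != 0` the trajectory
#' relaxes toward `x* = mu * sqrt(I) / lam` and crosses the bound at
#' `t = log((x* - x0) / (x* - B)) / lam` when a crossing is attainable;
#' with `lam = 0` the crossing is at `(B - x0) / (mu * sqrt(I))`. Used as an
#' independent oracle for the simulator.
#'
#' @param params [ddm_params()] (with `sigma` ignored; the formula is the
#'   `sigma = 0` limit).
#' @param I Stimulus strength.
#' @param x0 Starting state.
#' @return Crossing time of `+B` in seconds, or `Inf` when unattainable.
#' @export
first_passage_deterministic <- function(params, I, x0 = 0) {
  drive <- params$mu * input_transform(I)
  B <- params$bound
  if (params$lam == 0) {
    if (drive <= 0) return(Inf)
    return((B - x0) / drive)
  }
  xs <- drive / params$lam
  ratio <- (xs - x0) / (xs - B)
  if (!is.finite(ratio) || ratio <= 0) return(Inf)
  t <- log(ratio) / params$lam
  if (t <= 0) Inf else t
}
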
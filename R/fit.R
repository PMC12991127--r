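# Map between the unit cube used by the optimizer and parameter space.
unit_to_params <- function(u, space) {
  lo <- vapply(space, `[`, numeric(1), 1)
  ddm_params(sigma = lo[["sigma"]] + u[1] * (space$sigma[2] - space$sigma[1]),
             mu = lo[["mu"]] + u[2] * (space$mu[2] - space$mu[1]),
             lam = lo[["lam"]] + u[3] * (space$lam[2] - space$lam[1]),
             r = min(max(lo[["r"]] + u[4] * (space$r[2] - space$r[1]), 0), 1),
             delta = lo[["delta"]] + u[5] * (space$delta[2] - space$delta[1]))
}

params_to_unit <- function(params, space) {
  p <- params_vector(params)
  lo <- vapply(space, `[`, numeric(1), 1)
  w <- space_width(space)
  (p - lo[names(p)]) / w[names(p)]
}

# Simulate a candidate parameter set under the evaluation protocol and score
# it against the target histograms. The evaluation seed depends only on the
# call index (common random numbers across proposals at the same index).
evaluate_candidate <- function(params, target, protocol, trials_per_eval,
                               dt, eval_seed, metric, height_convention) {
  cfg <- if (protocol$mode == "trial") {
    sim_config(dt = dt, seed = eval_seed, n_trials = trials_per_eval)
  } else {
    sim_config(dt = dt, seed = eval_seed,
               duration_per_coherence = trials_per_eval * protocol$stim_dur)
  }
  ev <- simulate_ddm(params, protocol, cfg)
  h <- isi_histograms(ev, protocol, bin_width = target$bin_width,
                      isi_max = max(target$bin_edges),
                      height_convention = height_convention)
  total_loss(target, h, metric = metric)
}

#' Fit drift-diffusion parameters to target histograms
#'
#' Minimizes the histogram loss over the five-dimensional search space by
#' Bayesian optimization: a Gaussian-process surrogate with a Matern 5/2
#' covariance on the unit-cube-scaled parameters, `n_init` uniform random
#' initial evaluations, and thereafter a hedged acquisition that chooses
#' probabilistically among lower confidence bound, expected improvement and
#' probability of improvement (the hedge weights update with the surrogate
#' mean at each strategy's proposal). Every function call simulates the
#' candidate model for `trials_per_eval` trials per coherence level under
#' the evaluation protocol and scores the resulting histograms against the
#' target with [total_loss()]. The loss is stochastic; each call index uses
#' a fixed derived seed so that runs are reproducible bit-for-bit from the
#' master seed.
#'
#' @param target `isi_histograms` to match.
#' @param space [search_space()].
#' @param budget Total number of function calls (default 1500).
#' @param n_init Random initial evaluations before the surrogate is used
#'   (default 100).
#' @param trials_per_eval Trials per coherence level per call (default 2000;
#'   with a continuous evaluation protocol, each "trial" contributes one
#'   `stim_dur` of stimulation).
#' @param seed Master seed (all randomness derives from it).
#' @param protocol Evaluation protocol; defaults to the protocol the target
#'   histograms were built under (matching the generating process avoids a
#'   systematic histogram mismatch), falling back to the standard trial
#'   structure over the target's coherence levels.
#' @param dt Euler step (s).
#' @param metric `"dkl_star"` or `"dkl"`.
#' @param optimizer `"gp"` (Bayesian optimization) or `"random"` (uniform
#'   random search with the same budget and evaluation settings; a
#'   correctness baseline).
#' @param preset `"desk"` applies the reduced desk-scale settings
#'   (budget 300, n_init 50, 300 trials per evaluation) unless those
#'   arguments are given explicitly.
#' @param refit_every Re-select GP hyperparameters every this many
#'   iterations (the factorization itself is updated every iteration).
#' @return A `fit_result`: list with `best_params`, `best_loss`, `trace`
#'   (data frame of evaluated parameters, losses and best-so-far loss),
#'   and `settings`.
#' @export
fit_ddm <- function(target, space, budget = 1500, n_init = 100,
                    trials_per_eval = 2000, seed = 1,
                    protocol = NULL, dt = 0.01,
                    metric = c("dkl_star", "dkl"),
                    optimizer = c("gp", "random"),
                    preset = NULL, refit_every = 10) {
  metric <- match.arg(metric)
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(target, "isi_histograms"), inherits(space, "search_space"))
  if (!is.null(preset) && preset == "desk") {
    if (missing(budget)) budget <- 300
    if (missing(n_init)) n_init <- 50
    if (missing(trials_per_eval)) trials_per_eval <- 300
  }
  if (budget <= n_init) stop("budget must exceed n_init")
  if (is.null(protocol)) protocol <- target$protocol
  if (is.null(protocol))
    protocol <- stimulus_protocol(mode = "trial",
                                  coherence_levels = target$coherence_levels)
  d <- 5L
  U <- matrix(NA_real_, budget, d)
  losses <- numeric(budget)
  hedge_gains <- c(lcb = 0, ei = 0, pi = 0)
  gp <- NULL
  hypers <- NULL
  for (j in seq_len(budget)) {
    if (optimizer == "random" || j <= n_init) {
      set.seed(derive_seed(seed, j, 4L))
      u <- stats::runif(d)
    } else {
      refit <- is.null(hypers) || (j - n_init - 1) %% refit_every == 0
      # the loss spans orders of magnitude near its noise floor; the
      # surrogate models log-loss so the bottom of the basin stays resolved
      yobs <- log(pmax(losses[seq_len(j - 1)], 1e-12))
      gp <- gp_train(U[seq_len(j - 1), , drop = FALSE], yobs,
                     hypers = if (refit) NULL else hypers)
      hypers <- list(ls = gp$ls, noise = gp$noise)
      set.seed(derive_seed(seed, j, 4L))
      # GP prediction is orders of magnitude cheaper than one simulation,
      # so the candidate pool is large: global uniform cover plus local
      # refinement around the best observed points at several scales
      ncand <- 2000L
      cand <- matrix(stats::runif(ncand * d), ncand, d)
      ord <- order(losses[seq_len(j - 1)])
      for (top in seq_len(min(3, length(ord)))) {
        centre <- U[ord[top], ]
        for (s in c(0.02, 0.05, 0.15)) {
          local <- matrix(rep(centre, each = 60L), 60L, d) +
            matrix(stats::rnorm(60L * d, sd = s), 60L, d)
          cand <- rbind(cand, pmin(pmax(local, 0), 1))
        }
      }
      pred <- gp_predict(gp, cand)
      best_z <- (min(yobs) - gp$ym) / gp$ys
      acq <- acquisition_scores(pred, best_z)
      proposals <- vapply(acq, which.max, integer(1))
      pr <- exp(hedge_gains - max(hedge_gains))
      pick <- sample(3L, 1L, prob = pr / sum(pr))
      u <- cand[proposals[pick], ]
      # hedge update: reward each strategy by the (negated) surrogate mean
      # at its own proposal
      hedge_gains <- hedge_gains - pred$mean[proposals]
    }
    U[j, ] <- u
    params <- unit_to_params(u, space)
    losses[j] <- evaluate_candidate(params, target, protocol, trials_per_eval,
                                    dt, derive_seed(seed, j, 3L), metric,
                                    target$height_convention)
    if (!is.finite(losses[j])) losses[j] <- NA_real_
  }
  if (all(is.na(losses))) stop("all evaluations were non-finite")
  best_j <- which.min(losses)
  pmat <- t(apply(U, 1, function(u) params_vector(unit_to_params(u, space))))
  colnames(pmat) <- c("sigma", "mu", "lam", "r", "delta")
  trace <- data.frame(iteration = seq_len(budget), pmat, loss = losses,
                      best_loss = cummin(ifelse(is.na(losses), Inf, losses)))
  structure(list(
    best_params = unit_to_params(U[best_j, ], space),
    best_loss = losses[best_j],
    trace = trace,
    settings = list(budget = budget, n_init = n_init,
                    trials_per_eval = trials_per_eval, seed = seed,
                    dt = dt, metric = metric, optimizer = optimizer,
                    protocol = protocol, space = space,
                    acquisition = list(kind = "gp_hedge",
                                       members = c("lcb", "ei", "pi"),
                                       kappa = 1.96, xi = 0.01),
                    refit_every = refit_every)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Drift-diffusion fit (", x$settings$optimizer, " optimizer, ",
      x$settings$budget, " calls, metric ", x$settings$metric, ")\n", sep = "")
  cat(sprintf("  best loss %.6g at iteration %d\n", x$best_loss,
              which.min(x$trace$loss)))
  print(x$best_params)
  invisible(x)
}

#' Normalized parameter estimation error
#'
#' `e(j) = |p(j) - p_target| / |m_max - m_min|` per parameter: the absolute
#' estimation error normalized by the width of that parameter's search
#' range. Only computable for model-generated targets, where the true
#' parameters are known.
#'
#' @param p Estimated parameters ([ddm_params()] or named vector).
#' @param p_target True generating parameters.
#' @param space [search_space()].
#' @return Named numeric vector of five normalized errors.
#' @export
estimation_error <- function(p, p_target, space) {
  w <- space_width(space)
  if (any(w <= 0)) stop("zero-width search range")
  abs(params_vector(p) - params_vector(p_target)) / w[names(params_vector(p))]
}

#' Normalized distance to the final estimate
#'
#' `d(j) = |p(j) - p_final| / |m_max - m_min|`: as [estimation_error()] but
#' relative to the final estimate, usable when the true parameters are
#' unknown (experimental targets).
#'
#' @param p Parameters at optimization step `j`.
#' @param p_final Final estimated parameters.
#' @param space [search_space()].
#' @return Named numeric vector of five normalized distances.
#' @export
estimation_distance <- function(p, p_final, space) {
  estimation_error(p, p_final, space)
}

#' Repeated fits with distinct seeds
#'
#' Runs [fit_ddm()] `n_runs` times with seeds derived from the master seed
#' and summarises the per-parameter estimates by their median and the
#' 10th-90th percentile interval across runs.
#'
#' @param target,space,... Passed to [fit_ddm()].
#' @param n_runs Number of repeated optimization runs (default 10).
#' @param seed Master seed.
#' @return List with `fits` (the individual `fit_result`s), `estimates`
#'   (runs x parameters matrix), `median`, and `interval` (2 x parameters,
#'   rows `p10`/`p90`).
#' @export
repeat_fit <- function(target, space, n_runs = 10, seed = 1, ...) {
  stopifnot(n_runs >= 2)
  fits <- lapply(seq_len(n_runs), function(k)
    fit_ddm(target, space, seed = derive_seed(seed, k, 5L), ...))
  est <- t(vapply(fits, function(f) params_vector(f$best_params), numeric(5)))
  med <- apply(est, 2, stats::median)
  interval <- apply(est, 2, stats::quantile, probs = c(0.1, 0.9))
  rownames(interval) <- c("p10", "p90")
  list(fits = fits, estimates = est, median = med, interval = interval)
}

#' Write a fit result (including the full trace) as JSON
#' @param fit A `fit_result`.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  doc <- list(
    best_params = fit$best_params[c("sigma", "mu", "lam", "r", "delta")],
    best_loss = fit$best_loss,
    trace = fit$trace,
    settings = list(budget = fit$settings$budget,
                    n_init = fit$settings$n_init,
                    trials_per_eval = fit$settings$trials_per_eval,
                    seed = fit$settings$seed, dt = fit$settings$dt,
                    metric = fit$settings$metric,
                    optimizer = fit$settings$optimizer,
                    acquisition = fit$settings$acquisition))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}
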
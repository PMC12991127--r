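# Shared fixtures built in code at test time.

# A quiet stochastic parameter set with moderate event rates.
fixture_params <- function() ddm_params(sigma = 0.8, mu = 1.5, lam = 0.5,
                                        r = 0.3, delta = 0.2)

fixture_protocol_cont <- function(coherences = c(0, 0.25, 0.5, 1))
  stimulus_protocol(mode = "continuous", coherence_levels = coherences)

# Small histogram pair over two bins for hand-computed loss checks.
fixture_hists_manual <- function(h_correct, h_incorrect = h_correct,
                                 coherences = c(0, 1), total_time = 100,
                                 bin_width = 0.05) {
  nb <- length(h_correct)
  heights <- array(0, dim = c(nb, length(coherences), 2),
                   dimnames = list(NULL, as.character(coherences),
                                   c("correct", "incorrect")))
  for (ci in seq_along(coherences)) {
    heights[, ci, 1] <- h_correct
    heights[, ci, 2] <- h_incorrect
  }
  tt <- stats::setNames(rep(total_time, length(coherences)),
                        as.character(coherences))
  structure(list(bin_edges = seq(0, by = bin_width, length.out = nb + 1),
                 heights = heights, total_time = tt,
                 counts = sweep(heights, 2, tt, "*"), n_excluded = 0L,
                 bin_width = bin_width, height_convention = "per_bin",
                 coherence_levels = coherences,
                 protocol = stimulus_protocol(
                   mode = "continuous", coherence_levels = coherences)),
            class = "isi_histograms")
}

# Direct-summation oracle for the weighted divergence (independent of the
# package implementation; no smoothing, assumes strictly positive bins).
oracle_dkl_star <- function(p0, p1, p2) {
  s <- 0
  for (n in seq_along(p1))
    if (p0[n] > 0 && p1[n] > 0) s <- s + p0[n] * p1[n] * log(p1[n] / p2[n])
  s
}

oracle_dkl <- function(p1, p2) {
  s <- 0
  for (n in seq_along(p1)) if (p1[n] > 0) s <- s + p1[n] * log(p1[n] / p2[n])
  s
}

# Windowed-variance oracle: literal centered window, population variance.
oracle_rolling_var <- function(x, k) {
  n <- length(x)
  half_lo <- (k - 1) %/% 2
  half_hi <- k - 1 - half_lo
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half_lo):min(n, i + half_hi)]
    mean(w^2) - mean(w)^2
  }, numeric(1))
}

make_event_table <- function(isi, label = "correct", coherence = 1,
                             t_stim = 10) {
  n <- length(isi)
  data.frame(isi_s = isi, label = rep_len(label, n),
             coherence = rep_len(coherence, n),
             phase = rep_len("stimulus", n), t_stim_s = rep_len(t_stim, n))
}
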
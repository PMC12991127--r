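#' Labeled inter-swim-interval histograms
#'
#' Bins inter-event intervals of steady-state stimulus-phase events per
#' (coherence, label) pair into half-open bins `[lo, hi)` spanning 0-2 s in
#' 0.05 s steps (the bin width is five simulation steps, which makes binning
#' of model-generated events robust), and normalizes counts by the total
#' analysed stimulation time. Events are retained when they occur in the
#' stimulus phase at least `exclusion_window` seconds after stimulus onset
#' (steady state), carry a `correct`/`incorrect` label, and have an interval
#' inside `[0, isi_max)`; intervals outside the range are tallied as
#' excluded.
#'
#' Height conventions: `"per_bin"` (default) divides bin counts by the total
#' stimulation time only, so heights are events per second falling in the
#' bin and the histogram area `A = sum(h)` is the in-range event rate
#' (events/s). `"density"` additionally divides by the bin width; the area
#' `A = sum(h) * binwidth` is the same event rate. The two conventions only
#' rescale heights by a constant.
#'
#' @param events An `event_series` from [simulate_ddm()] or a swim-event
#'   table with columns `isi_s`, `label`, `coherence`, `phase`, `t_stim_s`.
#' @param protocol [stimulus_protocol()]; defaulted from the `event_series`
#'   attribute when absent.
#' @param total_time Named vector of analysed stimulation seconds per
#'   coherence; defaulted from the `event_series` attribute.
#' @param bin_width,isi_max Bin width and upper interval bound (s).
#' @param height_convention `"per_bin"` or `"density"`.
#' @return An `isi_histograms` object: list with `bin_edges`, `heights`
#'   (array `bins x coherences x labels`), `total_time`, `counts` (retained
#'   per histogram), `n_excluded`, `bin_width`, `height_convention`.
#' @export
isi_histograms <- function(events, protocol = attr(events, "protocol"),
                           total_time = attr(events, "stim_time"),
                           bin_width = 0.05, isi_max = 2,
                           height_convention = c("per_bin", "density")) {
  height_convention <- match.arg(height_convention)
  if (is.null(protocol)) stop("a stimulus protocol is required")
  if (is.null(total_time)) stop("total stimulation time per coherence is required")
  coh <- protocol$coherence_levels
  total_time <- total_time[as.character(coh)]
  if (any(is.na(total_time)))
    stop("total_time must be named by every protocol coherence level")
  ev <- as.data.frame(events)
  req <- c("isi_s", "label", "coherence", "phase", "t_stim_s")
  miss <- setdiff(req, names(ev))
  if (length(miss)) stop("event table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(ev) && !all(ev$coherence %in% coh))
    stop("event table contains coherence levels absent from the protocol")

  edges <- seq(0, isi_max, by = bin_width)
  nb <- length(edges) - 1L
  labels <- c("correct", "incorrect")
  counts <- array(0, dim = c(nb, length(coh), 2),
                  dimnames = list(NULL, as.character(coh), labels))
  keep <- !is.na(ev$isi_s) & ev$phase == "stimulus" &
    !is.na(ev$t_stim_s) & ev$t_stim_s >= protocol$exclusion_window &
    ev$label %in% labels
  ev <- ev[keep, , drop = FALSE]
  in_range <- ev$isi_s >= 0 & ev$isi_s < isi_max
  n_excluded <- sum(!in_range)
  ev <- ev[in_range, , drop = FALSE]
  if (nrow(ev)) {
    bin <- pmin(floor(ev$isi_s / bin_width) + 1L, nb)  # half-open [lo, hi)
    ci <- match(ev$coherence, coh)
    li <- match(ev$label, labels)
    tab <- table(factor(bin, levels = seq_len(nb)),
                 factor(ci, levels = seq_along(coh)),
                 factor(li, levels = 1:2))
    counts[] <- as.numeric(tab)
  }
  heights <- sweep(counts, 2, total_time, "/")
  heights[!is.finite(heights)] <- 0  # zero observation time -> empty histogram
  if (height_convention == "density") heights <- heights / bin_width
  structure(list(bin_edges = edges, heights = heights,
                 total_time = total_time,
                 counts = counts, n_excluded = n_excluded,
                 bin_width = bin_width,
                 height_convention = height_convention,
                 coherence_levels = coh, protocol = protocol),
            class = "isi_histograms")
}

#' @export
print.isi_histograms <- function(x, ...) {
  cat("Labeled ISI histograms:", dim(x$heights)[1], "bins of", x$bin_width,
      "s,", length(x$coherence_levels), "coherences x 2 labels (",
      x$height_convention, ")\n")
  cat("  event rates (events/s):\n")
  print(round(histogram_areas(x), 4))
  cat("  intervals outside range:", x$n_excluded, "\n")
  invisible(x)
}

#' Histogram areas (labeled event rates)
#'
#' The area under each time-normalized histogram equals the rate of in-range
#' events of that label (events per second of analysed stimulation),
#' identical under both height conventions.
#'
#' @param hists An `isi_histograms` object.
#' @return Matrix `labels x coherences` of event rates.
#' @export
histogram_areas <- function(hists) {
  a <- apply(hists$heights, c(2, 3), sum)
  if (hists$height_convention == "density") a <- a * hists$bin_width
  t(a)
}

#' Kullback-Leibler divergence between time-normalized histograms
#'
#' `dkl(P1, P2) = sum_n P1(n) * log(P1(n) / P2(n))` with the conventions
#' `0 * log(0 / x) = 0` and denominator bins clamped at
#' `eps = 1e-6 * max(1, max(P1))` so the sum is defined when `P2` has empty
#' bins. Heights are used as printed (not renormalized to probabilities).
#'
#' @param p1,p2 Nonnegative height vectors of equal length.
#' @return Scalar divergence (0 when `p1 == p2`).
#' @examples
#' dkl(c(0.2, 0.1), c(0.1, 0.2))  # 0.1 * log(2)
#' @export
dkl <- function(p1, p2) {
  check_hist_pair(p1, p2)
  eps <- 1e-6 * max(1, max(p1))
  q <- pmax(p2, eps)
  terms <- ifelse(p1 > 0, p1 * log(p1 / q), 0)
  sum(terms)
}

#' Height-weighted Kullback-Leibler divergence
#'
#' `dkl_star(P0, P1, P2) = sum_n P0(n) * P1(n) * log(P1(n) / P2(n))`:
#' each bin's contribution is weighted by a reference histogram `P0`
#' (normally the target), so errors in tall peak bins dominate errors in
#' flat tails. Zero-bin conventions as in [dkl()].
#'
#' @param p0 Weighting histogram.
#' @param p1,p2 Compared histograms.
#' @return Scalar weighted divergence.
#' @export
dkl_star <- function(p0, p1, p2) {
  check_hist_pair(p1, p2)
  if (length(p0) != length(p1) || any(p0 < 0) || any(!is.finite(p0)))
    stop("p0 must be a nonnegative vector matching p1 in length")
  eps <- 1e-6 * max(1, max(p1))
  q <- pmax(p2, eps)
  terms <- ifelse(p0 > 0 & p1 > 0, p0 * p1 * log(p1 / q), 0)
  sum(terms)
}

check_hist_pair <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("histograms must have equal length")
  if (any(p1 < 0) || any(p2 < 0)) stop("histogram bins must be nonnegative")
  if (any(!is.finite(p1)) || any(!is.finite(p2)))
    stop("histogram bins must be finite")
  invisible(TRUE)
}

#' Symmetrized histogram distance
#'
#' The weighted divergence is asymmetric, so both orientations are computed,
#' `d0 = dkl_star(Pt, Pt, Pm)` and `d1 = dkl_star(Pt, Pm, Pt)`, and the
#' larger value taken. With `metric = "dkl"` the unweighted divergence is
#' used in both orientations instead.
#'
#' @param p_target,p_model Height vectors.
#' @param metric `"dkl_star"` (default) or `"dkl"`.
#' @return `max(d0, d1)`.
#' @export
pair_distance <- function(p_target, p_model, metric = c("dkl_star", "dkl")) {
  metric <- match.arg(metric)
  if (metric == "dkl_star") {
    d0 <- dkl_star(p_target, p_target, p_model)
    d1 <- dkl_star(p_target, p_model, p_target)
  } else {
    d0 <- dkl(p_target, p_model)
    d1 <- dkl(p_model, p_target)
  }
  max(d0, d1)
}

#' Total loss between two labeled histogram sets
#'
#' Mean of [pair_distance()] over the (coherence, label) histogram pairs
#' (eight with the default four coherence levels). Pairs that are empty in
#' both sets (for example incorrect events at full coherence) contribute 0.
#'
#' @param target,model `isi_histograms` objects with identical binning,
#'   coherence levels and height convention.
#' @param metric Passed to [pair_distance()].
#' @return Scalar loss; 0 when the histogram sets are identical.
#' @export
total_loss <- function(target, model, metric = c("dkl_star", "dkl")) {
  metric <- match.arg(metric)
  stopifnot(inherits(target, "isi_histograms"), inherits(model, "isi_histograms"))
  if (!isTRUE(all.equal(target$bin_edges, model$bin_edges)))
    stop("histogram sets differ in binning")
  if (!identical(target$coherence_levels, model$coherence_levels))
    stop("histogram sets differ in coherence levels")
  if (!identical(target$height_convention, model$height_convention))
    stop("histogram sets differ in height convention")
  d <- 0
  npairs <- 0L
  for (ci in seq_along(target$coherence_levels)) {
    for (li in 1:2) {
      npairs <- npairs + 1L
      d <- d + pair_distance(target$heights[, ci, li],
                             model$heights[, ci, li], metric = metric)
    }
  }
  d / npairs
}

#' Write / read labeled histograms as JSON
#' @param hists An `isi_histograms` object.
#' @param file Path to a JSON file.
#' @return `write_histograms_json` returns `file` invisibly;
#'   `read_histograms_json` an `isi_histograms` object.
#' @export
write_histograms_json <- function(hists, file) {
  coh <- hists$coherence_levels
  hh <- list()
  for (ci in seq_along(coh)) for (li in 1:2) {
    key <- paste0(c("correct", "incorrect")[li], "_", coh[ci])
    hh[[key]] <- hists$heights[, ci, li]
  }
  doc <- list(bin_edges = hists$bin_edges, heights = hh,
              total_time = as.list(hists$total_time),
              n_excluded = hists$n_excluded, bin_width = hists$bin_width,
              height_convention = hists$height_convention,
              coherence_levels = coh)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_histograms_json
#' @export
read_histograms_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  coh <- doc$coherence_levels
  nb <- length(doc$bin_edges) - 1L
  heights <- array(0, dim = c(nb, length(coh), 2),
                   dimnames = list(NULL, as.character(coh),
                                   c("correct", "incorrect")))
  for (ci in seq_along(coh)) for (li in 1:2) {
    key <- paste0(c("correct", "incorrect")[li], "_", coh[ci])
    heights[, ci, li] <- doc$heights[[key]]
  }
  total_time <- unlist(doc$total_time)
  names(total_time) <- as.character(coh)
  counts <- sweep(heights, 2, total_time, "*")
  if (doc$height_convention == "density") counts <- counts * doc$bin_width
  structure(list(bin_edges = doc$bin_edges, heights = heights,
                 total_time = total_time, counts = counts,
                 n_excluded = doc$n_excluded, bin_width = doc$bin_width,
                 height_convention = doc$height_convention,
                 coherence_levels = coh),
            class = "isi_histograms")
}
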
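# Surrogate-data controls: spike-time jitter, spike-count subsampling, and
# jitter-width calibration against the intact condition.

#' Jitter every spike time
#'
#' Perturbs each spike independently by zero-mean noise of SD (Gaussian) or
#' half-width (uniform) \code{width_ms}, clips back into the (0, 500] window
#' and re-sorts. Spike counts are preserved exactly: clipping never deletes.
#' Uses the current RNG state.
#'
#' @param resp a \code{\link{responses}} list.
#' @param width_ms jitter width in ms (>= 0; 0 is the identity).
#' @param dist \code{"gaussian"} (default) or \code{"uniform"}.
#' @return A jittered \code{response_set} of the same shape.
#' @export
jitter_spikes <- function(resp, width_ms, dist = c("gaussian", "uniform")) {
  dist <- match.arg(dist)
  stopifnot(width_ms >= 0)
  if (width_ms == 0) return(resp)
  out <- lapply(resp, function(r) {
    r$spikes <- lapply(r$spikes, function(t) {
      if (!length(t)) return(t)
      eps <- if (dist == "gaussian") stats::rnorm(length(t), 0, width_ms)
             else stats::runif(length(t), -width_ms, width_ms)
      sort(pmin(pmax(t + eps, 1e-6), 500))
    })
    r
  })
  structure(out, class = "response_set", grid = attr(resp, "grid"),
            window_ms = attr(resp, "window_ms"))
}

#' Subsample blocked-condition spikes to match control spike counts
#'
#' For each electrode, deletes spikes uniformly at random (across all trials
#' pooled) until the across-trial mean spike count matches the control
#' condition's mean; the output spike sets are subsets of the input. When an
#' electrode's control mean is not below its blocked mean, nothing is
#' deleted and a warning is raised. Uses the current RNG state.
#'
#' @param blocked,control \code{\link{responses}} lists over the same
#'   electrode set.
#' @return The subsampled blocked \code{response_set}.
#' @export
subsample_to_match <- function(blocked, control) {
  elec <- names(blocked[[1]]$spikes)
  if (!identical(elec, names(control[[1]]$spikes)))
    stop("blocked and control responses have different electrode sets")
  nb <- length(blocked)
  cnt_b <- electrode_counts(blocked)
  cnt_c <- electrode_counts(control)
  target <- round(cnt_c / length(control) * nb)
  out <- lapply(blocked, function(r) { r })
  excess_warned <- character(0)
  for (e in elec) {
    if (target[[e]] >= cnt_b[[e]]) {
      if (cnt_c[[e]] / length(control) > cnt_b[[e]] / nb)
        excess_warned <- c(excess_warned, e)
      next
    }
    # global indices of this electrode's spikes across trials
    per_trial <- vapply(blocked, function(r) length(r$spikes[[e]]),
                        numeric(1))
    keep <- sort(sample.int(cnt_b[[e]], target[[e]]))
    offs <- cumsum(c(0, per_trial))
    for (i in seq_len(nb)) {
      local <- keep[keep > offs[i] & keep <= offs[i + 1L]] - offs[i]
      out[[i]]$spikes[[e]] <- out[[i]]$spikes[[e]][local]
    }
  }
  if (length(excess_warned))
    warning("control mean exceeds blocked mean for electrode(s) ",
            paste(utils::head(excess_warned, 5L), collapse = ", "),
            "; no deletion applied there")
  structure(out, class = "response_set", grid = attr(blocked, "grid"),
            window_ms = attr(blocked, "window_ms"))
}

# dispersion statistic of a screened response set for one feature type
dispersion_statistic <- function(resp, electrodes,
                                 feature = c("order", "fsl", "words"),
                                 statistic = c("c13", "mean_distance"),
                                 fill = "zero") {
  feature <- match.arg(feature)
  statistic <- match.arg(statistic)
  fm <- feature_matrix(resp, feature = feature, electrodes = electrodes,
                       fill = fill)
  d <- pairwise_distances(fm$x, metric = "cosine")
  if (statistic == "mean_distance") return(mean(d[upper.tri(d)]))
  c_one_third(cluster_content_curve(single_linkage_tree(d)))$value
}

#' Calibrate the jitter width that mimics the intact condition
#'
#' Generates noisy surrogates of the blocked-inhibition responses by
#' jittering their spike times at each candidate width, measures a
#' dispersion statistic (default: the C 1/3 of the chosen feature's
#' cosine-distance dendrogram) and returns the width whose statistic lands
#' closest to the control condition's. A best width near 10 ms says the
#' intact network behaves like the disinhibited one plus ~10 ms of spike
#' timing noise.
#'
#' @param blocked,control screened \code{\link{responses}} lists (one
#'   stimulation source).
#' @param widths_ms candidate jitter widths in ms (>= 3 values).
#' @param electrodes ordered electrode ids used by the feature.
#' @param feature feature type, see \code{\link{feature_matrix}}. Default
#'   \code{"fsl"} (zero-filled): latency vectors respond monotonically to
#'   the jitter width, whereas rank-based features saturate once the jitter
#'   exceeds the spread of onset latencies and no longer identify it.
#' @param statistic \code{"c13"} (default) or \code{"mean_distance"}.
#' @return List with \code{widths_ms}, \code{statistic} (per width),
#'   \code{control_statistic} and \code{best_width_ms}.
#' @export
calibrate_jitter <- function(blocked, control, widths_ms, electrodes,
                             feature = "fsl", statistic = "c13") {
  if (length(widths_ms) < 1L) stop("no candidate widths")
  stat_ctrl <- dispersion_statistic(control, electrodes, feature, statistic)
  stats_w <- vapply(widths_ms, function(w) {
    dispersion_statistic(jitter_spikes(blocked, w), electrodes,
                         feature, statistic)
  }, numeric(1))
  best <- widths_ms[which.min(abs(stats_w - stat_ctrl))]
  list(widths_ms = widths_ms, statistic = stats_w,
       control_statistic = stat_ctrl, best_width_ms = best)
}
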
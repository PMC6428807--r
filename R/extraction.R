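# Response screening and electrode selection.

# centered moving average with shrinking window at the edges (no padding)
ma_shrink <- function(v, half) {
  n <- length(v)
  if (n == 0L || half == 0L) return(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Peri-stimulus time histogram of one response
#'
#' Pools the spikes of all electrodes, bins them at 1 ms over the
#' 10--500 ms post-stimulus range and smooths with a centered 5 ms moving
#' average (the window shrinks at the edges instead of zero-padding).
#' A spike at exactly 500 ms belongs to the last bin.
#'
#' @param r one response (element of a \code{\link{responses}} list).
#' @param bin_ms bin width in ms (default 1).
#' @param window numeric length-2, analysis range in ms (default
#'   \code{c(10, 500)}).
#' @param smooth_ms moving-average span in ms (default 5; 0 disables).
#' @return Numeric vector of smoothed rates in spikes/ms, one value per bin
#'   (491 for the defaults).
#' @export
response_psth <- function(r, bin_ms = 1, window = c(10, 500),
                          smooth_ms = 5) {
  n_bins <- as.integer(floor((window[2] - window[1]) / bin_ms)) + 1L
  v <- numeric(n_bins)
  t <- unlist(r$spikes, use.names = FALSE)
  t <- t[t >= window[1] & t <= window[2]]
  if (length(t)) {
    idx <- pmin(as.integer(floor((t - window[1]) / bin_ms)) + 1L, n_bins)
    tab <- tabulate(idx, nbins = n_bins)
    v <- tab / bin_ms
  }
  if (smooth_ms > bin_ms) v <- ma_shrink(v, as.integer(smooth_ms %/% 2))
  v
}

#' Detect network spikes in pooled activity
#'
#' A network spike is an episode in which the 3-ms-binned, array-summed
#' firing rate crosses a threshold. Bins are half-open \code{[t, t+3)};
#' a run of consecutive supra-threshold bins counts as a single event whose
#' time is the start of its first bin. Only the first
#' \code{search_window_ms} after the stimulus are searched.
#'
#' @param spike_times numeric vector of pooled post-stimulus spike times (ms).
#' @param threshold minimum spike count per bin to call an event (> 0).
#' @param bin_ms bin width in ms (default 3).
#' @param search_window_ms search horizon in ms (default 400).
#' @return Numeric vector of event onset times (bin starts, ms); empty if no
#'   crossing.
#' @export
detect_network_spikes <- function(spike_times, threshold, bin_ms = 3,
                                  search_window_ms = 400) {
  stopifnot(threshold > 0)
  t <- spike_times[spike_times >= 0 & spike_times < search_window_ms]
  if (!length(t)) return(numeric(0))
  n_bins <- as.integer(ceiling(search_window_ms / bin_ms))
  counts <- tabulate(as.integer(floor(t / bin_ms)) + 1L, nbins = n_bins)
  supra <- counts >= threshold
  onset <- which(supra & !c(FALSE, supra[-n_bins]))
  (onset - 1L) * bin_ms
}

#' Screen responses by PSTH peak amplitude
#'
#' Keeps only trials whose smoothed peri-stimulus time histogram reaches a
#' peak of at least \code{min_peak} spikes/ms; the remaining trials are
#' passed through unchanged.
#'
#' @param resp a \code{\link{responses}} list.
#' @param min_peak minimum smoothed PSTH peak in spikes/ms (default 1.5).
#' @param ... further arguments to \code{\link{response_psth}}.
#' @return List with \code{kept} (screened \code{response_set}),
#'   \code{kept_idx}, \code{peaks} (per input trial) and \code{psth}
#'   (matrix, one row per input trial).
#' @export
screen_responses <- function(resp, min_peak = 1.5, ...) {
  if (!length(resp))
    return(list(kept = resp, kept_idx = integer(0), peaks = numeric(0),
                psth = NULL))
  psth <- do.call(rbind, lapply(resp, response_psth, ...))
  peaks <- apply(psth, 1L, max)
  keep <- which(peaks >= min_peak)
  list(kept = resp[keep], kept_idx = keep, peaks = peaks, psth = psth)
}

#' Select electrodes by response participation
#'
#' An electrode is included if it fires at least one spike in at least
#' \code{min_participation} of the kept trials. When several response sets
#' are given (e.g. the two pharmacological conditions, or several sources),
#' participation is evaluated jointly over all their trials so that one and
#' the same electrode assembly is analyzed throughout. The boundary is
#' inclusive: firing in exactly 90\% of trials qualifies.
#'
#' @param ... one or more \code{\link{responses}} lists.
#' @param min_participation minimum participation fraction (default 0.9).
#' @return Integer vector of included electrode ids (possibly empty, with a
#'   warning).
#' @export
select_electrodes <- function(..., min_participation = 0.9) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  all_resp <- do.call(c, lapply(sets, unclass))
  if (!length(all_resp)) stop("no responses supplied")
  elec <- names(all_resp[[1]]$spikes)
  hits <- stats::setNames(numeric(length(elec)), elec)
  for (r in all_resp) hits <- hits + (lengths(r$spikes) > 0)
  frac <- hits / length(all_resp)
  sel <- as.integer(elec[frac >= min_participation])
  if (!length(sel))
    warning("no electrode reaches ", min_participation,
            " participation; empty selection")
  sel
}

#' Most active electrodes
#'
#' Ranks the included electrodes by total spike count over the kept trials
#' of the reference (control) condition and returns the top \code{k}; ties
#' at the boundary are broken in favor of the lower electrode id. The same
#' set is meant to be reused for the paired condition, so electrode choice
#' is never driven by the disinhibited recording.
#'
#' @param resp the reference \code{\link{responses}} list.
#' @param k number of electrodes to return (default 8).
#' @param electrodes candidate electrode ids (e.g. from
#'   \code{\link{select_electrodes}}); default: all grid electrodes.
#' @return Integer vector of \code{k} electrode ids, most active first.
#' @export
top_active_electrodes <- function(resp, k = 8L, electrodes = NULL) {
  counts <- electrode_counts(resp)
  if (!is.null(electrodes))
    counts <- counts[as.character(electrodes)]
  if (k > length(counts))
    stop("requested k = ", k, " electrodes but only ", length(counts),
         " are included")
  ids <- as.integer(names(counts))
  ord <- order(-counts, ids)
  ids[ord][seq_len(k)]
}
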
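# The four response representations: population rate, binary words,
# first-spike latencies, recruitment order.

#' Population rate trace of one response
#'
#' Spikes of all electrodes are pooled, binned at 1 ms over 10--500 ms post
#' stimulus and smoothed with a centered 5 ms moving average; identical to
#' \code{\link{response_psth}} and kept as a named feature extractor.
#'
#' @param r one response.
#' @param smooth logical; disable to obtain the raw binned rate whose sum
#'   (times the 1 ms bin) equals the pooled spike count in the window.
#' @return Numeric vector of length 491 (spikes/ms).
#' @export
population_rate <- function(r, smooth = TRUE) {
  response_psth(r, bin_ms = 1, window = c(10, 500),
                smooth_ms = if (smooth) 5 else 0)
}

#' Binary word of one electrode's response
#'
#' Marks which 2-ms bins of the first 250 ms post stimulus contain at least
#' one spike: bit \code{b} (0-based) covers \code{[2b, 2b + 2)} ms. The
#' resolution is chosen so a bin maximally contains a single action
#' potential; multiple spikes in a bin still yield a single 1.
#'
#' @param r one response.
#' @param electrode electrode id.
#' @param span_ms word span in ms (default 250).
#' @param bin_ms bin width in ms (default 2).
#' @param offset_ms start of the word relative to the stimulus (default 0).
#' @return Integer 0/1 vector of length \code{span_ms / bin_ms} (125 for the
#'   defaults).
#' @export
binary_word <- function(r, electrode, span_ms = 250, bin_ms = 2,
                        offset_ms = 0) {
  n_bits <- as.integer(span_ms / bin_ms)
  t <- r$spikes[[as.character(electrode)]]
  if (is.null(t))
    stop("electrode not present in response: ", electrode)
  t <- t - offset_ms
  t <- t[t >= 0 & t < span_ms]
  bits <- integer(n_bits)
  if (length(t)) bits[unique(as.integer(floor(t / bin_ms))) + 1L] <- 1L
  bits
}

#' First-spike latency vector
#'
#' For each of the \code{k} selected electrodes, the latency of its first
#' spike in the response. Electrodes that fail to participate receive a
#' random value drawn from Uniform[10, 500] ms (so a classifier cannot
#' trivially key on missingness) or, optionally, zero. Uses the current RNG
#' state; seed with \code{set.seed()} for reproducible fills.
#'
#' @param r one response.
#' @param electrodes ordered electrode ids (the k most active, see
#'   \code{\link{top_active_electrodes}}).
#' @param fill \code{"uniform"} (default) or \code{"zero"}.
#' @return List with \code{latency_ms} (named numeric, length k) and
#'   \code{filled} (logical mask of substituted entries).
#' @export
first_spike_latencies <- function(r, electrodes, fill = c("uniform", "zero")) {
  fill <- match.arg(fill)
  fsl <- response_fsl(r, electrodes)
  miss <- is.na(fsl)
  if (any(miss))
    fsl[miss] <- if (fill == "uniform")
      stats::runif(sum(miss), 10, 500) else 0
  list(latency_ms = fsl, filled = miss)
}

#' Recruitment order of a response
#'
#' Ranks the \code{k} selected electrodes by their observed first-spike
#' latencies (rank 1 = earliest). Ties at the recording resolution share
#' the average of their ranks. Electrodes that did not respond each receive
#' the mean of the ranks left unassigned, so the rank sum is always
#' \code{k(k+1)/2}. Ranks are computed from the observed latencies only,
#' never from random fills.
#'
#' @param r one response.
#' @param electrodes ordered electrode ids.
#' @return Named numeric vector of (possibly fractional) ranks.
#' @export
recruitment_order <- function(r, electrodes) {
  fsl <- response_fsl(r, electrodes)
  k <- length(fsl)
  miss <- is.na(fsl)
  m <- sum(!miss)
  ranks <- stats::setNames(numeric(k), names(fsl))
  if (m) ranks[!miss] <- rank(fsl[!miss], ties.method = "average")
  if (m < k) ranks[miss] <- mean(seq(m + 1L, k))
  ranks
}

#' Feature matrices for a screened response set
#'
#' Convenience extractor: one row per trial, plus the trial's source label.
#' For \code{"fsl"} the random fills depend on the current RNG state.
#'
#' @param resp a \code{\link{responses}} list (screened).
#' @param feature one of \code{"rate"}, \code{"words"}, \code{"fsl"},
#'   \code{"order"}.
#' @param electrodes ordered electrode ids, required for all features except
#'   \code{"rate"}; for \code{"words"} the per-electrode words of all listed
#'   electrodes are concatenated.
#' @param fill missing-latency fill rule for \code{"fsl"}, see
#'   \code{\link{first_spike_latencies}}.
#' @return List with \code{x} (numeric matrix) and \code{source} (integer
#'   vector of stimulation sources).
#' @export
feature_matrix <- function(resp, feature = c("order", "fsl", "words", "rate"),
                           electrodes = NULL, fill = "uniform") {
  feature <- match.arg(feature)
  if (feature != "rate" && is.null(electrodes))
    stop("electrodes must be given for feature '", feature, "'")
  rows <- lapply(resp, function(r) switch(
    feature,
    rate  = population_rate(r),
    words = unlist(lapply(electrodes, function(e) binary_word(r, e)),
                   use.names = FALSE),
    fsl   = first_spike_latencies(r, electrodes, fill = fill)$latency_ms,
    order = recruitment_order(r, electrodes)))
  list(x = do.call(rbind, rows),
       source = vapply(resp, function(r) as.integer(r$source), integer(1)))
}
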
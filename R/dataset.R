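#' Trial-structured spike dataset
#'
#' The in-memory container for one recording condition: a table of spike
#' events stamped with trial and electrode, the stimulation log, and the
#' array geometry. All spike times are in milliseconds relative to the
#' stimulus of their trial and must lie in the (0, 500] analysis window.
#'
#' @param events data frame with columns \code{trial} (integer),
#'   \code{electrode} (integer id on the grid) and \code{time_ms}.
#' @param stim_log data frame with columns \code{trial}, \code{abs_time_s},
#'   \code{source} (stimulation electrode id) and \code{condition}
#'   (e.g. \code{"control"} or \code{"blocked"}).
#' @param grid a \code{\link{grid_geometry}}.
#' @return An object of class \code{"spike_dataset"}.
#' @export
spike_dataset <- function(events, stim_log, grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  need_ev <- c("trial", "electrode", "time_ms")
  need_st <- c("trial", "abs_time_s", "source", "condition")
  if (!all(need_ev %in% names(events)))
    stop("events must have columns: ", paste(need_ev, collapse = ", "))
  if (!all(need_st %in% names(stim_log)))
    stop("stim_log must have columns: ", paste(need_st, collapse = ", "))
  if (anyDuplicated(stim_log$trial))
    stop("duplicated trial index in stim_log")
  if (nrow(events)) {
    bad_tr <- setdiff(unique(events$trial), stim_log$trial)
    if (length(bad_tr))
      stop("events reference trials absent from stim_log: ",
           paste(utils::head(bad_tr, 5L), collapse = ", "))
    bad_el <- setdiff(unique(events$electrode), grid$electrode_ids)
    if (length(bad_el))
      stop("events reference unknown electrode(s): ",
           paste(utils::head(bad_el, 5L), collapse = ", "))
    if (!all(is.finite(events$time_ms)) || any(events$time_ms < 0))
      stop("event times must be finite and non-negative")
  }
  bad_src <- setdiff(unique(stim_log$source), grid$electrode_ids)
  if (length(bad_src))
    stop("stim_log references unknown source electrode(s): ",
         paste(bad_src, collapse = ", "))
  structure(list(events = events, stim_log = stim_log, grid = grid),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf(
    "spike_dataset: %d trials, %d spike events, %d sources, condition(s): %s\n",
    nrow(x$stim_log), nrow(x$events),
    length(unique(x$stim_log$source)),
    paste(unique(x$stim_log$condition), collapse = ", ")))
  invisible(x)
}

#' Cut a dataset into per-trial responses
#'
#' Converts the event table into a list of per-trial responses, keeping only
#' spikes inside the half-open analysis window \code{(0, window_ms]}. The
#' operation is idempotent: re-windowing a windowed response changes nothing.
#'
#' @param dataset a \code{\link{spike_dataset}}.
#' @param window_ms length of the post-stimulus analysis window (default 500).
#' @return A list of class \code{"response_set"}; each element is a list with
#'   \code{trial}, \code{source}, \code{condition} and \code{spikes}, a named
#'   list (one sorted numeric vector per grid electrode, possibly empty).
#'   The grid is attached as attribute \code{"grid"}.
#' @export
responses <- function(dataset, window_ms = 500) {
  stopifnot(inherits(dataset, "spike_dataset"))
  ev <- dataset$events
  keep <- ev$time_ms > 0 & ev$time_ms <= window_ms
  ev <- ev[keep, , drop = FALSE]
  elec <- dataset$grid$electrode_ids
  empty <- stats::setNames(
    rep(list(numeric(0)), length(elec)), as.character(elec))
  sl <- dataset$stim_log
  out <- vector("list", nrow(sl))
  ev_by_trial <- if (nrow(ev)) split(ev, factor(ev$trial, levels = sl$trial))
                 else NULL
  for (i in seq_len(nrow(sl))) {
    spikes <- empty
    if (!is.null(ev_by_trial)) {
      e <- ev_by_trial[[as.character(sl$trial[i])]]
      if (!is.null(e) && nrow(e)) {
        sp <- split(e$time_ms, factor(e$electrode, levels = elec))
        sp <- lapply(sp, sort)
        spikes[names(sp)] <- sp
      }
    }
    out[[i]] <- list(trial = sl$trial[i], source = sl$source[i],
                     condition = sl$condition[i], spikes = spikes)
  }
  structure(out, class = "response_set", grid = dataset$grid,
            window_ms = window_ms)
}

#' @export
print.response_set <- function(x, ...) {
  nsp <- sum(vapply(x, function(r) sum(lengths(r$spikes)), numeric(1)))
  cat(sprintf("response_set: %d trials, %d spikes in window\n",
              length(x), nsp))
  invisible(x)
}

# Subset a response_set, keeping class and attributes.
#' @export
`[.response_set` <- function(x, i) {
  structure(unclass(x)[i], class = "response_set",
            grid = attr(x, "grid"), window_ms = attr(x, "window_ms"))
}

# total spike count per electrode over a response set (named vector)
electrode_counts <- function(resp) {
  elec <- names(resp[[1]]$spikes)
  counts <- stats::setNames(numeric(length(elec)), elec)
  for (r in resp) counts <- counts + lengths(r$spikes)
  counts
}

# first-spike latency per electrode for one response (NA if silent)
response_fsl <- function(r, electrodes) {
  vapply(as.character(electrodes), function(e) {
    s <- r$spikes[[e]]
    if (length(s)) s[1] else NA_real_
  }, numeric(1))
}
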
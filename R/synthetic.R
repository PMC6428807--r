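#' Traveling-wave response template
#'
#' Builds the deterministic skeleton of an evoked network response: a wave
#' that starts at the stimulation electrode and radiates outward at a fixed
#' velocity, so each electrode's onset latency is the source distance divided
#' by the velocity plus a base synaptic delay. Expected burst spike counts
#' decay exponentially with distance from the source (set
#' \code{count_decay_um = Inf} for a source-independent burst envelope).
#'
#' @param grid a \code{\link{grid_geometry}}.
#' @param source stimulation electrode id (must be on the grid).
#' @param velocity_m_s propagation velocity in m/s (default 0.5).
#' @param base_latency_ms delay at the source electrode in ms (default 5).
#' @param peak_count expected burst spike count at the source (default 8).
#' @param count_decay_um length constant of the distance decay of expected
#'   counts, in micrometers (default 2000; \code{Inf} = no decay).
#' @param tau_ms burst decay time constant in ms: within-burst spikes after
#'   the first follow the onset by exponentially distributed delays with this
#'   mean (default 30).
#' @return Object of class \code{"wave_template"} with per-electrode
#'   \code{onset_ms} and \code{expected_count} (named vectors in electrode
#'   order), plus the generating parameters.
#' @export
wave_template <- function(grid, source, velocity_m_s = 0.5,
                          base_latency_ms = 5, peak_count = 8,
                          count_decay_um = 2000, tau_ms = 30) {
  stopifnot(inherits(grid, "grid_geometry"))
  if (!source %in% grid$electrode_ids)
    stop("source electrode not on grid: ", source)
  stopifnot(velocity_m_s > 0, base_latency_ms > 0, tau_ms > 0)
  d_um <- electrode_distance(grid, grid$electrode_ids,
                             rep(source, length(grid$electrode_ids)))
  # velocity in um/ms = 1000 * m/s
  onset <- base_latency_ms + d_um / (velocity_m_s * 1000)
  if (any(onset >= 500))
    stop("template onset latency reaches the 500 ms window edge")
  counts <- peak_count * exp(-d_um / count_decay_um)
  structure(list(
    source = source,
    onset_ms = stats::setNames(onset, grid$electrode_ids),
    expected_count = stats::setNames(counts, grid$electrode_ids),
    dist_um = stats::setNames(d_um, grid$electrode_ids),
    velocity_m_s = velocity_m_s, base_latency_ms = base_latency_ms,
    tau_ms = tau_ms
  ), class = "wave_template")
}

#' Condition noise model
#'
#' Summarizes how one pharmacological condition corrupts the stereotyped
#' wave template: independent zero-mean Gaussian jitter on every spike time,
#' wholesale per-electrode participation failures, and a multiplicative
#' scaling of burst spike counts. Optionally the failure probability grows
#' with distance from the stimulation source
#' (\code{1 - (1 - failure_prob) * exp(-d / failure_length_um)}), emulating
#' inhibition that curtails wave propagation to distal sites; the default
#' (\code{Inf}) applies the same failure probability everywhere.
#'
#' @param jitter_ms SD of the spike-time jitter in ms (>= 0).
#' @param failure_prob probability that an electrode emits no spikes in a
#'   trial, in [0, 1].
#' @param rate_scale multiplicative factor on expected burst counts (> 0).
#' @param failure_length_um length constant of distance-dependent failure
#'   (default \code{Inf}: distance-independent).
#' @return Object of class \code{"noise_model"}.
#' @export
noise_model <- function(jitter_ms, failure_prob, rate_scale,
                        failure_length_um = Inf) {
  stopifnot(jitter_ms >= 0, failure_prob >= 0, failure_prob <= 1,
            rate_scale > 0, failure_length_um > 0)
  structure(list(jitter_ms = jitter_ms, failure_prob = failure_prob,
                 rate_scale = rate_scale,
                 failure_length_um = failure_length_um),
            class = "noise_model")
}

#' Default condition noise models
#'
#' The intact-inhibition ("control") regime is modeled as a heavily jittered,
#' failure-prone, lower-rate rendering of the same wave templates that the
#' disinhibited ("blocked") regime expresses almost faithfully: jitter 10 ms
#' vs 1 ms, participation failure 0.3 vs 0.05, rate scale 0.5 vs 1.
#' @name default_noise
NULL

#' @rdname default_noise
#' @export
control_noise_default <- function() noise_model(10, 0.30, 0.5)

#' @rdname default_noise
#' @export
blocked_noise_default <- function() noise_model(1, 0.05, 1.0)

#' Synthetic experiment configuration
#'
#' @param grid a \code{\link{grid_geometry}} (default 6 x 10 at 500 um).
#' @param sources stimulation electrode ids; must be distinct grid
#'   electrodes. Default \code{c(1, 25)}: two sources more than two grid
#'   steps apart.
#' @param n_trials_per_source responses per source and condition (default 40).
#' @param control_noise,blocked_noise \code{\link{noise_model}}s for the two
#'   conditions.
#' @param velocity_m_s,base_latency_ms,peak_count,count_decay_um,tau_ms wave
#'   template parameters shared by all sources, see
#'   \code{\link{wave_template}}.
#' @param seed integer seed; a dataset pair is fully reproducible from it.
#' @return Object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(grid = grid_geometry(), sources = c(1L, 25L),
                             n_trials_per_source = 40L,
                             control_noise = control_noise_default(),
                             blocked_noise = blocked_noise_default(),
                             velocity_m_s = 0.5, base_latency_ms = 5,
                             peak_count = 8, count_decay_um = 2000,
                             tau_ms = 30, seed = 1L) {
  sources <- as.integer(sources)
  if (anyDuplicated(sources)) stop("stimulation sources must be distinct")
  if (!all(sources %in% grid$electrode_ids))
    stop("source electrode(s) not on grid: ",
         paste(setdiff(sources, grid$electrode_ids), collapse = ", "))
  stopifnot(n_trials_per_source >= 2L,
            inherits(control_noise, "noise_model"),
            inherits(blocked_noise, "noise_model"))
  structure(list(grid = grid, sources = sources,
                 n_trials_per_source = as.integer(n_trials_per_source),
                 control_noise = control_noise,
                 blocked_noise = blocked_noise,
                 velocity_m_s = velocity_m_s,
                 base_latency_ms = base_latency_ms,
                 peak_count = peak_count, count_decay_um = count_decay_um,
                 tau_ms = tau_ms, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic 31-bit sub-seed from a master seed and a label, so each
# trial owns an RNG sub-stream: changing the trial count never reshuffles
# the spikes of earlier trials.
derive_seed <- function(master, label) {
  h <- 5381
  for (b in utf8ToInt(label)) h <- (h * 33 + b) %% 2147483647
  as.integer((h + as.numeric(master) * 48271) %% 2147483647)
}

#' Draw one noisy response from a wave template
#'
#' Each surviving electrode emits a first spike at its template onset plus
#' extra within-burst spikes whose delays after onset are exponential with
#' mean \code{tau_ms}; the expected total count is the template's expected
#' count times \code{rate_scale}. Every spike time is then perturbed by
#' independent zero-mean Gaussian jitter of SD \code{jitter_ms} and clipped
#' to the (0, 500] window. Electrodes fail wholesale with the model's
#' participation failure probability. Uses the current RNG state; seed with
#' \code{set.seed()} for reproducibility.
#'
#' @param template a \code{\link{wave_template}}.
#' @param noise a \code{\link{noise_model}}.
#' @return Named list (one sorted numeric spike-time vector per electrode).
#' @export
generate_response <- function(template, noise) {
  stopifnot(inherits(template, "wave_template"),
            inherits(noise, "noise_model"))
  elec <- names(template$onset_ms)
  p_fail <- if (is.finite(noise$failure_length_um)) {
    1 - (1 - noise$failure_prob) *
      exp(-template$dist_um / noise$failure_length_um)
  } else rep(noise$failure_prob, length(elec))
  fails <- stats::runif(length(elec)) < p_fail
  out <- stats::setNames(vector("list", length(elec)), elec)
  for (i in seq_along(elec)) {
    if (fails[i]) { out[[i]] <- numeric(0); next }
    mu <- template$expected_count[i] * noise$rate_scale
    n_extra <- stats::rpois(1L, max(mu - 1, 0))
    t0 <- template$onset_ms[[i]]
    times <- c(t0, t0 + stats::rexp(n_extra, rate = 1 / template$tau_ms))
    if (noise$jitter_ms > 0)
      times <- times + stats::rnorm(length(times), 0, noise$jitter_ms)
    times <- pmin(pmax(times, 1e-6), 500)
    out[[i]] <- sort(times[times <= 500])
  }
  out
}

#' Generate a paired control / blocked-inhibition dataset
#'
#' Both conditions are driven by the \emph{same} per-source wave templates;
#' only the noise model differs. This shared-template construction is what
#' makes response structure transferable across conditions. The stimulation
#' log interleaves sources in a seeded random order (shared by the two
#' conditions, so trial i of each dataset answers the same stimulus).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return List with elements \code{control} and \code{blocked}, each a
#'   \code{\link{spike_dataset}}, plus \code{templates} (one
#'   \code{\link{wave_template}} per source) and \code{config}.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  templates <- lapply(config$sources, function(s)
    wave_template(config$grid, s, config$velocity_m_s,
                  config$base_latency_ms, config$peak_count,
                  config$count_decay_um, config$tau_ms))
  names(templates) <- as.character(config$sources)

  n_tot <- length(config$sources) * config$n_trials_per_source
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "stim_order"))
  src_seq <- sample(rep(config$sources, each = config$n_trials_per_source))

  make_one <- function(cond, noise) {
    ev <- vector("list", n_tot)
    for (tr in seq_len(n_tot)) {
      set.seed(derive_seed(config$seed, paste0(cond, ":", tr)))
      sp <- generate_response(templates[[as.character(src_seq[tr])]], noise)
      n_per <- lengths(sp)
      if (sum(n_per)) {
        ev[[tr]] <- data.frame(
          trial = tr,
          electrode = rep(as.integer(names(sp)), n_per),
          time_ms = unlist(sp, use.names = FALSE))
      }
    }
    events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
    if (is.null(events))
      events <- data.frame(trial = integer(0), electrode = integer(0),
                           time_ms = numeric(0))
    stim_log <- data.frame(trial = seq_len(n_tot),
                           abs_time_s = 6 * (seq_len(n_tot) - 1),
                           source = src_seq, condition = cond)
    spike_dataset(events, stim_log, config$grid)
  }

  list(control = make_one("control", config$control_noise),
       blocked = make_one("blocked", config$blocked_noise),
       templates = templates, config = config)
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
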
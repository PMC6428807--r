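# Propagation structure: conditional firing probability profiles, typical
# delays, latency maps and contrast vs source separation.

# 3-point moving average with zero padding (constant denominator), so an
# isolated peak smooths to a symmetric plateau and the window edges cannot
# gain spuriously inflated values
ma_pad3 <- function(v) {
  n <- length(v)
  (c(0, v[-n]) + v + c(v[-1L], 0)) / 3
}

# binarize a response set: (n_trials * n_bins) x n_electrode 0/1 matrix,
# trials stacked in blocks of n_bins rows; 2 ms bins over (0, 500]
binarize_responses <- function(resp, bin_ms = 2, window_ms = 500) {
  nb <- as.integer(window_ms / bin_ms)
  elec <- names(resp[[1]]$spikes)
  x <- matrix(0, nrow = length(resp) * nb, ncol = length(elec),
              dimnames = list(NULL, elec))
  for (tr in seq_along(resp)) {
    off <- (tr - 1L) * nb
    sp <- resp[[tr]]$spikes
    for (e in seq_along(elec)) {
      t <- sp[[e]]
      if (length(t))
        x[off + pmin(as.integer(floor(t / bin_ms)) + 1L, nb), e] <- 1
    }
  }
  attr(x, "n_bins") <- nb
  x
}

# first local maximum (>= both neighbors) of the smoothed profile,
# scanning lags upward. Smoothing an isolated raw peak creates a flat
# 3-lag plateau, so a plateau resolves to the lag with the largest raw
# value (ties: smallest lag); profiles with no local maximum fall back to
# the global maximum.
first_local_max <- function(v, raw = v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left <- c(-Inf, v[-n])
  right <- c(v[-1L], -Inf)
  cand <- which(v >= left & v >= right & v > 0)
  if (!length(cand)) return(which.max(v))
  first <- cand[1L]
  # extend over the plateau of equal smoothed values containing `first`
  plateau <- first
  while (max(plateau) < n && v[max(plateau) + 1L] == v[first])
    plateau <- c(plateau, max(plateau) + 1L)
  plateau[which.max(raw[plateau])]
}

#' Conditional firing probability profiles for all electrode pairs
#'
#' For every ordered electrode pair (condition on j, observe i), estimates
#' the probability that i fires in the 2-ms bin lagging tau behind a spike
#' of j, over all trials' response windows, for tau = 0..100 ms in 2-ms
#' steps. Conditioning spikes near the window end contribute only the lags
#' that fit; the denominator counts conditioning spikes per lag. Each
#' profile is smoothed with a 3-point moving average; the lag of its first
#' local maximum is the pair's typical delay. Pairs are excluded when either
#' electrode carries fewer than \code{min_spikes} spikes or when the
#' smoothed peak stays below \code{peak_min}.
#'
#' @param resp a \code{\link{responses}} list.
#' @param electrodes electrode ids to analyze (default: all on the grid).
#' @param min_spikes minimum spikes per electrode over the whole set
#'   (default 100).
#' @param peak_min minimum smoothed peak probability (default 0.05).
#' @param max_lag_ms largest lag (default 100).
#' @param bin_ms bin width (default 2).
#' @param keep_profiles attach the smoothed profiles of retained pairs.
#' @return List with \code{pairs}: data frame (\code{j}, \code{i},
#'   \code{typical_delay_ms}, \code{peak}, \code{excluded}, \code{reason}),
#'   \code{lags_ms}, and optionally \code{profiles} (named list
#'   \code{"j->i"}).
#' @export
cfp_profiles <- function(resp, electrodes = NULL, min_spikes = 100,
                         peak_min = 0.05, max_lag_ms = 100, bin_ms = 2,
                         keep_profiles = FALSE) {
  if (is.null(electrodes))
    electrodes <- as.integer(names(resp[[1]]$spikes))
  x <- binarize_responses(resp, bin_ms = bin_ms)
  nb <- attr(x, "n_bins")
  x <- x[, as.character(electrodes), drop = FALSE]
  n_lag <- as.integer(max_lag_ms / bin_ms) + 1L
  lags_ms <- (seq_len(n_lag) - 1L) * bin_ms
  ne <- ncol(x)
  counts <- electrode_counts(resp)[as.character(electrodes)]

  bin_in_trial <- rep(seq_len(nb), length(resp))
  p <- array(0, dim = c(ne, ne, n_lag))   # [j, i, lag]
  for (l in seq_len(n_lag)) {
    shift <- l - 1L
    valid <- which(bin_in_trial <= nb - shift)
    x1 <- x[valid, , drop = FALSE]
    x2 <- x[valid + shift, , drop = FALSE]
    num <- crossprod(x1, x2)            # num[j, i]
    den <- colSums(x1)                  # conditioning spikes of j
    p[, , l] <- num / ifelse(den == 0, 1, den)
  }

  pairs <- expand.grid(j = electrodes, i = electrodes,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$j != pairs$i, ]
  res <- vector("list", nrow(pairs))
  profiles <- if (keep_profiles) list() else NULL
  for (r in seq_len(nrow(pairs))) {
    j <- pairs$j[r]; i <- pairs$i[r]
    ji <- match(j, electrodes); ii <- match(i, electrodes)
    if (counts[[as.character(j)]] < min_spikes ||
        counts[[as.character(i)]] < min_spikes) {
      res[[r]] <- data.frame(j = j, i = i, typical_delay_ms = NA_real_,
                             peak = NA_real_, excluded = TRUE,
                             reason = "min_spikes")
      next
    }
    raw <- p[ji, ii, ]
    prof <- ma_pad3(raw)
    peak <- max(prof)
    if (peak < peak_min) {
      res[[r]] <- data.frame(j = j, i = i, typical_delay_ms = NA_real_,
                             peak = peak, excluded = TRUE,
                             reason = "low_peak")
      next
    }
    delay <- lags_ms[first_local_max(prof, raw)]
    res[[r]] <- data.frame(j = j, i = i, typical_delay_ms = delay,
                           peak = peak, excluded = FALSE, reason = "")
    if (keep_profiles)
      profiles[[paste0(j, "->", i)]] <- prof
  }
  out <- list(pairs = do.call(rbind, res), lags_ms = lags_ms)
  if (keep_profiles) out$profiles <- profiles
  out
}

#' Typical delay as a function of electrode distance
#'
#' Groups retained CFP pair delays by exact inter-electrode grid distance,
#' averages them, and reports the Spearman rank correlation between delay
#' and distance over the retained pairs.
#'
#' @param cfp result of \code{\link{cfp_profiles}}.
#' @param grid the \code{\link{grid_geometry}}.
#' @return List with \code{curve} (data frame \code{distance_um},
#'   \code{mean_delay_ms}, \code{n_pairs}), \code{rho} (Spearman, NA if
#'   undefined), \code{n_pairs} and \code{pairs} (per-pair table with
#'   distances).
#' @export
delay_vs_distance <- function(cfp, grid) {
  pr <- cfp$pairs[!cfp$pairs$excluded, , drop = FALSE]
  if (!nrow(pr)) stop("no retained CFP profiles")
  pr$distance_um <- electrode_distance(grid, pr$j, pr$i)
  curve <- stats::aggregate(typical_delay_ms ~ distance_um, pr, mean)
  names(curve)[2] <- "mean_delay_ms"
  curve$n_pairs <- as.vector(table(factor(pr$distance_um,
                                          levels = curve$distance_um)))
  rho <- if (nrow(pr) >= 3L)
    spearman_cor(pr$distance_um, pr$typical_delay_ms)$rho
  else NA_real_
  list(curve = curve, rho = rho, n_pairs = nrow(pr), pairs = pr)
}

#' Propagation velocity from CFP delays
#'
#' For a single stimulation source, the radial propagation model predicts a
#' pair delay equal to the difference of the two electrodes' distances from
#' the source divided by the wave velocity. Regressing retained typical
#' delays on that radial distance difference (with a free intercept that
#' absorbs the lag-grid discretization offset) yields the velocity as the
#' inverse slope.
#'
#' @param cfp result of \code{\link{cfp_profiles}}.
#' @param grid the \code{\link{grid_geometry}}.
#' @param source the stimulation electrode id.
#' @return List with \code{velocity_m_s}, \code{slope_ms_per_um},
#'   \code{intercept_ms}, \code{n_pairs} and the fitting table \code{pairs}.
#' @export
estimate_velocity <- function(cfp, grid, source) {
  pr <- cfp$pairs[!cfp$pairs$excluded, , drop = FALSE]
  if (nrow(pr) < 3L) stop("need >= 3 retained CFP profiles")
  dd <- electrode_distance(grid, pr$i, rep(source, nrow(pr))) -
    electrode_distance(grid, pr$j, rep(source, nrow(pr)))
  keep <- dd > 0
  pr <- pr[keep, , drop = FALSE]
  dd <- dd[keep]
  fit <- stats::lm(pr$typical_delay_ms ~ dd)
  slope <- unname(stats::coef(fit)[2])
  pr$radial_dd_um <- dd
  list(velocity_m_s = 1 / (slope * 1000), slope_ms_per_um = slope,
       intercept_ms = unname(stats::coef(fit)[1]), n_pairs = nrow(pr),
       pairs = pr)
}

#' First-spike latency map for one stimulation source
#'
#' Per-electrode median time to first spike over the trials of one source;
#' electrodes that never respond are flagged as non-responders (NA latency).
#'
#' @param resp a \code{\link{responses}} list (trials of one source).
#' @param grid the \code{\link{grid_geometry}}.
#' @return Data frame with \code{electrode}, \code{row}, \code{col},
#'   \code{median_fsl_ms} and \code{responder}.
#' @export
latency_map <- function(resp, grid) {
  if (!length(resp)) stop("no responses")
  elec <- as.integer(names(resp[[1]]$spikes))
  fsl <- vapply(resp, response_fsl, numeric(length(elec)),
                electrodes = elec)
  med <- apply(matrix(fsl, nrow = length(elec)), 1L, stats::median,
               na.rm = TRUE)
  out <- grid$positions[match(elec, grid$positions$electrode),
                        c("electrode", "row", "col")]
  out$median_fsl_ms <- ifelse(is.nan(med), NA_real_, med)
  out$responder <- !is.na(out$median_fsl_ms)
  out
}

#' Contrast as a function of inter-source distance
#'
#' Pairs the per-source-pair contrasts of the two conditions with the
#' Euclidean distance between the stimulation sites, reports the Spearman
#' correlation of contrast with distance per condition, and the per-pair
#' contrast difference blocked - control (negative values flag source pairs
#' whose discrimination worsens when inhibition is blocked).
#'
#' @param control,blocked data frames with columns \code{source_a},
#'   \code{source_b}, \code{contrast} (same pair order).
#' @param grid the \code{\link{grid_geometry}}.
#' @return List with \code{table} (distance, contrasts, delta) and
#'   \code{rho_control}, \code{rho_blocked} (NA and flagged when distances
#'   are constant).
#' @export
contrast_vs_source_distance <- function(control, blocked, grid) {
  stopifnot(nrow(control) == nrow(blocked),
            all(control$source_a == blocked$source_a),
            all(control$source_b == blocked$source_b))
  if (nrow(control) < 3L) stop("need >= 3 source pairs")
  d <- electrode_distance(grid, control$source_a, control$source_b)
  tab <- data.frame(source_a = control$source_a,
                    source_b = control$source_b,
                    distance_um = d,
                    contrast_control = control$contrast,
                    contrast_blocked = blocked$contrast,
                    delta = blocked$contrast - control$contrast)
  rc <- spearman_cor(tab$distance_um, tab$contrast_control)
  rb <- spearman_cor(tab$distance_um, tab$contrast_blocked)
  list(table = tab, rho_control = rc$rho, rho_blocked = rb$rho,
       rho_defined = rc$defined && rb$defined)
}
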
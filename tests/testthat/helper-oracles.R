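# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# build a single response from a named list of spike-time vectors,
# defaulting unnamed electrodes of the grid to silence
make_response <- function(spikes, grid = grid_geometry(), source = 1L,
                          trial = 1L, condition = "control") {
  all_e <- as.character(grid$electrode_ids)
  full <- stats::setNames(rep(list(numeric(0)), length(all_e)), all_e)
  for (nm in names(spikes)) full[[nm]] <- sort(spikes[[nm]])
  list(trial = trial, source = source, condition = condition,
       spikes = full)
}

make_response_set <- function(trials, grid = grid_geometry()) {
  structure(trials, class = "response_set", grid = grid, window_ms = 500)
}

# naive O(n^3) single-linkage agglomeration returning sorted merge heights
oracle_single_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- min(d[clusters[[i]], clusters[[j]]])
      if (dd < best) { best <- dd; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# cluster count at a cutoff: union-find over all pairs with d <= cutoff
oracle_cluster_count <- function(d, cutoff) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# element-by-element cosine distance matrix
oracle_cosine_matrix <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- x[i, ]; v <- x[j, ]
    nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
    d[i, j] <- if (nu == 0 && nv == 0) 0
               else if (nu == 0 || nv == 0) 1
               else 1 - sum(u * v) / (nu * nv)
  }
  pmax(d, 0)
}

# brute-force contrast from labeled feature rows
oracle_contrast <- function(x, labels) {
  n <- nrow(x)
  d_in <- 0; d_out <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dd <- cosine_distance(x[i, ], x[j, ])
    if (labels[i] == labels[j]) d_in <- d_in + dd else d_out <- d_out + dd
  }
  if (d_in + d_out == 0) 0 else (d_out - d_in) / (d_out + d_in)
}

# exhaustive signed-rank tail probability over all 2^n sign patterns
oracle_signed_rank_p <- function(d, tail = "right") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    pos <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    sum(r[pos])
  }, numeric(1))
  switch(tail,
         right = mean(ws >= w_obs),
         left = mean(ws <= w_obs),
         two = min(1, 2 * min(mean(ws >= w_obs), mean(ws <= w_obs))))
}

# brute-force conditional firing probability for one ordered pair:
# loop over every conditioning spike-bin of j and every lag
oracle_cfp <- function(resp, j, i, max_lag_ms = 100, bin_ms = 2,
                       window_ms = 500) {
  nb <- window_ms / bin_ms
  n_lag <- max_lag_ms / bin_ms + 1
  num <- numeric(n_lag); den <- numeric(n_lag)
  bins_of <- function(t) unique(pmin(floor(t / bin_ms) + 1, nb))
  for (r in resp) {
    bj <- bins_of(r$spikes[[as.character(j)]])
    bi <- bins_of(r$spikes[[as.character(i)]])
    for (b in bj) for (l in seq_len(n_lag)) {
      tgt <- b + (l - 1)
      if (tgt > nb) next
      den[l] <- den[l] + 1
      if (tgt %in% bi) num[l] <- num[l] + 1
    }
  }
  ifelse(den == 0, 0, num / den)
}

# brute-force network-spike detection by bin-and-scan
oracle_network_spikes <- function(times, threshold, bin_ms = 3,
                                  search_ms = 400) {
  n_bins <- ceiling(search_ms / bin_ms)
  counts <- numeric(n_bins)
  for (t in times[times >= 0 & times < search_ms]) {
    b <- floor(t / bin_ms) + 1
    counts[b] <- counts[b] + 1
  }
  onsets <- numeric(0)
  in_event <- FALSE
  for (b in seq_len(n_bins)) {
    if (counts[b] >= threshold && !in_event) {
      onsets <- c(onsets, (b - 1) * bin_ms)
      in_event <- TRUE
    } else if (counts[b] < threshold) in_event <- FALSE
  }
  onsets
}

# a small deterministic two-source pair for pipeline tests
tiny_config <- function(seed = 11L, n_trials = 12L)
  synthetic_config(sources = c(1L, 25L), n_trials_per_source = n_trials,
                   seed = seed)
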
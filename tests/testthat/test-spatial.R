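# CFP profiles, typical delays, latency maps and velocity recovery.

test_that("CFP estimator matches the brute-force conditional count", {
  g <- grid_geometry(2, 2)
  set.seed(67)
  for (rep in 1:8) {
    trials <- lapply(1:6, function(tr) {
      sp <- lapply(1:4, function(e) sort(runif(sample(5:40, 1), 0, 500)))
      names(sp) <- as.character(1:4)
      make_response(sp, g, trial = tr)
    })
    rs <- make_response_set(trials, g)
    cfp <- cfp_profiles(rs, min_spikes = 1, peak_min = 0,
                        keep_profiles = TRUE)
    for (pr in sample(nrow(cfp$pairs), 4)) {
      j <- cfp$pairs$j[pr]; i <- cfp$pairs$i[pr]
      raw <- oracle_cfp(rs, j, i)
      # compare smoothed profiles (zero-padded 3-point moving average)
      padded <- c(0, raw, 0)
      sm <- vapply(seq_along(raw), function(k)
        sum(padded[k:(k + 2)]) / 3, numeric(1))
      expect_equal(cfp$profiles[[paste0(j, "->", i)]], sm,
                   tolerance = 1e-12)
    }
  }
})

test_that("a fixed 4 ms lead yields typical delay 4 and self-pairs delay 0", {
  g <- grid_geometry(2, 2)
  trials <- lapply(1:40, function(tr)
    make_response(list("1" = c(10, 20, 30), "2" = c(14, 24, 34)), g,
                  trial = tr))
  rs <- make_response_set(trials, g)
  cfp <- cfp_profiles(rs, min_spikes = 100, peak_min = 0.05)
  p12 <- cfp$pairs[cfp$pairs$j == 1 & cfp$pairs$i == 2, ]
  expect_false(p12$excluded)
  expect_equal(p12$typical_delay_ms, 4)
  # conditioning an electrode on itself peaks at lag zero
  trials_self <- lapply(1:40, function(tr)
    make_response(list("1" = c(10, 110, 210), "2" = c(10, 110, 210)), g,
                  trial = tr))
  cfp2 <- cfp_profiles(make_response_set(trials_self, g), min_spikes = 100,
                       peak_min = 0.05)
  p <- cfp2$pairs[cfp2$pairs$j == 1 & cfp2$pairs$i == 2, ]
  expect_equal(p$typical_delay_ms, 0)
})

test_that("under-threshold and flat-profile pairs are excluded with reasons", {
  g <- grid_geometry(2, 2)
  set.seed(71)
  # sparse independent Poisson trains: peaks fall below 0.05
  trials <- lapply(1:30, function(tr) {
    sp <- lapply(1:4, function(e) sort(runif(5, 0, 500)))
    names(sp) <- as.character(1:4)
    make_response(sp, g, trial = tr)
  })
  rs <- make_response_set(trials, g)
  cfp <- cfp_profiles(rs, min_spikes = 100, peak_min = 0.05)
  expect_gte(mean(cfp$pairs$excluded), 0.9)
  expect_true(all(cfp$pairs$reason[cfp$pairs$excluded] == "low_peak"))
  # fewer than 100 spikes per electrode: excluded before estimation
  cfp2 <- cfp_profiles(rs[1:2], min_spikes = 100)
  expect_true(all(cfp2$pairs$reason == "min_spikes"))
})

test_that("typical delay ignores trial order and appended empty trials", {
  g <- grid_geometry(2, 2)
  set.seed(73)
  trials <- lapply(1:30, function(tr) {
    base <- sort(runif(8, 10, 400))
    make_response(list("1" = base, "2" = base + 6), g, trial = tr)
  })
  rs <- make_response_set(trials, g)
  delay_of <- function(x) {
    cf <- cfp_profiles(x, min_spikes = 50, peak_min = 0.01)
    cf$pairs$typical_delay_ms[cf$pairs$j == 1 & cf$pairs$i == 2]
  }
  d0 <- delay_of(rs)
  expect_equal(delay_of(rs[sample(30)]), d0)
  with_empty <- make_response_set(
    c(unclass(rs), list(make_response(list(), g, trial = 31L))), g)
  expect_equal(delay_of(with_empty), d0)
})

test_that("zero-noise wave data recover the template map and velocity", {
  # deterministic single-spike wave: one spike per electrode at onset
  cfg <- synthetic_config(
    sources = 1L, n_trials_per_source = 10L,
    control_noise = noise_model(0, 0, 1), blocked_noise = noise_model(0, 0, 1),
    peak_count = 1, count_decay_um = Inf, seed = 79L)
  pair <- generate_dataset(cfg)
  resp <- responses(pair$blocked)
  tpl <- pair$templates[["1"]]
  # latency map equals template onsets, electrode by electrode
  lm_ <- latency_map(resp, cfg$grid)
  expect_equal(lm_$median_fsl_ms,
               unname(tpl$onset_ms[as.character(lm_$electrode)]))
  expect_true(all(lm_$responder))
  # CFP delays follow the radial-distance model at the configured velocity
  cfp <- cfp_profiles(resp, min_spikes = 10, peak_min = 0.05)
  vel <- estimate_velocity(cfp, cfg$grid, source = 1L)
  pred <- vel$pairs$radial_dd_um / (0.5 * 1000)
  expect_true(all(abs(vel$pairs$typical_delay_ms - pred) <= 2 + 1e-9))
  expect_equal(vel$velocity_m_s, 0.5, tolerance = 0.1)
  # delay increases with distance
  dvd <- delay_vs_distance(cfp, cfg$grid)
  expect_gt(dvd$rho, 0.5)
})

test_that("silent electrodes are flagged as non-responders in the map", {
  g <- grid_geometry(2, 2)
  trials <- lapply(1:5, function(tr)
    make_response(list("1" = 10 + tr, "2" = c(20, 30)), g, trial = tr))
  lm_ <- latency_map(make_response_set(trials, g), g)
  expect_equal(lm_$responder, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(lm_$median_fsl_ms[2], 20)
  expect_true(all(is.na(lm_$median_fsl_ms[3:4])))
})

test_that("contrast vs source distance pairs conditions and flags flat input", {
  g <- grid_geometry()
  ctrl <- data.frame(source_a = c(1L, 1L, 11L), source_b = c(2L, 11L, 12L),
                     contrast = c(0.1, 0.3, 0.2))
  blk <- ctrl; blk$contrast <- c(0.05, 0.6, 0.5)
  res <- contrast_vs_source_distance(ctrl, blk, g)
  expect_equal(res$table$delta, blk$contrast - ctrl$contrast)
  expect_equal(res$table$distance_um[1], 500)
  # all distances equal -> correlation undefined, flagged
  ctrl2 <- data.frame(source_a = c(1L, 11L, 21L),
                      source_b = c(2L, 12L, 22L),
                      contrast = c(0.1, 0.2, 0.3))
  res2 <- contrast_vs_source_distance(ctrl2, ctrl2, g)
  expect_false(res2$rho_defined)
  # contrast increasing in distance by construction -> Spearman 1
  ctrl3 <- data.frame(source_a = c(1L, 1L, 1L, 1L),
                      source_b = c(2L, 4L, 7L, 10L),
                      contrast = c(0.1, 0.2, 0.3, 0.4))
  res3 <- contrast_vs_source_distance(ctrl3, ctrl3, g)
  expect_equal(res3$rho_control, 1)
})
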
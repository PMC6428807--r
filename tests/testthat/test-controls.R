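# Jitter and subsampling surrogates, and jitter-width calibration.

test_that("zero-width jitter is the identity and counts are preserved", {
  pair <- generate_dataset(tiny_config(seed = 2L, n_trials = 5L))
  resp <- responses(pair$blocked)
  expect_identical(jitter_spikes(resp, 0), resp)
  set.seed(3)
  jit <- jitter_spikes(resp, 25)
  for (i in seq_along(resp))
    expect_equal(lengths(jit[[i]]$spikes), lengths(resp[[i]]$spikes))
  t <- unlist(lapply(jit, function(r) unlist(r$spikes)))
  expect_true(all(t > 0 & t <= 500))
})

test_that("a spike jittered past the window edge clips to 500", {
  g <- grid_geometry()
  r <- make_response_set(list(make_response(list("1" = 499.9), g)), g)
  hit <- FALSE
  set.seed(5)
  for (i in 1:50) {
    j <- jitter_spikes(r, 10)[[1]]$spikes[["1"]]
    expect_length(j, 1)
    if (j == 500) hit <- TRUE
  }
  expect_true(hit)
})

test_that("empirical jitter SD matches the requested width", {
  g <- grid_geometry()
  r <- make_response_set(
    list(make_response(list("1" = rep(250, 10000)), g)), g)
  set.seed(7)
  j <- jitter_spikes(r, 10)[[1]]$spikes[["1"]]
  expect_lt(abs(sd(j - 250) - 10) / 10, 0.03)
})

test_that("subsampling matches the control mean and never adds spikes", {
  cfg <- synthetic_config(sources = 1L, n_trials_per_source = 20L,
                          seed = 31L)
  pair <- generate_dataset(cfg)
  rb <- responses(pair$blocked); rc <- responses(pair$control)
  set.seed(11)
  sub <- subsample_to_match(rb, rc)
  cb <- electrode_counts(rb); cc <- electrode_counts(rc)
  cs <- electrode_counts(sub)
  for (e in names(cs)) {
    expect_lte(cs[[e]], cb[[e]])
    if (cc[[e]] / length(rc) < cb[[e]] / length(rb))
      expect_lt(abs(cs[[e]] / length(rb) - cc[[e]] / length(rc)), 1)
  }
  # subset property, spike by spike
  for (i in seq_along(rb)) for (e in names(rb[[i]]$spikes))
    expect_true(all(sub[[i]]$spikes[[e]] %in% rb[[i]]$spikes[[e]]))
})

test_that("an electrode silent under control is emptied", {
  g <- grid_geometry(1, 2)
  rb <- make_response_set(list(
    make_response(list("1" = c(10, 20), "2" = c(10, 20)), g),
    make_response(list("1" = c(30, 40), "2" = 15), g)), g)
  rc <- make_response_set(list(
    make_response(list("1" = 10), g),
    make_response(list("1" = 12), g)), g)
  set.seed(13)
  sub <- subsample_to_match(rb, rc)
  expect_equal(sum(vapply(sub, function(r) length(r$spikes[["2"]]), 1)), 0)
})

test_that("richer control rates trigger the no-deletion warning", {
  g <- grid_geometry(1, 2)
  rb <- make_response_set(list(make_response(list("1" = 10), g)), g)
  rc <- make_response_set(list(make_response(list("1" = c(1:5)), g)), g)
  set.seed(17)
  expect_warning(sub <- subsample_to_match(rb, rc), "control mean")
  expect_equal(sub[[1]]$spikes[["1"]], rb[[1]]$spikes[["1"]])
})

test_that("calibration degenerate cases behave as documented", {
  pair <- generate_dataset(tiny_config(seed = 8L, n_trials = 10L))
  rb <- responses(pair$blocked)
  set.seed(19)
  # single candidate width 0: trivially the best
  res0 <- calibrate_jitter(rb, rb, widths_ms = 0, electrodes = 1:8)
  expect_equal(res0$best_width_ms, 0)
  # control identical to blocked: the smallest width adds the least noise
  res <- calibrate_jitter(rb, rb, widths_ms = c(1, 8, 20),
                          electrodes = 1:8)
  expect_equal(res$best_width_ms, 1)
})

test_that("calibration recovers a known jitter width", {
  # control generated from the blocked templates at sigma = 10 ms: the
  # only difference between conditions is spike-time jitter
  widths <- c(2, 5, 8, 10, 12, 15, 20)
  best <- vapply(1:6, function(s) {
    cfg <- synthetic_config(
      sources = 1L, n_trials_per_source = 40L,
      control_noise = noise_model(10, 0.05, 1),
      blocked_noise = noise_model(1, 0.05, 1), seed = s)
    pair <- generate_dataset(cfg)
    set.seed(s + 100)
    calibrate_jitter(responses(pair$blocked), responses(pair$control),
                     widths_ms = widths, electrodes = 1:8)$best_width_ms
  }, numeric(1))
  expect_lt(abs(mean(best) - 10), 3)
})
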
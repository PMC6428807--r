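# Wave templates and the two-condition synthetic generator.

test_that("wave template onset latencies follow distance / velocity", {
  g <- grid_geometry()
  tpl <- wave_template(g, source = 1L, velocity_m_s = 0.5,
                       base_latency_ms = 5)
  # the source itself responds at the base latency
  expect_equal(unname(tpl$onset_ms["1"]), 5)
  # nearest neighbor: 500 um at 0.5 m/s (= 500 um/ms) is 1 ms later
  expect_equal(unname(tpl$onset_ms["2"]), 6)
  # far corner of the 6x10 grid: sqrt(9^2 + 5^2) * 500 um away
  d_corner <- sqrt(9^2 + 5^2) * 500
  expect_equal(unname(tpl$onset_ms["60"]), 5 + d_corner / 500)
  expect_equal(unname(tpl$onset_ms["60"]), 15.2956, tolerance = 1e-4)
  # latency is non-decreasing in distance from the source
  ord <- order(tpl$dist_um)
  expect_true(all(diff(tpl$onset_ms[ord]) >= 0))
  expect_true(all(tpl$onset_ms > 0 & tpl$onset_ms < 500))
})

test_that("off-grid source is rejected by name", {
  expect_error(wave_template(grid_geometry(), source = 99L), "99")
})

test_that("zero-noise responses reproduce the template exactly", {
  g <- grid_geometry()
  tpl <- wave_template(g, source = 1L)
  set.seed(42)
  r <- generate_response(tpl, noise_model(0, 0, 1))
  fsl <- vapply(r, function(t) t[1], numeric(1))
  expect_equal(fsl, tpl$onset_ms)
  # recruitment order equals the template's distance ranking
  resp <- make_response_set(list(make_response(r, g)), g)
  ro <- recruitment_order(resp[[1]], g$electrode_ids)
  expect_equal(unname(ro),
               unname(rank(tpl$dist_um, ties.method = "average")))
})

test_that("total participation failure empties the response", {
  tpl <- wave_template(grid_geometry(), 1L)
  set.seed(1)
  r <- generate_response(tpl, noise_model(0, 1, 1))
  expect_true(all(lengths(r) == 0))
})

test_that("spike times stay inside (0, 500] under heavy jitter", {
  tpl <- wave_template(grid_geometry(), 1L)
  set.seed(3)
  for (i in 1:5) {
    r <- generate_response(tpl, noise_model(200, 0, 1))
    t <- unlist(r)
    expect_true(all(t > 0 & t <= 500))
  }
})

test_that("first-spike latency spread matches a Monte-Carlo oracle", {
  # independent oracle: draw the burst model directly (first spike at the
  # onset, extras at exponential delays, Gaussian jitter, min of the set)
  g <- grid_geometry(2, 2, 500)
  tpl <- wave_template(g, 1L, peak_count = 5, count_decay_um = Inf,
                       tau_ms = 30)
  sigma <- 10
  onset <- tpl$onset_ms[["1"]]
  set.seed(99)
  oracle_fsl <- replicate(4000, {
    n_extra <- rpois(1, 4)
    sp <- onset + c(0, rexp(n_extra, 1 / 30)) +
      rnorm(n_extra + 1, 0, sigma)
    min(pmin(pmax(sp, 1e-6), 500))
  })
  set.seed(7)
  fsl <- replicate(4000, {
    r <- generate_response(tpl, noise_model(sigma, 0, 1))
    r[["1"]][1]
  })
  expect_lt(abs(sd(fsl) - sd(oracle_fsl)) / sd(oracle_fsl), 0.15)
  expect_lt(abs(mean(fsl) - mean(oracle_fsl)), 1)
})

test_that("dataset generation is reproducible and seed-sensitive", {
  cfg <- tiny_config(seed = 5L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$control$events, b$control$events)
  expect_identical(a$blocked$events, b$blocked$events)
  expect_identical(a$control$stim_log, b$control$stim_log)
  c <- generate_dataset(tiny_config(seed = 6L))
  expect_false(identical(a$control$events, c$control$events))
})

test_that("early trials are unchanged when the trial count grows", {
  cfg1 <- tiny_config(seed = 5L, n_trials = 6L)
  cfg2 <- tiny_config(seed = 5L, n_trials = 9L)
  a <- generate_dataset(cfg1)$blocked
  b <- generate_dataset(cfg2)$blocked
  shared <- intersect(a$stim_log$trial, b$stim_log$trial)
  # trials with the same index and source got identical spikes
  same_src <- shared[a$stim_log$source[shared] == b$stim_log$source[shared]]
  expect_gt(length(same_src), 0)
  for (tr in same_src) {
    ea <- a$events[a$events$trial == tr, ]
    eb <- b$events[b$events$trial == tr, ]
    rownames(ea) <- rownames(eb) <- NULL
    expect_identical(ea, eb)
  }
})

test_that("identical noise models yield statistically exchangeable data", {
  nm <- noise_model(5, 0.1, 1)
  ps <- vapply(1:10, function(s) {
    cfg <- synthetic_config(sources = c(1L, 25L), n_trials_per_source = 15L,
                           control_noise = nm, blocked_noise = nm, seed = s)
    pair <- generate_dataset(cfg)
    md <- function(ds) {
      resp <- responses(ds)
      fm <- feature_matrix(resp, "order", electrodes = 1:8)
      d <- pairwise_distances(fm$x)
      d[upper.tri(d)]
    }
    suppressWarnings(stats::ks.test(md(pair$control), md(pair$blocked))$p.value)
  }, numeric(1))
  # two-sample test should reject at alpha = 0.01 only rarely
  expect_lte(sum(ps < 0.01), 2)
})

test_that("blocked responses are mutually closer than control for every feature", {
  cfg <- synthetic_config(sources = 1L, n_trials_per_source = 30L, seed = 21L)
  pair <- generate_dataset(cfg)
  rc <- responses(pair$control); rb <- responses(pair$blocked)
  set.seed(1)
  for (ft in c("order", "fsl", "words", "rate")) {
    el <- if (ft == "words") 1:6 else if (ft == "rate") NULL else 1:8
    mean_pairwise <- function(resp) {
      fm <- feature_matrix(resp, ft, electrodes = el)
      d <- pairwise_distances(fm$x)
      mean(d[upper.tri(d)])
    }
    expect_lt(mean_pairwise(rb), mean_pairwise(rc))
  }
})

test_that("jitter width monotonically increases recruitment-order dispersion", {
  widths <- c(1, 5, 15)
  disp <- sapply(1:10, function(s) {
    vapply(widths, function(w) {
      cfg <- synthetic_config(sources = 1L, n_trials_per_source = 15L,
                              control_noise = noise_model(w, 0, 1),
                              blocked_noise = noise_model(w, 0, 1),
                              seed = s)
      resp <- responses(generate_dataset(cfg)$control)
      fm <- feature_matrix(resp, "order", electrodes = 1:8)
      d <- pairwise_distances(fm$x)
      mean(d[upper.tri(d)])
    }, numeric(1))
  })
  m <- rowMeans(disp)
  expect_true(all(diff(m) > 0))
})
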
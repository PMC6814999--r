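test_that("zero-rate profiles give empty spike trains and ground truth", {
  p <- sim_profile("silent", single_rate = 0, burst_rate = 0, duration = 100,
                   rate_cv = 0)
  sim <- simulate_spike_train(p, unit_seed = 1)
  expect_length(sim$train$spike_times, 0)
  expect_equal(nrow(sim$truth$burst_windows), 0)
})

test_that("single-spike counts follow Poisson statistics", {
  p <- sim_profile("pois", single_rate = 10, burst_rate = 0, duration = 600,
                   rate_cv = 0)
  sim <- simulate_spike_train(p, unit_seed = 11)
  n <- length(sim$train$spike_times)
  expect_lt(abs(n - 6000), 4 * sqrt(6000))  # 99.99% Poisson band
})

test_that("generated bursts respect the detector's criteria by construction", {
  p <- sim_profile("bursty", single_rate = 0, burst_rate = 0.1,
                   burst_size_mean = 3, duration = 600, rate_cv = 0)
  sim <- simulate_spike_train(p, unit_seed = 5)
  w <- sim$truth$burst_windows
  expect_lt(abs(nrow(w) - 60), 4 * sqrt(60))
  for (k in seq_len(nrow(w))) {
    spikes <- sim$train$spike_times[sim$train$spike_times >= w$start[k] &
                                      sim$train$spike_times <= w$end[k]]
    expect_gte(length(spikes), 3)
    expect_true(all(diff(spikes) < 0.015))
  }
  if (nrow(w) > 1)
    expect_true(all(w$start[-1] - w$end[-nrow(w)] > 0.100))
})

test_that("empirical rates converge to profile rates over a long recording", {
  p <- sim_profile("conv", single_rate = 5, burst_rate = 0.05,
                   duration = 3600, rate_cv = 0)
  sim <- simulate_spike_train(p, unit_seed = 3)
  single_emp <- length(sim$truth$single_times) / p$duration
  burst_emp <- nrow(sim$truth$burst_windows) / p$duration
  expect_lte(abs(single_emp - 5) / 5, 0.05 + 1e-12)
  expect_lte(abs(burst_emp - 0.05) / 0.05, 0.05 + 1e-12)
})

test_that("spike-train generation is deterministic given the seed", {
  p <- sim_profile("det", single_rate = 6, burst_rate = 0.1, duration = 300)
  a <- simulate_spike_train(p, unit_seed = 99)
  b <- simulate_spike_train(p, unit_seed = 99)
  expect_identical(a$train$spike_times, b$train$spike_times)
  expect_identical(a$truth$burst_windows, b$truth$burst_windows)
})

test_that("drug effect scales post-injection rates, by unit class", {
  p <- sim_profile("drug", single_rate = 20, burst_rate = 0, duration = 1200,
                   injection_time = 600, rate_cv = 0,
                   drug_effect = list(single = c(fast = 0.5, regular = 2)))
  sim <- simulate_spike_train(p, unit_seed = 21)
  st <- sim$train$spike_times
  pre <- sum(st < 600) / 600
  post <- sum(st >= 600) / 600
  expect_lt(abs(post / pre - 0.5), 0.15)  # fast unit (20 Hz) halves

  p2 <- sim_profile("drug2", single_rate = 4, burst_rate = 0, duration = 1200,
                    injection_time = 600, rate_cv = 0,
                    drug_effect = list(single = c(fast = 0.5, regular = 2)))
  sim2 <- simulate_spike_train(p2, unit_seed = 22)
  st2 <- sim2$train$spike_times
  ratio2 <- (sum(st2 >= 600) / 600) / (sum(st2 < 600) / 600)
  expect_lt(abs(ratio2 - 2), 0.4)        # regular unit (4 Hz) doubles
})

test_that("invalid profiles are rejected", {
  expect_error(sim_profile("bad", single_rate = -1), "non-negative")
  expect_error(sim_profile("bad", duration = 0), "positive")
  expect_error(sim_profile("bad", intra_burst_isi = 0.02), "0.015")
})

test_that("silent unit renders a constant trace at baseline fluorescence", {
  tr <- spike_train("u0", numeric(0), c(0, 60))
  truth <- list(burst_windows = data.frame(start = numeric(0), end = numeric(0),
                                           n_spikes = integer(0)),
                single_times = numeric(0))
  k <- kernel_params(noise_sd = 0, drift_amp = 0, baseline_f0 = 120)
  fl <- simulate_fluorescence(tr, truth, k)
  expect_true(all(fl$trace$raw_f == 120))
})

test_that("a lone burst produces one transient peaking at the kernel maximum", {
  tr <- spike_train("u1", c(100, 100.01, 100.02), c(0, 200))
  truth <- list(burst_windows = data.frame(start = 100, end = 100.02,
                                           n_spikes = 3L),
                single_times = numeric(0))
  k <- kernel_params(noise_sd = 0, drift_amp = 0)
  fl <- simulate_fluorescence(tr, truth, k)
  t <- fl$trace$frame_times
  peak_frame <- t[which.max(fl$trace$raw_f)]
  expected_peak <- 100 + caburst:::kernel_peak_lag(k)
  expect_lt(abs(peak_frame - expected_peak), k$frame_interval)
  d <- compute_dff(fl$trace, baseline_window = c(0, 90))
  ev <- detect_events(d)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$area, 0)
})

test_that("with zero single-spike amplitude, visible transients are exactly the bursts", {
  p <- sim_profile("mix", single_rate = 1, burst_rate = 0.05, duration = 400,
                   rate_cv = 0)
  sim <- simulate_spike_train(p, unit_seed = 8)
  k <- kernel_params(amp_per_single = 0, noise_sd = 0, drift_amp = 0)
  fl <- simulate_fluorescence(sim$train, sim$truth, k, seed = 1)
  expect_equal(length(fl$truth$event_times), nrow(sim$truth$burst_windows))
})

test_that("movie rendering is linear: recovered traces track the inputs", {
  nf <- 40L
  tt <- (0:(nf - 1)) * 1.109
  a <- fluor_trace("a", tt, 1 + 0.5 * sin(seq(0, 3, length.out = nf)))
  b <- fluor_trace("b", tt, 1 + 0.5 * cos(seq(0, 5, length.out = nf)))
  layout <- movie_layout(width = 48, height = 24, radii = 4,
                         centers = rbind(c(14, 12), c(34, 12)),
                         background_offset = 10, noise_sd = 0)
  mov <- simulate_movie(list(a, b), layout)
  rec <- extract_roi_traces(mov$stack, mov$masks, frame_times = tt)
  expect_gt(stats::cor(rec[[1]]$raw_f, a$raw_f), 0.99)
  expect_gt(stats::cor(rec[[2]]$raw_f, b$raw_f), 0.99)

  ## zero-intensity trace: ROI mean equals the background offset
  z <- fluor_trace("z", tt, rep(0, nf))
  movz <- simulate_movie(list(z), movie_layout(width = 24, height = 24,
                                               centers = rbind(c(12, 12)),
                                               radii = 4,
                                               background_offset = 7))
  recz <- extract_roi_traces(movz$stack, movz$masks, frame_times = tt)
  expect_true(all(abs(recz[[1]]$raw_f - 7) < 1e-9))
})

test_that("overlapping or out-of-frame somata are rejected", {
  expect_error(movie_layout(width = 32, height = 32,
                            centers = rbind(c(10, 10), c(14, 10)), radii = 4),
               "overlap")
  expect_error(movie_layout(width = 32, height = 32,
                            centers = rbind(c(2, 10)), radii = 4),
               "fit")
})

test_that("movies survive a 16-bit TIFF round trip", {
  nf <- 10L
  tt <- (0:(nf - 1)) * 1.109
  a <- fluor_trace("a", tt, seq(0, 1, length.out = nf))
  layout <- movie_layout(width = 24, height = 24, centers = rbind(c(12, 12)),
                         radii = 4, background_offset = 1)
  mov <- simulate_movie(list(a), layout)
  f <- tempfile(fileext = ".tif"); fm <- tempfile(fileext = ".tif")
  write_movie_tiff(mov, f, fm)
  back <- read_movie_tiff(f)
  expect_equal(dim(back), dim(mov$stack))
  sc <- max(mov$stack)
  expect_lt(max(abs(back - mov$stack / sc)), 2 / 65535)
  expect_equal(read_mask_tiff(fm), mov$masks[[1]])
})
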
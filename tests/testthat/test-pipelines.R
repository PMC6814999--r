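make_bundle <- function(dir, profiles, seed = 1, trace_profiles = character(0),
                        kernel = kernel_params()) {
  simulate_study(profiles = profiles, out_dir = dir, seed = seed,
                 trace_profiles = trace_profiles, kernel = kernel)
}

test_that("spike and trace tables round-trip through their text formats", {
  tr1 <- spike_train("u1", c(0.5, 1.0, 2.5), c(0, 10), injection_time = 5,
                     group_label = "g")
  tr2 <- spike_train("u2", c(0.1, 9.9), c(0, 10))
  f <- tempfile(fileext = ".tsv")
  write_spike_table(list(tr1, tr2), f, seed = 3)
  expect_match(readLines(f, n = 1), "^# caburst .*seed=3")
  meta <- data.frame(unit_id = c("u1", "u2"), group = "g",
                     injection_time_s = 5, span_start_s = 0, span_end_s = 10)
  back <- read_spike_table(f, metadata = meta)
  expect_equal(back$u1$spike_times, tr1$spike_times)
  expect_equal(back$u2$spike_times, tr2$spike_times)
  expect_equal(back$u1$injection_time, 5)

  tt <- (0:49) * 1.109
  fl <- list(fluor_trace("r1", tt, 100 + sin(tt)),
             fluor_trace("r2", tt, 90 + cos(tt)))
  g <- tempfile(fileext = ".csv")
  write_trace_table(fl, g)
  back2 <- read_trace_table(g, include = data.frame(roi_id = "r2",
                                                    include = FALSE))
  expect_equal(back2$r1$raw_f, fl[[1]]$raw_f)
  expect_false(back2$r2$include)
  expect_true(back2$r1$include)
})

test_that("study simulation writes a complete, reproducible bundle", {
  d1 <- tempfile("study1_"); d2 <- tempfile("study2_")
  profiles <- list(
    a = sim_profile("a", single_rate = 3, burst_rate = 0.05, duration = 120,
                    n_units = 4L),
    b = sim_profile("b", single_rate = 6, burst_rate = 0.05, duration = 120,
                    n_units = 4L))
  make_bundle(d1, profiles, seed = 10)
  make_bundle(d2, profiles, seed = 10)
  for (f in c("a/spikes.tsv", "a/metadata.tsv", "b/spikes.tsv",
              "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  mf <- read_manifest(file.path(d1, "manifest.json"))
  expect_equal(mf$seed, 10)
  expect_named(mf$conditions, c("a", "b"))

  ## different seed, different data
  d3 <- tempfile("study3_")
  make_bundle(d3, profiles, seed = 11)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "a/spikes.tsv"))),
                         unname(tools::md5sum(file.path(d3, "a/spikes.tsv")))))
})

test_that("unknown profile labels are a configuration error", {
  expect_error(simulate_study(profiles = c("control", "nope"),
                              out_dir = tempfile()),
               "unknown profile")
  expect_s3_class(tryCatch(simulate_study(profiles = "nope",
                                          out_dir = tempfile()),
                           error = identity),
                  "caburst_config_error")
})

test_that("the ephys pipeline recovers the control-vs-model rate contrast", {
  d <- tempfile("ephys_")
  profiles <- list(
    control = sim_profile("control", single_rate = 7.7, burst_rate = 0.1,
                          duration = 1200, injection_time = 600,
                          n_units = 12L),
    nrg1 = sim_profile("nrg1", single_rate = 19.7, burst_rate = 0.1,
                       duration = 1200, injection_time = 600, n_units = 12L))
  make_bundle(d, profiles, seed = 5)
  ## pool both conditions into one run via a merged table
  spikes <- rbind(
    utils::read.table(file.path(d, "control/spikes.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#"),
    utils::read.table(file.path(d, "nrg1/spikes.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#"))
  meta <- rbind(
    utils::read.table(file.path(d, "control/metadata.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#"),
    utils::read.table(file.path(d, "nrg1/metadata.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#"))
  sp <- file.path(d, "all_spikes.tsv"); mp <- file.path(d, "all_meta.tsv")
  utils::write.table(spikes, sp, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(meta, mp, sep = "\t", row.names = FALSE, quote = FALSE)

  cfg <- run_config("ephys", spike_table = sp, metadata = mp,
                    out_dir = file.path(d, "out"), seed = 5,
                    post_bin_s = 600, n_post_bins = 1L,
                    response_window = c(0, 600))
  res <- run_ephys(cfg)
  expect_true(all(file.exists(file.path(d, "out",
                                        c("bursts.csv", "rates.csv",
                                          "responses.csv")))))
  base <- res$rates[res$rates$bin == 0, ]
  grp <- res$responses$group[match(base$unit_id, res$responses$unit_id)]
  ratio <- mean(base$mean_rate[grp == "nrg1"]) /
    mean(base$mean_rate[grp == "control"])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 3.4)
  ## null drug: modal response class is no change
  fr <- res$fractions$control
  expect_equal(names(which.max(fr)), "no_change")
  ## identical rerun gives identical output bytes
  cfg2 <- run_config("ephys", spike_table = sp, metadata = mp,
                     out_dir = file.path(d, "out2"), seed = 5,
                     post_bin_s = 600, n_post_bins = 1L,
                     response_window = c(0, 600))
  run_ephys(cfg2)
  expect_identical(
    unname(tools::md5sum(file.path(d, "out", "responses.csv"))),
    unname(tools::md5sum(file.path(d, "out2", "responses.csv"))))
})

test_that("an empty unit list exits cleanly with empty tables", {
  d <- tempfile("empty_")
  dir.create(d)
  sp <- file.path(d, "spikes.tsv")
  writeLines("unit_id\ttime_s", sp)
  cfg <- run_config("ephys", spike_table = sp, out_dir = file.path(d, "out"))
  expect_warning(res <- run_ephys(cfg), "empty unit list")
  expect_equal(nrow(res$responses), 0)
  expect_true(file.exists(file.path(d, "out", "responses.csv")))
})

test_that("injection times outside the recording are a data error", {
  tr <- spike_train("u1", c(1, 2, 3), c(0, 10), injection_time = 5)
  d <- tempfile("badinj_"); dir.create(d)
  sp <- file.path(d, "spikes.tsv")
  write_spike_table(list(tr), sp)
  meta <- data.frame(unit_id = "u1", group = "g", injection_time_s = 50,
                     span_start_s = 0, span_end_s = 10)
  mp <- file.path(d, "meta.tsv")
  utils::write.table(meta, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- run_config("ephys", spike_table = sp, metadata = mp,
                    out_dir = file.path(d, "out"))
  err <- tryCatch(run_ephys(cfg), error = identity)
  expect_s3_class(err, "caburst_data_error")
  expect_match(conditionMessage(err), "injection_time outside")
})

test_that("the imaging pipeline leaves null-drug metrics near 100%", {
  d <- tempfile("imaging_")
  p <- imaging_profiles(injection_time = 600, duration = 1800)$null_drug
  p$n_units <- 6L
  make_bundle(d, list(null_drug = p), seed = 21,
              trace_profiles = "null_drug", kernel = imaging_kernel())
  cfg <- run_config("imaging", trace_table = file.path(d, "null_drug/traces.csv"),
                    out_dir = file.path(d, "out"), seed = 21,
                    baseline_s = 600)
  res <- run_imaging(cfg)
  expect_true(file.exists(file.path(d, "out", "normalized.csv")))
  freq <- res$normalized[res$normalized$metric == "freq_per_min", ]
  expect_gt(mean(freq$percent, na.rm = TRUE), 70)
  expect_lt(mean(freq$percent, na.rm = TRUE), 130)
  ## no significant drug effect in the digest
  if (!is.null(res$digest))
    expect_true(all(res$digest$p_value > 0.01))
})

test_that("missing inputs are caught at configuration time", {
  expect_error(run_config("ephys", spike_table = "/nonexistent.tsv"),
               "missing input")
  expect_error(run_config("imaging"), "needs trace_table")
})
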
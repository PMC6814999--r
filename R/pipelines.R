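## End-to-end pipelines binding the stages together: `run_ephys`
## (spike tables -> bursts, rates, responses, time course, stats),
## `run_imaging` (trace tables -> dF/F, events, metrics, normalised
## stats) and `run_simulate` (study bundle generation). Each pipeline is
## deterministic given (inputs, config, seed) and stamps every output
## table with a provenance header.

#' Pipeline run configuration
#'
#' Collects the tunable parameters of both pipelines with the study's
#' defaults baked in: 3 SD detection threshold, 60 s metric windows,
#' 15 ms / 3 spikes / 100 ms burst criteria, 10 Hz fast-spiking cutoff,
#' 80-120% response bounds, 10 min baseline before injection and
#' consecutive 30 min post-injection bins.
#'
#' @param pipeline one of "imaging", "ephys", "simulate".
#' @param spike_table,metadata,trace_table,include_table input paths
#'   (existence validated for the analysis pipelines).
#' @param out_dir output directory.
#' @param seed integer seed recorded in all outputs.
#' @param k_sd detection threshold in baseline-noise SDs.
#' @param window_s imaging metric window (s).
#' @param min_fraction fraction of lowest baseline frames averaged for F0.
#' @param criteria a [burst_criteria()].
#' @param response_bounds lower/upper SR bounds (%) for the
#'   decrease/no-change/increase classes.
#' @param fs_cutoff fast-spiking rate cutoff (Hz).
#' @param baseline_s baseline duration before injection (s).
#' @param post_bin_s post-injection bin length (s).
#' @param n_post_bins number of post-injection bins (30/60/90 min grid).
#' @param response_window offsets (s) after injection over which the
#'   burst-rate response class is evaluated (default 30-60 min).
#' @param burst_rate_kind `"bursts_per_s"` (default) or
#'   `"burst_spikes_per_s"`: which reading of "burst spike rate" drives
#'   response classification.
#' @param post_delay_s imaging-only delay between injection and the first
#'   post window (s).
#' @param profiles,trace_profiles,write_movies passed to
#'   [simulate_study()] for the simulate pipeline.
#' @return list of class `run_config`.
#' @export
run_config <- function(pipeline = c("ephys", "imaging", "simulate"),
                       spike_table = NULL, metadata = NULL,
                       trace_table = NULL, include_table = NULL,
                       out_dir = tempfile("caburst_run_"), seed = 1L,
                       k_sd = 3, window_s = 60, min_fraction = 0.1,
                       criteria = burst_criteria(),
                       response_bounds = c(80, 120), fs_cutoff = 10,
                       baseline_s = 600, post_bin_s = 1800, n_post_bins = 3L,
                       response_window = c(1800, 3600),
                       burst_rate_kind = c("bursts_per_s", "burst_spikes_per_s"),
                       post_delay_s = 0,
                       profiles = c("control", "nrg1"),
                       trace_profiles = character(0), write_movies = FALSE) {
  pipeline <- match.arg(pipeline)
  burst_rate_kind <- match.arg(burst_rate_kind)
  cfg <- list(pipeline = pipeline, spike_table = spike_table,
              metadata = metadata, trace_table = trace_table,
              include_table = include_table, out_dir = out_dir,
              seed = as.integer(seed), k_sd = k_sd, window_s = window_s,
              min_fraction = min_fraction, criteria = criteria,
              response_bounds = response_bounds, fs_cutoff = fs_cutoff,
              baseline_s = baseline_s, post_bin_s = post_bin_s,
              n_post_bins = as.integer(n_post_bins),
              response_window = response_window,
              burst_rate_kind = burst_rate_kind, post_delay_s = post_delay_s,
              profiles = profiles, trace_profiles = trace_profiles,
              write_movies = write_movies)
  if (pipeline == "ephys") {
    assert_that(!is.null(cfg$spike_table), "ephys pipeline needs spike_table")
    for (p in c(cfg$spike_table, cfg$metadata))
      if (!is.null(p)) assert_that(file.exists(p), sprintf("missing input: %s", p))
  }
  if (pipeline == "imaging") {
    assert_that(!is.null(cfg$trace_table), "imaging pipeline needs trace_table")
    assert_that(file.exists(cfg$trace_table),
                sprintf("missing input: %s", cfg$trace_table))
  }
  structure(cfg, class = "run_config")
}

## provenance hash over analysis parameters only; file-system locations
## must not change the recorded configuration identity
config_hash <- function(config) {
  drop <- c("spike_table", "metadata", "trace_table", "include_table",
            "out_dir")
  object_hash(unclass(config)[setdiff(names(config), drop)])
}

read_metadata_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

## post-injection analysis bins for one train, clipped to the recording
post_bins <- function(train, cfg) {
  inj <- train$injection_time
  ends <- train$recording_span[2]
  starts <- inj + (seq_len(cfg$n_post_bins) - 1L) * cfg$post_bin_s
  stops <- pmin(starts + cfg$post_bin_s, ends)
  ok <- stops > starts
  data.frame(bin = 30 * seq_len(cfg$n_post_bins)[ok],
             start = starts[ok], end = stops[ok])
}

## per-unit ephys analysis: bursts, windowed rates, SR per bin, response
ephys_unit <- function(train, cfg) {
  if (!is.finite(train$injection_time %||% NA))
    stop_data(sprintf("unit %s: injection time missing", train$unit_id))
  inj <- train$injection_time
  if (inj <= train$recording_span[1] || inj >= train$recording_span[2])
    stop_data(sprintf("unit %s: injection_time outside recording_span",
                      train$unit_id))
  bursts <- segment_bursts(train, cfg$criteria)
  base_win <- c(max(train$recording_span[1], inj - cfg$baseline_s), inj)
  bins <- post_bins(train, cfg)
  wins <- rbind(data.frame(bin = 0, start = base_win[1], end = base_win[2]),
                bins)
  rates <- compute_rates(train, bursts, wins[, c("start", "end")])
  rates$bin <- wins$bin
  base <- rates[rates$bin == 0, ]
  unit_class <- classify_unit(base$mean_rate, cfg$fs_cutoff)
  rates$unit_class <- unit_class

  ## response classification on the burst rate over the response window
  rw <- c(inj + cfg$response_window[1],
          min(inj + cfg$response_window[2], train$recording_span[2]))
  if (rw[2] <= rw[1]) rw <- c(inj, train$recording_span[2])
  resp_rates <- compute_rates(train, bursts, data.frame(start = rw[1], end = rw[2]))
  metric <- if (cfg$burst_rate_kind == "bursts_per_s") "burst_rate" else
    "burst_spike_rate"
  sr_burst <- if (base[[metric]] > 0)
    relative_change(base[[metric]], resp_rates[[metric]]) else NA_real_
  sr_mean <- if (base$mean_rate > 0)
    relative_change(base$mean_rate, resp_rates$mean_rate) else NA_real_

  sr_bins <- if (nrow(bins)) data.frame(
    unit_id = train$unit_id, bin = bins$bin,
    sr_percent = if (base$single_rate > 0)
      100 * rates$single_rate[rates$bin > 0] / base$single_rate else NA_real_)
  else NULL

  list(bursts = bursts, rates = rates, unit_class = unit_class,
       sr_burst = sr_burst, sr_mean = sr_mean, sr_bins = sr_bins)
}

#' Run the electrophysiology pipeline
#'
#' Reads spike and metadata tables, segments bursts, classifies units,
#' computes baseline and post-injection windowed rates, classifies each
#' unit's burst-rate response (decrease / no change / increase), builds
#' the baseline-normalised single-spike time course per group, and runs
#' between-group statistics. All tables are written under
#' `config$out_dir`.
#'
#' @param config a [run_config()] with `pipeline = "ephys"`.
#' @return invisibly, a list with `bursts`, `rates`, `responses`,
#'   `fractions`, `timecourse` and `digest`.
#' @export
run_ephys <- function(config) {
  stopifnot(inherits(config, "run_config"))
  meta <- if (!is.null(config$metadata)) read_metadata_table(config$metadata)
  trains <- read_spike_table(config$spike_table, metadata = meta)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  if (!length(trains)) {
    warning("empty unit list: writing empty tables")
    empty <- data.frame()
    for (f in c("bursts.csv", "rates.csv", "responses.csv"))
      write_table_prov(empty, file.path(config$out_dir, f), sep = ",",
                       seed = config$seed, config_hash = hash)
    return(invisible(list(bursts = empty, rates = empty, responses = empty)))
  }

  res <- lapply(trains, ephys_unit, cfg = config)
  burst_tab <- do.call(rbind, lapply(res, function(r)
    if (nrow(r$bursts$bursts))
      cbind(unit_id = r$bursts$unit_id, r$bursts$bursts) else NULL))
  burst_tab <- burst_tab %||%
    data.frame(unit_id = character(0), start = numeric(0), end = numeric(0),
               n_spikes = integer(0))
  rate_tab <- do.call(rbind, c(lapply(res, `[[`, "rates"),
                               make.row.names = FALSE))
  groups <- vapply(trains, function(tr) as.character(tr$group_label), "")
  responses <- data.frame(
    unit_id = vapply(trains, `[[`, "", "unit_id"),
    group = groups,
    unit_class = vapply(res, `[[`, "", "unit_class"),
    sr_mean_percent = vapply(res, `[[`, 1, "sr_mean"),
    sr_burst_percent = vapply(res, `[[`, 1, "sr_burst"))
  responses$response <- as.character(
    classify_response(responses$sr_burst_percent,
                      config$response_bounds[1], config$response_bounds[2]))

  fractions <- lapply(split(responses, responses$group), function(d) {
    cls <- d$response[!is.na(d$response)]
    if (length(cls)) fraction_by_class(factor(cls,
      levels = c("decrease", "no_change", "increase"))) else NULL
  })

  sr_bins <- do.call(rbind, c(lapply(res, `[[`, "sr_bins"),
                              make.row.names = FALSE))
  timecourse <- NULL
  if (!is.null(sr_bins) && nrow(sr_bins)) {
    sr_bins$group <- groups[match(sr_bins$unit_id,
                                  vapply(trains, `[[`, "", "unit_id"))]
    timecourse <- do.call(rbind, lapply(split(sr_bins, sr_bins$group),
      function(d) build_timecourse(d, group = d$group[1])))
    rownames(timecourse) <- NULL
  }

  tests <- list()
  glv <- unique(groups)
  if (length(glv) >= 2L) {
    a <- responses$sr_mean_percent[responses$group == glv[1]]
    b <- responses$sr_mean_percent[responses$group == glv[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) >= 2L && length(b) >= 2L)
      tests[[paste0("sr_mean_", glv[1], "_vs_", glv[2])]] <-
        ttest(a, b, labels = glv[1:2])
  }
  digest <- if (length(tests)) assemble_report(tests) else NULL

  write_table_prov(burst_tab, file.path(config$out_dir, "bursts.csv"),
                   sep = ",", seed = config$seed, config_hash = hash)
  write_table_prov(rate_tab, file.path(config$out_dir, "rates.csv"),
                   sep = ",", seed = config$seed, config_hash = hash)
  write_table_prov(responses, file.path(config$out_dir, "responses.csv"),
                   sep = ",", seed = config$seed, config_hash = hash)
  if (!is.null(timecourse))
    write_table_prov(timecourse, file.path(config$out_dir, "timecourse.csv"),
                     sep = ",", seed = config$seed, config_hash = hash)
  if (!is.null(digest)) {
    write_table_prov(digest, file.path(config$out_dir, "digest.csv"),
                     sep = ",", seed = config$seed, config_hash = hash)
    jsonlite::write_json(digest, file.path(config$out_dir, "digest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(bursts = burst_tab, rates = rate_tab, responses = responses,
                 fractions = fractions, timecourse = timecourse,
                 digest = digest))
}

#' Run the imaging pipeline
#'
#' Reads a trace table (plus optional ROI include-flag sidecar), converts
#' each ROI to dF/F using the pre-injection baseline, detects events,
#' summarises per-minute metrics in baseline and post-injection windows,
#' normalises each ROI's post metrics to its baseline, and tests the
#' normalised metrics of included ROIs against baseline (paired t-test of
#' per-ROI post vs baseline means).
#'
#' @param config a [run_config()] with `pipeline = "imaging"` and an
#'   `injection_time` attribute supplied via `baseline_s`: the baseline is
#'   the first `baseline_s` seconds of the recording, the post window
#'   starts `post_delay_s` after it.
#' @return invisibly, a list with `events`, `metrics`, `normalized` and
#'   `digest`.
#' @export
run_imaging <- function(config) {
  stopifnot(inherits(config, "run_config"))
  include <- if (!is.null(config$include_table))
    read_metadata_table(config$include_table)
  traces <- read_trace_table(config$trace_table, include = include)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  t0 <- traces[[1]]$frame_times[1]
  base_end <- t0 + config$baseline_s
  post_start <- base_end + config$post_delay_s
  if (base_end >= traces[[1]]$frame_times[length(traces[[1]]$frame_times)])
    stop_config("missing baseline segment: baseline_s covers the whole recording")

  events_all <- metrics_all <- norm_all <- list()
  for (tr in traces) {
    d <- compute_dff(tr, baseline_window = c(t0, base_end),
                     min_fraction = config$min_fraction)
    ev <- detect_events(d, k_sd = config$k_sd)
    met <- summarize_activity(ev, d, window_s = config$window_s)
    met$phase <- ifelse(met$window_end <= base_end, "baseline",
                        ifelse(met$window_start >= post_start, "post", "mid"))
    nm <- normalize_to_baseline(met[met$phase == "post", , drop = FALSE],
                                met[met$phase == "baseline", , drop = FALSE])
    nm <- cbind(roi_id = tr$roi_id, nm, include = tr$include)
    events_all[[tr$roi_id]] <- ev
    metrics_all[[tr$roi_id]] <- met
    norm_all[[tr$roi_id]] <- nm
  }
  events <- do.call(rbind, c(events_all, make.row.names = FALSE))
  metrics <- do.call(rbind, c(metrics_all, make.row.names = FALSE))
  normalized <- do.call(rbind, c(norm_all, make.row.names = FALSE))

  ## paired per-ROI baseline-vs-post comparison per metric (included ROIs)
  tests <- list()
  for (m in unique(normalized$metric)) {
    d <- normalized[normalized$metric == m & normalized$include, ]
    ok <- is.finite(d$baseline_mean) & is.finite(d$post_mean)
    if (sum(ok) >= 2L)
      tests[[m]] <- ttest(d$post_mean[ok], d$baseline_mean[ok], paired = TRUE,
                          labels = c("post", "baseline"))
  }
  digest <- if (length(tests)) assemble_report(tests) else NULL

  write_table_prov(events, file.path(config$out_dir, "events.csv"), sep = ",",
                   seed = config$seed, config_hash = hash)
  write_table_prov(metrics, file.path(config$out_dir, "metrics.csv"),
                   sep = ",", seed = config$seed, config_hash = hash)
  write_table_prov(normalized, file.path(config$out_dir, "normalized.csv"),
                   sep = ",", seed = config$seed, config_hash = hash)
  if (!is.null(digest)) {
    write_table_prov(digest, file.path(config$out_dir, "digest.csv"),
                     sep = ",", seed = config$seed, config_hash = hash)
    jsonlite::write_json(digest, file.path(config$out_dir, "digest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(events = events, metrics = metrics, normalized = normalized,
                 digest = digest))
}

#' Run the simulation pipeline
#'
#' Thin wrapper around [simulate_study()] driven by a [run_config()].
#'
#' @param config a [run_config()] with `pipeline = "simulate"`.
#' @return see [simulate_study()].
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  simulate_study(profiles = config$profiles, out_dir = config$out_dir,
                 seed = config$seed, trace_profiles = config$trace_profiles,
                 write_movies = config$write_movies)
}

#' Plot a baseline-normalised time course
#'
#' Group mean +/- SEM per time bin with the baseline level marked at
#' 100%. Requires ggplot2.
#'
#' @param timecourse output of [build_timecourse()] (possibly several
#'   groups row-bound).
#' @return a ggplot object.
#' @export
plot_timecourse <- function(timecourse) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_config("ggplot2 is required for plotting")
  tc <- timecourse
  tc$bin <- factor(tc$bin, levels = unique(tc$bin))
  tc$ymin <- tc$mean_percent - tc$sem_percent
  tc$ymax <- tc$mean_percent + tc$sem_percent
  ggplot2::ggplot(tc, ggplot2::aes_string(x = "bin", y = "mean_percent",
                                          group = "group", colour = "group")) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes_string(ymin = "ymin", ymax = "ymax")) +
    ggplot2::labs(x = "time after injection (min)",
                  y = "normalised rate (% of baseline)")
}
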
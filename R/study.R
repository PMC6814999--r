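## Whole-study simulation: populations of units per condition, written
## out as the pipeline's input bundle (spike tables, metadata, optional
## trace tables and movies, JSON manifest), fully reproducible from the
## master seed.

#' Simulate a population of units under one profile
#'
#' Draws `profile$n_units` spike trains with per-unit seeds derived
#' deterministically from `seed`.
#'
#' @param profile a [sim_profile()].
#' @param seed master seed for this population.
#' @return list with `trains` (list of [spike_train()]), `truths` (list of
#'   ground-truth lists) and `unit_seeds`.
#' @export
simulate_population <- function(profile, seed = profile$seed) {
  stopifnot(inherits(profile, "sim_profile"))
  unit_seeds <- derive_seeds(seed, profile$n_units)
  sims <- lapply(seq_len(profile$n_units), function(i)
    simulate_spike_train(profile, unit_seed = unit_seeds[i],
                         unit_id = sprintf("%s_u%03d", profile$label, i)))
  list(trains = lapply(sims, `[[`, "train"),
       truths = lapply(sims, `[[`, "truth"),
       unit_seeds = unit_seeds)
}

#' Simulate a full study and write its input bundle
#'
#' For each named profile, simulates the unit population and writes a
#' tab-delimited spike table plus a metadata sidecar into
#' `out_dir/<label>/`. Profiles listed in `trace_profiles` additionally
#' get a fluorescence trace table (forward-modelled with `kernel`), and
#' `write_movies = TRUE` renders a small synthetic movie (plus ROI masks)
#' for the first up-to-3 traced units. A JSON manifest records the seed,
#' profile parameters, per-unit seeds and ground-truth summaries; outputs
#' are byte-identical when re-run with the same configuration and seed.
#'
#' @param profiles named list of [sim_profile()] objects, or a character
#'   vector of [study_profiles()] names.
#' @param out_dir output directory (created).
#' @param seed master seed.
#' @param trace_profiles labels of profiles for which trace tables are
#'   written.
#' @param kernel a [kernel_params()] for trace forward-modelling.
#' @param write_movies render movies for traced profiles?
#' @return invisibly, a list with `manifest` and the in-memory
#'   `populations` (per condition: trains + truths).
#' @export
simulate_study <- function(profiles = c("control", "nrg1"),
                           out_dir, seed = 1L,
                           trace_profiles = character(0),
                           kernel = kernel_params(),
                           write_movies = FALSE) {
  if (is.character(profiles)) {
    known <- study_profiles()
    bad <- setdiff(profiles, names(known))
    if (length(bad))
      stop_config(sprintf("unknown profile label(s): %s",
                          paste(bad, collapse = ", ")))
    profiles <- known[profiles]
  }
  assert_that(length(profiles) >= 1L, "at least one profile required")
  assert_that(!is.null(names(profiles)) && all(nzchar(names(profiles))),
              "profiles must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_desc <- list(profiles = lapply(profiles, unclass), seed = seed,
                   trace_profiles = trace_profiles)
  cfg_hash <- object_hash(cfg_desc)
  cond_seeds <- derive_seeds(seed, length(profiles))

  conditions <- list()
  populations <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    label <- names(profiles)[i]
    cdir <- file.path(out_dir, label)
    dir.create(cdir, showWarnings = FALSE)
    pop <- simulate_population(p, seed = cond_seeds[i])
    populations[[label]] <- pop

    spike_path <- file.path(cdir, "spikes.tsv")
    write_spike_table(pop$trains, spike_path, seed = cond_seeds[i],
                      config_hash = cfg_hash)
    meta <- data.frame(
      unit_id = vapply(pop$trains, `[[`, "", "unit_id"),
      group = label,
      injection_time_s = vapply(pop$trains, function(tr)
        tr$injection_time %||% NA_real_, 1),
      span_start_s = vapply(pop$trains, function(tr) tr$recording_span[1], 1),
      span_end_s = vapply(pop$trains, function(tr) tr$recording_span[2], 1))
    meta_path <- file.path(cdir, "metadata.tsv")
    write_table_prov(meta, meta_path, sep = "\t", seed = cond_seeds[i],
                     config_hash = cfg_hash)

    ## manifest paths are relative to out_dir so bundles are relocatable
    ## and byte-identical across runs in different directories
    cond <- list(label = label, spike_table = file.path(label, "spikes.tsv"),
                 metadata = file.path(label, "metadata.tsv"),
                 unit_seeds = pop$unit_seeds,
                 units = data.frame(
                   unit_id = meta$unit_id,
                   n_spikes = vapply(pop$trains, function(tr)
                     length(tr$spike_times), 1L),
                   n_true_bursts = vapply(pop$truths, function(tt)
                     nrow(tt$burst_windows), 1L),
                   true_single_rate_pre = vapply(pop$truths, function(tt)
                     tt$true_rates$single_rate[1], 1)))

    if (label %in% trace_profiles) {
      trace_seeds <- derive_seeds(cond_seeds[i] + 1L, p$n_units)
      fl <- lapply(seq_along(pop$trains), function(k)
        simulate_fluorescence(pop$trains[[k]], pop$truths[[k]], kernel,
                              seed = trace_seeds[k]))
      traces <- lapply(fl, function(z) z$trace)
      populations[[label]]$truths <- lapply(fl, `[[`, "truth")
      populations[[label]]$traces <- traces
      trace_path <- file.path(cdir, "traces.csv")
      write_trace_table(traces, trace_path, seed = cond_seeds[i],
                        config_hash = cfg_hash)
      cond$trace_table <- file.path(label, "traces.csv")
      if (write_movies) {
        nmov <- min(3L, length(traces))
        centers <- cbind(16 + 16 * (seq_len(nmov) - 1L), 16)
        layout <- movie_layout(width = 16 + 16 * nmov, height = 32L,
                               centers = centers, radii = 4)
        ## render dF/F-scaled brightness so blobs stay near unit scale
        scaled <- lapply(traces[seq_len(nmov)], function(tr)
          fluor_trace(tr$roi_id, tr$frame_times,
                      tr$raw_f / kernel$baseline_f0))
        mov <- simulate_movie(scaled, layout, seed = cond_seeds[i] + 2L)
        mask_paths <- file.path(cdir, sprintf("mask_%02d.tif", seq_len(nmov)))
        write_movie_tiff(mov, file.path(cdir, "movie.tif"), mask_paths)
        cond$movie <- file.path(label, "movie.tif")
        cond$masks <- file.path(label, basename(mask_paths))
      }
    }
    conditions[[label]] <- cond
  }

  manifest <- list(seed = seed, config_hash = cfg_hash,
                   profiles = lapply(profiles, unclass),
                   conditions = lapply(conditions, function(cd)
                     cd[setdiff(names(cd), "units_full")]))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(manifest = manifest, populations = populations))
}
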
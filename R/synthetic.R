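## Synthetic-data generators: spike trains with known burst windows,
## fluorescence traces built from a calcium-indicator kernel, and (in
## movie.R) rendered image stacks. Every generator returns ground truth
## alongside the data so downstream detectors can be scored.

#' Simulation profile for one experimental condition
#'
#' Describes the firing statistics of a population of units under one
#' condition: a homogeneous-Poisson single-spike process superposed with a
#' Poisson process of tight bursts, and an optional multiplicative drug
#' effect applied after an injection time.
#'
#' @param label condition name, e.g. `"control"` or `"nrg1"`.
#' @param single_rate mean single-spike rate (Hz) of the population.
#' @param burst_rate burst occurrence rate (bursts/s).
#' @param burst_size_mean mean spikes per burst; sizes are drawn as
#'   `3 + Poisson(burst_size_mean - 3)` so every burst has at least 3
#'   spikes and satisfies the burst detector's count rule by construction.
#' @param intra_burst_isi spacing of spikes within a burst (s); must be
#'   below 0.015 s so generated bursts satisfy the detector's ISI rule.
#' @param drug_effect multiplicative rate factor applied after
#'   `injection_time`. Either a single number (applied to both processes),
#'   or a list with elements `single` and/or `burst`; `single` may itself
#'   be a named vector `c(fast = ..., regular = ...)` applied according to
#'   whether the unit's baseline mean rate exceeds 10 Hz.
#' @param injection_time injection time (s), or `NA` for no injection.
#' @param n_units number of units to simulate for this condition.
#' @param duration recording duration (s).
#' @param rate_cv coefficient of variation of per-unit single-spike rates
#'   (lognormal across units); 0 gives identical units.
#' @param drug_onset_ramp linear onset ramp of the drug effect (s);
#'   default 0 (step change at injection).
#' @param seed default RNG seed for this profile.
#' @return an object of class `sim_profile`.
#' @export
#' @examples
#' sim_profile("control", single_rate = 7.7, burst_rate = 0.1)
sim_profile <- function(label,
                        single_rate = 7.7,
                        burst_rate = 0.1,
                        burst_size_mean = 3,
                        intra_burst_isi = 0.010,
                        drug_effect = 1,
                        injection_time = NA_real_,
                        n_units = 80L,
                        duration = 600,
                        rate_cv = 0.25,
                        drug_onset_ramp = 0,
                        seed = 1L) {
  assert_that(single_rate >= 0 && burst_rate >= 0, "rates must be non-negative")
  assert_that(duration > 0, "duration must be positive")
  assert_that(intra_burst_isi > 0 && intra_burst_isi < 0.015,
              "intra_burst_isi must lie in (0, 0.015) s")
  assert_that(burst_size_mean >= 3, "burst_size_mean must be at least 3")
  assert_that(rate_cv >= 0, "rate_cv must be non-negative")
  structure(list(label = label, single_rate = single_rate,
                 burst_rate = burst_rate, burst_size_mean = burst_size_mean,
                 intra_burst_isi = intra_burst_isi, drug_effect = drug_effect,
                 injection_time = injection_time, n_units = as.integer(n_units),
                 duration = duration, rate_cv = rate_cv,
                 drug_onset_ramp = drug_onset_ramp, seed = as.integer(seed)),
            class = "sim_profile")
}

#' Study condition profiles
#'
#' The built-in conditions used by [simulate_study()]: an antibody control
#' population at a mean rate of 8 Hz, a schizophrenia-like population at
#' 20 Hz, an NMDAR-antagonist condition with bidirectional modulation
#' (single-spike rate reduced in fast-spiking units, increased ~26% in
#' regular-spiking units, burst generation suppressed), and null-drug
#' conditions with no post-injection change.
#'
#' The control and model mean rates (8 vs 20 Hz) and the 26% regular-
#' spiking increase are the headline group values the generator is
#' parameterised to; burst parameters contribute ~0.3 Hz so the
#' single-spike rate is set to make the total mean rate hit the target.
#'
#' @param injection_time injection time (s) for the drug conditions.
#' @param duration recording duration (s).
#' @return named list of [sim_profile()] objects.
#' @export
study_profiles <- function(injection_time = 600, duration = 4200) {
  base_single <- 8 - 0.1 * 3.0    # total mean rate 8 Hz incl. burst spikes
  nrg1_single <- 20 - 0.1 * 3.0   # total mean rate 20 Hz
  list(
    control = sim_profile("control", single_rate = base_single,
                          n_units = 88L, duration = duration),
    nrg1 = sim_profile("nrg1", single_rate = nrg1_single,
                       n_units = 78L, duration = duration),
    saline = sim_profile("saline", single_rate = base_single, n_units = 96L,
                         injection_time = injection_time, duration = duration,
                         rate_cv = 0.6),
    mk801 = sim_profile("mk801", single_rate = base_single, n_units = 71L,
                        injection_time = injection_time, duration = duration,
                        rate_cv = 0.6,
                        drug_effect = list(single = c(fast = 0.6, regular = 1.26),
                                           burst = 0.5)),
    dcs = sim_profile("dcs", single_rate = nrg1_single, n_units = 78L,
                      injection_time = injection_time, duration = duration),
    sarcosine = sim_profile("sarcosine", single_rate = nrg1_single,
                            n_units = 78L, injection_time = injection_time,
                            duration = duration)
  )
}

#' Imaging condition profiles and kernel
#'
#' Conditions for the two-photon arm, where discrete calcium events are
#' sparse: events are dominated by bursts at ~2 per minute in controls
#' and ~2.6 per minute in the schizophrenia-like condition, with isolated
#' single spikes contributing only sub-threshold fluorescence. The
#' NMDAR-antagonist condition suppresses burst generation to 20% after
#' injection; event amplitude suppression is applied at the fluorescence
#' stage (see `amp_scale_post` in [simulate_fluorescence()]).
#'
#' @param injection_time injection time (s) for the drug conditions.
#' @param duration recording duration (s).
#' @return named list of [sim_profile()] objects.
#' @export
imaging_profiles <- function(injection_time = 600, duration = 1800) {
  list(
    control = sim_profile("control", single_rate = 0.3,
                          burst_rate = 2.06 / 60, n_units = 113L,
                          duration = duration),
    nrg1 = sim_profile("nrg1", single_rate = 0.3, burst_rate = 2.55 / 60,
                       n_units = 116L, duration = duration),
    mk801 = sim_profile("mk801", single_rate = 0.3, burst_rate = 2.06 / 60,
                        n_units = 84L, duration = duration,
                        injection_time = injection_time,
                        drug_effect = list(single = 1, burst = 0.2)),
    null_drug = sim_profile("null_drug", single_rate = 0.3,
                            burst_rate = 2.06 / 60, n_units = 80L,
                            duration = duration,
                            injection_time = injection_time)
  )
}

#' @rdname imaging_profiles
#' @param amp_per_burst peak dF/F of a burst transient (control-level
#'   default 1.55).
#' @export
imaging_kernel <- function(amp_per_burst = 1.55) {
  kernel_params(amp_per_burst = amp_per_burst, amp_per_single = 0.02,
                baseline_f0 = 100, noise_sd = 1, drift_amp = 2)
}

## expected spikes per burst given the 3 + Poisson(mean - 3) draw
expected_burst_size <- function(profile) 3 + max(0, profile$burst_size_mean - 3)

## per-unit drug factors; classification of the unit uses its (known)
## generator baseline mean rate against the 10 Hz fast-spiking cutoff
resolve_drug_factors <- function(profile, unit_single_rate) {
  de <- profile$drug_effect
  base_mean <- unit_single_rate + profile$burst_rate * expected_burst_size(profile)
  pick <- function(x) {
    if (length(x) == 1L && is.null(names(x))) return(as.numeric(x))
    cls <- if (base_mean > 10) "fast" else "regular"
    assert_that(cls %in% names(x), "per-class drug_effect needs 'fast' and 'regular'")
    as.numeric(x[[cls]])
  }
  if (!is.list(de)) {
    f <- pick(de)
    return(list(single = f, burst = f))
  }
  list(single = if (is.null(de$single)) 1 else pick(de$single),
       burst  = if (is.null(de$burst)) 1 else pick(de$burst))
}

#' Sorted spike train for one unit
#'
#' @param unit_id unit identifier.
#' @param spike_times strictly increasing spike times (s).
#' @param recording_span numeric length-2, recording start/end (s).
#' @param injection_time injection time (s) or `NA`.
#' @param group_label condition label.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, recording_span,
                        injection_time = NA_real_, group_label = NA_character_) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0))
    stop_data("spike times must be strictly increasing")
  assert_that(length(recording_span) == 2L && recording_span[2] > recording_span[1],
              "recording_span must be (start, end) with end > start")
  if (length(spike_times) &&
      (min(spike_times) < recording_span[1] || max(spike_times) > recording_span[2]))
    stop_data("spike times outside recording_span")
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 recording_span = as.numeric(recording_span),
                 injection_time = injection_time, group_label = group_label),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes over [%g, %g] s",
              x$unit_id, length(x$spike_times),
              x$recording_span[1], x$recording_span[2]))
  if (is.finite(x$injection_time %||% NA))
    cat(sprintf(", injection at %g s", x$injection_time))
  cat("\n")
  invisible(x)
}

## guard gap between generated bursts; > the 100 ms inter-burst criterion
## so detected and generated bursts can never merge
.burst_guard_gap <- 0.110
## keep-out margin around burst windows for single spikes (> 15 ms ISI rule)
.single_margin <- 0.016

#' Simulate one unit's spike train with ground-truth bursts
#'
#' Homogeneous-Poisson single spikes superposed with Poisson-occurring
#' bursts of regularly spaced spikes. After `injection_time` both process
#' rates are scaled by the profile's drug factors. Generated bursts are
#' separated by more than 110 ms and single spikes are kept at least 16 ms
#' away from burst windows, so the three-rule burst detector recovers the
#' ground-truth windows by construction.
#'
#' @param profile a [sim_profile()].
#' @param unit_seed RNG seed for this unit.
#' @param unit_id identifier stored in the returned train.
#' @return list with elements `train` (a [spike_train()]) and `truth`
#'   (list: `burst_windows` data frame with columns start/end/n_spikes,
#'   `single_times`, `true_rates` per segment).
#' @export
#' @examples
#' p <- sim_profile("demo", single_rate = 5, burst_rate = 0.05, duration = 60)
#' sim <- simulate_spike_train(p, unit_seed = 7)
#' length(sim$train$spike_times)
#' nrow(sim$truth$burst_windows)
simulate_spike_train <- function(profile, unit_seed = profile$seed,
                                 unit_id = paste0(profile$label, "_u1")) {
  stopifnot(inherits(profile, "sim_profile"))
  set.seed(as.integer(unit_seed))
  dur <- profile$duration
  inj <- profile$injection_time
  has_inj <- is.finite(inj %||% NA) && inj > 0 && inj < dur

  ## per-unit rate heterogeneity (lognormal, mean preserved)
  us <- profile$single_rate
  if (profile$rate_cv > 0 && us > 0) {
    s2 <- log(1 + profile$rate_cv^2)
    us <- stats::rlnorm(1, meanlog = log(us) - s2 / 2, sdlog = sqrt(s2))
  }
  eff <- if (has_inj) resolve_drug_factors(profile, us) else list(single = 1, burst = 1)
  t_split <- if (has_inj) inj else dur

  singles <- c(rpois_times(us, 0, t_split),
               if (has_inj) rpois_times(us * eff$single, t_split, dur))
  onsets <- c(rpois_times(profile$burst_rate, 0, t_split),
              if (has_inj) rpois_times(profile$burst_rate * eff$burst, t_split, dur))

  ## draw sizes, lay out windows, enforce the inter-burst guard gap
  windows <- data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0))
  burst_spikes <- numeric(0)
  if (length(onsets)) {
    sizes <- 3L + stats::rpois(length(onsets), max(0, profile$burst_size_mean - 3))
    ends <- onsets + (sizes - 1L) * profile$intra_burst_isi
    ok <- ends <= dur
    onsets <- onsets[ok]; sizes <- sizes[ok]; ends <- ends[ok]
    keep <- logical(length(onsets))
    last_end <- -Inf
    for (i in seq_along(onsets)) {
      if (onsets[i] > last_end + .burst_guard_gap) {
        keep[i] <- TRUE
        last_end <- ends[i]
      }
    }
    onsets <- onsets[keep]; sizes <- sizes[keep]; ends <- ends[keep]
    if (length(onsets)) {
      burst_spikes <- unlist(lapply(seq_along(onsets), function(i)
        onsets[i] + (seq_len(sizes[i]) - 1L) * profile$intra_burst_isi))
      windows <- data.frame(start = onsets, end = ends, n_spikes = sizes)
    }
  }

  ## keep single spikes clear of burst windows so ground truth matches
  ## what the three-rule detector can see
  if (length(singles) && nrow(windows)) {
    edges <- as.vector(rbind(windows$start - .single_margin,
                             windows$end + .single_margin))
    inside <- findInterval(singles, edges) %% 2L == 1L
    singles <- singles[!inside]
  }

  spikes <- sort(unique(c(singles, burst_spikes)))
  rates <- data.frame(
    segment = if (has_inj) c("pre", "post") else "pre",
    t0 = if (has_inj) c(0, inj) else 0,
    t1 = if (has_inj) c(inj, dur) else dur,
    single_rate = if (has_inj) c(us, us * eff$single) else us,
    burst_rate = if (has_inj) profile$burst_rate * c(1, eff$burst) else profile$burst_rate)

  list(train = spike_train(unit_id, spikes, c(0, dur),
                           injection_time = if (has_inj) inj else NA_real_,
                           group_label = profile$label),
       truth = list(burst_windows = windows, single_times = singles,
                    true_rates = rates))
}

#' Calcium-indicator kernel and trace-noise parameters
#'
#' Double-exponential transient shape (difference of decay and rise
#' exponentials, normalised to unit peak) with slow GCaMP6s-like kinetics,
#' plus baseline fluorescence, white noise, and a slow sinusoidal drift
#' that stresses baseline estimation without mimicking events.
#'
#' @param rise_tau rise time constant (s).
#' @param decay_tau decay time constant (s); must exceed `rise_tau`.
#' @param amp_per_burst peak dF/F contributed by one burst.
#' @param amp_per_single peak dF/F contributed by an isolated spike;
#'   default one tenth of the burst amplitude, reflecting that slow
#'   indicators report bursts far more strongly than single spikes.
#' @param baseline_f0 baseline fluorescence (arbitrary units).
#' @param noise_sd white-noise SD (fluorescence units).
#' @param drift_amp amplitude of the slow sinusoidal drift (fluorescence
#'   units).
#' @param drift_period drift period (s).
#' @param frame_interval frame interval (s); default 1.109 s (~0.9 Hz).
#' @return object of class `kernel_params`.
#' @export
kernel_params <- function(rise_tau = 0.2, decay_tau = 1.5,
                          amp_per_burst = 0.4,
                          amp_per_single = 0.1 * amp_per_burst,
                          baseline_f0 = 100, noise_sd = 1,
                          drift_amp = 0, drift_period = 300,
                          frame_interval = 1.109) {
  assert_that(is.finite(rise_tau) && is.finite(decay_tau) &&
                decay_tau > rise_tau && rise_tau > 0,
              "need decay_tau > rise_tau > 0")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(frame_interval > 0, "frame_interval must be positive")
  assert_that(baseline_f0 > 0, "baseline_f0 must be positive")
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 amp_per_burst = amp_per_burst, amp_per_single = amp_per_single,
                 baseline_f0 = baseline_f0, noise_sd = noise_sd,
                 drift_amp = drift_amp, drift_period = drift_period,
                 frame_interval = frame_interval),
            class = "kernel_params")
}

## normalised kernel evaluated at lags dt >= 0; peak value is exactly 1
## at dt = rise*decay/(decay-rise) * log(decay/rise)
kernel_shape <- function(dt, rise, decay) {
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  gmax <- exp(-tpk / decay) - exp(-tpk / rise)
  out <- numeric(length(dt))
  pos <- dt >= 0
  out[pos] <- (exp(-dt[pos] / decay) - exp(-dt[pos] / rise)) / gmax
  out
}

## time of the kernel peak after event onset
kernel_peak_lag <- function(kernel) {
  with(kernel, rise_tau * decay_tau / (decay_tau - rise_tau) *
         log(decay_tau / rise_tau))
}

#' Uniformly sampled ROI fluorescence trace
#'
#' @param roi_id ROI identifier.
#' @param frame_times frame times (s), strictly increasing and uniformly
#'   spaced to within 1e-6 s.
#' @param raw_f raw fluorescence per frame (arbitrary units).
#' @param background background fluorescence, scalar or per frame.
#' @param include logical; `FALSE` flags an ROI excluded from group
#'   summaries (e.g. nucleus-filled somata) while still being processed.
#' @return object of class `fluor_trace`.
#' @export
fluor_trace <- function(roi_id, frame_times, raw_f, background = 0,
                        include = TRUE) {
  assert_that(length(frame_times) == length(raw_f),
              "frame_times and raw_f lengths differ", kind = "data")
  if (length(frame_times) > 1L) {
    dts <- diff(frame_times)
    if (any(dts <= 0) || diff(range(dts)) > 1e-6)
      stop_data("frame_times must be strictly increasing and uniformly spaced")
  }
  if (!all(is.finite(raw_f))) stop_data("raw_f must be finite")
  assert_that(length(background) %in% c(1L, length(raw_f)),
              "background must be scalar or per-frame", kind = "data")
  structure(list(roi_id = roi_id, frame_times = as.numeric(frame_times),
                 raw_f = as.numeric(raw_f), background = as.numeric(background),
                 include = isTRUE(include)),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> ROI %s: %d frames, dt = %.3f s%s\n", x$roi_id,
              length(x$frame_times),
              if (length(x$frame_times) > 1) diff(x$frame_times[1:2]) else NA,
              if (x$include) "" else " [excluded]"))
  invisible(x)
}

#' Forward-model a fluorescence trace from a spike train
#'
#' Renders baseline + slow drift + one double-exponential transient per
#' event (bursts at `amp_per_burst`, isolated spikes at `amp_per_single`)
#' plus white noise, sampled at the kernel's frame interval. The returned
#' ground truth lists every transient whose noise-free peak exceeds
#' `3 * noise_sd / baseline_f0` in dF/F units.
#'
#' @param train a [spike_train()].
#' @param truth ground truth from [simulate_spike_train()].
#' @param kernel a [kernel_params()].
#' @param seed optional RNG seed for noise and drift phase.
#' @param amp_scale_post multiplicative scaling of transient amplitudes
#'   for events after the train's injection time (models drug suppression
#'   of calcium-response amplitude; default 1 = no change).
#' @return list with elements `trace` (a [fluor_trace()]) and `truth`
#'   (input truth plus `event_times`, `event_amps`).
#' @export
simulate_fluorescence <- function(train, truth, kernel = kernel_params(),
                                  seed = NULL, amp_scale_post = 1) {
  stopifnot(inherits(train, "spike_train"), inherits(kernel, "kernel_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  dur <- train$recording_span[2] - train$recording_span[1]
  fi <- kernel$frame_interval
  nframes <- floor(dur / fi) + 1L
  t <- train$recording_span[1] + (seq_len(nframes) - 1L) * fi

  w <- truth$burst_windows
  ev_t <- c(if (!is.null(w) && nrow(w)) w$start, truth$single_times)
  ev_a <- c(if (!is.null(w) && nrow(w)) rep(kernel$amp_per_burst, nrow(w)),
            rep(kernel$amp_per_single, length(truth$single_times)))
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_a <- ev_a[ord]
  inj <- train$injection_time
  if (amp_scale_post != 1 && is.finite(inj %||% NA))
    ev_a[ev_t >= inj] <- ev_a[ev_t >= inj] * amp_scale_post

  signal <- numeric(nframes)
  span <- 8 * kernel$decay_tau
  for (i in seq_along(ev_t)) {
    if (ev_a[i] == 0) next
    i0 <- max(1L, ceiling((ev_t[i] - t[1]) / fi) + 1L)
    i1 <- min(nframes, floor((ev_t[i] + span - t[1]) / fi) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    signal[idx] <- signal[idx] +
      ev_a[i] * kernel_shape(t[idx] - ev_t[i], kernel$rise_tau, kernel$decay_tau)
  }

  drift <- if (kernel$drift_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    kernel$drift_amp * sin(2 * pi * t / kernel$drift_period + phase)
  } else 0
  noise <- if (kernel$noise_sd > 0) stats::rnorm(nframes, 0, kernel$noise_sd) else 0
  raw <- kernel$baseline_f0 * (1 + signal) + drift + noise

  thr <- 3 * kernel$noise_sd / kernel$baseline_f0
  vis <- ev_a > thr
  truth$event_times <- ev_t[vis]
  truth$event_amps <- ev_a[vis]
  list(trace = fluor_trace(train$unit_id, t, raw, background = 0),
       truth = truth)
}
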
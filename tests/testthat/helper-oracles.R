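## Independent oracles used across the suite. These deliberately take the
## slow, exhaustive route so they share no code path with the package.

## Brute-force burst oracle: tests every contiguous spike subsequence
## against the three criteria (all ISIs below max_isi, count >= min_spikes,
## not extendable in either direction), then merges windows whose gap is
## within min_gap, counting all spikes inside the merged window.
oracle_bursts <- function(st, max_isi = 0.015, min_spikes = 3L,
                          min_gap = 0.100) {
  n <- length(st)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  if (n < min_spikes) return(empty)
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < min_spikes) next
      if (any(diff(st[i:j]) >= max_isi)) next
      left_max <- i == 1L || st[i] - st[i - 1L] >= max_isi
      right_max <- j == n || st[j + 1L] - st[j] >= max_isi
      if (left_max && right_max)
        wins[[length(wins) + 1L]] <- c(st[i], st[j])
    }
  }
  if (!length(wins)) return(empty)
  w <- do.call(rbind, wins)
  w <- w[order(w[, 1]), , drop = FALSE]
  merged <- list(w[1, ])
  for (k in seq_len(nrow(w))[-1]) {
    last <- merged[[length(merged)]]
    if (w[k, 1] - last[2] <= min_gap) {
      merged[[length(merged)]] <- c(last[1], w[k, 2])
    } else {
      merged[[length(merged) + 1L]] <- w[k, ]
    }
  }
  m <- do.call(rbind, merged)
  data.frame(start = m[, 1], end = m[, 2],
             n_spikes = vapply(seq_len(nrow(m)), function(k)
               as.integer(sum(st >= m[k, 1] & st <= m[k, 2])), 0L))
}

## random spike set stressing the criteria boundaries: ISIs drawn from a
## pool that includes values exactly at 15 ms and 100 ms
random_spike_set <- function(n) {
  if (n == 0L) return(numeric(0))
  pool <- c(0.003, 0.008, 0.010, 0.0149, 0.015, 0.0151, 0.02, 0.05,
            0.099, 0.100, 0.101, 0.2, 0.5)
  isis <- c(stats::runif(1, 0, 0.05),
            sample(pool, n - 1L, replace = TRUE) * stats::runif(n - 1L, 0.999, 1.001))
  cumsum(isis)
}

## Per-frame labeling oracle for event detection: walks the trace frame by
## frame, opening an event on the first supra-threshold frame and closing
## it on the first frame at or below threshold.
oracle_events <- function(d, k_sd = 3) {
  thr <- d$noise_mean + k_sd * d$noise_sd
  onsets <- offsets <- amps <- numeric(0)
  open <- FALSE
  for (i in seq_along(d$dff)) {
    if (d$dff[i] > thr) {
      if (!open) {
        open <- TRUE
        onsets <- c(onsets, d$frame_times[i])
        amps <- c(amps, d$dff[i])
      } else {
        amps[length(amps)] <- max(amps[length(amps)], d$dff[i])
      }
      offsets[length(onsets)] <- d$frame_times[i]
    } else {
      open <- FALSE
    }
  }
  data.frame(onset_time = onsets, offset_time = offsets, amplitude = amps)
}

## Calibration fixture: transients at the study's spontaneous event
## frequency (~2 per minute) with peaks drawn uniformly between 5 and 10
## baseline-noise SDs, slow-indicator kinetics, 1.109 s frames, white
## noise.
make_calibration_trace <- function(seed, duration = 600, mean_gap = 30) {
  set.seed(seed)
  onsets <- c()
  t <- 10
  while (TRUE) {
    t <- t + stats::runif(1, mean_gap - 3, mean_gap + 3)
    if (t > duration - 20) break
    onsets <- c(onsets, t)
  }
  ## amplitude floor at 5 noise SDs (the hard case for the detector);
  ## real transients in this preparation run far larger
  noise_dff <- 0.01  # noise_sd / baseline_f0
  amps <- stats::runif(length(onsets), 5, 20) * noise_dff
  kernel <- kernel_params(rise_tau = 0.2, decay_tau = 2.0,
                          amp_per_burst = 1, amp_per_single = 0,
                          baseline_f0 = 100, noise_sd = 1, drift_amp = 0)
  ## render transients with per-event amplitudes by summing kernels
  nframes <- floor(duration / kernel$frame_interval) + 1L
  tt <- (seq_len(nframes) - 1L) * kernel$frame_interval
  signal <- numeric(nframes)
  for (k in seq_along(onsets)) {
    dt <- tt - onsets[k]
    pos <- dt >= 0 & dt < 8 * kernel$decay_tau
    signal[pos] <- signal[pos] +
      amps[k] * caburst:::kernel_shape(dt[pos], kernel$rise_tau, kernel$decay_tau)
  }
  raw <- kernel$baseline_f0 * (1 + signal) + stats::rnorm(nframes, 0, kernel$noise_sd)
  list(trace = fluor_trace(paste0("cal", seed), tt, raw),
       onsets = onsets, amps = amps,
       frame_interval = kernel$frame_interval)
}

## greedy one-to-one onset matching within a tolerance; returns counts
match_onsets <- function(true_onsets, det_onsets, tol) {
  used <- rep(FALSE, length(det_onsets))
  tp <- 0L
  for (o in true_onsets) {
    d <- abs(det_onsets - o)
    d[used] <- Inf
    ## detected onsets trail true onsets; allow the tolerance both ways
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fn = length(true_onsets) - tp,
       fp = sum(!used))
}
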
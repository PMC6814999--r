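## Imaging analysis: ROI extraction, dF/F conversion, threshold-crossing
## event detection, and per-minute activity metrics.

#' Extract per-ROI fluorescence traces from a movie stack
#'
#' Per frame, the ROI signal is the mean pixel value inside the mask. The
#' background is the mean over a designated background mask when given,
#' otherwise the per-frame `percentile` pixel value of the whole frame.
#' Background subtraction itself is deferred to [compute_dff()].
#'
#' @param stack height x width x frames numeric array.
#' @param masks list of logical matrices (one per ROI) matching the frame
#'   size.
#' @param frame_times frame times (s); default uses a 1.109 s interval.
#' @param background_mask optional logical matrix marking a background
#'   region.
#' @param percentile background percentile when no mask is given.
#' @param roi_ids ROI identifiers.
#' @return list of [fluor_trace()] objects.
#' @export
extract_roi_traces <- function(stack, masks, frame_times = NULL,
                               background_mask = NULL, percentile = 0.1,
                               roi_ids = paste0("roi", seq_along(masks))) {
  d <- dim(stack)
  assert_that(length(d) == 3L, "stack must be a 3-d array", kind = "data")
  assert_that(length(masks) >= 1L, "at least one ROI mask required", kind = "data")
  frame_times <- frame_times %||% ((seq_len(d[3]) - 1L) * 1.109)
  assert_that(length(frame_times) == d[3], "frame_times/stack mismatch", kind = "data")
  for (m in masks) {
    if (!identical(dim(m), d[1:2])) stop_data("mask/stack shape mismatch")
    if (!any(m)) stop_data("empty ROI mask")
  }
  if (!is.null(background_mask) && !identical(dim(background_mask), d[1:2]))
    stop_data("background mask/stack shape mismatch")

  flat <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  bg <- if (!is.null(background_mask)) {
    colMeans(flat[as.vector(background_mask), , drop = FALSE])
  } else {
    apply(flat, 2L, stats::quantile, probs = percentile, names = FALSE)
  }
  lapply(seq_along(masks), function(k) {
    raw <- colMeans(flat[as.vector(masks[[k]]), , drop = FALSE])
    fluor_trace(roi_ids[k], frame_times, raw, background = bg)
  })
}

#' dF/F trace with baseline and noise estimates
#'
#' @param roi_id ROI identifier.
#' @param frame_times frame times (s).
#' @param dff fractional fluorescence change per frame.
#' @param f0 baseline fluorescence (must be positive).
#' @param noise_sd baseline noise SD in dF/F units.
#' @param noise_mean baseline mean level in dF/F units (non-zero when F0
#'   is taken from the low tail of the baseline distribution).
#' @param baseline_window (start, end) seconds used for the baseline.
#' @param include logical inclusion flag carried from the raw trace.
#' @return object of class `dff_trace`.
#' @export
dff_trace <- function(roi_id, frame_times, dff, f0, noise_sd,
                      noise_mean = 0, baseline_window = range(frame_times),
                      include = TRUE) {
  assert_that(f0 > 0, "f0 must be positive", kind = "data")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative", kind = "data")
  if (!all(is.finite(dff))) stop_data("dff must be finite")
  structure(list(roi_id = roi_id, frame_times = as.numeric(frame_times),
                 dff = as.numeric(dff), f0 = f0, noise_sd = noise_sd,
                 noise_mean = noise_mean,
                 baseline_window = as.numeric(baseline_window),
                 include = isTRUE(include)),
            class = "dff_trace")
}

#' Convert a fluorescence trace to dF/F
#'
#' Computes `F = raw_f - background`, takes F0 as the mean of the lowest
#' `min_fraction` of F values within the baseline window (reading
#' "mean of minimum fluorescence" as a low-tail mean, since a single
#' minimum is noise-dominated), and returns `dff = (F - F0) / F0`.
#'
#' The baseline noise level is estimated on baseline frames robustly:
#' frames more than 3 SDs above the baseline mean are excluded as likely
#' events and the mean/SD re-estimated, iterating until the kept set is
#' stable; `noise_mean` and `noise_sd` are the mean and SD of the final
#' kept frames, in dF/F units.
#'
#' @param trace a [fluor_trace()].
#' @param baseline_window (start, end) seconds; default the whole trace.
#' @param min_fraction fraction of lowest baseline frames averaged for F0.
#' @return a [dff_trace()].
#' @export
#' @examples
#' tr <- fluor_trace("r1", (0:99) * 1.109, rep(100, 100))
#' d <- compute_dff(tr)
#' d$f0        # 100
#' range(d$dff)  # all zero
compute_dff <- function(trace, baseline_window = NULL, min_fraction = 0.1) {
  stopifnot(inherits(trace, "fluor_trace"))
  assert_that(min_fraction > 0 && min_fraction <= 1,
              "min_fraction must be in (0, 1]")
  t <- trace$frame_times
  baseline_window <- baseline_window %||% range(t)
  assert_that(baseline_window[1] >= t[1] - 1e-9 &&
                baseline_window[2] <= t[length(t)] + 1e-9,
              "baseline_window must lie inside the recording")
  f <- trace$raw_f - trace$background
  base_idx <- which(t >= baseline_window[1] & t <= baseline_window[2])
  if (length(base_idx) < 10L) stop_data("baseline shorter than 10 frames")

  fb <- f[base_idx]
  k <- max(1L, ceiling(min_fraction * length(fb)))
  f0 <- mean(sort(fb)[seq_len(k)])
  if (f0 <= 0) stop_data("degenerate baseline: F0 <= 0")
  dff <- (f - f0) / f0

  ## noise level from baseline frames, excluding likely-event frames.
  ## The exclusion pass (> centre + 3 scale) is seeded with median/MAD --
  ## a mean/SD start stalls at a contaminated fixed point when transients
  ## occupy an appreciable fraction of the baseline window -- and then
  ## iterated with the classical mean/SD until the kept set is stable.
  db <- dff[base_idx]
  m <- stats::median(db)
  s <- stats::mad(db)
  keep_prev <- rep(NA, length(db))
  for (it in 1:20) {
    if (!is.finite(s) || s == 0) {
      keep <- rep(TRUE, length(db))
      break
    }
    keep <- db <= m + 3 * s
    if (identical(keep, keep_prev)) break
    keep_prev <- keep
    m <- mean(db[keep])
    s <- stats::sd(db[keep])
  }
  noise_mean <- mean(db[keep])
  noise_sd <- stats::sd(db[keep])
  if (!is.finite(noise_sd)) noise_sd <- 0

  dff_trace(trace$roi_id, t, dff, f0, noise_sd, noise_mean,
            baseline_window, include = trace$include)
}

#' Detect calcium events by a noise-scaled threshold
#'
#' Events are maximal contiguous runs of frames whose dF/F exceeds the
#' baseline level by more than `k_sd` baseline noise SDs, i.e.
#' `dff > noise_mean + k_sd * noise_sd`. Per event the onset/offset are
#' the first/last supra-threshold frame times, the amplitude is the
#' maximum dF/F in the run, and the area is the trapezoidal integral of
#' dF/F over the run (a single-frame run contributes `dff * dt`).
#'
#' @param dff a [dff_trace()].
#' @param k_sd threshold in baseline-noise SDs (default 3).
#' @return data frame with columns `roi_id`, `onset_time`, `peak_time`,
#'   `offset_time`, `amplitude`, `area`; attribute `"threshold"` carries
#'   the absolute dF/F threshold used.
#' @export
detect_events <- function(dff, k_sd = 3) {
  stopifnot(inherits(dff, "dff_trace"))
  assert_that(k_sd > 0, "k_sd must be positive")
  x <- dff$dff
  ## a zero noise SD is only coherent when the baseline segment really is
  ## constant (e.g. clean synthetic traces); otherwise the threshold is
  ## meaningless
  bw <- dff$frame_times >= dff$baseline_window[1] &
    dff$frame_times <= dff$baseline_window[2]
  if (dff$noise_sd == 0 && sum(bw) > 1L && diff(range(x[bw])) > 0)
    stop_data("degenerate noise estimate: noise_sd = 0 on a non-constant baseline")
  thr <- dff$noise_mean + k_sd * dff$noise_sd

  empty <- data.frame(roi_id = character(0), onset_time = numeric(0),
                      peak_time = numeric(0), offset_time = numeric(0),
                      amplitude = numeric(0), area = numeric(0))
  above <- x > thr
  if (!any(above)) return(structure(empty, threshold = thr))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  t <- dff$frame_times
  fi <- if (length(t) > 1L) t[2] - t[1] else NA_real_
  out <- lapply(runs, function(j) {
    idx <- starts[j]:ends[j]
    pk <- idx[which.max(x[idx])]
    area <- if (length(idx) >= 2L) trapz(t[idx], x[idx]) else x[idx] * fi
    data.frame(roi_id = dff$roi_id, onset_time = t[idx[1]],
               peak_time = t[pk], offset_time = t[idx[length(idx)]],
               amplitude = max(x[idx]), area = area)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Per-minute activity metrics over tiling windows
#'
#' Windows of length `window_s` tile the recording from its first frame;
#' a partial terminal window is dropped. Events are assigned to windows
#' by onset time (half-open `[start, end)`); boundary-straddling area
#' counts wholly in the onset window. Frequency and total activity are
#' scaled to per-minute using exact window length.
#'
#' @param events event table from [detect_events()].
#' @param dff the [dff_trace()] the events came from.
#' @param window_s window length (s), default 60.
#' @return data frame with columns `roi_id`, `window_start`, `window_end`,
#'   `n_events`, `amplitude_mean` (NA when no events), `freq_per_min`,
#'   `total_activity_per_min`.
#' @export
summarize_activity <- function(events, dff, window_s = 60) {
  stopifnot(inherits(dff, "dff_trace"))
  t <- dff$frame_times
  fi <- if (length(t) > 1L) t[2] - t[1] else 0
  assert_that(window_s > fi, "window_s must exceed the frame interval")
  t0 <- t[1]; t_end <- t[length(t)]
  n_win <- floor((t_end - t0) / window_s)
  if (n_win < 1L)
    stop_config("recording shorter than one analysis window")
  starts <- t0 + (seq_len(n_win) - 1L) * window_s
  per_min <- window_s / 60

  out <- lapply(starts, function(w0) {
    w1 <- w0 + window_s
    sel <- events$onset_time >= w0 & events$onset_time < w1
    n <- sum(sel)
    data.frame(roi_id = dff$roi_id, window_start = w0, window_end = w1,
               n_events = n,
               amplitude_mean = if (n) mean(events$amplitude[sel]) else NA_real_,
               freq_per_min = n / per_min,
               total_activity_per_min = sum(events$area[sel]) / per_min)
  })
  do.call(rbind, out)
}

#' Normalise post-treatment activity metrics to baseline
#'
#' Each metric is reported as `100 * mean(post) / mean(baseline)` so the
#' baseline sits at 100%. A zero baseline mean yields `NA` with an
#' `undefined` flag rather than an error.
#'
#' @param post,baseline metric tables from [summarize_activity()] (one or
#'   more windows each).
#' @return data frame with columns `metric`, `baseline_mean`, `post_mean`,
#'   `percent`, `undefined`.
#' @export
#' @examples
#' # identical post and baseline windows normalise to exactly 100%
normalize_to_baseline <- function(post, baseline) {
  metrics <- c("amplitude_mean", "freq_per_min", "total_activity_per_min")
  out <- lapply(metrics, function(m) {
    b <- mean(baseline[[m]], na.rm = TRUE)
    p <- mean(post[[m]], na.rm = TRUE)
    undef <- !is.finite(b) || b == 0
    data.frame(metric = m, baseline_mean = b, post_mean = p,
               percent = if (undef) NA_real_ else 100 * p / b,
               undefined = undef)
  })
  do.call(rbind, out)
}
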
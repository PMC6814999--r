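## Spike-train analysis: three-rule burst segmentation, unit
## classification, windowed rates and drug-response classification.

#' Burst-segmentation criteria
#'
#' The three rules: (1) all inter-spike intervals inside a burst are below
#' `max_intra_isi` (default 15 ms); (2) a burst contains at least
#' `min_spikes` spikes (default 3, reading "larger than 2" literally);
#' (3) distinct bursts are separated by more than `min_inter_burst`
#' (default 100 ms) — candidate bursts closer than that are merged.
#'
#' @param max_intra_isi maximum intra-burst ISI (s).
#' @param min_spikes minimum spikes per burst.
#' @param min_inter_burst minimum inter-burst gap (s).
#' @return object of class `burst_criteria`.
#' @export
burst_criteria <- function(max_intra_isi = 0.015, min_spikes = 3L,
                           min_inter_burst = 0.100) {
  assert_that(max_intra_isi > 0 && min_inter_burst > 0,
              "intervals must be positive")
  assert_that(min_spikes >= 2L, "min_spikes must be at least 2")
  structure(list(max_intra_isi = max_intra_isi,
                 min_spikes = as.integer(min_spikes),
                 min_inter_burst = min_inter_burst),
            class = "burst_criteria")
}

#' Segment a spike train into bursts
#'
#' Finds maximal runs of consecutive spikes whose ISIs are all strictly
#' below `max_intra_isi`, keeps runs with at least `min_spikes` spikes,
#' and then merges kept runs whose end-to-start gap is at most
#' `min_inter_burst` into a single burst (spikes lying between merged runs
#' are counted in the merged burst). The output therefore satisfies all
#' three criteria: every burst has `>= min_spikes` spikes and consecutive
#' bursts are separated by more than `min_inter_burst`.
#'
#' @param train a [spike_train()].
#' @param criteria a [burst_criteria()].
#' @return object of class `burst_set`: list with `unit_id`, `bursts`
#'   (data frame start/end/n_spikes) and `criteria`.
#' @export
#' @examples
#' tr <- spike_train("u1", c(0, 0.010, 0.020, 0.500), c(0, 1))
#' segment_bursts(tr)$bursts   # one burst: 0-0.020 s, 3 spikes
segment_bursts <- function(train, criteria = burst_criteria()) {
  stopifnot(inherits(train, "spike_train"), inherits(criteria, "burst_criteria"))
  st <- train$spike_times
  empty <- data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0))
  mk <- function(b) structure(list(unit_id = train$unit_id, bursts = b,
                                   criteria = criteria), class = "burst_set")
  n <- length(st)
  if (n < criteria$min_spikes) return(mk(empty))

  tight <- diff(st) < criteria$max_intra_isi
  r <- rle(tight)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths + 1L >= criteria$min_spikes)
  if (!length(keep)) return(mk(empty))
  ## run over ISIs i..j corresponds to spikes i..(j+1)
  ws <- st[starts[keep]]
  we <- st[ends[keep] + 1L]

  ## merge kept runs separated by <= min_inter_burst
  ms <- me <- numeric(0)
  cs <- ws[1]; ce <- we[1]
  for (i in seq_along(ws)[-1]) {
    if (ws[i] - ce <= criteria$min_inter_burst) {
      ce <- we[i]
    } else {
      ms <- c(ms, cs); me <- c(me, ce)
      cs <- ws[i]; ce <- we[i]
    }
  }
  ms <- c(ms, cs); me <- c(me, ce)
  counts <- vapply(seq_along(ms), function(i)
    sum(st >= ms[i] & st <= me[i]), 0L)
  mk(data.frame(start = ms, end = me, n_spikes = counts))
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> unit %s: %d bursts\n", x$unit_id, nrow(x$bursts)))
  invisible(x)
}

#' Classify a unit as fast- or regular-spiking
#'
#' Fast-spiking iff the baseline rate strictly exceeds the cutoff
#' (default 10 spikes/s); a unit at exactly the cutoff is regular-spiking.
#'
#' @param baseline_rate baseline mean firing rate (Hz); vectorised.
#' @param cutoff rate cutoff (Hz).
#' @return character vector, `"fast_spiking"` or `"regular_spiking"`.
#' @export
classify_unit <- function(baseline_rate, cutoff = 10) {
  assert_that(all(baseline_rate >= 0), "baseline_rate must be non-negative")
  ifelse(baseline_rate > cutoff, "fast_spiking", "regular_spiking")
}

## spikes inside any burst interval (intervals disjoint, sorted)
in_burst <- function(times, bursts) {
  if (!nrow(bursts) || !length(times)) return(logical(length(times)))
  j <- findInterval(times, bursts$start)
  j >= 1L & times <= bursts$end[pmax(j, 1L)]
}

#' Windowed firing rates for one unit
#'
#' Per half-open window `[start, end)`: `mean_rate` counts all spikes,
#' `single_rate` counts spikes outside every burst interval,
#' `burst_rate` counts bursts whose start falls in the window (bursts/s),
#' and `burst_spike_rate` counts in-burst spikes (spikes/s) for users who
#' read "burst spike rate" that way.
#'
#' @param train a [spike_train()].
#' @param bursts a [burst_set()] from [segment_bursts()].
#' @param windows data frame or matrix with columns/cols start, end (s).
#' @return data frame with one row per window.
#' @export
compute_rates <- function(train, bursts, windows) {
  stopifnot(inherits(train, "spike_train"), inherits(bursts, "burst_set"))
  w <- as.data.frame(windows)
  names(w)[1:2] <- c("start", "end")
  assert_that(all(w$end > w$start), "zero-length analysis window")
  assert_that(all(w$start >= train$recording_span[1] - 1e-9) &&
                all(w$end <= train$recording_span[2] + 1e-9),
              "windows must lie within recording_span")
  st <- train$spike_times
  ib <- in_burst(st, bursts$bursts)
  out <- lapply(seq_len(nrow(w)), function(i) {
    dur <- w$end[i] - w$start[i]
    sel <- st >= w$start[i] & st < w$end[i]
    nb <- if (nrow(bursts$bursts))
      sum(bursts$bursts$start >= w$start[i] & bursts$bursts$start < w$end[i]) else 0L
    data.frame(unit_id = train$unit_id, window_start = w$start[i],
               window_end = w$end[i],
               n_spikes = sum(sel),
               mean_rate = sum(sel) / dur,
               single_rate = sum(sel & !ib) / dur,
               burst_rate = nb / dur,
               burst_spike_rate = sum(sel & ib) / dur)
  })
  do.call(rbind, out)
}

#' Relative spike rate after versus before injection
#'
#' `SR = 100 * after / before` (%). A zero baseline is flagged as
#' undefined (`NA` with a warning) rather than an error, so such units
#' can be excluded from normalised summaries and logged.
#'
#' @param before_rate,after_rate mean rates (Hz); vectorised.
#' @return SR in percent.
#' @export
#' @examples
#' relative_change(8, 20)   # 250
relative_change <- function(before_rate, after_rate) {
  assert_that(all(before_rate >= 0) && all(after_rate >= 0),
              "rates must be non-negative")
  out <- 100 * after_rate / before_rate
  bad <- before_rate == 0
  if (any(bad)) {
    warning(sprintf("%d unit(s) with zero baseline rate: SR undefined", sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Classify a relative spike rate as decrease / no change / increase
#'
#' A reduction of 20% or more (SR <= `lower`) is a decrease, an increase
#' of 20% or more (SR >= `upper`) an increase, and the open interval
#' between is no change. The boundaries themselves go to decrease and
#' increase respectively.
#'
#' @param sr relative spike rate in percent; vectorised, NAs propagate.
#' @param lower,upper class bounds in percent (default 80 and 120).
#' @return factor with levels decrease, no_change, increase.
#' @export
classify_response <- function(sr, lower = 80, upper = 120) {
  assert_that(all(sr >= 0, na.rm = TRUE), "SR must be non-negative")
  out <- rep(NA_character_, length(sr))
  ok <- !is.na(sr)
  out[ok & sr <= lower] <- "decrease"
  out[ok & sr >= upper] <- "increase"
  out[ok & sr > lower & sr < upper] <- "no_change"
  factor(out, levels = c("decrease", "no_change", "increase"))
}

#' Fraction of units per response class
#'
#' @param responses factor from [classify_response()] (NAs dropped).
#' @return named numeric vector over the three classes, summing to 1.
#' @export
fraction_by_class <- function(responses) {
  responses <- responses[!is.na(responses)]
  assert_that(length(responses) >= 1L, "no classified units", kind = "data")
  responses <- factor(responses, levels = c("decrease", "no_change", "increase"))
  tab <- table(responses)
  as.numeric(tab) / length(responses) -> fr
  names(fr) <- names(tab)
  fr
}
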
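## Readers and writers for the pipeline's plain-text formats: spike
## tables (TSV), trace tables (CSV), metadata sidecars and JSON
## manifests. Every table written carries a provenance comment header
## (package version, seed, config hash) that the readers skip.

prov_header <- function(seed = NA, config_hash = NA) {
  sprintf("# caburst %s; seed=%s; config=%s",
          as.character(utils::packageVersion("caburst")),
          as.character(seed), as.character(config_hash))
}

write_table_prov <- function(df, path, sep, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov_header(seed, config_hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spike trains as a tab-delimited spike table
#'
#' Columns `unit_id`, `time_s`, one row per spike, header line included.
#'
#' @param trains list of [spike_train()] objects.
#' @param path output path.
#' @param seed,config_hash provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path, seed = NA, config_hash = NA) {
  df <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$spike_times))
      data.frame(unit_id = tr$unit_id, time_s = tr$spike_times)
    else NULL))
  df <- df %||% data.frame(unit_id = character(0), time_s = numeric(0))
  write_table_prov(df, path, sep = "\t", seed = seed, config_hash = config_hash)
}

#' Read a spike table into spike trains
#'
#' @param path tab-delimited file with columns `unit_id`, `time_s`.
#' @param metadata optional data frame with columns `unit_id`, `group`,
#'   `injection_time_s`, `span_start_s`, `span_end_s`; units present in
#'   the metadata but absent from the table become empty trains.
#' @param recording_span fallback span when no metadata is given.
#' @return named list of [spike_train()] objects.
#' @export
read_spike_table <- function(path, metadata = NULL, recording_span = NULL) {
  assert_that(file.exists(path), sprintf("spike table not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  assert_that(all(c("unit_id", "time_s") %in% names(df)),
              "spike table needs columns unit_id, time_s", kind = "data")
  ids <- if (!is.null(metadata)) as.character(metadata$unit_id) else
    unique(as.character(df$unit_id))
  out <- lapply(ids, function(id) {
    times <- sort(df$time_s[df$unit_id == id])
    if (!is.null(metadata)) {
      m <- metadata[as.character(metadata$unit_id) == id, , drop = FALSE]
      span <- c(m$span_start_s[1] %||% 0, m$span_end_s[1])
      spike_train(id, times, span,
                  injection_time = m$injection_time_s[1] %||% NA_real_,
                  group_label = m$group[1] %||% NA_character_)
    } else {
      span <- recording_span %||% c(0, max(times, 1))
      spike_train(id, times, span)
    }
  })
  names(out) <- ids
  out
}

#' Write ROI traces as a comma-delimited trace table
#'
#' First column `frame_time_s`, then one column per ROI.
#'
#' @param traces list of [fluor_trace()] objects on a common time grid.
#' @param path output path.
#' @param seed,config_hash provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path, seed = NA, config_hash = NA) {
  assert_that(length(traces) >= 1L, "no traces to write", kind = "data")
  df <- data.frame(frame_time_s = traces[[1]]$frame_times)
  for (tr in traces) df[[as.character(tr$roi_id)]] <- tr$raw_f
  write_table_prov(df, path, sep = ",", seed = seed, config_hash = config_hash)
}

#' Read a trace table into ROI traces
#'
#' @param path comma-delimited file, first column `frame_time_s`.
#' @param include optional data frame (`roi_id`, `include`) flagging ROIs
#'   excluded from group summaries (still processed).
#' @return named list of [fluor_trace()] objects.
#' @export
read_trace_table <- function(path, include = NULL) {
  assert_that(file.exists(path), sprintf("trace table not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  assert_that(names(df)[1] == "frame_time_s",
              "trace table must start with frame_time_s", kind = "data")
  rois <- names(df)[-1]
  flags <- rep(TRUE, length(rois))
  if (!is.null(include))
    flags <- vapply(rois, function(r) {
      hit <- include$include[as.character(include$roi_id) == r]
      if (length(hit)) isTRUE(as.logical(hit[1])) else TRUE
    }, TRUE)
  out <- lapply(seq_along(rois), function(k)
    fluor_trace(rois[k], df$frame_time_s, df[[rois[k]]], include = flags[k]))
  names(out) <- rois
  out
}

#' Write a study manifest as JSON
#'
#' @param manifest named list (seeds, profiles, ground-truth summaries).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a study manifest
#'
#' @param path JSON manifest path.
#' @return named list.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), sprintf("manifest not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
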
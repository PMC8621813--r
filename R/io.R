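# Plain-CSV interchange for traces, events, and cohort manifests.

#' Read and write joint-angle trace files
#'
#' Trace files are CSV with header `time_s,hip_deg,knee_deg`, one row per
#' sample; event files are CSV with header `event,sample_index` where
#' `event` is `heel_strike` or `toe_off` and `sample_index` is 1-based.
#'
#' @param trace A `joint_angle_trace` (see [generate_participant()]).
#' @param path File path.
#' @param events_path Optional event-file path; if supplied, events are
#'   attached to the returned trace.
#' @param participant_id,group Labels attached to the trace on read.
#' @return `read_trace()` returns a `joint_angle_trace`; writers return
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(
    time_s = sprintf("%.6f", trace$time),
    hip_deg = sprintf("%.6f", trace$hip_deg),
    knee_deg = sprintf("%.6f", trace$knee_deg)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, events_path = NULL, participant_id = NA_character_,
                       group = NA_character_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "hip_deg", "knee_deg") %in% names(df)))
  if (anyNA(df$hip_deg) || anyNA(df$knee_deg)) {
    stop("trace contains missing samples: ", path, call. = FALSE)
  }
  dt <- diff(df$time_s)
  rate <- if (length(dt) > 0) 1 / stats::median(dt) else 100
  ev <- if (!is.null(events_path)) read_events(events_path) else
    data.frame(event = character(0), sample_index = integer(0))
  structure(
    list(
      time = df$time_s, hip_deg = df$hip_deg, knee_deg = df$knee_deg,
      events = ev, sample_rate = rate,
      participant_id = participant_id, group = group
    ),
    class = "joint_angle_trace"
  )
}

#' @rdname write_trace
#' @param events Event `data.frame` (`event`, `sample_index`).
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("event", "sample_index") %in% names(ev)))
  ev$sample_index <- as.integer(ev$sample_index)
  ev
}

#' Read a cohort manifest
#'
#' @param path Path to a manifest CSV written by [generate_cohort()]
#'   (`participant_id,group,trace_path,events_path,seed`). Relative trace
#'   and event paths are resolved against the manifest's directory.
#' @return A `data.frame` with attribute `"dir"` set to the manifest's
#'   directory.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "group", "trace_path", "events_path")
                %in% names(m)))
  attr(m, "dir") <- dirname(path)
  m
}

# resolve a manifest-relative path against the manifest directory
.resolve_path <- function(p, dir) {
  if (is.null(dir) || file.exists(p) || grepl("^(/|[A-Za-z]:)", p)) p
  else file.path(dir, p)
}
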
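# Gait-cycle segmentation and time normalization.
#
# A gait cycle runs from one heel strike of the analyzed limb to its next
# heel strike; stance is heel strike -> toe-off, swing is toe-off -> next
# heel strike. Each cycle is resampled to 101 points (the 0..100 normalized
# gait-cycle axis) by linear interpolation on the time axis, with no
# smoothing.

# round half up (base round() is round-half-even)
.rhu <- function(x) floor(x + 0.5)

.check_alternation <- function(events) {
  n <- nrow(events)
  if (n == 0) return(invisible(TRUE))
  if (any(diff(events$sample_index) <= 0)) {
    bad <- which(diff(events$sample_index) <= 0)[1] + 1L
    stop("event indices not strictly increasing at event ", bad, call. = FALSE)
  }
  expected <- rep(c("heel_strike", "toe_off"), length.out = n)
  if (events$event[1] != "heel_strike" || any(events$event != expected)) {
    bad <- which(events$event != expected)
    if (length(bad) == 0) bad <- 1L
    stop("events must alternate heel_strike, toe_off, ...; violation at event ",
         bad[1], call. = FALSE)
  }
  invisible(TRUE)
}

.new_gait_cycle <- function(hip, knee, stance_end, participant_id = NA_character_,
                            cycle = NA_integer_) {
  structure(
    list(hip_deg = hip, knee_deg = knee,
         stance_end_index = as.integer(stance_end),
         participant_id = participant_id, cycle = as.integer(cycle)),
    class = "gait_cycle"
  )
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf(
    "<gait_cycle %s #%s: 101 points, toe-off at %d%% of cycle>\n",
    x$participant_id, x$cycle, x$stance_end_index
  ))
  invisible(x)
}

#' Segment a trace into time-normalized gait cycles
#'
#' Cuts the trace at consecutive heel strikes, resamples hip and knee to the
#' 101-point normalized gait-cycle axis (0..100) by linear interpolation,
#' and maps the toe-off to `stance_end_index = round(100 * (t_toe-off -
#' t_heel-strike) / cycle duration)` (half rounded up). Cycles whose
#' boundary lands at 0 or 100 are dropped with a message. Partial cycles
#' before the first and after the last heel strike are discarded.
#'
#' @param trace A `joint_angle_trace` with events attached.
#' @return List of `gait_cycle` objects (empty, with a warning, if fewer
#'   than 2 heel strikes are present).
#' @export
segment_cycles <- function(trace) {
  stopifnot(inherits(trace, "joint_angle_trace"))
  ev <- trace$events
  .check_alternation(ev)
  hs <- ev$sample_index[ev$event == "heel_strike"]
  if (length(hs) < 2) {
    warning("fewer than 2 heel strikes; no cycles segmented", call. = FALSE)
    return(list())
  }
  to <- ev$sample_index[ev$event == "toe_off"]
  out <- list()
  k <- 0L
  for (j in seq_len(length(hs) - 1L)) {
    a <- hs[j]; b <- hs[j + 1L]
    tos <- to[to > a & to < b]
    if (length(tos) != 1L) next   # needs exactly one toe-off inside
    t0 <- trace$time[a]; t1 <- trace$time[b]
    grid <- t0 + (0:100) / 100 * (t1 - t0)
    hip <- stats::approx(trace$time, trace$hip_deg, xout = grid)$y
    knee <- stats::approx(trace$time, trace$knee_deg, xout = grid)$y
    se <- .rhu(100 * (trace$time[tos] - t0) / (t1 - t0))
    if (se <= 0 || se >= 100) {
      message(sprintf("dropping cycle %d: toe-off at normalized index %d", j, se))
      next
    }
    k <- k + 1L
    out[[k]] <- .new_gait_cycle(hip, knee, se, trace$participant_id, j)
  }
  out
}

#' Detect heel-strike and toe-off events from joint angles
#'
#' Fallback for traces lacking annotations. Heel strikes are placed at
#' local maxima of hip flexion separated by at least `min_cycle_s` (the
#' trace endpoints qualify if the angle falls away from them); toe-off is
#' placed at the knee-flexion upturn preceding the swing flexion peak
#' within each heel-strike pair.
#'
#' @param trace A `joint_angle_trace` (events, if any, are ignored).
#' @param min_cycle_s Minimum plausible cycle duration in seconds.
#' @return Event `data.frame` (`event`, `sample_index`) satisfying the
#'   alternation invariant; empty (with a warning) if no qualifying hip
#'   maxima exist.
#' @export
detect_events <- function(trace, min_cycle_s = 0.5) {
  stopifnot(inherits(trace, "joint_angle_trace"))
  hip <- trace$hip_deg
  n <- length(hip)
  if (n < 3 || diff(range(hip)) < sqrt(.Machine$double.eps)) {
    warning("no qualifying hip-flexion maxima; no events detected",
            call. = FALSE)
    return(data.frame(event = character(0), sample_index = integer(0)))
  }
  interior <- which(hip[2:(n - 1)] > hip[1:(n - 2)] &
                      hip[2:(n - 1)] >= hip[3:n]) + 1L
  cand <- interior
  # the leading sample counts if the angle falls away from it; the trailing
  # sample never does (a peak there cannot be confirmed)
  if (hip[1] >= hip[2]) cand <- c(1L, cand)
  # ignore shallow ripples: a heel-strike peak should stand well above the
  # hip-extension minimum
  floor_ <- min(hip) + 0.5 * diff(range(hip))
  cand <- cand[hip[cand] >= floor_]
  if (length(cand) == 0) {
    warning("no qualifying hip-flexion maxima; no events detected",
            call. = FALSE)
    return(data.frame(event = character(0), sample_index = integer(0)))
  }
  min_sep <- min_cycle_s * trace$sample_rate
  hs <- cand[1]
  for (i in cand[-1]) {
    if (i - hs[length(hs)] >= min_sep) {
      hs <- c(hs, i)
    } else if (hip[i] > hip[hs[length(hs)]]) {
      hs[length(hs)] <- i   # keep the higher of two close peaks
    }
  }
  if (length(hs) < 2) {
    warning("fewer than 2 heel strikes detected", call. = FALSE)
    return(data.frame(event = "heel_strike", sample_index = as.integer(hs[1])))
  }
  knee <- trace$knee_deg
  find_toe_off <- function(a, b) {
    seg <- knee[a:b]
    pk <- which.max(seg)
    i <- pk
    while (i > 1 && seg[i - 1] < seg[i]) i <- i - 1L  # walk back to the upturn
    a + i - 1L
  }
  ev_kind <- character(0)
  ev_idx <- integer(0)
  for (j in seq_len(length(hs) - 1L)) {
    a <- hs[j]; b <- hs[j + 1L]
    to <- find_toe_off(a, b)
    if (to <= a || to >= b) to <- a + .rhu(0.6 * (b - a))  # degenerate knee
    ev_kind <- c(ev_kind, "heel_strike", "toe_off")
    ev_idx <- c(ev_idx, a, to)
  }
  ev_kind <- c(ev_kind, "heel_strike")
  ev_idx <- c(ev_idx, hs[length(hs)])
  # a toe-off after the final heel strike is kept when the trailing segment
  # still shows a clear swing flexion peak
  a <- hs[length(hs)]
  if (n - a >= 2) {
    seg_rng <- max(knee[a:n]) - min(knee[a:n])
    if (seg_rng > 0.25 * diff(range(knee)) && seg_rng > sqrt(.Machine$double.eps)) {
      to <- find_toe_off(a, n)
      if (to > a && to < n) {
        ev_kind <- c(ev_kind, "toe_off")
        ev_idx <- c(ev_idx, to)
      }
    }
  }
  ev <- data.frame(event = ev_kind, sample_index = as.integer(ev_idx),
                   stringsAsFactors = FALSE)
  .check_alternation(ev)
  ev
}

#' Pointwise mean gait cycle
#'
#' Averages hip and knee trajectories across cycles point by point on the
#' normalized axis; the stance/swing boundary is the rounded mean of the
#' members' boundaries. This is the bold mean loop drawn over individual
#' cyclograms in group overlays.
#'
#' @param cycles Nonempty list of 101-point `gait_cycle` objects.
#' @return A `gait_cycle`.
#' @export
mean_cycle <- function(cycles) {
  if (length(cycles) == 0) stop("no cycles to average", call. = FALSE)
  stopifnot(all(vapply(cycles, inherits, logical(1), "gait_cycle")))
  hip <- rowMeans(vapply(cycles, `[[`, numeric(101), "hip_deg"))
  knee <- rowMeans(vapply(cycles, `[[`, numeric(101), "knee_deg"))
  se <- .rhu(mean(vapply(cycles, `[[`, integer(1), "stance_end_index")))
  .new_gait_cycle(hip, knee, se,
                  participant_id = cycles[[1]]$participant_id,
                  cycle = NA_integer_)
}
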
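# Synthetic gait-trace generator.
#
# The templates are low-order periodic waveforms with the qualitative
# landmarks of sagittal gait kinematics: hip flexed maximally at heel
# strike, extending monotonically through stance to a late-stance minimum,
# re-flexing in swing; knee with a small loading-response flexion wave in
# early stance and a large mid-swing flexion peak (the inverted-U swing
# loop of the hip-knee cyclogram), plus an optional late-stance
# hyperextension dip taking the knee below neutral. Amplitudes are exact:
# the template hip/knee ranges equal the requested ROMs by construction.

# smooth periodic raised-cosine bump with a flattened (quartic) top:
# 1 at `center`, 0 outside +/- `width`. The flat top keeps the waveform
# extrema insensitive to where the sampling grid lands.
.bump <- function(phase, center, width) {
  d <- abs(phase - center)
  d <- pmin(d, 1 - d)                       # wrap on the unit circle
  b <- ifelse(d < width, cos(pi * d / (2 * width))^2, 0)
  1 - (1 - b)^2
}

# phase of peak hip flexion: just before heel strike, as in physiologic gait
.HIP_PEAK_PHASE <- 0.98

# template pair at arbitrary ROM; phase in [0,1]. `hip_anchor_rom` fixes the
# hip angle at the cycle boundary to the value of the anchor-ROM waveform,
# so consecutive cycles with different ROM draws join continuously and each
# cycle's extrema stay strictly inside the cycle.
.cycle_shape <- function(phase, hip_rom, knee_rom, stance_fraction,
                         hyperextension_deg = 0, hip_anchor_rom = hip_rom) {
  sf <- stance_fraction
  # hip: peak flexion just before heel strike, extension minimum in late
  # stance; resting span -0.3*ROM .. +0.7*ROM
  w <- (cos(2 * pi * (phase - .HIP_PEAK_PHASE)) + 1) / 2
  w0 <- (cos(2 * pi * .HIP_PEAK_PHASE) + 1) / 2
  hip <- hip_rom * (w - w0) + hip_anchor_rom * (w0 - 0.3)
  # knee: loading-response wave (amplitude 1/4 of swing peak) + swing peak;
  # both vanish at heel strike and toe-off so the knee is neutral there
  pos <- 0.25 * .bump(phase, 0.25 * sf, 0.25 * sf) +
    .bump(phase, sf + (1 - sf) / 2, (1 - sf) / 2)
  knee <- (knee_rom - hyperextension_deg) * pos
  if (hyperextension_deg > 0) {
    # late-stance dip, support disjoint from the other waves, so the knee
    # minimum is exactly -hyperextension_deg and the range exactly knee_rom
    knee <- knee - hyperextension_deg * .bump(phase, 0.8 * sf, 0.15 * sf)
  }
  list(hip_deg = hip, knee_deg = knee)
}

#' Template hip/knee angles over one gait cycle
#'
#' Evaluates the smooth periodic template pair underlying the synthetic
#' generator at the given gait-cycle phases, scaled so the hip range equals
#' `profile$hip_rom_mean` and the knee range equals `profile$knee_rom_mean`
#' exactly. When `profile$hyperextension_deg > 0` the knee minimum lies that
#' many degrees below neutral, in late stance.
#'
#' @param phase Numeric vector of gait-cycle phases in `[0, 1]`
#'   (0 = heel strike, `stance_fraction` = toe-off, 1 = next heel strike).
#' @param profile A [gait_profile].
#' @return List with numeric vectors `hip_deg` and `knee_deg` (flexion
#'   positive, knee hyperextension negative).
#' @export
#' @examples
#' shp <- base_cycle_shape(seq(0, 1, length.out = 101),
#'                         default_profiles()$control)
#' max(shp$hip_deg) - min(shp$hip_deg)  # 45.51
base_cycle_shape <- function(phase, profile) {
  validate_profile(profile)
  if (any(!is.finite(phase)) || any(phase < 0 | phase > 1)) {
    stop("phase must lie in [0, 1]", call. = FALSE)
  }
  .cycle_shape(phase, profile$hip_rom_mean, profile$knee_rom_mean,
               profile$stance_fraction, profile$hyperextension_deg)
}

# run `expr` under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# ROM draw truncated at 20% of its mean; resampling logged via message()
.draw_rom <- function(n, mean, sd, what) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0.2 * mean)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    message(sprintf("resampling %d truncated %s draw(s)", length(bad), what))
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < 0.2 * mean)
    tries <- tries + 1L
  }
  if (length(bad) > 0) x[bad] <- 0.2 * mean
  x
}

#' Simulate one participant's joint-angle trace
#'
#' Concatenates `profile$n_cycles_per_participant` template cycles sampled
#' at `sample_rate`. The participant's mean hip and knee ROMs are drawn from
#' normal distributions centred on the profile means with the
#' between-participant SDs; each cycle's ROM is the participant mean times
#' `1 + e` with `e ~ N(0, rom_cv_within / 100)`. Draws falling below 20% of
#' their mean are resampled (and logged). Heel-strike events are recorded at
#' the exact first sample of each cycle (plus the final sample); toe-off at
#' `stance_fraction` of each cycle.
#'
#' @param profile A [gait_profile].
#' @param rng_seed Integer seed; equal seeds give bit-identical traces.
#' @param participant_id Label stored in the trace.
#' @param sample_rate Sampling frequency in Hz (default 100).
#' @return A `joint_angle_trace`: list with `time` (s), `hip_deg`,
#'   `knee_deg`, `events` (data.frame `event`, `sample_index`, 1-based),
#'   `sample_rate`, `participant_id`, `group`. The per-cycle ROM draws used
#'   in construction are attached as attribute `"per_cycle_rom"` for
#'   round-trip validation.
#' @export
generate_participant <- function(profile, rng_seed,
                                 participant_id = profile$name,
                                 sample_rate = 100) {
  validate_profile(profile)
  n_cyc <- profile$n_cycles_per_participant
  if (n_cyc < 2) stop("n_cycles_per_participant must be >= 2", call. = FALSE)

  .with_seed(rng_seed, {
    hip_m <- .draw_rom(1, profile$hip_rom_mean, profile$hip_rom_sd_between,
                       "participant hip ROM")
    knee_m <- .draw_rom(1, profile$knee_rom_mean, profile$knee_rom_sd_between,
                        "participant knee ROM")
    cv <- profile$rom_cv_within / 100
    hip_c <- .draw_rom(n_cyc, hip_m, hip_m * cv, "cycle hip ROM")
    knee_c <- .draw_rom(n_cyc, knee_m, knee_m * cv, "cycle knee ROM")
  })

  n_samp <- max(4L, round(profile$cycle_duration_mean * sample_rate))
  phase <- (seq_len(n_samp) - 1) / n_samp
  hip <- knee <- numeric(n_cyc * n_samp + 1L)
  hs <- integer(n_cyc + 1L)
  to <- integer(n_cyc)
  hyper <- pmin(profile$hyperextension_deg, 0.9 * knee_c)
  for (j in seq_len(n_cyc)) {
    shp <- .cycle_shape(phase, hip_c[j], knee_c[j],
                        profile$stance_fraction, hyper[j],
                        hip_anchor_rom = hip_m)
    idx <- (j - 1L) * n_samp + seq_len(n_samp)
    hip[idx] <- shp$hip_deg
    knee[idx] <- shp$knee_deg
    hs[j] <- idx[1]
    to[j] <- idx[1] + round(profile$stance_fraction * n_samp)
  }
  # closing sample: heel strike ending the last cycle
  last <- .cycle_shape(1, hip_c[n_cyc], knee_c[n_cyc],
                       profile$stance_fraction, hyper[n_cyc],
                       hip_anchor_rom = hip_m)
  hip[n_cyc * n_samp + 1L] <- last$hip_deg
  knee[n_cyc * n_samp + 1L] <- last$knee_deg
  hs[n_cyc + 1L] <- n_cyc * n_samp + 1L

  ev <- data.frame(
    event = c(rbind(rep("heel_strike", n_cyc), rep("toe_off", n_cyc)),
              "heel_strike"),
    sample_index = as.integer(c(rbind(hs[seq_len(n_cyc)], to), hs[n_cyc + 1L])),
    stringsAsFactors = FALSE
  )

  trace <- structure(
    list(
      time = (seq_along(hip) - 1) / sample_rate,
      hip_deg = hip, knee_deg = knee,
      events = ev, sample_rate = sample_rate,
      participant_id = participant_id, group = profile$name
    ),
    class = "joint_angle_trace"
  )
  attr(trace, "per_cycle_rom") <- data.frame(
    cycle = seq_len(n_cyc), hip_rom = hip_c, knee_rom = knee_c
  )
  trace
}

#' @export
print.joint_angle_trace <- function(x, ...) {
  cat(sprintf(
    "<joint_angle_trace '%s' (%s): %d samples @ %g Hz, %d events>\n",
    x$participant_id, x$group, length(x$hip_deg), x$sample_rate,
    nrow(x$events)
  ))
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Generates every participant of every profile and writes one trace CSV
#' (`time_s,hip_deg,knee_deg`) and one event CSV (`event,sample_index`) per
#' participant, plus a manifest CSV
#' (`participant_id,group,trace_path,events_path,seed`). Per-participant
#' seeds are derived from the master seed by a fixed offset (consecutive
#' integers in participant order), so the cohort is reproducible
#' participant-by-participant.
#'
#' @param profiles List of [gait_profile] objects (>= 1).
#' @param rng_seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @return The manifest `data.frame`, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_cohort <- function(profiles, rng_seed, out_dir) {
  if (inherits(profiles, "gait_profile")) profiles <- list(profiles)
  if (length(profiles) < 1) stop("need at least one profile", call. = FALSE)
  lapply(profiles, validate_profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)

  rows <- list()
  offset <- 0L
  for (p in profiles) {
    for (i in seq_len(p$n_participants)) {
      offset <- offset + 1L
      pid <- sprintf("%s_%03d", p$name, i)
      seed_i <- as.integer(rng_seed) + offset
      tr <- generate_participant(p, seed_i, participant_id = pid)
      trace_file <- paste0(pid, "_trace.csv")
      events_file <- paste0(pid, "_events.csv")
      write_trace(tr, file.path(out_dir, trace_file))
      write_events(tr$events, file.path(out_dir, events_file))
      # paths are stored relative to the manifest so the cohort directory is
      # relocatable and reruns are byte-identical wherever they land
      rows[[offset]] <- data.frame(
        participant_id = pid, group = p$name,
        trace_path = trace_file, events_path = events_file,
        seed = seed_i, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$participant_id)) {
    stop("duplicate participant ids (profiles must have distinct names)",
         call. = FALSE)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}
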
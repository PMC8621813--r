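#' Gait profile: simulation preset for one cohort group
#'
#' A `gait_profile` bundles everything the synthetic generator needs to
#' emulate one group of walkers: mean sagittal hip and knee ranges of motion
#' (ROM) with their between-participant standard deviations, the stance
#' fraction of the gait cycle, mean cycle duration, the within-participant
#' cycle-to-cycle ROM variability (a coefficient of variation, in percent),
#' an optional knee-hyperextension depth for the late-stance dip seen in
#' severe hemiplegic gait, and the cohort size.
#'
#' @param name Group label, e.g. `"control"`.
#' @param hip_rom_mean,knee_rom_mean Mean joint range of motion in degrees
#'   (must be positive).
#' @param hip_rom_sd_between,knee_rom_sd_between Between-participant SD of
#'   the ROM means, degrees.
#' @param stance_fraction Fraction of the cycle spent in stance, in (0, 1).
#' @param cycle_duration_mean Mean gait-cycle duration in seconds.
#' @param rom_cv_within Cycle-to-cycle ROM coefficient of variation per
#'   participant, in percent (>= 0).
#' @param hyperextension_deg Depth of the late-stance knee hyperextension in
#'   degrees (>= 0; 0 disables it). Must be smaller than `knee_rom_mean`.
#' @param n_participants Number of participants in the group.
#' @param n_cycles_per_participant Number of gait cycles simulated per
#'   participant (>= 2).
#'
#' @return An object of class `gait_profile` (a named list).
#' @seealso [default_profiles()] for the shipped control / mild-stroke /
#'   moderate-stroke presets, [generate_participant()], [generate_cohort()].
#' @export
#' @examples
#' gait_profile("control", hip_rom_mean = 45.51, knee_rom_mean = 57.43)
gait_profile <- function(name,
                         hip_rom_mean,
                         knee_rom_mean,
                         hip_rom_sd_between = 0,
                         knee_rom_sd_between = 0,
                         stance_fraction = 0.60,
                         cycle_duration_mean = 1.1,
                         rom_cv_within = 0,
                         hyperextension_deg = 0,
                         n_participants = 1,
                         n_cycles_per_participant = 10) {
  p <- list(
    name = as.character(name),
    hip_rom_mean = as.numeric(hip_rom_mean),
    hip_rom_sd_between = as.numeric(hip_rom_sd_between),
    knee_rom_mean = as.numeric(knee_rom_mean),
    knee_rom_sd_between = as.numeric(knee_rom_sd_between),
    stance_fraction = as.numeric(stance_fraction),
    cycle_duration_mean = as.numeric(cycle_duration_mean),
    rom_cv_within = as.numeric(rom_cv_within),
    hyperextension_deg = as.numeric(hyperextension_deg),
    n_participants = as.integer(n_participants),
    n_cycles_per_participant = as.integer(n_cycles_per_participant)
  )
  class(p) <- "gait_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "gait_profile"))
  if (!(p$stance_fraction > 0 && p$stance_fraction < 1)) {
    stop("stance_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (p$hip_rom_mean <= 0 || p$knee_rom_mean <= 0) {
    stop("ROM means must be positive", call. = FALSE)
  }
  if (p$rom_cv_within < 0) {
    stop("rom_cv_within must be >= 0", call. = FALSE)
  }
  if (p$hyperextension_deg < 0) {
    stop("hyperextension_deg must be >= 0", call. = FALSE)
  }
  if (p$hyperextension_deg >= p$knee_rom_mean) {
    stop("hyperextension_deg must be smaller than knee_rom_mean", call. = FALSE)
  }
  if (p$cycle_duration_mean <= 0) stop("cycle_duration_mean must be positive", call. = FALSE)
  if (p$n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<gait_profile '%s'>\n",
      "  hip ROM  %.2f +/- %.2f deg   knee ROM %.2f +/- %.2f deg\n",
      "  stance %.0f%%, cycle %.2f s, within-participant ROM CV %.1f%%\n",
      "  knee hyperextension %.1f deg; n = %d participants x %d cycles\n"
    ),
    x$name, x$hip_rom_mean, x$hip_rom_sd_between, x$knee_rom_mean,
    x$knee_rom_sd_between, 100 * x$stance_fraction, x$cycle_duration_mean,
    x$rom_cv_within, x$hyperextension_deg, x$n_participants,
    x$n_cycles_per_participant
  ))
  invisible(x)
}

#' Default cohort presets: control, mild stroke, moderate stroke
#'
#' Shipped presets for a three-group hemiplegic-gait study. Group sizes and
#' the group-level hip/knee ROM means and between-participant SDs follow the
#' published cohort the generator emulates (control n = 32, hip ROM
#' 45.51 +/- 5.92 deg, knee ROM 57.43 +/- 8.31 deg; mild stroke n = 18,
#' 38.82 +/- 6.09 and 40.62 +/- 7.50; moderate stroke n = 29,
#' 27.75 +/- 9.45 and 27.75 +/- 12.02). Stance fractions lengthen and cycle
#' durations slow with severity; the moderate group carries a 5-degree knee
#' hyperextension dip in late stance, producing the U-shaped (rather than
#' inverted-U) stance arc characteristic of severe hemiplegia. The
#' within-participant ROM CVs are calibration values chosen so the
#' pipeline's variability output lands near published cycle-to-cycle CV
#' magnitudes; they are not ground truth.
#'
#' @param n_cycles_per_participant Cycles simulated per participant
#'   (default 10, roughly what a 10 m straight walk yields).
#' @return Named list of three [gait_profile] objects.
#' @export
#' @examples
#' default_profiles()$control
default_profiles <- function(n_cycles_per_participant = 10) {
  list(
    control = gait_profile(
      "control",
      hip_rom_mean = 45.51, hip_rom_sd_between = 5.92,
      knee_rom_mean = 57.43, knee_rom_sd_between = 8.31,
      stance_fraction = 0.60, cycle_duration_mean = 1.1,
      rom_cv_within = 5, hyperextension_deg = 0,
      n_participants = 32,
      n_cycles_per_participant = n_cycles_per_participant
    ),
    mild_stroke = gait_profile(
      "mild_stroke",
      hip_rom_mean = 38.82, hip_rom_sd_between = 6.09,
      knee_rom_mean = 40.62, knee_rom_sd_between = 7.50,
      stance_fraction = 0.65, cycle_duration_mean = 1.3,
      rom_cv_within = 6, hyperextension_deg = 0,
      n_participants = 18,
      n_cycles_per_participant = n_cycles_per_participant
    ),
    moderate_stroke = gait_profile(
      "moderate_stroke",
      hip_rom_mean = 27.75, hip_rom_sd_between = 9.45,
      knee_rom_mean = 27.75, knee_rom_sd_between = 12.02,
      stance_fraction = 0.70, cycle_duration_mean = 1.7,
      rom_cv_within = 11, hyperextension_deg = 5,
      n_participants = 29,
      n_cycles_per_participant = n_cycles_per_participant
    )
  )
}

#' Read or write gait-profile presets as YAML
#'
#' A preset file holds one mapping per group, mirroring the fields of
#' [gait_profile()].
#'
#' @param path File path.
#' @param profiles Named list of [gait_profile] objects.
#' @return `read_profiles()` returns a named list of [gait_profile] objects;
#'   `write_profiles()` returns `path` invisibly.
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    do.call(gait_profile, c(list(name = nm), raw[[nm]]))
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  entries <- lapply(profiles, function(p) {
    validate_profile(p)
    p[setdiff(names(p), "name")]
  })
  names(entries) <- vapply(profiles, `[[`, character(1), "name")
  yaml::write_yaml(entries, path)
  invisible(path)
}
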
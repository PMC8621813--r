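# Hip-knee cyclogram geometry.
#
# The cyclogram is the closed angle-angle trajectory obtained by plotting
# the hip angle (abscissa) against the knee angle (ordinate) over one gait
# cycle, traversed in time order from heel strike. For normal-pattern data
# this traversal is clockwise. Geometry parameters per cycle: hip and knee
# ROM, the perimeter (summed Euclidean segment lengths, partitioned into
# stance and swing arcs), and the enclosed area (shoelace formula, absolute
# value so the clockwise loop yields a positive area).

#' Build a cyclogram from a normalized gait cycle
#'
#' @param cycle A 101-point `gait_cycle` (see [segment_cycles()]).
#' @return A `cyclogram`: list with `points` (101 x 2 matrix, columns
#'   `hip_deg`, `knee_deg`, row 1 = heel strike), `stance_end_index`
#'   (toe-off position on the 0..100 axis), `closed` (TRUE: parameter
#'   computations append the closing segment back to heel strike), and
#'   `source` (participant id, cycle ordinal).
#' @export
build_cyclogram <- function(cycle) {
  stopifnot(inherits(cycle, "gait_cycle"),
            length(cycle$hip_deg) == 101, length(cycle$knee_deg) == 101)
  pts <- cbind(hip_deg = cycle$hip_deg, knee_deg = cycle$knee_deg)
  structure(
    list(points = pts, stance_end_index = cycle$stance_end_index,
         closed = TRUE,
         source = list(participant_id = cycle$participant_id,
                       cycle = cycle$cycle)),
    class = "cyclogram"
  )
}

#' @export
print.cyclogram <- function(x, ...) {
  cat(sprintf("<cyclogram %s #%s: %d points, toe-off at index %d>\n",
              x$source$participant_id, x$source$cycle, nrow(x$points),
              x$stance_end_index))
  invisible(x)
}

#' Range of motion
#'
#' @param values Nonempty numeric vector of joint angles (degrees).
#' @return `max(values) - min(values)`, degrees.
#' @export
#' @examples
#' rom(c(10, 20, 5))  # 15
rom <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop("rom() needs a nonempty numeric vector", call. = FALSE)
  }
  max(values) - min(values)
}

#' Polyline length of a cyclogram arc
#'
#' Sum over consecutive point pairs of
#' `sqrt((h_i - h_{i+1})^2 + (k_i - k_{i+1})^2)`. Equivalently, with
#' `w = dangle/dt` the average angular velocities over each interval, each
#' segment is `dt * sqrt(w_h^2 + w_k^2)`, so the perimeter couples joint
#' excursion with average joint velocity.
#'
#' @param points Two-column matrix of (hip, knee) angles in traversal order
#'   (>= 2 rows).
#' @param close Append the segment from the last point back to the first?
#' @return Length in degrees (0 iff all points coincide).
#' @export
#' @examples
#' path_length(rbind(c(0, 0), c(3, 4)))  # 5
path_length <- function(points, close = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("path_length() needs >= 2 points", call. = FALSE)
  if (close) points <- rbind(points, points[1, , drop = FALSE])
  d <- diff(points)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Shoelace area of a closed polygonal arc
#'
#' `|1/2 * sum_i (h_i * k_{i+1} - h_{i+1} * k_i)|` with cyclic closure.
#' The absolute value is taken so the clockwise traversal of a
#' normal-pattern cyclogram (which has negative signed shoelace sum under
#' the standard orientation convention) reports a positive area. For
#' self-intersecting loops the shoelace sum nets out oppositely wound
#' sub-loops; the formula is applied literally (see [phase_params()] for
#' the accompanying warning).
#'
#' @param points Two-column matrix of (hip, knee) angles in traversal order
#'   (>= 3 rows; the closing edge back to row 1 is implicit).
#' @return Area in degrees squared (0 for collinear points).
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
polygon_area <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("polygon_area() needs >= 3 points", call. = FALSE)
  h <- points[, 1]; k <- points[, 2]
  hn <- h[c(2:n, 1)]; kn <- k[c(2:n, 1)]
  abs(sum(h * kn - hn * k)) / 2
}

# TRUE if any two non-adjacent edges of the closed polygon properly cross.
# Vectorized over all edge pairs; collinear overlaps (retraced segments,
# common in templates with a knee-neutral plateau) are not flagged.
.self_intersects <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  # drop an exactly repeated closing point
  if (all(pts[n, ] == pts[1, ])) {
    pts <- pts[-n, , drop = FALSE]
    n <- n - 1L
    if (n < 4) return(FALSE)
  }
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  keep <- i < j & j - i > 1L & !(i == 1L & j == n)   # non-adjacent pairs
  i <- i[keep]; j <- j[keep]
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Cyclogram geometry parameters, partitioned by gait phase
#'
#' Computes the eight per-cycle parameters: hip ROM, knee ROM, and the
#' perimeter and area for the stance arc (heel strike to toe-off), the
#' swing arc (toe-off to the next heel strike), and the full cycle.
#'
#' The perimeter partition is exact: the swing arc is extended by the
#' closing chord from the last point back to heel strike, so
#' `perimeter_stance + perimeter_swing == perimeter_total` (the closed
#' full-cycle path length). Phase areas close each open arc with the
#' straight chord between its endpoints; because those chord regions may
#' overlap, `area_stance + area_swing` is not constrained to equal
#' `area_total`. A warning is emitted when the full loop self-intersects
#' (possible in pathological gait), since the shoelace area then nets out
#' oppositely wound sub-loops.
#'
#' @param cyclo A `cyclogram` with `0 < stance_end_index < 100`.
#' @param warn_self_intersect Warn when the closed loop properly
#'   self-intersects (default TRUE).
#' @return A `cyclogram_params` object: named list of the eight scalars
#'   `hip_rom`, `knee_rom`, `perimeter_stance`, `perimeter_swing`,
#'   `perimeter_total` (degrees), `area_stance`, `area_swing`, `area_total`
#'   (degrees squared); all nonnegative.
#' @export
phase_params <- function(cyclo, warn_self_intersect = TRUE) {
  stopifnot(inherits(cyclo, "cyclogram"))
  se <- cyclo$stance_end_index
  if (se <= 0 || se >= 100) {
    stop("stance_end_index must lie strictly between 0 and 100", call. = FALSE)
  }
  pts <- cyclo$points
  r_to <- se + 1L                      # matrix row of the toe-off point
  stance <- pts[1:r_to, , drop = FALSE]
  swing <- pts[c(r_to:nrow(pts), 1L), , drop = FALSE]  # arc + chord home
  if (warn_self_intersect && .self_intersects(pts)) {
    warning("cyclogram self-intersects; shoelace area nets opposing loops",
            call. = FALSE)
  }
  p <- list(
    hip_rom = rom(pts[, 1]),
    knee_rom = rom(pts[, 2]),
    perimeter_stance = path_length(stance, close = FALSE),
    perimeter_swing = path_length(swing, close = FALSE),
    perimeter_total = NA_real_,
    area_stance = polygon_area(stance),
    area_swing = polygon_area(swing),
    area_total = polygon_area(pts)
  )
  p$perimeter_total <- p$perimeter_stance + p$perimeter_swing
  structure(p, class = "cyclogram_params")
}

#' @export
print.cyclogram_params <- function(x, ...) {
  cat(sprintf(
    paste0("<cyclogram_params>\n",
           "  ROM (deg):       hip %.2f, knee %.2f\n",
           "  perimeter (deg): stance %.2f, swing %.2f, total %.2f\n",
           "  area (deg^2):    stance %.2f, swing %.2f, total %.2f\n"),
    x$hip_rom, x$knee_rom, x$perimeter_stance, x$perimeter_swing,
    x$perimeter_total, x$area_stance, x$area_swing, x$area_total
  ))
  invisible(x)
}

#' Per-cycle and mean cyclogram parameters for one participant
#'
#' Computes [phase_params()] for every cycle and averages them field by
#' field, which is the participant-level summary entering the group
#' comparison. (The alternative — parameters of the pointwise [mean_cycle()]
#' — is available by composing the primitives; per-cycle averaging is the
#' default because the cycle-to-cycle values also feed the variability
#' analysis.)
#'
#' @param cycles Nonempty list of `gait_cycle` objects.
#' @param warn_self_intersect Passed to [phase_params()].
#' @return List with `mean` (a `cyclogram_params`) and `per_cycle` (a
#'   `data.frame`, one row per cycle with the eight parameter columns).
#' @export
participant_params <- function(cycles, warn_self_intersect = FALSE) {
  if (length(cycles) == 0) stop("no cycles", call. = FALSE)
  rows <- lapply(cycles, function(cy) {
    p <- phase_params(build_cyclogram(cy),
                      warn_self_intersect = warn_self_intersect)
    data.frame(cycle = cy$cycle, as.data.frame(unclass(p)))
  })
  per_cycle <- do.call(rbind, rows)
  mean_p <- as.list(colMeans(per_cycle[, cyclogram_param_names(), drop = FALSE]))
  class(mean_p) <- "cyclogram_params"
  list(mean = mean_p, per_cycle = per_cycle)
}

#' Names of the eight cyclogram parameters
#' @return Character vector.
#' @export
cyclogram_param_names <- function() {
  c("hip_rom", "knee_rom",
    "perimeter_stance", "perimeter_swing", "perimeter_total",
    "area_stance", "area_swing", "area_total")
}
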
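# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written without reference to the package's
# own geometry/statistics code paths.

# --- Monte-Carlo point-in-polygon area oracle (convex polygons) -----------

# vertices must be in counter-clockwise order
mc_convex_area <- function(verts, n_samples = 1.5e5) {
  xr <- range(verts[, 1]); yr <- range(verts[, 2])
  px <- stats::runif(n_samples, xr[1], xr[2])
  py <- stats::runif(n_samples, yr[1], yr[2])
  inside <- rep(TRUE, n_samples)
  n <- nrow(verts)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- verts[j, 1] - verts[i, 1]
    ey <- verts[j, 2] - verts[i, 2]
    inside <- inside & (ex * (py - verts[i, 2]) - ey * (px - verts[i, 1]) >= 0)
  }
  mean(inside) * diff(xr) * diff(yr)
}

# random convex polygon as the convex hull of m uniform points, CCW order
random_convex_polygon <- function(m = 12, scale = 10) {
  pts <- matrix(stats::runif(2 * m, -scale, scale), ncol = 2)
  hull <- grDevices::chull(pts)          # clockwise order
  verts <- pts[rev(hull), , drop = FALSE]  # reversed -> counter-clockwise
  verts
}

# signed shoelace, used only to confirm the CCW convention of the fixtures
signed_area2 <- function(v) {
  n <- nrow(v)
  sum(v[, 1] * v[c(2:n, 1), 2] - v[c(2:n, 1), 1] * v[, 2])
}

# --- Fisher exact enumeration oracle (r x c, full enumeration) ------------

# all tables with the observed margins, probability by the multivariate
# hypergeometric; p = sum of probabilities <= observed probability.
# Returns list(p, total_prob) so tests can also assert the probabilities
# sum to 1 over the enumeration.
fisher_enum <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  log_prob <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(m))
  }
  # all ways to fill one row of length nc summing to s with cell j <= cap[j]
  row_fills <- function(s, cap) {
    nc <- length(cap)
    if (nc == 1) {
      if (s <= cap[1]) return(list(s)) else return(list())
    }
    out <- list()
    for (v in 0:min(s, cap[1])) {
      for (rest in row_fills(s - v, cap[-1])) {
        out[[length(out) + 1]] <- c(v, rest)
      }
    }
    out
  }
  tables <- list()
  fill <- function(rows_done, col_left, row_idx) {
    if (row_idx > length(rs)) {
      tables[[length(tables) + 1]] <<- do.call(rbind, rows_done)
      return(invisible())
    }
    if (row_idx == length(rs)) {
      # last row is forced by the column margins
      if (sum(col_left) == rs[row_idx] && all(col_left >= 0)) {
        fill(c(rows_done, list(col_left)), col_left * 0, row_idx + 1)
      }
      return(invisible())
    }
    for (r in row_fills(rs[row_idx], col_left)) {
      fill(c(rows_done, list(r)), col_left - r, row_idx + 1)
    }
  }
  fill(list(), cs, 1)
  probs <- vapply(tables, function(m) exp(log_prob(m)), numeric(1))
  p_obs <- exp(log_prob(tab))
  list(p = sum(probs[probs <= p_obs * (1 + 1e-7)]),
       total_prob = sum(probs))
}

# --- fixture builders -----------------------------------------------------

new_cycle <- function(hip, knee, stance_end = 60, pid = "t", cyc = 1L) {
  cyclogait:::.new_gait_cycle(hip, knee, stance_end, pid, cyc)
}

# a 101-point circular cyclogram traversed clockwise, point 0 at angle 0;
# point 50 is diametrically opposite, so stance_end = 50 splits it evenly
circle_cycle <- function(r = 10, cx = 0, cy = 0, stance_end = 50) {
  th <- -2 * pi * (0:100) / 100
  new_cycle(cx + r * cos(th), cy + r * sin(th), stance_end)
}

# trace evaluated at arbitrary gait phases (template waveform, fixed ROM)
trace_from_phases <- function(phases, profile, sample_rate = 100) {
  shp <- cyclogait:::.cycle_shape(phases %% 1, profile$hip_rom_mean,
                                  profile$knee_rom_mean,
                                  profile$stance_fraction,
                                  profile$hyperextension_deg)
  structure(
    list(
      time = (seq_along(phases) - 1) / sample_rate,
      hip_deg = shp$hip_deg, knee_deg = shp$knee_deg,
      events = data.frame(event = character(0), sample_index = integer(0)),
      sample_rate = sample_rate, participant_id = "tpl", group = "tpl"
    ),
    class = "joint_angle_trace"
  )
}

# plain-profile shortcut with deterministic defaults
quiet_profile <- function(name = "t", hip = 45, knee = 57, sf = 0.6,
                          dur = 1.1, cv = 0, sd_b = 0, hyper = 0,
                          n = 1, cycles = 10) {
  gait_profile(name, hip_rom_mean = hip, knee_rom_mean = knee,
               hip_rom_sd_between = sd_b, knee_rom_sd_between = sd_b,
               stance_fraction = sf, cycle_duration_mean = dur,
               rom_cv_within = cv, hyperextension_deg = hyper,
               n_participants = n, n_cycles_per_participant = cycles)
}
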
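test_that("rom is max minus min", {
  expect_equal(rom(c(10, 20, 5)), 15)
  expect_equal(rom(rep(4.2, 50)), 0)
  expect_error(rom(numeric(0)), "nonempty")
  hip <- base_cycle_shape(seq(0, 1, length.out = 101),
                          default_profiles()$control)$hip_deg
  expect_equal(rom(hip), 45.51, tolerance = 0.1 / 45.51)
})

test_that("path_length matches closed forms", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(path_length(square, close = TRUE), 4, tolerance = 1e-12)
  expect_equal(path_length(rbind(c(0, 0), c(3, 4))), 5, tolerance = 1e-12)
  n <- 360; r <- 10
  th <- 2 * pi * (0:(n - 1)) / n
  ngon <- cbind(r * cos(th), r * sin(th))
  expect_equal(path_length(ngon, close = TRUE), 2 * n * r * sin(pi / n),
               tolerance = 1e-9)
  expect_equal(path_length(ngon, close = TRUE), 2 * pi * r, tolerance = 1e-4)
  expect_error(path_length(rbind(c(1, 1))), "2 points")
})

test_that("polygon_area matches closed forms and the Monte-Carlo oracle", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))), 0)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 points")
  set.seed(77)
  for (i in 1:10) {
    v <- random_convex_polygon(12)
    a_mc <- mc_convex_area(v, n_samples = 2e5)
    expect_equal(polygon_area(v), a_mc, tolerance = 0.01)
  }
})

test_that("build_cyclogram carries points and landmarks faithfully", {
  x <- seq(-10, 30, length.out = 101)
  diag_cy <- new_cycle(x, x, 55)
  cg <- build_cyclogram(diag_cy)
  expect_true(all(cg$points[, 1] == cg$points[, 2]))
  expect_equal(cg$stance_end_index, 55L)
  const <- build_cyclogram(new_cycle(rep(5, 101), rep(9, 101), 60))
  expect_true(all(const$points[, 1] == 5) && all(const$points[, 2] == 9))
  # heel-strike posture of the control template
  p <- default_profiles()$control
  shp <- base_cycle_shape(seq(0, 1, length.out = 101), p)
  cg2 <- build_cyclogram(new_cycle(shp$hip_deg, shp$knee_deg, 60))
  expect_gt(cg2$points[1, 1], 0.95 * max(cg2$points[, 1]))
  expect_lt(abs(cg2$points[1, 2]), 1e-9)
})

test_that("phase partition: perimeters add exactly, symmetric areas split evenly", {
  # symmetric closed curve split at its midpoint
  circ <- build_cyclogram(circle_cycle(r = 8, stance_end = 50))
  pp <- phase_params(circ)
  expect_equal(pp$area_stance, pp$area_swing, tolerance = 1e-9)
  expect_equal(pp$perimeter_stance + pp$perimeter_swing, pp$perimeter_total,
               tolerance = 1e-12)
  expect_equal(pp$perimeter_total, path_length(circ$points, close = TRUE),
               tolerance = 1e-12)
  # collinear stance arc: zero area but positive length
  hip <- c(seq(0, 10, length.out = 61), 10 + 5 * sin(pi * (0:39) / 40))
  knee <- c(seq(0, 20, length.out = 61), 20 * cos(pi * (0:39) / 40 / 2))
  flat <- phase_params(build_cyclogram(new_cycle(hip, knee, 60)),
                       warn_self_intersect = FALSE)
  expect_equal(flat$area_stance, 0, tolerance = 1e-9)
  expect_gt(flat$perimeter_stance, 0)
  # degenerate boundaries rejected
  bad <- build_cyclogram(circle_cycle())
  bad$stance_end_index <- 0L
  expect_error(phase_params(bad), "between 0 and 100")
})

test_that("swing loop dominates stance area for the control template", {
  p <- default_profiles()$control
  shp <- base_cycle_shape(seq(0, 1, length.out = 101), p)
  pp <- phase_params(build_cyclogram(new_cycle(shp$hip_deg, shp$knee_deg, 60)),
                     warn_self_intersect = FALSE)
  expect_gt(pp$area_swing, 3 * pp$area_stance)
})

test_that("geometry is equivariant under scaling, translation, reversal", {
  set.seed(5)
  for (i in 1:5) {
    hip <- cumsum(rnorm(101)); knee <- cumsum(rnorm(101))
    cy <- build_cyclogram(new_cycle(hip, knee, 40 + i * 5))
    pp <- phase_params(cy, warn_self_intersect = FALSE)
    c_s <- 3.7
    sc <- build_cyclogram(new_cycle(c_s * hip, c_s * knee, 40 + i * 5))
    ps <- phase_params(sc, warn_self_intersect = FALSE)
    expect_equal(ps$perimeter_total / pp$perimeter_total, c_s, tolerance = 1e-9)
    expect_equal(ps$area_total / pp$area_total, c_s^2, tolerance = 1e-9)
    expect_equal(ps$hip_rom / pp$hip_rom, c_s, tolerance = 1e-9)
    tr <- build_cyclogram(new_cycle(hip + 112, knee - 55, 40 + i * 5))
    pt <- phase_params(tr, warn_self_intersect = FALSE)
    for (f in c("perimeter_stance", "perimeter_swing", "perimeter_total",
                "area_stance", "area_swing", "area_total",
                "hip_rom", "knee_rom")) {
      expect_equal(pt[[f]], pp[[f]], tolerance = 1e-9)
    }
    pts <- cy$points
    expect_equal(path_length(pts[101:1, ], close = TRUE),
                 path_length(pts, close = TRUE), tolerance = 1e-12)
    expect_equal(polygon_area(pts[101:1, ]), polygon_area(pts),
                 tolerance = 1e-12)
  }
})

test_that("segment lengths equal dt times mean angular speed", {
  set.seed(9)
  hip <- cumsum(rnorm(50)); knee <- cumsum(rnorm(50))
  dt <- runif(49, 0.005, 0.02)
  wh <- diff(hip) / dt; wk <- diff(knee) / dt
  expect_equal(path_length(cbind(hip, knee)),
               sum(dt * sqrt(wh^2 + wk^2)), tolerance = 1e-12)
})

test_that("self-intersecting loops are flagged", {
  # bow-tie: two opposing lobes crossing at the center
  t <- seq(0, 2 * pi, length.out = 102)[-102]
  hip <- 10 * sin(t); knee <- 10 * sin(2 * t)
  expect_warning(phase_params(build_cyclogram(new_cycle(hip, knee, 50))),
                 "self-intersect")
  # a plain convex loop is not
  expect_silent(phase_params(build_cyclogram(circle_cycle())))
})

test_that("participant_params averages per-cycle parameters", {
  p <- quiet_profile(cv = 0, cycles = 4)
  cycles <- segment_cycles(generate_participant(p, 2))
  out <- participant_params(cycles)
  expect_equal(nrow(out$per_cycle), 4)
  for (f in cyclogram_param_names()) {
    expect_equal(out$mean[[f]], mean(out$per_cycle[[f]]))
    # zero-noise construction: per-cycle params constant to < 0.1%
    expect_lt(diff(range(out$per_cycle[[f]])) / mean(out$per_cycle[[f]]),
              0.001)
  }
  expect_error(participant_params(list()), "no cycles")
})
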
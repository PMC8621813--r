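make_trace <- function(hip, knee, events, rate = 100) {
  structure(
    list(time = (seq_along(hip) - 1) / rate, hip_deg = hip, knee_deg = knee,
         events = events, sample_rate = rate,
         participant_id = "m", group = "m"),
    class = "joint_angle_trace"
  )
}

alt_events <- function(hs, to) {
  n <- length(to)
  data.frame(
    event = c(rbind(rep("heel_strike", n), rep("toe_off", n)), "heel_strike"),
    sample_index = as.integer(c(rbind(hs[seq_len(n)], to), hs[n + 1])),
    stringsAsFactors = FALSE
  )
}

test_that("heel-strike pairs with toe-off at 60% give stance boundary 60", {
  n <- 300
  hip <- sin(2 * pi * (0:(n - 1)) / 100) * 20
  knee <- cos(2 * pi * (0:(n - 1)) / 100) * 25 + 25
  ev <- alt_events(hs = c(1, 101, 201), to = c(61, 161))
  cycles <- segment_cycles(make_trace(hip, knee, ev))
  expect_length(cycles, 2)
  expect_equal(vapply(cycles, `[[`, integer(1), "stance_end_index"), c(60L, 60L))
  expect_length(cycles[[1]]$hip_deg, 101)
  # constant-angle trace stays constant after resampling
  cyc_const <- segment_cycles(make_trace(rep(7, n), rep(-2, n), ev))
  expect_true(all(abs(cyc_const[[1]]$hip_deg - 7) < 1e-12))
  expect_true(all(abs(cyc_const[[1]]$knee_deg + 2) < 1e-12))
})

test_that("per-cycle ROM recovery matches the generator's construction draws", {
  p <- default_profiles(n_cycles_per_participant = 20)$control
  tr <- generate_participant(p, 31)
  gt <- attr(tr, "per_cycle_rom")
  cycles <- segment_cycles(tr)
  expect_length(cycles, 20)
  rec_h <- vapply(cycles, function(cy) rom(cy$hip_deg), numeric(1))
  rec_k <- vapply(cycles, function(cy) rom(cy$knee_deg), numeric(1))
  expect_lt(max(abs(rec_h - gt$hip_rom)), 0.05)
  expect_lt(max(abs(rec_k - gt$knee_rom)), 0.05)
})

test_that("resampling a trace already on the normalized grid is the identity", {
  hip <- cumsum(rnorm(101)); knee <- cumsum(rnorm(101))
  ev <- alt_events(hs = c(1, 101), to = 61)
  cy <- segment_cycles(make_trace(hip, knee, ev))[[1]]
  expect_lt(max(abs(cy$hip_deg - hip)), 1e-9)
  expect_lt(max(abs(cy$knee_deg - knee)), 1e-9)
  expect_equal(cy$stance_end_index, 60L)
})

test_that("segmentation is invariant to uniform time shifts", {
  p <- quiet_profile(cv = 3, cycles = 5)
  tr <- generate_participant(p, 17)
  shifted <- tr
  shifted$time <- tr$time + 13.7
  a <- segment_cycles(tr)
  b <- segment_cycles(shifted)
  expect_equal(length(a), length(b))
  expect_equal(a[[3]]$hip_deg, b[[3]]$hip_deg, tolerance = 1e-12)
  # cycle count = heel strikes - 1 for well-formed events
  n_hs <- sum(tr$events$event == "heel_strike")
  expect_length(a, n_hs - 1)
})

test_that("malformed events fail loudly, sparse events fail softly", {
  hip <- rep(1, 50); knee <- rep(1, 50)
  bad <- data.frame(event = c("heel_strike", "heel_strike", "toe_off"),
                    sample_index = c(1L, 10L, 20L))
  expect_error(segment_cycles(make_trace(hip, knee, bad)), "event 2")
  unsorted <- data.frame(event = c("heel_strike", "toe_off"),
                         sample_index = c(30L, 10L))
  expect_error(segment_cycles(make_trace(hip, knee, unsorted)),
               "increasing")
  one_hs <- data.frame(event = "heel_strike", sample_index = 5L)
  expect_warning(out <- segment_cycles(make_trace(hip, knee, one_hs)),
                 "fewer than 2")
  expect_length(out, 0)
})

test_that("event detection recovers construction events on clean traces", {
  p <- default_profiles(n_cycles_per_participant = 8)$control
  tr <- generate_participant(p, 41)
  ev <- detect_events(tr)
  hs_d <- ev$sample_index[ev$event == "heel_strike"]
  hs_c <- tr$events$sample_index[tr$events$event == "heel_strike"]
  to_d <- ev$sample_index[ev$event == "toe_off"]
  to_c <- tr$events$sample_index[tr$events$event == "toe_off"]
  expect_length(hs_d, length(hs_c))
  expect_length(to_d, length(to_c))
  expect_lte(max(abs(hs_d - hs_c)), 3)
  expect_lte(max(abs(to_d - to_c)), 3)
})

test_that("detector handles flat and short traces gracefully", {
  flat <- make_trace(rep(3, 200), rep(1, 200),
                     data.frame(event = character(0),
                                sample_index = integer(0)))
  expect_warning(ev <- detect_events(flat), "no qualifying")
  expect_equal(nrow(ev), 0)
})

test_that("detector finds two heel strikes and two toe-offs in two clean cycles", {
  # a recording that starts and ends mid-swing, covering two full cycles
  phases <- seq(0.7, 2.7, by = 1 / 110)[-1]
  tr <- trace_from_phases(phases, quiet_profile())
  ev <- detect_events(tr)
  expect_equal(sum(ev$event == "heel_strike"), 2)
  expect_equal(sum(ev$event == "toe_off"), 2)
  tr$events <- ev
  expect_length(segment_cycles(tr), 1)
})

test_that("mean_cycle averages pointwise and preserves structure", {
  hip <- sin(seq(0, 2 * pi, length.out = 101)) * 15
  knee <- cos(seq(0, 2 * pi, length.out = 101)) * 20 + 20
  a <- new_cycle(hip, knee, 60)
  expect_equal(mean_cycle(list(a, a, a))$hip_deg, hip)
  # antisymmetric pair cancels
  b <- new_cycle(-hip, knee, 62)
  m <- mean_cycle(list(a, b))
  expect_true(all(abs(m$hip_deg) < 1e-12))
  expect_equal(m$stance_end_index, 61L)
  expect_error(mean_cycle(list()), "no cycles")
})

test_that("the mean of noisy cycles approaches the template trajectory", {
  p <- quiet_profile(cv = 5, cycles = 50)
  cycles <- segment_cycles(generate_participant(p, 8))
  m <- mean_cycle(cycles)
  se_rom <- 0.05 * p$hip_rom_mean / sqrt(50)
  expect_lt(abs(rom(m$hip_deg) - p$hip_rom_mean), 2 * se_rom + 0.05)
})
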
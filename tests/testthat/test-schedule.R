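test_that("tilt range and oscillation angle reproduce the logged values", {
  expect_equal(tilt_range(-64.06, 63.91), 127.97)
  expect_equal(tilt_range(-43.90, 58.65), 102.55)
  expect_equal(tilt_range(5, 5), 0)
  # data set 2: printed 0.2336; the formula gives 0.23367 (one ulp of the
  # printed precision — the published inputs are themselves rounded)
  expect_equal(oscillation_angle(102.55, 224.7, 0.512), 0.2336,
               tolerance = 1e-4 / 0.2336)
  expect_equal(oscillation_angle(10, 10, 1), 1.0)
  # data set 1: the formula value, not the printed rounding
  expect_equal(round(oscillation_angle(127.97, 283.0, 0.512), 4), 0.2315)
  expect_error(oscillation_angle(100, 0, 0.5), "positive")
})

test_that("schedule interleaves one defocus slot per n_interval data frames", {
  s <- build_schedule(430, 10)
  expect_equal(s$n_defocus, 43L)
  expect_equal(nrow(s$slots), 473L)
  expect_equal(which(s$slots$kind == "defocus_tracking"), 11 * (1:43))
  s1 <- build_schedule(554, 10)
  expect_equal(s1$n_defocus, 55L)             # 55 full cycles + 4 trailing
  expect_equal(nrow(s1$slots), 609L)
  expect_equal(tail(s1$slots$kind, 4), rep("data", 4))
  s2 <- build_schedule(5, 10)
  expect_equal(s2$n_defocus, 0L)              # no complete cycle
  expect_error(build_schedule(0, 10), ">= 1")
  expect_error(build_schedule(10, 0), ">= 1")
})

test_that("slot angles tile the rotation exactly with equal gaps", {
  s <- build_schedule(97, 7, frame_time = 0.512, start_angle = -20,
                      rotation_speed = 0.45)
  osc <- 0.45 * 0.512
  sweep <- s$slots$angle_end - s$slots$angle_start
  expect_equal(sweep, rep(osc, nrow(s$slots)))
  expect_equal(sum(sweep), osc * nrow(s$slots))
  expect_equal(s$slots$angle_start[-1], s$slots$angle_end[-nrow(s$slots)])
  # every gap spans exactly one frame oscillation
  gaps <- s$slots[s$slots$kind == "defocus_tracking", ]
  expect_equal(gaps$angle_end - gaps$angle_start, rep(osc, nrow(gaps)))
  # the 0.2 s delay shifts the time origin only
  expect_equal(s$slots$time_start[1], 0.2)
  expect_equal(diff(s$slots$time_start), rep(0.512, nrow(s$slots) - 1))
})

test_that("excluded ranges enumerate the defocus slots", {
  s <- build_schedule(430, 10)
  exc <- excluded_ranges(s)
  expect_equal(nrow(exc), 43L)
  expect_true(all(exc[, "first"] == exc[, "last"]))   # singletons
  expect_equal(exc[, "first"], 11 * (1:43), ignore_attr = TRUE)
  # no defocus slots -> empty
  expect_equal(nrow(excluded_ranges(build_schedule(5, 10))), 0L)
  # n_interval = 1: slots d,D,d,D -> singletons {2},{4}
  s2 <- build_schedule(2, 1)
  exc2 <- excluded_ranges(s2)
  expect_equal(unname(exc2[, "first"]), c(2L, 4L))
  expect_equal(unname(exc2[, "last"]), c(2L, 4L))
})

test_that("DIALS scan_range is the exact complement of exclude_images", {
  s <- build_schedule(430, 10)
  ex <- dials_exclusions(s)
  expect_equal(unname(ex$scan_range[1, ]), c(1L, 10L))
  expect_equal(unname(ex$scan_range[2, ]), c(12L, 21L))
  # no gaps: a single run
  ex0 <- dials_exclusions(build_schedule(7, 10))
  expect_equal(unname(ex0$scan_range), cbind(1L, 7L), ignore_attr = TRUE)
  # alternating schedule: data runs of length 1
  ex1 <- dials_exclusions(build_schedule(3, 1))
  expect_true(all(ex1$scan_range[, "first"] == ex1$scan_range[, "last"]))
  # partition property over a grid of schedules
  for (n_data in c(1, 7, 30, 101)) {
    for (n_int in c(1, 3, 10, 12)) {
      sch <- build_schedule(n_data, n_int)
      n_slots <- nrow(sch$slots)
      p <- dials_exclusions(sch)
      covered <- c(
        unlist(apply(p$scan_range, 1, function(r) r[1]:r[2], simplify = FALSE)),
        if (nrow(p$exclude_images) > 0)
          unlist(apply(p$exclude_images, 1, function(r) r[1]:r[2],
                       simplify = FALSE)))
      expect_equal(sort(covered), 1:n_slots)
    }
  }
})

test_that("rotation metadata assembles the derived quantities", {
  s <- build_schedule(430, 10, frame_time = 0.512, start_angle = -43.90,
                      rotation_speed = 102.55 / 224.7)
  md <- rotation_metadata(s, total_time = 224.7, camera_length = 250,
                          aperture_radius = 0.35)
  expect_equal(md$n_data_frames, 430L)
  expect_equal(md$n_defocus_frames, 43L)
  expect_equal(md$oscillation_angle,
               oscillation_angle(md$tilt_range, 224.7, 0.512))
  expect_output(print(md), "430 data frames")
})
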
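test_that("preprocessing meets its contract on arbitrary input", {
  set.seed(3)
  # constant pattern: no contrast -> all zeros
  out <- preprocess_pattern(matrix(7, 516, 516))
  expect_equal(dim(out), c(150L, 150L))
  expect_true(all(out == 0))
  # generic noisy pattern: shape and range
  z <- matrix(rpois(516 * 516, 5), 516, 516)
  out <- preprocess_pattern(z)
  expect_equal(dim(out), c(150L, 150L))
  expect_true(all(out >= 0 & out <= 1))
  # capping bound holds on the crop before scaling
  crop <- crop_about_beam(z, attr(out, "beam_center"), 400)
  capped <- cap_intensity(crop, 4)
  expect_lte(max(capped), mean(crop) + 4 * sd(as.vector(crop)) + 1e-9)
})

test_that("crop centres the beam and zero-pads outside the frame", {
  z <- matrix(0, 516, 516)
  z[101, 101] <- 1000  # blob at (x = 101, y = 101), near the corner
  w <- crop_about_beam(z, c(100, 100), 400)
  expect_equal(dim(w), c(400L, 400L))
  # window rows are y in [-99, 300]: out-of-bounds part is zero padding
  expect_equal(sum(w), 1000)
  expect_equal(w[202, 202], 1000)  # (101,101) lands at offset +101 from -100
  # a centred blob survives preprocessing near the output centre
  zb <- matrix(rpois(516 * 516, 1), 516, 516)
  zb[246:266, 246:266] <- 5000
  out <- preprocess_pattern(zb)
  ctr <- out[70:80, 70:80]
  expect_gt(mean(ctr), mean(out) * 5)
})

test_that("feature scaling and same-size resize are idempotent stages", {
  set.seed(4)
  z <- matrix(runif(100), 10, 10)
  s1 <- feature_scale(z)
  expect_equal(feature_scale(s1), s1)
  expect_true(all(s1 >= 0 & s1 <= 1) && min(s1) == 0 && max(s1) == 1)
  expect_equal(resize_area(s1, c(10, 10)), s1)
  # area resize preserves the mean and never leaves the input range
  big <- matrix(runif(400 * 400), 400, 400)
  small <- resize_area(big, c(150, 150))
  expect_equal(mean(small), mean(big), tolerance = 1e-3)
  expect_true(all(small >= min(big) - 1e-12 & small <= max(big) + 1e-12))
})

test_that("isolation filter applies the distance rules exactly", {
  frame <- c(-5, 15, -5, 15)
  pos <- rbind(c(0, 0), c(1.0, 0), c(10, 10))
  keep <- isolation_filter(pos, frame)
  expect_equal(keep, c(FALSE, FALSE, TRUE))  # both close-pair members go
  expect_equal(isolation_filter(matrix(numeric(0), 0, 2), frame), logical(0))
  # single crystal 0.4 um from an edge is discarded
  expect_false(isolation_filter(rbind(c(-4.6, 5)), frame))
  expect_true(isolation_filter(rbind(c(0, 5)), frame))
  expect_error(isolation_filter(rbind(c(NA, 1)), frame), "finite")
})

test_that("isolation filter agrees with the brute-force oracle", {
  set.seed(99)
  frame <- c(0, 20, 0, 20)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    pos <- cbind(runif(n, -1, 21), runif(n, -1, 21))
    expect_equal(isolation_filter(pos, frame),
                 oracle_isolation(pos, frame))
  }
})

test_that("candidate CSV round-trips with the documented format", {
  set.seed(5)
  n <- 100
  cand <- crystal_candidates(
    image_path = sprintf("images/img_%03d.tiff", sample(1:50, n, TRUE)),
    image_seq = sample(1:50, n, TRUE), crystal_seq = 1:n,
    score = round(runif(n), 4), object_size = round(runif(n, 0.2, 2), 6),
    stage_x = round(runif(n, 0, 200), 3), stage_y = round(runif(n, 0, 200), 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_candidates(cand, path)
  lines <- readLines(path)
  expect_length(lines, n + 1)
  expect_equal(strsplit(lines[1], ",")[[1]],
               c("image_path", "image_seq", "crystal_seq", "score",
                 "object_size", "stage_x", "stage_y"))
  # scores are printed with 4 decimals
  expect_match(lines[2], ",[0-9]\\.[0-9]{4},")
  back <- read_candidates(path)
  expect_equal(as.data.frame(back), as.data.frame(cand))
  expect_error(crystal_candidates("a", 1, 1, 1.2, 1, 0, 0), "\\[0, 1\\]")
})
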
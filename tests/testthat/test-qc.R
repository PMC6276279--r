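make_frames <- function(scales, base = 40, size = 64, center = c(32, 32),
                        seed = 17) {
  set.seed(seed)
  lapply(seq_along(scales), function(i) {
    lam <- matrix(base * scales[i], size, size)
    lam[30:34, 30:34] <- 5000  # central beam, excluded by the QC mask
    detector_frame(matrix(rpois(size * size, lam), size, size),
                   kind = "data", frame_index = i)
  })
}

test_that("scale series normalizes to the median and tracks attenuation", {
  # constant series: all scales ~1 (exactly 1 without noise)
  frames <- lapply(1:5, function(i)
    detector_frame(matrix(10, 64, 64), frame_index = i))
  s <- scale_series(frames, c(32, 32), beam_exclusion_radius = 5)
  expect_equal(s$scale, rep(1, 5))
  # planted linear attenuation 1 -> 0.2: monotone decreasing scale,
  # strongly correlated with the planted profile
  planted <- seq(1, 0.2, length.out = 30)
  s2 <- scale_series(make_frames(planted), c(32, 32),
                     beam_exclusion_radius = 8)
  expect_gt(cor(s2$scale, planted, method = "pearson"), 0.9)
  expect_lt(mean(diff(s2$scale) > 0), 0.2)  # noise aside, decreasing
  # fully obscured frame: scale < 0.05
  fr3 <- make_frames(c(1, 1, 1, 1))
  dark <- matrix(0, 64, 64); dark[30:34, 30:34] <- 5000
  fr3[[3]] <- detector_frame(dark, frame_index = 3L)
  s3 <- scale_series(fr3, c(32, 32), beam_exclusion_radius = 8)
  expect_lt(s3$scale[3], 0.05)
  expect_error(scale_series(frames[1], c(32, 32)), "at least 2")
})

test_that("scale series statistic is scale-invariant and permutable", {
  planted <- c(1, 0.9, 0.7, 0.9, 1, 0.5, 0.4, 1, 1, 0.8)
  f1 <- make_frames(planted, seed = 3)
  s1 <- scale_series(f1, c(32, 32), beam_exclusion_radius = 8)
  # global multiplication of all frames leaves scales unchanged
  f2 <- lapply(f1, function(f) { f$pixels <- f$pixels * 7; f })
  s2 <- scale_series(f2, c(32, 32), beam_exclusion_radius = 8)
  expect_equal(s2$scale, s1$scale)
  # permuting frames permutes scales identically
  perm <- c(3, 1, 4, 2, 9, 10, 6, 5, 8, 7)
  s3 <- scale_series(f1[perm], c(32, 32), beam_exclusion_radius = 8)
  expect_equal(s3$scale, s1$scale[perm])
  # defocus frames are ignored by the statistic
  f4 <- append(f1, list(detector_frame(matrix(0, 64, 64),
                                       kind = "defocus_tracking",
                                       frame_index = 99L)), after = 2)
  s4 <- scale_series(f4, c(32, 32), beam_exclusion_radius = 8)
  expect_equal(s4$scale, s1$scale)
})

test_that("tracking verdict distinguishes dips, spikes and flat series", {
  mk <- function(scales) {
    s <- data.frame(frame_index = seq_along(scales), scale = scales)
    class(s) <- c("scale_series", "data.frame")
    s
  }
  flat <- mk(rep(1, 50) + seq(-0.02, 0.02, length.out = 50))
  v <- tracking_flags(flat)
  expect_equal(sum(v$flags), 0L)
  expect_equal(v$verdict, "tracked")
  # 10-frame dip to 0.3: poorly tracked
  dip <- mk(c(rep(1, 20), rep(0.3, 10), rep(1, 20)))
  expect_equal(tracking_flags(dip)$verdict, "poorly tracked")
  # single-frame spike (grid shadow): flagged but the verdict holds
  spike <- mk(c(rep(1, 30), 0.1, rep(1, 19)))
  vs <- tracking_flags(spike, cv_cutoff = 0.3)
  expect_equal(sum(vs$flags), 1L)
  expect_equal(vs$verdict, "tracked")
  # rapidly varying scale trips the coefficient-of-variation rule
  wild <- mk(rep(c(1.8, 0.55), 25))
  expect_equal(tracking_flags(wild)$verdict, "poorly tracked")
})

test_that("scale series CSV output is plot-ready", {
  planted <- c(1, 1, 0.4, 1, 1)
  s <- scale_series(make_frames(planted, seed = 5), c(32, 32),
                    beam_exclusion_radius = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scale_series(s, path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("frame", "scale", "flag"))
  expect_equal(tab$flag[3], 1L)
  expect_output(print(s), "data frames")
})
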
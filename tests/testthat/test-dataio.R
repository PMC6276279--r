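test_that("SMV frames round-trip bit-exactly with clamping", {
  set.seed(21)
  px <- matrix(sample(0:65535, 516 * 516, TRUE), 516, 516)
  path <- withr::local_tempfile(fileext = ".img")
  write_smv(px, smv_header(osc_start = -43.90, osc_range = 0.2336), path)
  back <- read_smv(path)
  expect_identical(back$pixels, px)
  expect_equal(back$header$SIZE1, 516)
  expect_equal(back$header$OSC_RANGE, 0.2336)
  expect_equal(back$header$WAVELENGTH, 0.02508)
  # overload clamp
  path2 <- withr::local_tempfile(fileext = ".img")
  write_smv(matrix(70000, 4, 4), smv_header(), path2)
  expect_true(all(read_smv(path2)$pixels == 65535))
  # header osc_range derived from the schedule formula
  h <- smv_header(osc_range = oscillation_angle(102.55, 224.7, 0.512))
  path3 <- withr::local_tempfile(fileext = ".img")
  write_smv(matrix(0, 4, 4), h, path3)
  expect_equal(read_smv(path3)$header$OSC_RANGE, 0.2337)  # %.4f of 0.23367
  # deterministic bytes
  p4 <- withr::local_tempfile(); p5 <- withr::local_tempfile()
  write_smv(px, smv_header(), p4); write_smv(px, smv_header(), p5)
  expect_identical(unname(tools::md5sum(p4)), unname(tools::md5sum(p5)))
})

test_that("malformed SMV headers fail with a parse diagnostic", {
  path <- withr::local_tempfile(fileext = ".img")
  con <- file(path, "wb")
  hdr <- charToRaw("{\nGARBAGE WITHOUT EQUALS;\nSIZE1=4;\n}\n")
  writeBin(c(hdr, raw(512 - length(hdr))), con)
  writeBin(integer(16), con, size = 2)
  close(con)
  expect_error(read_smv(path), "SIZE2|parse")
})

test_that("GEO_CORR SMV files carry signed offsets losslessly", {
  m <- distortion_model(0.22, azimuth = 25, center = c(33, 30))
  tab <- geo_corr_tables(m, shape = c(64, 64))
  expect_true(any(tab$x < 0) && any(tab$x > 0))  # genuinely signed
  dir <- withr::local_tempdir()
  paths <- write_geo_corr_smv(tab, dir)
  bx <- read_smv(paths[1]); by <- read_smv(paths[2])
  expect_identical(bx$pixels, tab$x)
  expect_identical(by$pixels, tab$y)
  expect_equal(bx$header$TYPE, "signed_short")
})

test_that("MRC and TIFF writers round-trip frames and metadata", {
  set.seed(22)
  px <- matrix(rpois(128 * 96, 50), 96, 128)  # non-square on purpose
  pm <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(px, pm)
  bm <- read_mrc(pm)
  expect_equal(bm$pixels, px, tolerance = 1e-7)  # float32 storage
  expect_equal(bm$header$nx, 128)
  pt <- withr::local_tempfile(fileext = ".tiff")
  write_tiff16(px, pt, metadata = list(exposure = 0.5, frame = 3))
  bt <- read_tiff16(pt)
  expect_identical(bt$pixels, px)
  expect_equal(bt$metadata$exposure, 0.5)
})

test_that("XDS.INP encodes schedule, masking and distortion consistently", {
  sched <- build_schedule(430, 10, frame_time = 0.512, start_angle = -43.90,
                          rotation_speed = 102.55 / 224.7)
  beam <- beam_parameters(200, 250, 55)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "XDS.INP")
  write_xds_inp(sched, c(257.8, 255.2), beam, path,
                distortion = distortion_model(0.22))
  lines <- readLines(path)
  expect_length(grep("^EXCLUDE_DATA_RANGE=", lines), 43L)
  expect_equal(grep("EXCLUDE_DATA_RANGE= 11 11", lines, fixed = TRUE,
                    value = TRUE), "EXCLUDE_DATA_RANGE= 11 11")
  expect_match(lines[grep("^WAVELENGTH", lines)], "0.02508", fixed = TRUE)
  expect_match(lines[grep("^DATA_RANGE", lines)], "1 473", fixed = TRUE)
  expect_match(lines[grep("^NX", lines)],
               "NX= 516 NY= 516 QX= 0.0550 QY= 0.0550", fixed = TRUE)
  expect_length(grep("^UNTRUSTED_RECTANGLE= 255 262 0 517", lines), 1L)
  expect_length(grep("GEO_CORR", lines), 2L)
  # identity distortion: no GEO_CORR lines
  path0 <- file.path(dir, "XDS0.INP")
  write_xds_inp(sched, c(258, 258), beam, path0,
                distortion = distortion_model(0))
  expect_length(grep("GEO_CORR", readLines(path0)), 0L)
  # oscillation printed at 4 decimals from the schedule
  osc_line <- grep("^OSCILLATION_RANGE", lines, value = TRUE)
  expect_equal(osc_line, sprintf("OSCILLATION_RANGE= %.4f",
                                 102.55 / 224.7 * 0.512))
  # refusal without a beam centre
  expect_error(write_xds_inp(sched, NULL, beam, tempfile()), "beam-centre")
})

test_that("DIALS parameter files round-trip the exclusion ranges", {
  sched <- build_schedule(430, 10)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dials.phil")
  write_dials_params(sched, p)
  lines <- readLines(p)
  expect_length(grep("^exclude_images=", lines), 43L)
  back <- parse_dials_params(p)
  ex <- dials_exclusions(sched)
  expect_equal(back$scan_range, ex$scan_range, ignore_attr = TRUE)
  expect_equal(back$exclude_images, ex$exclude_images, ignore_attr = TRUE)
  # no gaps: single scan_range token
  p0 <- file.path(dir, "dials0.phil")
  write_dials_params(build_schedule(8, 10), p0)
  expect_equal(grep("^scan_range", readLines(p0), value = TRUE),
               "scan_range=1,8")
})

test_that("REDp table lists data frames at mid-slot angles", {
  s <- build_schedule(10, 99, frame_time = 1, start_angle = 0,
                      rotation_speed = 1)  # 10 data slots, 1 deg/frame
  dir <- withr::local_tempdir()
  p <- file.path(dir, "redp.txt")
  write_redp(s, p)
  tab <- read.table(p, comment.char = "#", col.names = c("frame", "angle"))
  expect_equal(tab$angle, seq(0.5, 9.5, 1))
  expect_true(all(diff(tab$angle) > 0))
  # negative rotation: monotone decreasing
  s2 <- build_schedule(5, 99, frame_time = 1, rotation_speed = -1)
  write_redp(s2, p)
  tab2 <- read.table(p, comment.char = "#", col.names = c("frame", "angle"))
  expect_true(all(diff(tab2$angle) < 0))
})

test_that("experiment logs round-trip and directories never collide", {
  root <- withr::local_tempdir()
  d1 <- new_experiment_dir(root)
  d2 <- new_experiment_dir(root)
  expect_equal(basename(d1), "exp_000001")
  expect_equal(basename(d2), "exp_000002")
  # rotation speed chosen so the 609 slots sweep exactly -64.06..63.91 deg
  s <- build_schedule(554, 10, frame_time = 0.512, start_angle = -64.06,
                      rotation_speed = tilt_range(-64.06, 63.91) /
                        (609 * 0.512))
  md <- rotation_metadata(s, total_time = 283.0, camera_length = 250)
  expect_equal(md$tilt_range, 127.97)
  p <- file.path(d1, "cRED_log.yaml")
  write_experiment_log(md, p)
  back <- read_experiment_log(p)
  expect_equal(back$tilt_range, 127.97, tolerance = 1e-9)
  expect_equal(back$n_data_frames, 554L)
  expect_equal(back$camera_length, 250)
})
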
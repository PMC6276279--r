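test_that("spot projection follows the small-angle camera equation", {
  # cubic a = 10 A at L = 1000 mm: first-order spots at
  # r = L * lambda / d = 1000 * 0.02508 / 10 = 2.508 mm = 45.6 px @ 55 um
  sched <- build_schedule(3, 99, frame_time = 1, start_angle = -0.5,
                          rotation_speed = 1)
  exp <- synthetic_experiment(cell = c(10, 10, 10, 90, 90, 90),
                              camera_length = 1000, d_min = 2.0,
                              excitation_tol = 0.01, background = 0,
                              beam_counts = 0, seed = 5)
  sim <- simulate_rotation_series(exp, sched, size = 516)
  spots <- do.call(rbind, sim$truth$spots)
  expect_gt(nrow(spots), 0)
  first_order <- spots[abs(spots$h^2 + spots$k^2 + spots$l^2 - 1) < 1e-9, ]
  r <- sqrt((first_order$x - 258)^2 + (first_order$y - 258)^2)
  expect_true(all(abs(r - 45.6) < 1.5))
  # all spots respect the excitation tolerance by construction, and
  # frames carry Poisson-sampled counts at the truth positions
  f <- sim$frames[[1]]
  expect_s3_class(f, "detector_frame")
  expect_equal(dim(f$pixels), c(516L, 516L))
})

test_that("drift attenuates diffracted intensity via aperture overlap", {
  sched <- build_schedule(10, 99)
  # no drift: all attenuation factors are 1
  e0 <- synthetic_experiment(seed = 1)
  s0 <- simulate_rotation_series(e0, sched, size = 128)
  expect_true(all(s0$truth$attenuation == 1))
  # linear drift: attenuation is non-increasing and eventually < 1
  drift <- function(i) c(0.08 * (i - 1), 0)
  e1 <- synthetic_experiment(drift = drift, aperture_radius = 0.35,
                             crystal_radius = 0.25, seed = 1)
  s1 <- simulate_rotation_series(e1, sched, size = 128)
  att <- s1$truth$attenuation
  expect_true(all(diff(att) <= 1e-12))
  expect_lt(att[length(att)], 0.5)
  # overlap geometry oracle: concentric -> 1, far -> 0
  expect_equal(credkit:::disc_overlap_fraction(0, 0.25, 0.35), 1)
  expect_equal(credkit:::disc_overlap_fraction(5, 0.25, 0.35), 0)
  half <- credkit:::disc_overlap_fraction(0.35, 0.25, 0.35)
  expect_true(half > 0 && half < 1)
})

test_that("defocus slots render a tracking silhouette, data slots spots", {
  sched <- build_schedule(4, 2)  # d d D d d D
  e <- synthetic_experiment(seed = 3)
  s <- simulate_rotation_series(e, sched, size = 128)
  kinds <- vapply(s$frames, function(f) f$kind, character(1))
  expect_equal(kinds, sched$slots$kind)
  expect_equal(vapply(s$frames, function(f) f$frame_index, integer(1)), 1:6)
})

test_that("pattern classes are reproducible and class-separable", {
  a <- simulate_pattern_classes(3, classes = c("spots", "rings", "blank"),
                                seed = 42, size = 256)
  b <- simulate_pattern_classes(3, classes = c("spots", "rings", "blank"),
                                seed = 42, size = 256)
  expect_identical(a$images, b$images)  # byte-identical per seed
  expect_equal(a$labels, rep(c(1L, 0L, 0L), each = 3))  # rings are "bad"
  # spot-class images: at least 5 local maxima above 5 sigma of background
  img <- a$images[, , 1]
  bg <- img[img < quantile(img, 0.9)]
  thresh <- mean(bg) + 5 * sd(bg)
  sm <- gaussian_smooth(img, 1)
  # strict 8-neighbourhood local maxima above threshold
  ctr <- sm[2:255, 2:255]
  is_peak <- ctr > thresh
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_peak <- is_peak & (ctr >= sm[2:255 + dy, 2:255 + dx])
  }
  expect_gte(sum(is_peak), 5)
  # ring class: azimuthal coefficient of variation < 0.2 at the ring radius
  set.seed(1)
  ring <- a$images[, , 4]
  sm <- gaussian_smooth(ring, 2)
  ctr <- center_gaussian_max(ring, 5)$position  # primary-beam blob
  prof <- vapply(20:100, function(r) {
    th <- seq(0, 2 * pi, length.out = 181)[1:180]
    mean(sm[cbind(pmin(pmax(round(ctr[2] + r * sin(th)), 1), 256),
                  pmin(pmax(round(ctr[1] + r * cos(th)), 1), 256))])
  }, numeric(1))
  r_ring <- (20:100)[which.max(prof)]
  th <- seq(0, 2 * pi, length.out = 181)[1:180]
  vals <- sm[cbind(pmin(pmax(round(ctr[2] + r_ring * sin(th)), 1), 256),
                   pmin(pmax(round(ctr[1] + r_ring * cos(th)), 1), 256))]
  expect_lt(sd(vals) / mean(vals), 0.2)
  expect_error(simulate_pattern_classes(2, classes = "swirl"), "unknown")
})

test_that("preprocessed pattern classes feed the CNN directly", {
  p <- simulate_pattern_classes(2, classes = c("spots", "blank"), seed = 1,
                                size = 256, preprocess = TRUE)
  expect_equal(dim(p$images)[1:2], c(150L, 150L))
  expect_true(all(p$images >= 0 & p$images <= 1))
})

test_that("distortion eccentricity is recovered from rendered ring images", {
  set.seed(31)
  m <- distortion_model(0.22, azimuth = 25, center = c(128, 128))
  ideal <- ellipse_points(240, 80, 80, center = c(128, 128))
  obs <- distort_points(m, ideal)
  lam <- matrix(1, 256, 256)
  for (k in seq_len(nrow(obs)))
    lam <- credkit:::.add_blob(lam, obs[k, 1], obs[k, 2], 200, 1.5)
  img <- matrix(rpois(256 * 256, lam), 256, 256)
  bright <- which(img > 60, arr.ind = TRUE)   # (row = y, col = x)
  fit <- fit_elliptical_distortion(bright[, c(2, 1)])
  expect_lt(abs(fit$eccentricity - 0.22), 0.01)
  expect_lt(max(abs(fit$center - c(128, 128))), 1)
})

test_that("a full rotation crosses the Ewald sphere an even number of times", {
  # 2-D toy lattice (l = 0 plane), rotation about x: for each in-range
  # reflection the excitation error changes sign an even number of times
  # over 360 degrees (the sphere is entered and left), and Friedel mates
  # cross equally often
  B <- cell_bmatrix(c(12, 12, 12, 90, 90, 90))
  kmag <- 1 / electron_wavelength(200)
  theta <- seq(0, 2 * pi, length.out = 2001)[1:2000]
  crossings <- function(h) {
    s0 <- B %*% h
    z <- vapply(theta, function(th) {
      s <- credkit:::rotation_about(c(1, 0, 0), th) %*% s0
      kmag - sqrt(s[1]^2 + s[2]^2 + (s[3] + kmag)^2)
    }, numeric(1))
    z <- c(z, z[1])   # periodic: count the wrap-around crossing too
    sum(abs(diff(sign(z))) > 0)
  }
  for (h in list(c(0, 1, 0), c(0, 2, 1), c(1, 1, 0), c(0, 3, 2))) {
    n <- crossings(h)
    expect_gte(n, 2)
    expect_identical(n %% 2L, 0L)
    expect_identical(crossings(-h), n)   # Friedel symmetry
  }
})

test_that("crystal fields plant close pairs that the filter removes", {
  f <- simulate_crystal_field(area = 200, n_crystals = 200, seed = 8,
                              n_pairs = 3, pair_distance = 1.0)
  frame <- attr(f, "frame")
  keep <- isolation_filter(f[, c("x", "y")], frame)
  # every planted-pair member is removed (distance 1.0 < 1.5)
  expect_true(all(!keep[f$planted_pair]))
  # agreement with the brute-force oracle on the full map
  expect_equal(keep, oracle_isolation(as.matrix(f[, c("x", "y")]), frame))
  expect_equal(nrow(simulate_crystal_field(n_crystals = 0, n_pairs = 0)), 0L)
})
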
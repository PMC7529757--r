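test_that("a-trous B-spline filter removes DC and keeps spot maxima", {
  k <- tcsmlm:::bspline_kernel(3, 2)
  expect_equal(k, c(1, 4, 6, 4, 1) / 16, tolerance = 1e-12)
  const <- matrix(7, 20, 20)
  wl <- wavelet_filter(const)
  expect_equal(max(abs(wl$filtered)), 0, tolerance = 1e-12)
  # single Gaussian spot: filtered maximum stays on the spot pixel
  xs <- outer(rep(1, 21), 1:21); ys <- t(xs)
  spot <- exp(-((xs - 11)^2 + (ys - 11)^2) / (2 * 1.5^2))
  wf <- wavelet_filter(spot)
  pk <- which(wf$filtered == max(wf$filtered), arr.ind = TRUE)
  expect_identical(as.integer(pk[1, ]), c(11L, 11L))
  # linearity
  set.seed(1)
  a <- matrix(stats::rnorm(400), 20); b <- matrix(stats::rnorm(400), 20)
  expect_equal(wavelet_filter(a + b)$filtered,
               wavelet_filter(a)$filtered + wavelet_filter(b)$filtered,
               tolerance = 1e-12)
  expect_error(wavelet_filter(matrix(0, 3, 3)), "smaller")
})

test_that("peak finding thresholds local maxima with a raster tie rule", {
  z <- matrix(0, 15, 15)
  wl <- wavelet_filter(z)
  expect_identical(nrow(find_peaks(wl$filtered, wl$first_level)), 0L)

  # two separated spots, both above threshold
  xs <- outer(rep(1, 15), 1:15); ys <- t(xs)
  img <- 10 * exp(-((xs - 4)^2 + (ys - 4)^2) / 2) +
         8 * exp(-((xs - 12)^2 + (ys - 11)^2) / 2) +
         matrix(stats::rnorm(225, 0, 0.01), 15)
  wl <- wavelet_filter(img)
  pk <- find_peaks(wl$filtered, wl$first_level,
                   detection_params(threshold_factor = 1.5))
  expect_identical(nrow(pk), 2L)
  expect_setequal(paste(pk$row, pk$col), c("4 4", "11 12"))

  # plateau of equal values: only the first raster-order pixel is kept
  flat <- matrix(0, 15, 15)
  flat[7:9, 7:9] <- 5
  pk2 <- tcsmlm:::local_maxima_cpp(flat, 1)
  expect_identical(nrow(pk2), 1L)
  expect_identical(as.integer(pk2[1, ]), c(7L, 7L))
})

test_that("integrated-Gaussian fits recover noiseless sub-pixel positions", {
  op <- optics_camera()
  pos <- data.frame(x = 10.37 * op$pixel_size, y = 9.81 * op$pixel_size)
  fr <- render_frames(pos, matrix(1, 1, 1), op, 1e5, 1e-3, 20)
  img <- matrix(fr[1, , ], 20)
  pk <- which(img == max(img), arr.ind = TRUE)
  fit <- fit_gaussian(img, data.frame(row = pk[1], col = pk[2]),
                      detection_params(fit_radius = 4, initial_sigma = 0.6),
                      pixel_size = op$pixel_size)
  expect_identical(nrow(fit), 1L)
  expect_lt(abs(fit$x - pos$x) / op$pixel_size, 1e-3)
  expect_lt(abs(fit$y - pos$y) / op$pixel_size, 1e-3)
  expect_equal(fit$sigma, op$sigma_psf, tolerance = 0.02)
  expect_equal(fit$intensity, 100, tolerance = 0.02)
})

test_that("Thompson uncertainty reduces to its b = 0 closed form", {
  expect_equal(thompson_uncertainty(150, 1000, 0, 160),
               sqrt((150^2 + 160^2 / 12) / 1000), tolerance = 1e-12)
  expect_equal(thompson_uncertainty(150, 1000, 0, 160), 4.96, tolerance = 0.01)
  # background term grows the uncertainty
  expect_gt(thompson_uncertainty(150, 1000, 5, 160),
            thompson_uncertainty(150, 1000, 0, 160))
})

test_that("localize_stack finds a persistent emitter once per frame", {
  op <- optics_camera()
  pos <- data.frame(x = 8.3 * op$pixel_size, y = 7.6 * op$pixel_size)
  fr <- render_frames(pos, matrix(1, 1, 30), op, 1e5, 1e-3, 16)
  st <- image_stack(fr, 1e-3, op$pixel_size)
  det <- detection_params(initial_sigma = op$sigma_psf / op$pixel_size,
                          fit_radius = 2)
  tab <- localize_stack(st, det)
  expect_identical(nrow(tab), 30L)
  expect_identical(tab$frame, 1:30)
  expect_lt(max(abs(tab$x - pos$x)), 0.2)
  merged <- localize_stack(st, det, merge = merge_params(50, 5))
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$intensity, sum(tab$intensity), tolerance = 1e-6)

  empty <- localize_stack(image_stack(array(0, c(3, 16, 16)), 1e-3, 165), det)
  expect_identical(nrow(empty), 0L)
})

test_that("merging groups by distance and frame gap and conserves intensity", {
  base <- loc_table(frame = c(1L, 2L), x = c(100, 100), y = c(50, 50),
                    sigma = 150, intensity = c(500, 700),
                    background = 1, uncertainty = c(10, 10))
  m <- merge_locs(base, merge_params(max_distance = 20, off_frames = 5))
  expect_identical(nrow(m), 1L)
  expect_equal(m$intensity, 1200)
  expect_equal(m$uncertainty, 1 / sqrt(2 / 100), tolerance = 1e-9)
  expect_identical(m$frame, 1L)

  # frame gap of off_frames + 2 must not merge
  gap <- loc_table(frame = c(1L, 8L), x = c(100, 100), y = c(50, 50),
                   sigma = 150, intensity = 500, background = 1,
                   uncertainty = 10)
  expect_identical(nrow(merge_locs(gap, merge_params(20, 5))), 2L)

  # weighted mean of three collinear detections (hand-computed)
  tri <- loc_table(frame = 1:3, x = c(0, 30, 60), y = c(0, 0, 0),
                   sigma = 150, intensity = c(1, 2, 1), background = 0,
                   uncertainty = 10)
  mt <- merge_locs(tri, merge_params(100, 5))
  expect_identical(nrow(mt), 1L)
  expect_equal(mt$x, (0 * 1 + 30 * 2 + 60 * 1) / 4)

  # merging never increases rows, conserves total intensity, unique ids
  set.seed(2)
  big <- loc_table(frame = sort(sample(1:50, 200, TRUE)),
                   x = stats::runif(200, 0, 2000),
                   y = stats::runif(200, 0, 2000),
                   sigma = 150, intensity = stats::runif(200, 100, 1000),
                   background = 1, uncertainty = stats::runif(200, 5, 20))
  mb <- merge_locs(big, merge_params(80, 10))
  expect_lte(nrow(mb), nrow(big))
  expect_equal(sum(mb$intensity), sum(big$intensity), tolerance = 1e-9)
  expect_identical(anyDuplicated(mb$id), 0L)
})

test_that("localization error scales like 1/sqrt(N) with photon budget", {
  op <- optics_camera()
  pos <- data.frame(x = 8.25 * op$pixel_size, y = 8.4 * op$pixel_size)
  det <- detection_params(initial_sigma = op$sigma_psf / op$pixel_size,
                          fit_radius = 3, threshold_factor = 1)
  rmse <- vapply(c(2e5, 2e6), function(rate) {
    ph <- render_frames(pos, matrix(1, 1, 150), op, rate, 1e-3, 16)
    st <- image_stack(camera_noise(ph, op, 1e-3, seed = 42), 1e-3,
                      op$pixel_size)
    tab <- localize_stack(st, det, calibration = camera_calibration(op))
    sqrt(mean((tab$x - pos$x)^2 + (tab$y - pos$y)^2))
  }, numeric(1))
  # 10x photons: error drops by about sqrt(10); allow generous slack
  expect_gt(rmse[1] / rmse[2], 2)
  expect_lt(rmse[1] / rmse[2], 5)
})

test_that("external localizer contract round-trips through a shell command", {
  fixture <- loc_table(frame = c(1L, 2L), x = c(10, 20), y = c(30, 40),
                       sigma = 150, intensity = 500, background = 1,
                       uncertainty = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_locs(fixture, csv)
  st <- image_stack(array(1, c(2, 8, 8)), 1e-3, 165)
  tab <- external_localizer(st, paste("cp", shQuote(csv), "{out}"))
  expect_equal(tab$x, fixture$x)
  expect_equal(tab$frame, fixture$frame)
  expect_error(external_localizer(st, "definitely-not-a-command {in} {out}"))
})

test_that("tc calibration maps transformed movies onto the photon scale", {
  sim <- small_star_sim()
  model <- model_acf(sim$blink, sim$stack$frame_period, 12)
  tc <- tc_transform(sim$stack, tc_params(mw = 24, n_lags = 12,
                                          model = model))
  cal <- tc_photon_calibration(tc, sim$stack, camera_calibration(sim$optics))
  phot <- (as.vector(tc$frames) - cal$offset) / cal$counts_per_photon
  raw_phot <- (as.vector(sim$stack$frames) - sim$optics$baseline) /
    sim$optics$gain
  expect_equal(stats::median(phot), 0, tolerance = 1e-6)
  expect_equal(as.numeric(stats::quantile(phot, 0.999)),
               as.numeric(stats::quantile(raw_phot, 0.999) -
                          stats::median(raw_phot)),
               tolerance = 0.01)
})
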
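test_that("analytic model ACF follows the telegraph correlation time", {
  # t_on = t_off = 2T gives tau_c = T, so AC at one lag of period T is 1/e
  m <- model_acf(blink_model(t_on = 0.02, t_off = 0.02, t_bleach = Inf),
                 frame_period = 0.01, n_lags = 10)
  expect_equal(m$values[1], 1)
  expect_equal(m$values[2], exp(-1), tolerance = 1e-12)
  expect_true(all(diff(m$values) < 0))
  # 180/120 ms gives tau_c = 72 ms
  m2 <- model_acf(blink_model(0.18, 0.12), 0.001, 5)
  expect_equal(m2$values[2], exp(-0.001 / 0.072), tolerance = 1e-12)
})

test_that("pixel autocovariance matches its definition", {
  expect_identical(pixel_acf(rep(3.2, 50), 5)$values, rep(0, 5))
  set.seed(1)
  x <- sample(c(-1, 1), 200, replace = TRUE)
  ac <- pixel_acf(x, 8)
  # direct-sum oracle for a few lags
  xb <- x - mean(x)
  for (k in c(0, 1, 4))
    expect_equal(ac$values[k + 1],
                 sum(xb[1:(200 - k)] * xb[(1 + k):200]) / (200 - k))
  expect_equal(ac$values[1], stats::var(x) * 199 / 200, tolerance = 1e-12)
  # bilinearity: scaling by c scales the curve by c^2
  expect_equal(pixel_acf(3 * x, 8)$values, 9 * ac$values, tolerance = 1e-12)
})

test_that("empirical model ACF recovers the blink decay from data", {
  # movie whose pixels all carry the same exponential AC (AR(1) processes)
  set.seed(2)
  tau <- 15
  phi <- exp(-1 / tau)
  n <- 800
  mk <- function() as.vector(stats::arima.sim(list(ar = phi), n))
  fr <- array(0, c(n, 4, 4))
  for (r in 1:4) for (c in 1:4) fr[, r, c] <- 100 + 10 * mk()
  st <- image_stack(fr, 0.001, 165)
  em <- empirical_model_acf(st, quantile = 0.5, n_pixels = 16, n_lags = 30)
  expect_equal(em$values[1], 1)
  k <- 1:20
  tau_hat <- -1 / stats::coef(stats::lm(log(em$values[k + 1]) ~ k))[["k"]]
  expect_equal(tau_hat, tau, tolerance = 0.2)
  expect_error(empirical_model_acf(image_stack(array(5, c(100, 4, 4)),
                                               0.001, 165), n_lags = 10),
               "degenerate")
})

test_that("empirical model ACF on simulated movies recovers tau_c = 72 ms", {
  op <- optics_camera(); bm <- blink_model(0.18, 0.12, Inf)
  taus <- vapply(1:5, function(seed) {
    sim <- simulate_movie(phantom("siemens_star", 10, 12, 25), bm, op,
                          1500, 1e-3, seed = seed)
    em <- empirical_model_acf(sim$stack, n_lags = 40)
    v <- em$values[2:40]
    k <- which(v > 0.05)
    stats::coef(stats::lm(log(v[k]) ~ k))[["k"]] * -1
  }, numeric(1))
  tau_hat <- 1 / mean(taus)             # frames at 1000 fps = ms
  expect_equal(tau_hat, 72, tolerance = 0.25)
})

test_that("tc_frame scores model-matched pixels above mismatched ones", {
  bm <- blink_model(0.02, 0.02, Inf)     # tau_c = 10 ms = 10 frames
  model <- model_acf(bm, 0.001, 15)
  # two-pixel toy movie: one pixel follows the model decay, one is white
  set.seed(3)
  n <- 40
  decay_pix <- 5 + exp(-(0:(n - 1)) / 10) * 3
  noise_pix <- 5 + stats::rnorm(n, 0, 1)
  fr <- array(0, c(n, 1, 2))
  fr[, 1, 1] <- decay_pix
  fr[, 1, 2] <- noise_pix
  st <- image_stack(fr, 0.001, 165)
  v <- tc_frame(st, 1, tc_params(mw = n, n_lags = 15, model = model))
  expect_gt(v[1, 1], 0)
  expect_gt(v[1, 1], v[1, 2])
  # constant pixel scores exactly zero
  fr[, 1, 2] <- 7
  v2 <- tc_frame(image_stack(fr, 0.001, 165), 1,
                 tc_params(mw = n, n_lags = 15, model = model))
  expect_identical(v2[1, 2], 0)
  # doubling the amplitude quadruples the (positive) output
  fr2 <- fr; fr2[, 1, 1] <- 5 + 2 * (decay_pix - 5)
  v4 <- tc_frame(image_stack(fr2, 0.001, 165), 1,
                 tc_params(mw = n, n_lags = 15, model = model))
  expect_equal(v4[1, 1] / v2[1, 1], 4, tolerance = 1e-9)
})

test_that("tc_transform length, non-negativity and scale equivariance", {
  sim <- small_star_sim()
  model <- model_acf(sim$blink, sim$stack$frame_period, 15)
  st <- image_stack(sim$stack$frames[1:100, , ], sim$stack$frame_period,
                    sim$stack$pixel_size)
  tc1 <- tc_transform(st, tc_params(mw = 30, n_lags = 15, model = model))
  expect_identical(n_frames(tc1), 70L)            # N - mw at step 1
  expect_true(all(tc1$frames >= 0))
  expect_equal(tc1$frame_period, st$frame_period)
  tc2 <- tc_transform(st, tc_params(mw = 30, step = 2, n_lags = 15,
                                    model = model))
  expect_identical(n_frames(tc2), 35L)            # window-count oracle
  expect_equal(tc2$frame_period, 2 * st$frame_period)
  expect_error(tc_transform(st, tc_params(mw = 100, n_lags = 15,
                                          model = model)), "shorter")
  # unclipped transform scales as c^2 under intensity scaling
  pu <- tc_params(mw = 30, n_lags = 15, model = model, clip_negative = FALSE)
  sc <- image_stack(3 * st$frames, st$frame_period, st$pixel_size)
  expect_equal(tc_transform(sc, pu)$frames, 9 * tc_transform(st, pu)$frames,
               tolerance = 1e-9)
})

test_that("movies with a model-matched emitter outscore pure noise", {
  op <- optics_camera(); bm <- blink_model(0.18, 0.12, Inf)
  set.seed(9)
  noise <- array(stats::rnorm(300 * 64, 100, 3), c(300, 8, 8))
  pos <- data.frame(x = 4.2 * op$pixel_size, y = 4.4 * op$pixel_size)
  tr <- matrix(blink_trace(bm, 300, 1e-3, seed = 10), 1)
  sig <- render_frames(pos, tr, op, 1e6, 1e-3, 8)
  model <- model_acf(bm, 1e-3, 12)
  pars <- tc_params(mw = 24, n_lags = 12, model = model)
  tc_noise <- tc_transform(image_stack(noise, 1e-3, 165), pars)
  tc_sig <- tc_transform(image_stack(noise + sig, 1e-3, 165), pars)
  expect_gt(mean(tc_sig$frames), 10 * mean(tc_noise$frames))
})

test_that("model selectivity prefers the matching decay time", {
  # three AR(1) pixels with decay 0.2 tau_c, tau_c, 5 tau_c, equal variance
  tau_c <- 20
  set.seed(4)
  mkar <- function(tau, n) {
    x <- as.vector(stats::arima.sim(list(ar = exp(-1 / tau)), n))
    x / stats::sd(x)
  }
  n <- 6000
  fr <- array(0, c(n, 1, 3))
  fr[, 1, 1] <- mkar(0.2 * tau_c, n)
  fr[, 1, 2] <- mkar(tau_c, n)
  fr[, 1, 3] <- mkar(5 * tau_c, n)
  st <- image_stack(fr, 0.001, 165)
  # lags must extend beyond the model correlation time for the covariance
  # to discriminate against faster decays
  model <- acf_curve(exp(-(0:39) / tau_c), normalized = TRUE)
  tc <- tc_transform(st, tc_params(mw = 80, n_lags = 40, model = model))
  means <- apply(tc$frames, 3, mean)
  expect_identical(which.max(means), 2L)
})

test_that("theoretical moving window reproduces the worked example", {
  expect_identical(theoretical_mw(blink_model(0.18, 0.12), 0.001, step = 2),
                   36L)
  expect_identical(theoretical_mw(blink_model(0.1, 0.1), 0.001, step = 1),
                   50L)
  # symmetric case: t_on = t_off = 2T gives tau_c = T, one frame
  expect_identical(theoretical_mw(blink_model(0.02, 0.02), 0.01, step = 1),
                   1L)
})

test_that("ACF smoothing is a shrinking-edge moving average", {
  curve <- acf_curve(c(5, 5, 5, 5, 5, 5))
  expect_equal(smooth_acf(curve, 1)$values, curve$values)
  expect_equal(smooth_acf(curve, 3)$values, curve$values)
  set.seed(6)
  noisy <- acf_curve(stats::rnorm(6000))
  sm <- smooth_acf(noisy, 15)
  mid <- 50:5950
  expect_equal(stats::var(noisy$values[mid]) / stats::var(sm$values[mid]),
               15, tolerance = 0.25)
  # explicit edge behaviour
  v <- c(1, 2, 3, 4, 5)
  expect_equal(smooth_acf(acf_curve(v), 3)$values,
               c(1.5, 2, 3, 4, 4.5))
})

test_that("log-ACF linearity cutoffs separate signal from background", {
  # exact exponential: |r| = 1 for every prefix, cutoff = usable length
  exact <- acf_curve(exp(-(0:60) / 12))
  r <- pi_cutoff(exact)
  expect_identical(r$cutoff, 60L)
  # two-regime curve: exponential for k <= 40 then a flat plateau; the
  # cutoff must agree with an independent brute-force prefix scan and lie
  # after the linear region
  v <- c(1, exp(-(1:40) / 10), rep(exp(-4), 160))
  two <- pi_cutoff(acf_curve(v))
  g <- log(v[-1])
  r <- vapply(5:length(g), function(L) abs(stats::cor(g[1:L], 1:L)),
              numeric(1))
  first_bad <- which(r < 0.9)[1]
  oracle <- (5:length(g))[first_bad] - 1L
  expect_identical(two$cutoff, oracle)
  expect_gte(two$cutoff, 40)
  expect_lt(two$cutoff, 100)
  # white-noise ACFs are background-like: majority of cutoffs are 0
  set.seed(7)
  zeros <- vapply(1:100, function(i) {
    ac <- pixel_acf(stats::rnorm(400), 60)
    pi_cutoff(smooth_acf(ac, 5))$cutoff
  }, integer(1))
  expect_gt(mean(zeros == 0), 0.5)
})

test_that("probe-pixel window selection takes the minimum non-zero cutoff", {
  # every pixel carries the same decay trajectory (scaled): the Pearson
  # trace is scale-invariant, so all probes report the same cutoff
  set.seed(8)
  n <- 1200
  base <- as.vector(stats::arima.sim(list(ar = exp(-1 / 15)), n))
  fr <- array(0, c(n, 5, 5))
  amp <- matrix(stats::runif(25, 2, 12), 5)
  for (r in 1:5) for (c in 1:5) fr[, r, c] <- 50 * amp[r, c] + amp[r, c] * base
  st <- image_stack(fr, 0.001, 165)
  res <- optimal_mw(st, n_lags = 150)
  expect_true(all(res$probes$cutoff == res$probes$cutoff[1]))
  expect_identical(res$mw, res$probes$cutoff[1])

  # background-dominated movie: bright pixels carry a correlated decay,
  # the low-intensity probe sees white noise and reports cutoff 0
  set.seed(9)
  fr2 <- array(stats::rnorm(n * 36, 100, 5), c(n, 6, 6))
  fr2[, 2, 2] <- fr2[, 2, 2] + 45 +
    40 * as.vector(stats::arima.sim(list(ar = exp(-1 / 15)), n))
  fr2[, 4, 5] <- fr2[, 4, 5] + 40 +
    35 * as.vector(stats::arima.sim(list(ar = exp(-1 / 15)), n))
  st2 <- image_stack(fr2, 0.001, 165)
  res2 <- optimal_mw(st2, n_lags = 150, smoothing_window = 5)
  low <- which.min(res2$probes$quantile)
  expect_identical(res2$probes$cutoff[low], 0L)
  expect_gt(res2$mw, 0)

  # all-background movie errors out with diagnostics
  set.seed(10)
  st3 <- image_stack(array(stats::rnorm(400 * 16, 0, 1), c(400, 4, 4)),
                     0.001, 165)
  expect_error(optimal_mw(st3), "background")
})

test_that("time-summed tc movie shrinks the PSF by sqrt(2)", {
  fx <- single_emitter_movie()
  mw <- matched_mw(fx$blink, fx$stack$frame_period)
  pars <- tc_params(mw = mw, model = model_acf(fx$blink,
                                               fx$stack$frame_period,
                                               max(2, floor(mw / 2))))
  tc <- tc_transform(fx$stack, pars)
  w_raw <- fitted_width_px(apply(fx$stack$frames, c(2, 3), sum))
  w_tc <- fitted_width_px(apply(tc$frames, c(2, 3), sum))
  expect_equal(w_raw / w_tc, sqrt(2), tolerance = 0.05)
})
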
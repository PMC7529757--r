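# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# one bright noiseless blinking emitter at a known sub-pixel position, on a
# fine grid (55 nm pixels) so the PSF is well sampled
single_emitter_movie <- function(n_frames = 2000, seed = 7) {
  cached(paste0("single_", n_frames, "_", seed), function() {
    op <- optics_camera(magnification = 300)
    pos <- data.frame(x = 20.31 * op$pixel_size, y = 20.67 * op$pixel_size)
    bm <- blink_model(0.18, 0.12, Inf)
    tr <- matrix(blink_trace(bm, n_frames, 1e-3, seed = seed), 1)
    ph <- render_frames(pos, tr, op, bm$photon_rate, 1e-3, 40)
    list(stack = image_stack(ph, 1e-3, op$pixel_size), pos = pos,
         blink = bm, optics = op, traces = tr)
  })
}

# small crowded star simulation with camera noise
small_star_sim <- function(seed = 5) {
  cached(paste0("star_", seed), function() {
    op <- optics_camera()
    bm <- blink_model()
    sim <- simulate_movie(phantom("siemens_star", 10, 16, 40), bm, op,
                          600, 1e-3, seed = seed, background_rate = 1)
    c(sim, list(optics = op, blink = bm))
  })
}

# fitted Gaussian width (px) of an image around its global maximum
fitted_width_px <- function(img, radius = 6, init = 1.5) {
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  f <- fit_gaussian(img, data.frame(row = pk[1], col = pk[2]),
                    detection_params(fit_radius = radius,
                                     initial_sigma = init),
                    pixel_size = 1)
  f$sigma[1]
}
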
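#' Fluorophore blinking kinetics
#'
#' A two-state telegraph model with exponential on/off dwell times and an
#' exponential time to irreversible photobleaching. The characteristic
#' correlation time of the resulting intensity fluctuations is
#' `tau_c = t_on * t_off / (t_on + t_off)`.
#'
#' @param t_on mean on-state dwell time, seconds.
#' @param t_off mean off-state dwell time, seconds.
#' @param t_bleach mean time to irreversible bleaching, seconds (may be `Inf`).
#' @param photon_rate photons emitted per second while on.
#' @return object of class `blink_model`.
#' @export
blink_model <- function(t_on = 0.18, t_off = 0.12, t_bleach = 5,
                        photon_rate = 5e5) {
  stopifnot(t_on > 0, t_off > 0, t_bleach > 0, photon_rate > 0)
  structure(list(t_on = t_on, t_off = t_off, t_bleach = t_bleach,
                 photon_rate = photon_rate), class = "blink_model")
}

#' Optics and camera description
#'
#' Defaults follow a widefield TIRF setup with an EM camera: NA 1.3,
#' 600 nm emission, x100 magnification, 16.5 um detector pixels (165 nm in
#' the sample plane), readout 1.6 e- rms, dark current 0.06 e-/px/s,
#' quantum efficiency 0.7 and gain 6 counts/e-.
#'
#' @param na numerical aperture.
#' @param wavelength emission wavelength, nm.
#' @param magnification objective magnification.
#' @param detector_pixel physical detector pixel, um.
#' @param readout_noise electrons rms per read.
#' @param dark_current electrons/pixel/s.
#' @param quantum_efficiency detected fraction of incident photons.
#' @param gain counts per photoelectron.
#' @param baseline camera offset, counts.
#' @param psf_factor Gaussian PSF width as a multiple of `wavelength / na`.
#' @return object of class `optics_camera` with derived `pixel_size` (nm)
#'   and `sigma_psf` (nm).
#' @export
optics_camera <- function(na = 1.3, wavelength = 600, magnification = 100,
                          detector_pixel = 16.5, readout_noise = 1.6,
                          dark_current = 0.06, quantum_efficiency = 0.7,
                          gain = 6, baseline = 100, psf_factor = 0.21) {
  stopifnot(na > 0, quantum_efficiency > 0, quantum_efficiency <= 1)
  structure(list(na = na, wavelength = wavelength,
                 magnification = magnification,
                 detector_pixel = detector_pixel,
                 readout_noise = readout_noise, dark_current = dark_current,
                 quantum_efficiency = quantum_efficiency, gain = gain,
                 baseline = baseline,
                 pixel_size = detector_pixel * 1000 / magnification,
                 sigma_psf = psf_factor * wavelength / na),
            class = "optics_camera")
}

#' Phantom description
#'
#' @param kind `"siemens_star"`, `"nanoruler"` or `"uniform"`.
#' @param wings number of star wings (alternating on/off sectors).
#' @param field field of view, pixels (square).
#' @param n_emitters emitters to place (nanoruler: number of marker pairs
#'   is `n_emitters / 2`).
#' @param ruler_length marker separation for nanorulers, nm.
#' @param background_emitters optional out-of-focus population:
#'   `list(count, defocus_sigma_factor, photon_rate)`.
#' @return object of class `phantom`.
#' @export
phantom <- function(kind = c("siemens_star", "nanoruler", "uniform"),
                    wings = 10, field = 25, n_emitters = 250,
                    ruler_length = 50, background_emitters = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_emitters > 0)
  structure(list(kind = kind, wings = wings, field = field,
                 n_emitters = n_emitters, ruler_length = ruler_length,
                 background_emitters = background_emitters),
            class = "phantom")
}

#' Rasterized Siemens-star mask
#'
#' Alternating angular sectors of width `pi / wings` inside a disk of
#' diameter `field`, centred on the field; the pattern is invariant under
#' rotation by `2 * pi / wings` and the "on" sectors cover half the disk.
#'
#' @param wings number of wings (>= 2).
#' @param field field size in pixels (>= 8).
#' @return `field x field` logical matrix (row = y, col = x).
#' @export
siemens_star_mask <- function(wings, field) {
  if (wings < 2) stop("a Siemens star needs at least 2 wings")
  stopifnot(field >= 8)
  ctr <- field / 2
  xc <- matrix(rep(seq_len(field) - 0.5, each = field), field) - ctr
  yc <- matrix(rep(seq_len(field) - 0.5, times = field), field) - ctr
  ang <- atan2(yc, xc) %% (2 * pi)
  rad <- sqrt(xc^2 + yc^2)
  (floor(ang / (pi / wings)) %% 2 == 0) & (rad <= ctr)
}

#' Place ground-truth emitters inside a phantom
#'
#' Siemens star / uniform: uniform rejection sampling of continuous
#' positions over true mask pixels. Nanoruler: pairs of points separated by
#' exactly `ruler_length` nm at uniformly random centres and orientations.
#'
#' @param ph a [phantom()].
#' @param pixel_size sample-plane pixel size, nm.
#' @param seed RNG seed.
#' @return `data.frame(id, x, y)` in nm.
#' @export
place_emitters <- function(ph, pixel_size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  field_nm <- ph$field * pixel_size
  if (ph$kind == "nanoruler") {
    n_pairs <- max(1L, round(ph$n_emitters / 2))
    margin <- ph$ruler_length
    cx <- stats::runif(n_pairs, margin, field_nm - margin)
    cy <- stats::runif(n_pairs, margin, field_nm - margin)
    th <- stats::runif(n_pairs, 0, pi)
    dx <- ph$ruler_length / 2 * cos(th)
    dy <- ph$ruler_length / 2 * sin(th)
    x <- as.vector(rbind(cx - dx, cx + dx))
    y <- as.vector(rbind(cy - dy, cy + dy))
    return(data.frame(id = seq_along(x), x = x, y = y))
  }
  mask <- if (ph$kind == "siemens_star")
    siemens_star_mask(ph$wings, ph$field) else
    matrix(TRUE, ph$field, ph$field)
  if (!any(mask)) stop("phantom mask is empty")
  x <- numeric(0); y <- numeric(0)
  while (length(x) < ph$n_emitters) {
    m <- 4 * (ph$n_emitters - length(x)) + 16
    px <- stats::runif(m, 0, field_nm)
    py <- stats::runif(m, 0, field_nm)
    col <- pmin(ph$field, floor(px / pixel_size) + 1)
    row <- pmin(ph$field, floor(py / pixel_size) + 1)
    keep <- mask[cbind(row, col)]
    x <- c(x, px[keep]); y <- c(y, py[keep])
  }
  data.frame(id = seq_len(ph$n_emitters),
             x = x[seq_len(ph$n_emitters)], y = y[seq_len(ph$n_emitters)])
}

rexp_mean <- function(n, mean) {
  if (is.infinite(mean)) rep(Inf, n) else stats::rexp(n, rate = 1 / mean)
}

#' Simulate one emitter's per-frame emission fraction
#'
#' Continuous-time two-state telegraph process with exponential dwell times,
#' started from its stationary state and killed at an exponential bleaching
#' time. The returned value per frame is the fraction of the frame interval
#' spent emitting, so fast blinking is integrated rather than snapshotted;
#' after bleaching the trace is identically zero.
#'
#' @param model a [blink_model()].
#' @param n_frames frames to simulate.
#' @param frame_period seconds per frame.
#' @param seed RNG seed.
#' @return numeric vector of length `n_frames` with values in `[0, 1]`.
#' @export
blink_trace <- function(model, n_frames, frame_period, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_frames >= 1)
  total <- n_frames * frame_period
  bleach <- rexp_mean(1, model$t_bleach)
  p_on <- if (is.infinite(model$t_off)) 0
          else if (is.infinite(model$t_on)) 1
          else model$t_on / (model$t_on + model$t_off)
  on <- stats::runif(1) < p_on
  t <- 0
  starts <- numeric(0); ends <- numeric(0)
  horizon <- min(total, bleach)
  while (t < horizon) {
    dwell <- rexp_mean(1, if (on) model$t_on else model$t_off)
    t2 <- min(t + dwell, horizon)
    if (on) { starts <- c(starts, t); ends <- c(ends, t2) }
    t <- t2
    on <- !on
    if (is.infinite(dwell)) break
  }
  trace <- numeric(n_frames)
  if (length(starts)) {
    for (i in seq_along(starts)) {
      f0 <- floor(starts[i] / frame_period)
      f1 <- min(n_frames - 1, floor((ends[i] - 1e-12) / frame_period))
      for (f in f0:f1) {
        lo <- max(starts[i], f * frame_period)
        hi <- min(ends[i], (f + 1) * frame_period)
        trace[f + 1] <- trace[f + 1] + max(0, hi - lo) / frame_period
      }
    }
  }
  pmin(trace, 1)
}

blink_traces <- function(model, n_emitters, n_frames, frame_period,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t(vapply(seq_len(n_emitters),
           function(i) blink_trace(model, n_frames, frame_period),
           numeric(n_frames)))
}

#' Render noiseless photon-flux frames from emitters and traces
#'
#' Each emitter contributes an integrated 2-D Gaussian PSF of width
#' `sigma_psf = psf_factor * wavelength / na` (optionally widened by
#' `sigma_factor` per emitter, e.g. for a defocused background population),
#' with per-frame amplitude `photon_rate * frame_period * emission
#' fraction`; a uniform `background_rate` (photons/px/frame) is added.
#'
#' @param positions `data.frame(x, y)` in nm.
#' @param traces `n_emitters x n_frames` emission-fraction matrix.
#' @param optics an [optics_camera()].
#' @param photon_rate photons/s while fully on.
#' @param frame_period seconds per frame.
#' @param field field size, pixels.
#' @param background_rate uniform photons/pixel/frame.
#' @param sigma_factor scalar or per-emitter PSF width multiplier.
#' @return `(T, field, field)` photon array.
#' @export
render_frames <- function(positions, traces, optics, photon_rate,
                          frame_period, field, background_rate = 0,
                          sigma_factor = 1) {
  n_em <- nrow(positions)
  stopifnot(n_em == nrow(traces))
  px <- optics$pixel_size
  sig <- optics$sigma_psf * rep_len(sigma_factor, n_em) / px   # px units
  cx <- positions$x / px
  cy <- positions$y / px
  ii <- list(); jj <- list(); vv <- list()
  for (e in seq_len(n_em)) {
    rad <- ceiling(5 * sig[e])
    cols <- max(1, floor(cx[e]) - rad + 1):min(field, floor(cx[e]) + rad + 1)
    rows <- max(1, floor(cy[e]) - rad + 1):min(field, floor(cy[e]) + rad + 1)
    wx <- stats::pnorm(cols, cx[e], sig[e]) -
          stats::pnorm(cols - 1, cx[e], sig[e])
    wy <- stats::pnorm(rows, cy[e], sig[e]) -
          stats::pnorm(rows - 1, cy[e], sig[e])
    w <- outer(wy, wx)
    idx <- as.matrix(expand.grid(row = rows, col = cols))
    ii[[e]] <- idx[, "row"] + (idx[, "col"] - 1) * field
    jj[[e]] <- rep(e, nrow(idx))
    vv[[e]] <- as.vector(w)
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(field * field, n_em))
  amp <- photon_rate * frame_period * traces         # photons per frame
  M <- as.matrix(P %*% amp)                          # (field^2) x T
  arr <- aperm(array(M, dim = c(field, field, ncol(traces))), c(3, 1, 2))
  arr + background_rate
}

#' Apply camera noise to a photon movie
#'
#' `counts = baseline + gain * Poisson(QE * photons + dark * frame_period)
#' + Normal(0, readout * gain)`, rounded to integer counts and clipped at 0.
#' The gain is a deterministic multiplier (no EM excess-noise factor).
#'
#' @param photon_movie `(T, H, W)` non-negative photon array.
#' @param optics an [optics_camera()].
#' @param frame_period seconds per frame.
#' @param seed RNG seed.
#' @return `(T, H, W)` array of integer-valued counts.
#' @export
camera_noise <- function(photon_movie, optics, frame_period, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(min(photon_movie) >= 0)
  lam <- optics$quantum_efficiency * photon_movie +
    optics$dark_current * frame_period
  n <- length(lam)
  counts <- optics$baseline +
    optics$gain * stats::rpois(n, as.vector(lam)) +
    stats::rnorm(n, 0, optics$readout_noise * optics$gain)
  counts <- pmax(0, round(counts))
  array(counts, dim = dim(photon_movie))
}

#' Simulate a blinking-emitter movie with ground truth
#'
#' Composition of [place_emitters()], [blink_trace()], [render_frames()] and
#' [camera_noise()]. An optional out-of-focus population
#' (`phantom$background_emitters`) is rendered with a widened PSF and
#' independent slower blinking, raising the background level.
#'
#' @param ph a [phantom()].
#' @param blink a [blink_model()].
#' @param optics an [optics_camera()].
#' @param n_frames movie length.
#' @param frame_period seconds per frame.
#' @param seed RNG seed (controls placement, blinking and noise).
#' @param background_rate uniform background, photons/pixel/frame.
#' @return `list(stack = image_stack, gt = ground_truth)`.
#' @export
simulate_movie <- function(ph, blink, optics, n_frames, frame_period,
                           seed = NULL, background_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  pos <- place_emitters(ph, optics$pixel_size)
  traces <- blink_traces(blink, nrow(pos), n_frames, frame_period)
  photons <- render_frames(pos, traces, optics, blink$photon_rate,
                           frame_period, ph$field,
                           background_rate = background_rate)
  bg <- ph$background_emitters
  if (!is.null(bg) && bg$count > 0) {
    bpos <- data.frame(
      x = stats::runif(bg$count, 0, ph$field * optics$pixel_size),
      y = stats::runif(bg$count, 0, ph$field * optics$pixel_size))
    bblink <- blink_model(t_on = blink$t_on * 5, t_off = blink$t_off * 5,
                          t_bleach = blink$t_bleach,
                          photon_rate = bg$photon_rate %||% blink$photon_rate)
    btr <- blink_traces(bblink, bg$count, n_frames, frame_period)
    photons <- photons + render_frames(
      bpos, btr, optics, bblink$photon_rate, frame_period, ph$field,
      sigma_factor = bg$defocus_sigma_factor %||% 4)
  }
  counts <- camera_noise(photons, optics, frame_period)
  stack <- image_stack(counts, frame_period, optics$pixel_size)
  gt <- ground_truth(pos, traces, blink$photon_rate)
  list(stack = stack, gt = gt)
}
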
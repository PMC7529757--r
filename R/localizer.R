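#' Spot-detection and fitting parameters
#'
#' Defaults mirror the common wavelet-filter workflow: B-spline order 3 at
#' scale 2, local maxima over the 8-neighbourhood thresholded at
#' `threshold_factor` times the standard deviation of the first wavelet
#' level, then least-squares Gaussian fitting in a `(2 * fit_radius + 1)^2`
#' window.
#'
#' @param wavelet_order B-spline order (order = degree + 1; default 3).
#' @param wavelet_scale kernel scale (default 2).
#' @param threshold_factor detection threshold in first-level stdevs.
#' @param fit_radius fit window half-size, px (>= 2).
#' @param initial_sigma starting Gaussian width, px; fits with width outside
#'   `[0.5, 3] * initial_sigma` are rejected.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(wavelet_order = 3, wavelet_scale = 2,
                             threshold_factor = 1.5, fit_radius = 3,
                             initial_sigma = 1.3) {
  stopifnot(fit_radius >= 2, threshold_factor > 0)
  structure(list(wavelet_order = wavelet_order,
                 wavelet_scale = wavelet_scale,
                 threshold_factor = threshold_factor,
                 fit_radius = as.integer(fit_radius),
                 initial_sigma = initial_sigma),
            class = "detection_params")
}

#' Temporal grouping parameters
#'
#' @param max_distance maximum distance (nm) from a track's running mean.
#' @param off_frames maximum number of dark frames bridged within a track.
#' @return object of class `merge_params`.
#' @export
merge_params <- function(max_distance = 60, off_frames = 20) {
  stopifnot(max_distance >= 0, off_frames >= 0)
  structure(list(max_distance = max_distance,
                 off_frames = as.integer(off_frames)),
            class = "merge_params")
}

# Normalized B-spline smoothing kernel: the degree-(order-1) B-spline
# sampled at integer offsets divided by `scale`. Order 3, scale 2 gives the
# classic [1, 4, 6, 4, 1] / 16.
bspline_kernel <- function(order = 3, scale = 2) {
  deg <- order - 1
  size <- 2 * ceiling(order * scale / 2) - 1
  x <- (seq_len(size) - (size + 1) / 2) / scale
  # Irwin-Hall / B-spline closed form of degree `deg`
  b <- vapply(x, function(xi) {
    k <- 0:(deg + 1)
    sum((-1)^k * choose(deg + 1, k) * pmax(xi + (deg + 1) / 2 - k, 0)^deg) /
      factorial(deg)
  }, numeric(1))
  b / sum(b)
}

#' Undecimated (a-trous) B-spline wavelet filter
#'
#' `V1` is the frame convolved with the B-spline kernel; `V2` convolves `V1`
#' with the same kernel dilated by 2. The returned `filtered` image is the
#' second wavelet level `V1 - V2` (band-passed spots); `first_level` is
#' `frame - V1`, whose standard deviation is used for thresholding.
#'
#' @param frame 2-D numeric matrix.
#' @param order,scale B-spline kernel parameters.
#' @return `list(filtered, first_level)`.
#' @export
wavelet_filter <- function(frame, order = 3, scale = 2) {
  k <- bspline_kernel(order, scale)
  if (nrow(frame) < length(k) || ncol(frame) < length(k))
    stop("frame smaller than the wavelet kernel")
  v1 <- conv_sep_cpp(frame, k, 1L)
  v2 <- conv_sep_cpp(v1, k, 2L)
  list(filtered = v1 - v2, first_level = frame - v1)
}

#' Approximate peak detection by thresholded local maxima
#'
#' Pixels that are maxima over their 8-neighbourhood and exceed
#' `threshold_factor * sd(first_level)`. On plateaus of equal values only
#' the first pixel in (row, col) order is kept.
#'
#' @param filtered,first_level images from [wavelet_filter()].
#' @param params a [detection_params()].
#' @return `data.frame(row, col)` of 1-based peak pixels (possibly empty).
#' @export
find_peaks <- function(filtered, first_level, params = detection_params()) {
  thr <- params$threshold_factor * stats::sd(as.vector(first_level))
  pk <- local_maxima_cpp(filtered, thr)
  data.frame(row = pk[, 1], col = pk[, 2])
}

#' Thompson localization uncertainty
#'
#' `sigma_loc^2 = (s^2 + a^2 / 12) / N + 8 * pi * s^4 * b^2 / (a^2 * N^2)`
#' with `s` the fitted PSF width (nm), `a` the pixel size (nm), `N` the
#' photon count and `b` the background (photons/pixel).
#'
#' @param s fitted width, nm.
#' @param N photons.
#' @param b background photons per pixel.
#' @param a pixel size, nm.
#' @return uncertainty in nm.
#' @export
thompson_uncertainty <- function(s, N, b, a) {
  sqrt((s^2 + a^2 / 12) / N + 8 * pi * s^4 * b^2 / (a^2 * N^2))
}

#' Sub-pixel Gaussian fit at detected peaks
#'
#' Levenberg-Marquardt least squares of a symmetric 2-D Gaussian plus a
#' constant offset. Fits that do not converge, have non-positive amplitude,
#' drift out of the fit window, or end with width outside
#' `[0.5, 3] * initial_sigma` are rejected.
#'
#' @param frame 2-D matrix (already converted to photons, see
#'   [photon_calibration()]).
#' @param peaks `data.frame(row, col)` from [find_peaks()].
#' @param params a [detection_params()].
#' @param pixel_size nm per pixel.
#' @return [loc_table()] rows (without frame index); intensity is the
#'   fitted Gaussian volume (total photons). The model is the integrated
#'   Gaussian (pixel-averaged), appropriate when the PSF width is
#'   comparable to the pixel.
#' @export
fit_gaussian <- function(frame, peaks, params = detection_params(),
                         pixel_size = 160) {
  if (nrow(peaks) == 0) return(loc_table())
  fits <- fit_gaussians_cpp(frame, as.matrix(peaks), params$fit_radius,
                            params$initial_sigma, 60L)
  x0 <- fits[, 1]; y0 <- fits[, 2]; s_px <- fits[, 3]
  N <- fits[, 4]; b <- fits[, 5]; conv <- fits[, 7]
  ok <- !is.na(conv) & conv > 0 & N > 0 &
    s_px >= 0.5 * params$initial_sigma & s_px <= 3 * params$initial_sigma &
    abs(x0 - (peaks$col - 1)) <= params$fit_radius &
    abs(y0 - (peaks$row - 1)) <= params$fit_radius
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(loc_table())
  x0 <- x0[ok]; y0 <- y0[ok]; s_px <- s_px[ok]; N <- N[ok]; b <- pmax(b[ok], 0)
  s_nm <- s_px * pixel_size
  unc <- thompson_uncertainty(s_nm, pmax(N, 1e-9), b, pixel_size)
  loc_table(frame = rep(1L, sum(ok)),
            x = (x0 + 0.5) * pixel_size, y = (y0 + 0.5) * pixel_size,
            sigma = s_nm, intensity = N, background = b, uncertainty = unc)
}

#' Photon calibration of a movie
#'
#' Raw camera movies: `photons = (counts - offset) / counts_per_photon`
#' with `offset` the camera baseline and `counts_per_photon` the gain.
#' Time-correlated movies are not in count units; [tc_photon_calibration()]
#' derives an affine map by matching the robust background level and
#' dynamic range against the raw movie's photon scale.
#'
#' @param offset subtracted level, in the movie's own units.
#' @param counts_per_photon units per detected photon.
#' @return `list(offset, counts_per_photon)` of class `photon_calibration`.
#' @export
photon_calibration <- function(offset = 0, counts_per_photon = 1) {
  stopifnot(counts_per_photon > 0)
  structure(list(offset = offset, counts_per_photon = counts_per_photon),
            class = "photon_calibration")
}

#' @rdname photon_calibration
#' @param optics an [optics_camera()]; calibration for its raw count movies.
#' @export
camera_calibration <- function(optics) {
  photon_calibration(offset = optics$baseline, counts_per_photon = optics$gain)
}

#' @rdname photon_calibration
#' @param tc_stack the time-correlated [image_stack()].
#' @param raw_stack the raw movie it came from.
#' @param raw_cal the raw movie's [photon_calibration()].
#' @param q upper quantile used to match dynamic ranges.
#' @export
tc_photon_calibration <- function(tc_stack, raw_stack, raw_cal, q = 0.999) {
  raw_phot <- (as.vector(raw_stack$frames) - raw_cal$offset) /
    raw_cal$counts_per_photon
  tc_v <- as.vector(tc_stack$frames)
  med_tc <- stats::median(tc_v)
  span_tc <- stats::quantile(tc_v, q) - med_tc
  span_raw <- stats::quantile(raw_phot, q) - stats::median(raw_phot)
  if (span_tc <= 0 || span_raw <= 0)
    return(photon_calibration(med_tc, 1))
  photon_calibration(offset = med_tc,
                     counts_per_photon = as.numeric(span_tc / span_raw))
}

#' Localize every frame of a movie
#'
#' Per frame: wavelet filter, local-maxima detection, Gaussian fitting;
#' optionally followed by temporal grouping ([merge_locs()]). The same
#' parameters apply unchanged to raw and time-correlated movies.
#'
#' @param stack an [image_stack()].
#' @param detection a [detection_params()].
#' @param merge a [merge_params()] or `NULL` for no grouping.
#' @param calibration a [photon_calibration()] mapping movie units to
#'   photons before fitting.
#' @return a [loc_table()].
#' @export
localize_stack <- function(stack, detection = detection_params(),
                           merge = NULL,
                           calibration = photon_calibration()) {
  N <- n_frames(stack)
  px <- stack$pixel_size
  out <- vector("list", N)
  for (t in seq_len(N)) {
    fr <- (get_frame(stack, t) - calibration$offset) /
      calibration$counts_per_photon
    wl <- wavelet_filter(fr, detection$wavelet_order, detection$wavelet_scale)
    pk <- find_peaks(wl$filtered, wl$first_level, detection)
    if (nrow(pk) == 0) next
    tab <- fit_gaussian(fr, pk, detection, px)
    if (nrow(tab)) { tab$frame <- t; out[[t]] <- tab }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  tab <- if (length(out)) do.call(rbind, out) else loc_table()
  tab$id <- seq_len(nrow(tab))
  class(tab) <- c("loc_table", "data.frame")
  if (!is.null(merge) && nrow(tab)) tab <- merge_locs(tab, merge)
  tab
}

#' Group localizations of one emitter across frames
#'
#' Greedy chaining: a localization joins an open track if it lies within
#' `max_distance` of the track's running intensity-weighted mean and the
#' frame gap is at most `off_frames + 1`. Merged rows take the
#' intensity-weighted mean position, summed intensity, first frame, and
#' uncertainty recomputed as `1 / sqrt(sum(1 / sigma_i^2))`.
#'
#' @param table a [loc_table()] (sorted by frame internally).
#' @param merge a [merge_params()].
#' @return merged [loc_table()] with one row per track (unique `id`).
#' @export
merge_locs <- function(table, merge) {
  if (nrow(table) == 0) return(table)
  tab <- table[order(table$frame), , drop = FALSE]
  tid <- merge_tracks_cpp(tab$frame, tab$x, tab$y,
                          ifelse(is.finite(tab$intensity) & tab$intensity > 0,
                                 tab$intensity, 1),
                          merge$max_distance, merge$off_frames)
  w <- ifelse(is.finite(tab$intensity) & tab$intensity > 0, tab$intensity, 1)
  agg <- function(f) as.numeric(tapply(seq_len(nrow(tab)), tid, f))
  out <- loc_table(
    frame = agg(function(i) tab$frame[i][1]),
    x = agg(function(i) sum(tab$x[i] * w[i]) / sum(w[i])),
    y = agg(function(i) sum(tab$y[i] * w[i]) / sum(w[i])),
    sigma = agg(function(i) sum(tab$sigma[i] * w[i]) / sum(w[i])),
    intensity = agg(function(i) sum(tab$intensity[i])),
    background = agg(function(i) mean(tab$background[i])),
    uncertainty = agg(function(i) {
      u <- tab$uncertainty[i]
      u <- u[is.finite(u) & u > 0]
      if (!length(u)) NA_real_ else 1 / sqrt(sum(1 / u^2))
    }),
    id = seq_along(unique(tid)))
  out[order(out$frame), , drop = FALSE]
}

#' Run an external reconstruction back-end on a movie
#'
#' Writes the movie to a temporary TIFF, substitutes `{in}` and `{out}` in
#' the command template, runs it, and parses the resulting localization
#' CSV. Applying this contract to the output of [tc_transform()] yields a
#' time-correlated reconstruction with any third-party localizer.
#'
#' @param stack an [image_stack()].
#' @param command_template shell command containing `{in}` and `{out}`.
#' @return a [loc_table()].
#' @export
external_localizer <- function(stack, command_template) {
  tif <- tempfile(fileext = ".tif")
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tif, csv, sidecar_path(tif))), add = TRUE)
  write_stack(stack, tif)
  cmd <- gsub("{out}", csv, gsub("{in}", tif, command_template, fixed = TRUE),
              fixed = TRUE)
  status <- suppressWarnings(system(cmd))
  if (status != 0)
    stop("external localizer failed (exit ", status, "): ", cmd)
  if (!file.exists(csv)) stop("external localizer produced no output table")
  tryCatch(read_locs(csv),
           error = function(e) stop("unparsable external localizer output: ",
                                    conditionMessage(e)))
}
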
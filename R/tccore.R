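#' Lag-indexed autocorrelation curve
#'
#' @param values autocovariance (or normalized autocorrelation) per lag,
#'   starting at lag 0.
#' @param lag_step lag spacing in frames.
#' @param normalized whether `values[1]` has been scaled to 1.
#' @return object of class `acf_curve`.
#' @export
acf_curve <- function(values, lag_step = 1, normalized = FALSE) {
  if (length(values) < 2) stop("an ACF needs at least 2 lags")
  if (!all(is.finite(values))) stop("non-finite ACF values")
  structure(list(values = as.numeric(values), lag_step = lag_step,
                 n_lags = length(values), normalized = normalized),
            class = "acf_curve")
}

#' Analytic model fluorophore autocorrelation
#'
#' For a two-state telegraph emitter the intensity autocorrelation decays as
#' a single exponential with correlation time
#' `tau_c = t_on * t_off / (t_on + t_off)`:
#' `AC_f(k) = exp(-k * frame_period / tau_c)`, normalized to 1 at lag 0.
#'
#' @param blink a [blink_model()].
#' @param frame_period seconds per frame.
#' @param n_lags number of lags (from 0).
#' @return normalized [acf_curve()].
#' @export
model_acf <- function(blink, frame_period, n_lags) {
  stopifnot(n_lags >= 2, frame_period > 0)
  if (blink$t_on <= 0 || blink$t_off <= 0)
    stop("dwell times must be positive")
  tau_c <- blink$t_on * blink$t_off / (blink$t_on + blink$t_off)
  k <- seq_len(n_lags) - 1
  acf_curve(exp(-k * frame_period / tau_c), normalized = TRUE)
}

#' Empirical model autocorrelation from representative data
#'
#' Averages per-pixel normalized autocovariances over the brightest pixels
#' (by temporal-variance ranking above `quantile`), then renormalizes to 1
#' at lag 0. Serves as the data-driven alternative to [model_acf()].
#'
#' @param stack an [image_stack()].
#' @param quantile temporal-variance quantile above which pixels qualify.
#' @param n_pixels number of qualifying pixels to average.
#' @param n_lags lags to keep.
#' @return normalized [acf_curve()].
#' @export
empirical_model_acf <- function(stack, quantile = 0.99, n_pixels = 50,
                                n_lags = 50) {
  fr <- stack$frames
  N <- dim(fr)[1]
  if (N <= n_lags) stop("movie shorter than the requested number of lags")
  px <- matrix(fr, nrow = N)                   # frames x pixels
  v <- apply(px, 2, stats::var)
  if (max(v) <= 0) stop("degenerate movie: all pixels constant")
  ord <- order(v, decreasing = TRUE)
  keep <- ord[seq_len(min(n_pixels, max(1, sum(v >= stats::quantile(v, quantile)))))]
  curves <- vapply(keep, function(j) {
    ac <- pixel_acf(px[, j], n_lags)$values
    if (ac[1] > 0) ac / ac[1] else rep(0, n_lags)
  }, numeric(n_lags))
  m <- rowMeans(curves)
  if (m[1] <= 0) stop("degenerate movie: zero-variance model pixels")
  acf_curve(m / m[1], normalized = TRUE)
}

#' Unnormalized autocovariance of one pixel trajectory
#'
#' `AC(k) = (1/(n-k)) * sum_t (I_t - mean)(I_{t+k} - mean)` for
#' `k = 0 .. n_lags - 1`. Deliberately not normalized: the amplitude
#' information (square of the pixel's signal) must survive so that the
#' downstream covariance against the model preserves spatial contrast.
#' A constant trajectory yields an all-zero curve.
#'
#' @param trajectory intensity sequence.
#' @param n_lags lags to compute (`2 <= n_lags <= length(trajectory)`).
#' @return [acf_curve()] in squared-intensity units.
#' @export
pixel_acf <- function(trajectory, n_lags) {
  n <- length(trajectory)
  stopifnot(n_lags >= 2, n >= n_lags)
  x <- trajectory - mean(trajectory)
  v <- vapply(seq_len(n_lags) - 1, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / (n - k)
  }, numeric(1))
  acf_curve(v)
}

#' Parameters of the time-correlation transform
#'
#' @param mw moving-window length, frames.
#' @param step window shift between output frames (default 1).
#' @param n_lags lags used per window; defaults to `floor(mw / 2)` (lags
#'   beyond half the window average over too few samples).
#' @param model normalized model [acf_curve()] (e.g. from [model_acf()]);
#'   recycled/truncated to `n_lags`.
#' @param clip_negative clip negative covariances to 0 (default `TRUE`).
#' @param include_lag0 include lag 0 (which carries shot-noise variance) in
#'   the covariance (default `TRUE`).
#' @return object of class `tc_params`.
#' @export
tc_params <- function(mw, step = 1, n_lags = NULL, model,
                      clip_negative = TRUE, include_lag0 = TRUE) {
  n_lags <- n_lags %||% max(2L, floor(mw / 2))
  stopifnot(mw >= 2, step >= 1, n_lags >= 2, n_lags <= mw)
  if (!inherits(model, "acf_curve")) stop("`model` must be an acf_curve")
  structure(list(mw = as.integer(mw), step = as.integer(step),
                 n_lags = as.integer(n_lags), model = model,
                 clip_negative = clip_negative,
                 include_lag0 = include_lag0),
            class = "tc_params")
}

tc_lags_model <- function(params) {
  lags <- if (params$include_lag0) 0:(params$n_lags - 1) else 1:params$n_lags
  mv <- params$model$values
  if (length(mv) < max(lags) + 1)
    stop("model ACF has fewer lags than requested (need ", max(lags) + 1, ")")
  m <- mv[lags + 1]
  list(lags = as.integer(lags), model_c = m - mean(m))
}

#' One frame of the time-correlation transform
#'
#' For each pixel, the windowed trajectory `I_j(t0 .. t0+mw-1)` is reduced to
#' its unnormalized autocovariance, and the output value is the covariance
#' of that curve with the model decay over the used lags. Pixels whose
#' autocorrelation decays very differently from the model score near zero;
#' negative covariances are clipped when `clip_negative`.
#'
#' @param stack an [image_stack()].
#' @param t0 1-based start frame of the window.
#' @param params a [tc_params()].
#' @return `H x W` matrix.
#' @export
tc_frame <- function(stack, t0, params) {
  N <- n_frames(stack)
  if (t0 < 1 || t0 + params$mw - 1 > N)
    stop("window [", t0, ", ", t0 + params$mw - 1, "] outside movie of ", N)
  lm <- tc_lags_model(params)
  H <- dim(stack$frames)[2]; W <- dim(stack$frames)[3]
  traj <- matrix(aperm(stack$frames[t0:(t0 + params$mw - 1), , , drop = FALSE],
                       c(2, 3, 1)), nrow = H * W)
  v <- tc_transform_cpp(traj, lm$model_c, lm$lags, params$mw, 1L,
                        params$clip_negative)
  matrix(v[, 1], H, W)
}

#' Time-correlation transform of a movie
#'
#' Slides the moving window from frame 1 in steps of `params$step` and
#' stacks the per-window covariance images. For `step = 1` the output has
#' exactly `N - mw` frames; only full windows are used. Output values are
#' non-negative when `clip_negative`; the output frame period is
#' `step * frame_period`.
#'
#' @param stack an [image_stack()] with more than `mw` frames.
#' @param params a [tc_params()].
#' @return an [image_stack()] (the time-correlated movie).
#' @export
tc_transform <- function(stack, params) {
  N <- n_frames(stack)
  if (params$mw >= N)
    stop("moving window (", params$mw, ") must be shorter than the movie (",
         N, ")")
  lm <- tc_lags_model(params)
  H <- dim(stack$frames)[2]; W <- dim(stack$frames)[3]
  traj <- matrix(aperm(stack$frames, c(2, 3, 1)), nrow = H * W)
  # windows start at 1, 1+step, ...; with step 1 keep N - mw frames
  n_out <- if (params$step == 1) N - params$mw
           else floor((N - params$mw - 1) / params$step) + 1
  v <- tc_transform_cpp(traj, lm$model_c, lm$lags, params$mw, params$step,
                        params$clip_negative)
  v <- v[, seq_len(n_out), drop = FALSE]
  arr <- aperm(array(v, dim = c(H, W, n_out)), c(3, 1, 2))
  image_stack(arr, frame_period = params$step * stack$frame_period,
              pixel_size = stack$pixel_size)
}

#' Theoretical optimal moving-window length
#'
#' The window should match the emitter's correlation time expressed in
#' output time steps: `round((t_on * t_off / (t_on + t_off)) /
#' (step * frame_period))`.
#'
#' @param blink a [blink_model()].
#' @param frame_period seconds per frame.
#' @param step tcData time step, frames.
#' @return integer window length in frames.
#' @export
theoretical_mw <- function(blink, frame_period, step = 1) {
  stopifnot(frame_period > 0, step >= 1)
  tau_c <- blink$t_on * blink$t_off / (blink$t_on + blink$t_off)
  as.integer(round(tau_c / (step * frame_period)))
}

#' Moving-average smoothing of an ACF
#'
#' Centred moving average whose window shrinks at the edges; `window = 1`
#' is the identity.
#'
#' @param acf an [acf_curve()].
#' @param window smoothing window, frames (1 .. n_lags).
#' @return smoothed [acf_curve()].
#' @export
smooth_acf <- function(acf, window) {
  stopifnot(window >= 1, window <= acf$n_lags)
  v <- acf$values
  h <- (window - 1) %/% 2
  out <- vapply(seq_along(v), function(i) {
    mean(v[max(1, i - h):min(length(v), i + h)])
  }, numeric(1))
  acf_curve(out, lag_step = acf$lag_step, normalized = acf$normalized)
}

#' Linearity cutoff of a log-ACF trajectory
#'
#' The early part of a signal pixel's autocorrelation decays as a single
#' exponential (the fluorophore's intrinsic blinking decay), so its log is
#' linear in the lag; later lags pick up slower decays from background and
#' overlapping trajectories. The cutoff is the longest prefix of
#' `log(AC(k))`, `k = 1 ..` (truncated at the first non-positive value),
#' over which the absolute Pearson correlation with the lag index stays at
#' or above `r_min` for every prefix length from `min_prefix` up. A cutoff
#' of 0 marks a background-like trajectory whose linearity fails from the
#' start (or with fewer than `min_prefix` usable lags).
#'
#' @param acf an [acf_curve()] (typically smoothed, see [smooth_acf()]).
#' @param r_min Pearson threshold (default 0.9).
#' @param min_prefix shortest prefix considered (default 5; avoids
#'   spuriously perfect short fits).
#' @return list with `cutoff` (frames), `pearson_trace` (|r| per prefix
#'   length, named by prefix) and `usable_lags`.
#' @export
pi_cutoff <- function(acf, r_min = 0.9, min_prefix = 5) {
  v <- acf$values[-1]                     # lags 1..
  pos <- which(v <= 0)
  K <- if (length(pos)) pos[1] - 1 else length(v)
  if (K < min_prefix)
    return(list(cutoff = 0L, pearson_trace = numeric(0), usable_lags = K))
  g <- log(v[seq_len(K)])
  lens <- min_prefix:K
  r <- vapply(lens, function(L) abs(stats::cor(g[seq_len(L)], seq_len(L))),
              numeric(1))
  r[is.na(r)] <- 0
  names(r) <- lens
  bad <- which(r < r_min)
  cutoff <- if (!length(bad)) K else if (bad[1] == 1) 0L else lens[bad[1] - 1]
  list(cutoff = as.integer(cutoff), pearson_trace = r, usable_lags = K)
}

#' Select the moving window from probe-pixel autocorrelations
#'
#' Picks `n_probe` pixels at spread intensity quantiles of the
#' sum-intensity image (including one low-signal pixel expected to contain
#' only background), computes each pixel's full-trajectory autocovariance,
#' smooths it, and finds its log-ACF linearity cutoff ([pi_cutoff()]). The
#' chosen window is the minimum over the non-zero cutoffs; zero cutoffs
#' flag background probes and are excluded.
#'
#' @param stack an [image_stack()].
#' @param n_probe number of probe pixels (>= 2).
#' @param r_min Pearson threshold.
#' @param smoothing_window ACF moving-average window.
#' @param n_lags lags of the full-trajectory ACF (default
#'   `min(300, floor(N / 3))`).
#' @param quantiles sum-image quantiles at which probes are taken.
#' @param seed unused except to break ties among equal-intensity pixels
#'   reproducibly.
#' @return list with `mw`, per-probe `reports`, `probes`
#'   (`data.frame(row, col, quantile, cutoff)`).
#' @export
optimal_mw <- function(stack, n_probe = 4, r_min = 0.9,
                       smoothing_window = 9, n_lags = NULL,
                       quantiles = c(0.999, 0.99, 0.9, 0.2), seed = NULL) {
  stopifnot(n_probe >= 2)
  if (!is.null(seed)) set.seed(seed)
  N <- n_frames(stack)
  n_lags <- n_lags %||% min(300L, floor(N / 3))
  quantiles <- rep_len(quantiles, n_probe)
  H <- dim(stack$frames)[2]; W <- dim(stack$frames)[3]
  sums <- apply(stack$frames, c(2, 3), sum)
  ord <- order(as.vector(sums))            # ascending
  idx <- unique(pmax(1, pmin(length(ord), ceiling(quantiles * length(ord)))))
  reports <- list()
  probes <- data.frame(row = integer(), col = integer(),
                       quantile = numeric(), cutoff = integer())
  for (i in seq_along(idx)) {
    lin <- ord[idx[i]]
    row <- ((lin - 1) %% H) + 1
    col <- ((lin - 1) %/% H) + 1
    ac <- pixel_acf(stack$frames[, row, col], n_lags)
    ac <- smooth_acf(ac, min(smoothing_window, ac$n_lags))
    rep_i <- pi_cutoff(ac, r_min = r_min)
    rep_i$pixel <- c(row = row, col = col)
    rep_i$smoothing_window <- smoothing_window
    reports[[i]] <- rep_i
    probes <- rbind(probes, data.frame(row = row, col = col,
                                       quantile = quantiles[i],
                                       cutoff = rep_i$cutoff))
  }
  nz <- probes$cutoff[probes$cutoff > 0]
  if (!length(nz))
    stop("all probe pixels look like background (every linearity cutoff 0)")
  list(mw = min(nz), reports = reports, probes = probes)
}
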
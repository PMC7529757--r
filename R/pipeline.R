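#' Default end-to-end run configuration
#'
#' Nested list consumed by [run_pipeline()]; any subset can be overridden in
#' a YAML file read with [read_run_config()]. The defaults describe a
#' 10-wing Siemens-star field of 250 emitters on 25 x 25 px at 165 nm/px,
#' imaged at 2000 fps for 2 s with on/off dwell times of 180/120 ms, a 5 s
#' bleaching time and standard EM-camera noise.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    simulator = list(
      phantom = list(kind = "siemens_star", wings = 10, field = 25,
                     n_emitters = 250),
      blink = list(t_on = 0.18, t_off = 0.12, t_bleach = 5,
                   photon_rate = 5e5),
      optics = list(na = 1.3, wavelength = 600, magnification = 100,
                    detector_pixel = 16.5, readout_noise = 1.6,
                    dark_current = 0.06, quantum_efficiency = 0.7,
                    gain = 6, baseline = 100),
      n_frames = 4000, frame_period = 5e-4, background_rate = 1),
    tc = list(mw = "matched", step = 1, n_lags = NULL,
              model = "analytic", clip_negative = TRUE),
    localizer = list(threshold_factor = 1.0, fit_radius = NULL,
                     initial_sigma = NULL, filter_sigma_range = c(0.6, 1.5),
                     merge = list(max_distance = 60, off_frames = 20)),
    metrics = list(render_px = 5, sigma_render = 2, match_radius = 82.5,
                   radii = seq(13.75, 137.5, length.out = 10))
  )
}

#' Preset study configurations
#'
#' Three simulated-experiment presets used throughout the package:
#' \describe{
#'   \item{`"fast_star"`}{250 emitters on a 10-wing Siemens star, 25 x 25 px
#'     at 165 nm/px, 2000 fps for 2 s, near-zero background (the
#'     [default_config()]).}
#'   \item{`"large_field"`}{600 emitters on a 100 x 100 px star at 1000 fps
#'     for 2 s, negligible background, grouping enabled.}
#'   \item{`"dense_background"`}{high density (about 100 emitters/um^2 of
#'     star area, 670 emitters) at 1000 fps with an equally sized
#'     out-of-focus emitter population (defocus factor 4) plus uniform
#'     background: the low signal-to-background regime.}
#' }
#'
#' @param preset preset name.
#' @return nested configuration list for [run_pipeline()].
#' @export
study_config <- function(preset = c("fast_star", "large_field",
                                    "dense_background")) {
  preset <- match.arg(preset)
  cfg <- default_config()
  if (preset == "large_field") {
    cfg$simulator$phantom <- list(kind = "siemens_star", wings = 10,
                                  field = 100, n_emitters = 600)
    cfg$simulator$n_frames <- 2000
    cfg$simulator$frame_period <- 1e-3
  } else if (preset == "dense_background") {
    cfg$simulator$phantom <- list(
      kind = "siemens_star", wings = 10, field = 25, n_emitters = 670,
      background_emitters = list(count = 670, defocus_sigma_factor = 4))
    cfg$simulator$n_frames <- 2000
    cfg$simulator$frame_period <- 1e-3
    cfg$simulator$background_rate <- 5
  }
  cfg
}

#' Deterministic child seed for sweeps and replicates
#'
#' Pure integer hash of (master seed, sweep value index, replicate index);
#' keeps independent arms decorrelated while making every arm reproducible
#' from the master seed alone.
#'
#' @param master master seed.
#' @param value_index 1-based sweep-value index.
#' @param replicate 1-based replicate index.
#' @return integer seed below 2^31.
#' @export
child_seed <- function(master, value_index = 1, replicate = 1) {
  h <- (abs(as.numeric(master)) %% 2147483647) * 48271 +
    value_index * 69621 + replicate * 16807
  as.integer(h %% 2147483629 + 1)
}

build_sim <- function(cfg) {
  s <- cfg$simulator
  list(phantom = do.call(phantom, s$phantom),
       blink = do.call(blink_model, s$blink),
       optics = do.call(optics_camera, s$optics),
       n_frames = s$n_frames, frame_period = s$frame_period,
       background_rate = s$background_rate %||% 0)
}

#' Kinetics-matched moving window
#'
#' One third of the blink correlation time, in frames:
#' `round(tau_c / (3 * frame_period))`, never below 4. Windows of this
#' length sit inside the empirically optimal quality band (about 20-30
#' frames at 1000 fps for 180/120 ms kinetics): shorter windows approach
#' plain frame-by-frame reconstruction, while windows near or above `tau_c`
#' admit several overlapping emitter bursts per window and blur the
#' time-correlated frames.
#'
#' @param blink a [blink_model()].
#' @param frame_period seconds per frame.
#' @return integer window length in frames.
#' @export
matched_mw <- function(blink, frame_period) {
  tau_c <- blink$t_on * blink$t_off / (blink$t_on + blink$t_off)
  max(4L, as.integer(round(tau_c / (3 * frame_period))))
}

resolve_mw <- function(cfg, stack, blink) {
  mw <- cfg$tc$mw
  step <- cfg$tc$step %||% 1
  if (is.numeric(mw)) return(as.integer(mw))
  switch(mw,
         matched = matched_mw(blink, stack$frame_period),
         theoretical = theoretical_mw(blink, stack$frame_period, step),
         optimal = optimal_mw(stack)$mw,
         stop("unknown mw rule: ", mw))
}

evaluate_arm <- function(locs, gt_pos, field_nm, metrics_cfg) {
  rec <- render_image(locs, pixel = metrics_cfg$render_px,
                      field_nm = field_nm,
                      sigma_render = metrics_cfg$sigma_render)
  gtr <- render_image(gt_pos, pixel = metrics_cfg$render_px,
                      field_nm = field_nm,
                      sigma_render = metrics_cfg$sigma_render)
  fc <- frc_curve(rec, gtr, pixel = metrics_cfg$render_px)
  res <- frc_resolution(fc)
  m <- match_locs(locs, gt_pos, metrics_cfg$match_radius)
  prec <- loc_precision(m, locs)
  ji_by_radius <- vapply(metrics_cfg$radii, function(r)
    jaccard(match_locs(locs, gt_pos, r)), numeric(1))
  list(n_locs = nrow(locs), frc_nm = as.numeric(res),
       frc_unresolved = isTRUE(attr(res, "unresolved_limit")),
       jaccard = jaccard(m), ji_by_radius = ji_by_radius,
       precision_nm = prec$median, tp = m$tp, fp = m$fp, fn = m$fn)
}

#' Run the full simulate / transform / localize / evaluate pipeline
#'
#' Simulates a movie (or ingests one given as `stack` + `gt`), builds the
#' time-correlated movie with the configured window, localizes both movies
#' with identical parameters, and evaluates both against ground truth.
#'
#' @param config nested list as from [default_config()] /
#'   [read_run_config()].
#' @param seed overrides `config$seed` when given.
#' @param out_dir optional run directory: intermediates (movies, tables)
#'   and a JSON report are written there.
#' @return report list with `smlm` and `tcsmlm` metric blocks, the resolved
#'   `mw`, and the resolved configuration.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL) {
  cfg <- modifyList(default_config(), config)
  seed <- seed %||% cfg$seed
  sim <- build_sim(cfg)
  simres <- simulate_movie(sim$phantom, sim$blink, sim$optics, sim$n_frames,
                           sim$frame_period, seed = seed,
                           background_rate = sim$background_rate)
  raw <- simres$stack
  mw <- resolve_mw(cfg, raw, sim$blink)
  step <- cfg$tc$step %||% 1
  n_lags <- cfg$tc$n_lags %||% max(2L, floor(mw / 2))
  model <- if (identical(cfg$tc$model, "empirical"))
    empirical_model_acf(raw, n_lags = n_lags) else
    model_acf(sim$blink, raw$frame_period, n_lags)
  params <- tc_params(mw = mw, step = step, n_lags = n_lags, model = model,
                      clip_negative = cfg$tc$clip_negative %||% TRUE)
  tc <- tc_transform(raw, params)

  # default starting width: the optical PSF expressed in pixels; the fit
  # window spans about 3 sigma
  init_sigma <- cfg$localizer$initial_sigma %||%
    (sim$optics$sigma_psf / sim$optics$pixel_size)
  fit_radius <- cfg$localizer$fit_radius %||% max(2, ceiling(3 * init_sigma))
  det <- detection_params(threshold_factor = cfg$localizer$threshold_factor,
                          fit_radius = fit_radius,
                          initial_sigma = init_sigma)
  mrg <- if (!is.null(cfg$localizer$merge))
    do.call(merge_params, cfg$localizer$merge) else NULL
  raw_cal <- camera_calibration(sim$optics)
  tc_cal <- tc_photon_calibration(tc, raw, raw_cal)
  # shared fitted-width quality filter, in multiples of the optical PSF
  # width (covers both the raw PSF and its sqrt(2)-narrowed tc counterpart)
  srange <- cfg$localizer$filter_sigma_range %||% c(0, Inf)
  qfilter <- function(tab) {
    tab[tab$sigma >= srange[1] * sim$optics$sigma_psf &
        tab$sigma <= srange[2] * sim$optics$sigma_psf, , drop = FALSE]
  }
  locs_raw <- qfilter(localize_stack(raw, det, NULL, raw_cal))
  locs_tc <- qfilter(localize_stack(tc, det, NULL, tc_cal))
  if (!is.null(mrg)) {
    locs_raw <- merge_locs(locs_raw, mrg)
    locs_tc <- merge_locs(locs_tc, mrg)
  }

  field_nm <- sim$phantom$field * sim$optics$pixel_size
  gt_pos <- simres$gt$emitters
  report <- list(
    seed = seed, mw = mw, step = step,
    smlm = evaluate_arm(locs_raw, gt_pos, field_nm, cfg$metrics),
    tcsmlm = evaluate_arm(locs_tc, gt_pos, field_nm, cfg$metrics),
    config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(raw, file.path(out_dir, "raw.tif"))
    write_stack(tc, file.path(out_dir, "tc.tif"))
    write_locs(locs_raw, file.path(out_dir, "locs_smlm.csv"))
    write_locs(locs_tc, file.path(out_dir, "locs_tcsmlm.csv"))
    write_ground_truth(simres$gt, file.path(out_dir, "gt.csv"))
    jsonlite::write_json(report[c("seed", "mw", "step", "smlm", "tcsmlm")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

set_config_value <- function(cfg, variable, value) {
  switch(variable,
    mw = { cfg$tc$mw <- value; cfg },
    density = { cfg$simulator$phantom$n_emitters <- value; cfg },
    frame_rate = {
      total <- cfg$simulator$n_frames * cfg$simulator$frame_period
      cfg$simulator$frame_period <- 1 / value
      cfg$simulator$n_frames <- round(total * value)
      cfg
    },
    sbr = {
      cfg$simulator$phantom$background_emitters <-
        modifyList(cfg$simulator$phantom$background_emitters %||%
                     list(count = 50, defocus_sigma_factor = 4), list())
      cfg$simulator$background_rate <- value
      cfg
    },
    stop("unknown sweep variable: ", variable))
}

#' Replicate-averaged parameter sweep
#'
#' Runs [run_pipeline()] for every combination of sweep value and replicate
#' (child seeds derived from the master seed), and reports per-value mean
#' and standard error of the mean of the headline metrics for both arms.
#'
#' @param variable one of `"mw"`, `"density"`, `"frame_rate"`, `"sbr"`.
#' @param values sweep values.
#' @param replicates simulations per value (default 5).
#' @param base base configuration.
#' @param seed master seed.
#' @return `data.frame` with one row per (value, metric, arm): columns
#'   `value, arm, metric, mean, sem, n`.
#' @export
run_sweep <- function(variable, values, replicates = 5,
                      base = default_config(), seed = 1) {
  stopifnot(replicates >= 1, length(values) >= 1)
  rows <- list()
  for (vi in seq_along(values)) {
    cfg <- set_config_value(base, variable, values[vi])
    per_rep <- lapply(seq_len(replicates), function(r) {
      rep_seed <- child_seed(seed, vi, r)
      rp <- run_pipeline(cfg, seed = rep_seed)
      data.frame(arm = c("smlm", "tcsmlm"),
                 frc_nm = c(rp$smlm$frc_nm, rp$tcsmlm$frc_nm),
                 jaccard = c(rp$smlm$jaccard, rp$tcsmlm$jaccard),
                 precision_nm = c(rp$smlm$precision_nm,
                                  rp$tcsmlm$precision_nm))
    })
    reps <- do.call(rbind, per_rep)
    for (arm in c("smlm", "tcsmlm"))
      for (metric in c("frc_nm", "jaccard", "precision_nm")) {
        v <- reps[reps$arm == arm, metric]
        v <- v[is.finite(v)]
        sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
        rows[[length(rows) + 1]] <- data.frame(
          value = values[vi], arm = arm, metric = metric,
          mean = if (length(v)) mean(v) else NA_real_,
          sem = sem, n = length(v))
      }
  }
  do.call(rbind, rows)
}
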
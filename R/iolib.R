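#' Movie container for raw and time-correlated data
#'
#' An `image_stack` holds a movie as a `frames x rows x cols` numeric array
#' together with the acquisition frame period and the sample-plane pixel
#' size. Raw camera movies and the time-correlated movies produced by
#' [tc_transform()] share this container.
#'
#' @param frames numeric array `(T, H, W)`, or a list of equal-size matrices.
#' @param frame_period seconds per frame (> 0).
#' @param pixel_size sample-plane pixel size in nm (> 0).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_period, pixel_size) {
  if (is.list(frames)) {
    frames <- simplify2array(frames)          # H x W x T
    frames <- aperm(frames, c(3, 1, 2))
  }
  if (length(dim(frames)) != 3)
    stop("`frames` must be a (T, H, W) array")
  storage.mode(frames) <- "double"
  if (dim(frames)[1] < 1) stop("empty movie: at least one frame required")
  if (!all(is.finite(frames))) stop("non-finite intensities in movie")
  stopifnot(frame_period > 0, pixel_size > 0)
  structure(list(frames = frames,
                 frame_period = as.numeric(frame_period),
                 pixel_size = as.numeric(pixel_size)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px, %g ms/frame, %g nm/px\n",
              d[1], d[2], d[3], 1000 * x$frame_period, x$pixel_size))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an [image_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1L]

#' Extract one frame as a matrix
#' @param stack an [image_stack()].
#' @param t 1-based frame index.
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(stack, t) {
  stopifnot(t >= 1, t <= n_frames(stack))
  matrix(stack$frames[t, , ], nrow = dim(stack$frames)[2])
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read a movie from a multipage TIFF
#'
#' Grayscale 16-bit unsigned TIFFs are read as raw counts. 32-bit float
#' TIFFs written by [write_stack()] are rescaled back to physical values
#' using the offset/scale stored in the sidecar metadata file. Frame period
#' and pixel size are taken from the sidecar when present, otherwise from
#' the arguments.
#'
#' @param path TIFF file path.
#' @param frame_period,pixel_size metadata fallbacks when no sidecar exists.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, frame_period = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- list()
  if (file.exists(sidecar_path(path)))
    meta <- yaml::read_yaml(sidecar_path(path))
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                    info = TRUE)),
    error = function(e) stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")"))
  if (length(pages) == 0) stop("empty TIFF: ", path)
  bps <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bps) && bps == 32) {
    # float storage: tiff clamps to [0,1]; re-read unscaled and undo mapping
    pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
    off <- meta$float_offset %||% 0
    sc <- meta$float_scale %||% 1
    pages <- lapply(pages, function(m) m * sc + off)
  }
  fp <- meta$frame_period %||% frame_period %||% 0.01
  px <- meta$pixel_size %||% pixel_size %||% 160
  image_stack(pages, frame_period = fp, pixel_size = px)
}

#' Write a movie to a multipage TIFF
#'
#' Non-negative integer movies with maximum below 2^16 are written as 16-bit
#' unsigned; anything else is written as 32-bit float, linearly rescaled
#' into `[0, 1]` with the affine map recorded in a YAML sidecar so that
#' [read_stack()] restores physical values. The sidecar also carries
#' `frame_period` and `pixel_size`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  fr <- stack$frames
  T_ <- dim(fr)[1]
  pages <- lapply(seq_len(T_), function(t) matrix(fr[t, , ], nrow = dim(fr)[2]))
  meta <- list(frame_period = stack$frame_period, pixel_size = stack$pixel_size)
  is_int <- all(fr == round(fr)) && min(fr) >= 0 && max(fr) <= 65535
  if (is_int) {
    tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                    bits.per.sample = 16L)
  } else {
    lo <- min(fr); hi <- max(fr)
    sc <- if (hi > lo) hi - lo else 1
    meta$float_offset <- lo
    meta$float_scale <- sc
    suppressWarnings(
      tiff::writeTIFF(lapply(pages, function(m) (m - lo) / sc), path,
                      bits.per.sample = 32L, reduce = FALSE))
  }
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

loc_columns <- c("id", "frame", "x", "y", "sigma", "intensity",
                 "background", "uncertainty")

#' Construct a localization table
#'
#' Positions are in nm with the origin at the outer corner of pixel (0,0):
#' a localization at the centre of pixel (0,0) has `x = y = pixel_size / 2`.
#' Frames are 1-based.
#'
#' @param frame 1-based frame indices.
#' @param x,y positions in nm.
#' @param sigma fitted Gaussian width in nm.
#' @param intensity photons.
#' @param background photons per pixel (fit offset).
#' @param uncertainty localization uncertainty in nm.
#' @param id integer identifier (unique after merging).
#' @return `data.frame` of class `loc_table`.
#' @export
loc_table <- function(frame = integer(), x = numeric(), y = numeric(),
                      sigma = numeric(), intensity = numeric(),
                      background = numeric(), uncertainty = numeric(),
                      id = seq_along(frame)) {
  n <- length(frame)
  df <- data.frame(id = as.integer(id), frame = as.integer(frame),
                   x = as.numeric(x), y = as.numeric(y),
                   sigma = rep_len(as.numeric(sigma), n),
                   intensity = rep_len(as.numeric(intensity), n),
                   background = rep_len(as.numeric(background), n),
                   uncertainty = rep_len(as.numeric(uncertainty), n))
  class(df) <- c("loc_table", "data.frame")
  df
}

# ThunderSTORM-style header names with bracketed unit suffixes
ts_header <- c(id = "id", frame = "frame", x = "x [nm]", y = "y [nm]",
               sigma = "sigma [nm]", intensity = "intensity [photon]",
               background = "offset [photon]",
               uncertainty = "uncertainty [nm]")

#' Read a localization table (ThunderSTORM CSV dialect)
#'
#' Headers may carry bracketed unit suffixes (`"x [nm]"`); units are assumed
#' to be nm and photons. Unknown columns are preserved. `frame`, `x` and `y`
#' are mandatory.
#'
#' @param path CSV path.
#' @return a [loc_table()].
#' @export
read_locs <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- sub("^\"?(.*?)\"?$", "\\1", names(df))
  canon <- sub("\\s*\\[[^]]*\\]\\s*$", "", names(df))
  canon[canon == "offset"] <- "background"
  names(df) <- canon
  missing_cols <- setdiff(c("frame", "x", "y"), canon)
  if (length(missing_cols))
    stop("localization table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in setdiff(loc_columns, canon)) {
    df[[cc]] <- if (cc == "id") seq_len(nrow(df)) else rep(NA_real_, nrow(df))
  }
  df <- df[, c(loc_columns, setdiff(canon, loc_columns)), drop = FALSE]
  df$id <- as.integer(df$id); df$frame <- as.integer(df$frame)
  class(df) <- c("loc_table", "data.frame")
  df
}

#' Write a localization table (ThunderSTORM CSV dialect)
#'
#' @param table a [loc_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_locs <- function(table, path) {
  df <- as.data.frame(table)
  nm <- names(df)
  nm[match(names(ts_header), nm, nomatch = 0)] <-
    ts_header[names(ts_header) %in% nm]
  names(df) <- nm
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Ground-truth container
#'
#' @param emitters `data.frame(id, x, y)` true positions in nm.
#' @param activity `n_emitters x n_frames` matrix of per-frame emission
#'   fractions in `[0, 1]` (0 after photobleaching).
#' @param photon_rate photons per second emitted while fully on.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(emitters, activity, photon_rate) {
  stopifnot(nrow(emitters) == nrow(activity))
  structure(list(emitters = emitters, activity = activity,
                 photon_rate = photon_rate),
            class = "ground_truth")
}

#' Read/write ground truth as plain CSV
#'
#' Positions go to one CSV (`id, x [nm], y [nm]`), the per-frame activity
#' matrix to a second CSV with one row per emitter.
#'
#' @param gt a [ground_truth()].
#' @param positions_path,activity_path CSV paths.
#' @return [ground_truth()] (reader) or paths invisibly (writer).
#' @export
write_ground_truth <- function(gt, positions_path, activity_path = NULL) {
  pos <- gt$emitters
  names(pos) <- c("id", "x [nm]", "y [nm]")[seq_along(pos)]
  utils::write.csv(pos, positions_path, row.names = FALSE)
  if (!is.null(activity_path))
    utils::write.csv(as.data.frame(gt$activity), activity_path,
                     row.names = FALSE)
  invisible(c(positions_path, activity_path))
}

#' @rdname write_ground_truth
#' @param photon_rate photons/s used when reconstructing the object.
#' @export
read_ground_truth <- function(positions_path, activity_path = NULL,
                              photon_rate = NA_real_) {
  pos <- utils::read.csv(positions_path, check.names = FALSE)
  names(pos) <- sub("\\s*\\[[^]]*\\]\\s*$", "", names(pos))
  act <- if (!is.null(activity_path))
    as.matrix(utils::read.csv(activity_path)) else
    matrix(NA_real_, nrow(pos), 0)
  ground_truth(pos, act, photon_rate)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with nested `simulator`, `tc`, `localizer`,
#'   `metrics` and `seed` entries; missing entries fall back to defaults.
#' @return a nested list merged over [default_config()].
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
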
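#' Render a localization table to a super-resolved image
#'
#' Gaussian mode adds a unit-mass integrated Gaussian per localization, of
#' width `sigma_render` (or the row's own uncertainty when
#' `sigma_render = NULL`); histogram mode bins unit counts.
#'
#' @param table a [loc_table()] or a `data.frame(x, y)` in nm.
#' @param pixel render pixel size, nm.
#' @param field_nm rendered extent, nm (square); defaults to covering the
#'   localizations.
#' @param mode `"gaussian"` or `"histogram"`.
#' @param sigma_render Gaussian rendering width in nm (typically 1-2 nm).
#' @return numeric matrix (`row = y`).
#' @export
render_image <- function(table, pixel = 5, field_nm = NULL,
                         mode = c("gaussian", "histogram"),
                         sigma_render = 2) {
  mode <- match.arg(mode)
  stopifnot(pixel > 0)
  field_nm <- field_nm %||% (max(c(table$x, table$y, 0)) + 4 * pixel)
  n <- ceiling(field_nm / pixel)
  if (nrow(table) == 0) return(matrix(0, n, n))
  if (mode == "histogram") {
    img <- matrix(0, n, n)
    col <- pmin(n, pmax(1, floor(table$x / pixel) + 1))
    row <- pmin(n, pmax(1, floor(table$y / pixel) + 1))
    for (i in seq_along(row)) img[row[i], col[i]] <- img[row[i], col[i]] + 1
    return(img)
  }
  sig <- if (is.null(sigma_render)) table$uncertainty else
    rep_len(sigma_render, nrow(table))
  sig <- pmax(sig, pixel / 10)
  render_gaussian_cpp(table$x, table$y, sig, pixel, n, n)
}

#' Fourier ring correlation between two images
#'
#' `FRC(q) = Re(sum_ring F_A * conj(F_B)) / sqrt(sum_ring |F_A|^2 *
#' sum_ring |F_B|^2)` over rings one Fourier pixel wide.
#'
#' @param img_a,img_b equal-size square images.
#' @param pixel image pixel size, nm.
#' @return object of class `frc_curve`: `data.frame(spatial_frequency,
#'   correlation)` plus `pixel` attribute; frequencies in 1/nm.
#' @export
frc_curve <- function(img_a, img_b, pixel = 5) {
  if (!all(dim(img_a) == dim(img_b)))
    stop("images must have identical dimensions")
  if (nrow(img_a) != ncol(img_a)) stop("images must be square")
  n <- nrow(img_a)
  fa <- stats::fft(img_a - mean(img_a))
  fb <- stats::fft(img_b - mean(img_b))
  f1 <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) # cycles per image
  kr <- round(sqrt(outer(f1^2, f1^2, "+")))
  qmax <- floor(n / 2) - 1
  num <- Re(fa * Conj(fb)); pa <- Mod(fa)^2; pb <- Mod(fb)^2
  ring <- as.vector(pmin(kr, qmax + 1))
  s_num <- rowsum(as.vector(num), ring)
  s_pa <- rowsum(as.vector(pa), ring)
  s_pb <- rowsum(as.vector(pb), ring)
  q <- 1:qmax
  key <- match(q, as.integer(rownames(s_num)))
  corr <- s_num[key] / sqrt(s_pa[key] * s_pb[key])
  corr[!is.finite(corr)] <- 0
  out <- data.frame(spatial_frequency = q / (n * pixel),
                    correlation = as.numeric(corr))
  attr(out, "pixel") <- pixel
  class(out) <- c("frc_curve", "data.frame")
  out
}

#' FRC resolution at a threshold crossing
#'
#' The curve is lightly smoothed (3-ring moving average) and the resolution
#' is `1 / q*` at the first downward crossing of `threshold` (default 1/7),
#' with linear interpolation between rings. If the curve never drops below
#' the threshold the Nyquist bound `2 * pixel` is returned with attribute
#' `unresolved_limit = TRUE`.
#'
#' @param curve an [frc_curve()].
#' @param threshold crossing level (default `1/7`).
#' @return resolution in nm.
#' @export
frc_resolution <- function(curve, threshold = 1 / 7) {
  v <- curve$correlation
  sm <- vapply(seq_along(v), function(i)
    mean(v[max(1, i - 1):min(length(v), i + 1)]), numeric(1))
  q <- curve$spatial_frequency
  below <- which(sm < threshold)
  if (!length(below)) {
    res <- 2 * attr(curve, "pixel")
    attr(res, "unresolved_limit") <- TRUE
    return(res)
  }
  i <- below[1]
  if (i == 1) return(structure(1 / q[1], unresolved_limit = FALSE))
  f <- (sm[i - 1] - threshold) / (sm[i - 1] - sm[i])
  qs <- q[i - 1] + f * (q[i] - q[i - 1])
  structure(1 / qs, unresolved_limit = FALSE)
}

#' Match localizations against ground truth
#'
#' Greedy one-to-one matching by ascending pairwise distance among all
#' pairs within `radius`; unmatched test points are false positives,
#' unmatched ground-truth points false negatives.
#'
#' @param test `data.frame(x, y)` (nm) of localizations.
#' @param gt `data.frame(x, y)` (nm) of true positions.
#' @param radius matching radius, nm.
#' @return `list(tp, fp, fn, pairs, radius)` where `pairs` is a two-column
#'   matrix of (test, gt) row indices.
#' @export
match_locs <- function(test, gt, radius) {
  stopifnot(radius > 0)
  nt <- nrow(test); ng <- nrow(gt)
  if (nt == 0 || ng == 0)
    return(list(tp = 0L, fp = nt, fn = ng,
                pairs = matrix(integer(), 0, 2), radius = radius))
  pr <- list(); k <- 1
  chunk <- max(1, floor(2e7 / ng))
  for (lo in seq(1, nt, by = chunk)) {
    hi <- min(nt, lo + chunk - 1)
    d <- sqrt(outer(test$x[lo:hi], gt$x, "-")^2 +
              outer(test$y[lo:hi], gt$y, "-")^2)
    w <- which(d <= radius, arr.ind = TRUE)
    if (nrow(w)) {
      pr[[k]] <- cbind(ti = w[, 1] + lo - 1, gi = w[, 2], d = d[w])
      k <- k + 1
    }
  }
  if (!length(pr))
    return(list(tp = 0L, fp = nt, fn = ng,
                pairs = matrix(integer(), 0, 2), radius = radius))
  cand <- do.call(rbind, pr)
  cand <- cand[order(cand[, "d"]), , drop = FALSE]
  used_t <- logical(nt); used_g <- logical(ng)
  pairs <- matrix(integer(), 0, 2)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ti <- cand[i, "ti"]; gi <- cand[i, "gi"]
    if (!used_t[ti] && !used_g[gi]) {
      used_t[ti] <- TRUE; used_g[gi] <- TRUE; keep[i] <- TRUE
    }
  }
  pairs <- cand[keep, c("ti", "gi"), drop = FALSE]
  list(tp = nrow(pairs), fp = nt - nrow(pairs), fn = ng - nrow(pairs),
       pairs = pairs, radius = radius)
}

#' Jaccard index of a match
#'
#' `JI = TP / (TP + FN + FP)`; defined as 0 when all three are zero.
#'
#' @param match result of [match_locs()].
#' @return fraction in `[0, 1]`.
#' @export
jaccard <- function(match) {
  denom <- match$tp + match$fp + match$fn
  if (denom == 0) 0 else match$tp / denom
}

#' Coordinate-based colocalization
#'
#' For each point of `set_a`, the area-normalized cumulative neighbour
#' distributions of `set_a` and `set_b` over the radius grid are rank
#' correlated (Spearman), and the score is damped by the nearest-neighbour
#' distance to `set_b`: `CBC_i = S_i * exp(-d_i / r_max)`. Values range
#' from -1 (anticorrelated) through 0 (uncorrelated) to 1 (correlated).
#'
#' @param set_a,set_b `data.frame(x, y)` in nm.
#' @param r_max largest radius, nm.
#' @param r_step radius grid spacing, nm.
#' @return numeric vector (one value per point of `set_a`) in `[-1, 1]`.
#' @export
cbc <- function(set_a, set_b, r_max = 200, r_step = 10) {
  if (r_step <= 0 || r_max <= r_step)
    stop("need at least two radius steps (r_max > r_step > 0)")
  radii <- seq(r_step, r_max, by = r_step)
  na <- nrow(set_a); nb <- nrow(set_b)
  da <- sqrt(outer(set_a$x, set_a$x, "-")^2 + outer(set_a$y, set_a$y, "-")^2)
  diag(da) <- Inf
  db <- sqrt(outer(set_a$x, set_b$x, "-")^2 + outer(set_a$y, set_b$y, "-")^2)
  out <- numeric(na)
  for (i in seq_len(na)) {
    ca <- vapply(radii, function(r) sum(da[i, ] <= r), numeric(1))
    # exact coincidences act as the point itself and are excluded from the
    # neighbour distribution (they still set the nearest-neighbour distance)
    cb <- vapply(radii, function(r) sum(db[i, ] <= r & db[i, ] > 0),
                 numeric(1))
    Da <- if (ca[length(radii)] > 0)
      ca / ca[length(radii)] * (r_max / radii)^2 else rep(0, length(radii))
    Db <- if (cb[length(radii)] > 0)
      cb / cb[length(radii)] * (r_max / radii)^2 else rep(0, length(radii))
    s <- suppressWarnings(stats::cor(Da, Db, method = "spearman"))
    if (!is.finite(s)) s <- 0
    d_i <- min(db[i, ])
    out[i] <- s * exp(-d_i / r_max)
  }
  out
}

#' Localization precision over true-positive detections
#'
#' The median uncertainty restricted to matched (true-positive) rows;
#' false positives are excluded by construction.
#'
#' @param match result of [match_locs()] computed on `table`'s positions.
#' @param table the [loc_table()] that was matched.
#' @return `list(median, uncertainties, tp)`; `median` is `NA` (flagged)
#'   when there are no true positives.
#' @export
loc_precision <- function(match, table) {
  if (match$tp == 0)
    return(list(median = NA_real_, uncertainties = numeric(0), tp = 0L))
  u <- table$uncertainty[match$pairs[, 1]]
  list(median = stats::median(u, na.rm = TRUE), uncertainties = u,
       tp = match$tp)
}

#' Two-point nanoruler ground truth from a rendered peak crop
#'
#' Fits an intensity-weighted second-moment ellipse to the crop and places
#' two points `separation` nm apart symmetrically about the ellipse centre
#' along its major axis. For circularly symmetric blobs the orientation is
#' degenerate and falls back to the x-axis (flagged). Downstream, an
#' unresolved ruler's FRC resolution is conventionally floored at 100 nm.
#'
#' @param crop intensity image containing one particle (e.g. 20 x 20 px).
#' @param pixel crop pixel size, nm.
#' @param separation marker distance, nm (default 50).
#' @return `list(points = data.frame(x, y), center, angle, degenerate)`.
#' @export
nanoruler_gt <- function(crop, pixel, separation = 50) {
  w <- pmax(crop, 0)
  tot <- sum(w)
  if (tot <= 0) stop("empty crop: no intensity to fit")
  xs <- (col(crop) - 0.5) * pixel
  ys <- (row(crop) - 0.5) * pixel
  cx <- sum(w * xs) / tot; cy <- sum(w * ys) / tot
  sxx <- sum(w * (xs - cx)^2) / tot
  syy <- sum(w * (ys - cy)^2) / tot
  sxy <- sum(w * (xs - cx) * (ys - cy)) / tot
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2))
  degenerate <- (ev$values[1] - ev$values[2]) / max(ev$values[1], 1e-12) < 1e-6
  axis <- if (degenerate) c(1, 0) else ev$vectors[, 1]
  ang <- atan2(axis[2], axis[1]) %% pi
  pts <- data.frame(
    x = cx + c(-1, 1) * separation / 2 * cos(ang),
    y = cy + c(-1, 1) * separation / 2 * sin(ang))
  list(points = pts, center = c(x = cx, y = cy), angle = ang,
       degenerate = degenerate)
}
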
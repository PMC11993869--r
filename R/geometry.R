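#' Detect the lumen/tissue interface in a polar frame
#'
#' Per A-line the boundary is the first radial sample whose causally
#' smoothed intensity exceeds an adaptive threshold placed between the
#' frame's noise-floor and signal quantiles.  The smoothing window is
#' trailing (it averages the current and preceding depths only), so an
#' ideal noise-free step is crossed exactly at the step.  A-lines with no
#' supra-threshold pixel are interpolated circularly from their
#' neighbours; the contour is then despiked with a circular
#' Hampel-style median filter (values further than `despike_px` from the
#' local circular median are replaced by it, all others kept untouched).
#'
#' @param frame an `ivoct_frame` or an intensity matrix (A-lines x depth).
#' @param smooth_px trailing running-mean window along depth.
#' @param noise_q,signal_q frame quantiles bracketing noise and signal.
#' @param k threshold position between the two quantiles.
#' @param median_window circular median window (odd).
#' @param despike_px deviation from the local median that triggers
#'   replacement.
#' @return integer vector of 1-based first-tissue columns, one per A-line.
#' @export
detect_lumen <- function(frame, smooth_px = 5, noise_q = 0.2,
                         signal_q = 0.98, k = 0.15,
                         median_window = 11, despike_px = 3) {
  M <- if (is.list(frame)) frame$intensities else frame
  stopifnot(is.matrix(M))
  if (any(M < 0)) stop_data("intensities must be non-negative")
  if (all(M == 0)) stop_data("no lumen found")
  lo <- quantile(M, noise_q, names = FALSE)
  hi <- quantile(M, signal_q, names = FALSE)
  thr <- lo + k * (hi - lo)
  Msm <- trailing_mean_depth(M, smooth_px)
  boundary <- first_true_by_row(Msm > thr)
  if (all(is.na(boundary))) stop_data("no lumen found")
  boundary <- interp_circular(as.numeric(boundary))
  med <- circular_running_median(boundary, median_window)
  spike <- abs(boundary - med) > despike_px
  boundary[spike] <- med[spike]
  as.integer(round(boundary))
}

#' Lumen-justified flattening
#'
#' Shifts every A-line so its lumen boundary lands at depth 1 and keeps the
#' first `crop_depth` samples (default 200 px, ~1 mm at 5 um/px, matching
#' the limited penetration depth of OCT).  The gather is a pure integer
#' shift with no interpolation, so it is exactly invertible on the cropped
#' band via [unflatten_frame()].
#'
#' @param frame an `ivoct_frame` or any matrix (intensities or labels).
#' @param contour integer vector of 1-based first-tissue columns per
#'   A-line, e.g. from [detect_lumen()] or the phantom truth.
#' @param crop_depth number of depth samples kept.
#' @return a `flat_frame` list: `intensities` (A-lines x crop_depth),
#'   `offsets` (the contour used), `source_shape`, `crop_depth`.
#' @export
flatten_frame <- function(frame, contour, crop_depth = 200L) {
  M <- if (is.list(frame)) frame$intensities else frame
  stopifnot(is.matrix(M))
  n <- nrow(M); W <- ncol(M)
  contour <- as.integer(contour)
  if (length(contour) != n) stop_data("contour length must equal A-line count")
  bad <- which(contour < 1L | contour > W - crop_depth + 1L)
  if (length(bad) > 0) {
    stop_data(paste0("contour out of range at A-line(s) ",
                     paste(head(bad, 5), collapse = ", "),
                     ": need 1 <= boundary <= depth_px - crop_depth + 1"))
  }
  J <- matrix(contour, n, crop_depth) +
    matrix(0:(crop_depth - 1L), n, crop_depth, byrow = TRUE)
  lin <- (J - 1L) * n + seq_len(n)
  out <- matrix(M[lin], n, crop_depth)
  structure(list(intensities = out, offsets = contour,
                 source_shape = c(n, W), crop_depth = as.integer(crop_depth)),
            class = "flat_frame")
}

#' Invert lumen-justified flattening
#'
#' Scatters a flattened array (a predicted mask or probability map) back to
#' the full polar geometry: `out[i, offsets[i] + j - 1] = x[i, j]`.  Pixels
#' outside the cropped band take `fill` (the exclusion code for masks, 0
#' for probabilities).
#'
#' @param x matrix `[n_alines x crop_depth]` or a `flat_frame`.
#' @param offsets the contour used at flatten time.
#' @param target_shape `c(n_alines, depth_px)` of the full frame.
#' @param fill value outside the band.
#' @return full-size polar matrix.
#' @export
unflatten_frame <- function(x, offsets = NULL, target_shape = NULL,
                            fill = MASK_EXCLUSION) {
  if (inherits(x, "flat_frame")) {
    offsets <- offsets %||% x$offsets
    target_shape <- target_shape %||% x$source_shape
    x <- x$intensities
  }
  stopifnot(is.matrix(x), !is.null(offsets), !is.null(target_shape))
  n <- nrow(x); crop <- ncol(x)
  if (length(offsets) != n) stop_data("offsets length must equal A-line count")
  if (target_shape[1] != n) stop_data("target_shape A-line count mismatch")
  if (any(offsets < 1L | offsets > target_shape[2] - crop + 1L)) {
    stop_data("offsets incompatible with target_shape and input width")
  }
  out <- matrix(fill, target_shape[1], target_shape[2])
  J <- matrix(as.integer(offsets), n, crop) +
    matrix(0:(crop - 1L), n, crop, byrow = TRUE)
  lin <- (J - 1L) * n + seq_len(n)
  out[lin] <- x
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polar to cartesian scan conversion
#'
#' Renders a polar array (rows = angle over [0, 2*pi), columns = radius)
#' as a square cartesian image for viewing.  Label maps must use nearest
#' interpolation so no label values are invented; bilinear interpolation
#' (with angular wraparound) is available for intensities.
#'
#' @param polar 2-D array, axis 0 periodic.
#' @param out_px output side length (even).
#' @param interpolation `"nearest"` or `"bilinear"`.
#' @param fill background value beyond the maximum radius.
#' @return `out_px` x `out_px` matrix.
#' @export
polar_to_cartesian <- function(polar, out_px = 2L * ncol(polar),
                               interpolation = c("nearest", "bilinear"),
                               fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.matrix(polar))
  if (out_px %% 2L != 0L) stop_config("out_px must be even")
  n <- nrow(polar); depth <- ncol(polar)
  ctr <- (out_px + 1) / 2
  xy <- seq_len(out_px) - ctr
  X <- matrix(xy, out_px, out_px, byrow = TRUE)   # column offset
  Y <- matrix(xy, out_px, out_px)                 # row offset
  R <- sqrt(X^2 + Y^2) * (depth / (out_px / 2))
  TH <- (atan2(Y, X) %% (2 * pi)) / (2 * pi) * n  # in A-line units
  inside <- R < depth
  out <- matrix(fill, out_px, out_px)
  if (interpolation == "nearest") {
    i <- (round(TH) %% n) + 1L
    j <- pmin(floor(R) + 1L, depth)
    out[inside] <- polar[cbind(i[inside], j[inside])]
  } else {
    i0 <- floor(TH); fi <- TH - i0
    j0 <- pmin(floor(R), depth - 1L); fj <- R - j0
    fj[fj > 1] <- 1
    ia <- (i0 %% n) + 1L; ib <- ((i0 + 1L) %% n) + 1L
    ja <- j0 + 1L; jb <- pmin(j0 + 2L, depth)
    v <- (1 - fi) * (1 - fj) * polar[cbind(ia, ja)] +
      fi * (1 - fj) * polar[cbind(ib, ja)] +
      (1 - fi) * fj * polar[cbind(ia, jb)] +
      fi * fj * polar[cbind(ib, jb)]
    out[inside] <- v[inside]
  }
  out
}

#' Display log transform
#'
#' Maps intensities through `log(1 + I)` and rescales to 8-bit for
#' visualization; the transform is monotone, so pixel ordering is
#' preserved, and the maximum intensity maps to 255.
#'
#' @param frame an `ivoct_frame` or intensity matrix.
#' @return integer matrix in 0..255.
#' @export
log_display <- function(frame) {
  M <- if (is.list(frame)) frame$intensities else frame
  d <- log1p(M)
  mx <- max(d)
  if (mx > 0) d <- d / mx * 255
  out <- round(d)
  storage.mode(out) <- "integer"
  out
}
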
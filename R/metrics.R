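#' Signed closure velocity
#'
#' Folds the sign of the horizontal velocity so that positive always means
#' motion toward the wound on both sides of it: `s = u * sign(center - x)`
#' for a grid point at column `x`. At the wound centre column the sign is
#' zero, so `s = 0` there.
#'
#' @param field a `velocity_field`.
#' @param wound_center_col wound midline column (px), inside the frame.
#' @return matrix of signed closure velocity, same units as `u` (px/frame).
#' @export
signed_closure_velocity <- function(field, wound_center_col) {
  stopifnot(inherits(field, "velocity_field"))
  if (wound_center_col < 1 || wound_center_col > field$frame_shape[2])
    stop("wound_center_col outside the frame")
  sgn <- sign(wound_center_col - field$centers_col)
  sweep(field$u, 2, sgn, `*`)
}

#' Summation map: time-averaged signed closure velocity
#'
#' The per-grid-point mean over frame pairs of the signed closure velocity,
#' using valid (or replacement-filled) vectors only, converted to um/min.
#' Red/positive regions in its rendering correspond to net migration toward
#' the wound, blue/negative to net backward motion.
#'
#' @param series a `velocity_field_series`.
#' @param wound_center_col wound midline column (px).
#' @return object of class `summation_map`: `values` (um/min; NA where a
#'   grid point was never usable), grid centres, `n_frames_used`.
#' @export
summation_map <- function(series, wound_center_col) {
  stopifnot(inherits(series, "velocity_field_series"))
  if (length(series$fields) == 0) stop("empty series")
  f1 <- series$fields[[1]]
  acc <- cnt <- matrix(0, nrow(f1$u), ncol(f1$u))
  for (f in series$fields) {
    s <- signed_closure_velocity(f, wound_center_col)
    ok <- usable_mask(f) & is.finite(s)
    s[!ok] <- 0
    acc <- acc + s
    cnt <- cnt + ok
  }
  vals <- ifelse(cnt > 0, acc / cnt, NA_real_) *
    series$um_per_px / series$min_per_frame
  structure(list(values = vals, centers_row = f1$centers_row,
                 centers_col = f1$centers_col,
                 n_frames_used = length(series$fields),
                 units = "um/min"),
            class = "summation_map")
}

#' Distributions of summed displacement and mean closure speed
#'
#' Per grid point, the total signed distance travelled toward the wound
#' (time-mean signed closure speed times total elapsed time, um) and, per
#' frame pair, the spatial mean signed closure speed (um/min). Histograms
#' use bins symmetric about zero with range set by the 99th percentile of
#' absolute values (values beyond are clamped into the end bins).
#'
#' @param series a `velocity_field_series`.
#' @param wound_center_col wound midline column (px).
#' @param n_bins number of histogram bins (odd keeps a bin centred on 0).
#' @return object of class `displacement_distribution`: `summed` (matrix,
#'   um), `mean_speed_map` (um/min), `per_frame_mean_speed` (um/min),
#'   histogram `breaks`/`counts` for the summed displacements and
#'   `speed_breaks`/`speed_counts` for the per-frame speeds.
#' @export
displacement_distribution <- function(series, wound_center_col, n_bins = 41) {
  smap <- summation_map(series, wound_center_col)
  total_min <- length(series$fields) * series$stride * series$min_per_frame
  summed <- smap$values * total_min
  per_frame <- vapply(series$fields, function(f) {
    s <- signed_closure_velocity(f, wound_center_col)
    ok <- usable_mask(f) & is.finite(s)
    if (!any(ok)) return(NA_real_)
    mean(s[ok]) * series$um_per_px / series$min_per_frame
  }, numeric(1))

  hist_sym <- function(x) {
    x <- x[is.finite(x)]
    r <- stats::quantile(abs(x), 0.99, names = FALSE)
    if (!is.finite(r) || r <= 0) r <- 1e-6
    breaks <- seq(-r, r, length.out = n_bins + 1)
    h <- graphics::hist(pmin(pmax(x, -r), r), breaks = breaks, plot = FALSE)
    list(breaks = breaks, counts = h$counts)
  }
  hd <- hist_sym(summed)
  hs <- hist_sym(per_frame)
  structure(list(summed = summed, mean_speed_map = smap$values,
                 per_frame_mean_speed = per_frame,
                 total_min = total_min,
                 breaks = hd$breaks, counts = hd$counts,
                 speed_breaks = hs$breaks, speed_counts = hs$counts),
            class = "displacement_distribution")
}

#' Segment the wound band of a frame by local texture variance
#'
#' Cell sheets carry texture; the wound band does not. The frame's local
#' variance (sliding window) is thresholded by Otsu's method, and the wound
#' is the largest connected low-variance component intersecting the
#' configured wound band. A manually drawn gap mask - the traditional
#' ImageJ-style measurement - can be supplied instead via `manual_mask`.
#'
#' @param frame numeric matrix (one movie frame).
#' @param geometry optional [wound_geometry()] hint restricting candidate
#'   components to the initial wound band (plus one window of slack).
#' @param window side of the local-variance window (px).
#' @param um_per_px spatial calibration for the returned area.
#' @param allow_empty if TRUE, a frame with no wound-like component yields
#'   area 0 with `closed = TRUE` (the convention for fully healed frames)
#'   instead of an error.
#' @param min_component_frac smallest credible wound size, as a fraction of
#'   the frame area; low-variance speckle below this is not a wound.
#' @param manual_mask optional logical matrix overriding segmentation.
#' @return list with `mask` (logical matrix), `area` (um^2), `closed`
#'   (flag), and `threshold` (variance threshold used, NA for manual).
#' @export
segment_wound <- function(frame, geometry = NULL, window = 24, um_per_px = 1,
                          allow_empty = FALSE, min_component_frac = 0.005,
                          manual_mask = NULL) {
  stopifnot(is.matrix(frame))
  if (!is.null(manual_mask)) {
    stopifnot(is.logical(manual_mask), all(dim(manual_mask) == dim(frame)))
    return(list(mask = manual_mask, area = sum(manual_mask) * um_per_px^2,
                closed = !any(manual_mask), threshold = NA_real_))
  }
  v <- box_mean(frame^2, window) - box_mean(frame, window)^2
  v[v < 0] <- 0
  vmax <- max(v)
  if (vmax <= 0) stop("frame has no texture contrast; provide a manual wound mask")
  vn <- v / vmax
  th <- EBImage::otsu(vn, range = c(0, 1))
  low <- vn < th
  lab <- EBImage::bwlabel(low)
  band_cols <- if (!is.null(geometry)) {
    lo <- max(1, floor(geometry$wound_center_col - geometry$wound_halfwidth - window))
    hi <- min(ncol(frame), ceiling(geometry$wound_center_col +
                                     geometry$wound_halfwidth + window))
    lo:hi
  } else {
    seq_len(ncol(frame))
  }
  ids <- setdiff(unique(as.vector(lab[, band_cols])), 0)
  sizes <- if (length(ids)) tabulate(as.vector(lab))[ids] else integer(0)
  min_area <- min_component_frac * length(frame)
  no_wound <- function() {
    if (allow_empty)
      return(list(mask = matrix(FALSE, nrow(frame), ncol(frame)), area = 0,
                  closed = TRUE, threshold = th * vmax))
    stop("no low-variance wound component found in the configured band; ",
         "the wound may be closed or untextured - provide a manual mask")
  }
  if (!length(ids) || max(sizes) < min_area) return(no_wound())
  best <- ids[which.max(sizes)]
  mask <- lab == best
  # A genuine wound band must be markedly flatter than the sheets, not just
  # the low tail of homogeneous texture: require at least the factor-2
  # variance contrast that makes a wound segmentable at all.
  mu_low <- mean(v[mask])
  mu_high <- mean(v[vn >= th])
  if (!is.finite(mu_high) || mu_low > mu_high / 2) return(no_wound())
  list(mask = mask, area = sum(mask) * um_per_px^2, closed = FALSE,
       threshold = th * vmax)
}

#' Wound closure percentage
#'
#' `100 * (1 - area_t / area_0)`: 0% at the initial frame, 100% at full
#' closure, negative when the wound expands.
#'
#' @param area_t wound area at time t (um^2).
#' @param area_0 initial wound area (um^2, > 0).
#' @return closure percentage (vectorized over `area_t`).
#' @export
closure_percent <- function(area_t, area_0) {
  if (!is.numeric(area_0) || length(area_0) != 1 || area_0 <= 0)
    stop("area_0 must be a single positive number")
  100 * (1 - area_t / area_0)
}

#' Wound closure curve of a movie
#'
#' Segments the wound in each requested frame and expresses its area as a
#' closure percentage of the initial area.
#'
#' @param seq an [image_sequence()].
#' @param geometry a [wound_geometry()] hint.
#' @param frames frame indices to sample (default: all frames).
#' @param window local-variance window for [segment_wound()].
#' @return data frame of class `closure_curve` with columns `frame`,
#'   `time_h`, `area_um2`, `closure_pct`, `closed`.
#' @export
closure_curve <- function(seq, geometry = NULL, frames = NULL, window = 24) {
  stopifnot(inherits(seq, "image_sequence"))
  n <- dim(seq$frames)[3]
  frames <- frames %||% seq_len(n)
  stopifnot(all(frames >= 1 & frames <= n))
  res <- lapply(frames, function(k) {
    segment_wound(seq$frames[, , k], geometry, window = window,
                  um_per_px = seq$um_per_px, allow_empty = k != frames[1])
  })
  areas <- vapply(res, `[[`, numeric(1), "area")
  out <- data.frame(frame = frames,
                    time_h = (frames - frames[1]) * seq$min_per_frame / 60,
                    area_um2 = areas,
                    closure_pct = closure_percent(areas, areas[1]),
                    closed = vapply(res, `[[`, logical(1), "closed"))
  class(out) <- c("closure_curve", "data.frame")
  out
}

#' @export
print.summation_map <- function(x, ...) {
  cat(sprintf("summation_map: %d x %d grid over %d frame pairs; mean %.4g um/min\n",
              nrow(x$values), ncol(x$values), x$n_frames_used,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}
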
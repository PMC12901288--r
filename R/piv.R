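#' PIV engine configuration
#'
#' Defaults follow common practice for monolayer migration movies: a coarse
#' first pass with 48 x 48 px interrogation windows whose validated result
#' predicts the window offsets of a refinement pass at 24 x 24 px, both at
#' 50% overlap. Subpixel displacement uses a three-point Gaussian fit with
#' a parabolic fallback; vectors are screened by peak-to-second-peak ratio
#' and the normalized median test.
#'
#' @param initial_window first-pass interrogation window (positive even, px).
#' @param refine_window refinement-pass window (positive even,
#'   <= `initial_window`).
#' @param overlap fraction of window shared by neighbours, in \[0, 1).
#' @param n_passes number of passes (>= 1; passes after the first use
#'   `refine_window`).
#' @param subpixel subpixel peak estimator: `"gaussian2d"` (default; 2-D
#'   least-squares Gaussian over the 5 x 5 peak neighbourhood, which
#'   suppresses the texture-realization noise that limits three-point fits
#'   on smooth, non-particle images), `"gaussian3"` (axis-wise three-point
#'   Gaussian) or `"parabolic"`. The 2-D fit falls back to the three-point
#'   fit near the surface border or on non-positive samples.
#' @param snr_min minimum peak-to-second-peak ratio for a vector to count
#'   as valid.
#' @param validation_eps,validation_thresh normalized-median-test
#'   parameters (acceptance when residual <= `validation_thresh`, with
#'   `validation_eps` regularizing the neighbourhood median absolute
#'   deviation).
#' @param stride frame-pair stride: displacement is measured between frames
#'   k and k + stride and reported per frame.
#' @return an object of class `piv_config`.
#' @export
piv_config <- function(initial_window = 48, refine_window = 24, overlap = 0.5,
                       n_passes = 2, subpixel = c("gaussian2d", "gaussian3", "parabolic"),
                       snr_min = 1.2, validation_eps = 0.1,
                       validation_thresh = 2.0, stride = 1) {
  subpixel <- match.arg(subpixel)
  check_window <- function(w, what) {
    if (!is.numeric(w) || length(w) != 1 || w <= 0 || w %% 2 != 0)
      stop(what, " must be a positive even integer")
  }
  check_window(initial_window, "initial_window")
  check_window(refine_window, "refine_window")
  if (refine_window > initial_window) stop("refine_window must be <= initial_window")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (n_passes < 1) stop("n_passes must be >= 1")
  if (stride < 1) stop("stride must be >= 1")
  structure(list(initial_window = as.integer(initial_window),
                 refine_window = as.integer(refine_window),
                 overlap = overlap, n_passes = as.integer(n_passes),
                 subpixel = subpixel, snr_min = snr_min,
                 validation_eps = validation_eps,
                 validation_thresh = validation_thresh,
                 stride = as.integer(stride)),
            class = "piv_config")
}

#' Number of PIV grid positions along one frame dimension
#'
#' Windows are placed at top-left offsets `i * step`, `step =
#' round(window * (1 - overlap))`, and must lie fully inside the frame:
#' the count is `floor((frame_dim - window) / step) + 1`. For 600 x 800 px
#' frames with 24 px windows at 50% overlap this gives the 49 x 65 output
#' grid.
#'
#' @param frame_dim frame extent along the dimension (px).
#' @param window interrogation window size (px, <= `frame_dim`).
#' @param overlap overlap fraction in \[0, 1).
#' @return integer count of grid positions.
#' @export
grid_shape <- function(frame_dim, window, overlap) {
  if (window > frame_dim) stop("window must not exceed the frame dimension")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  as.integer(floor((frame_dim - window) / step) + 1L)
}

#' @rdname grid_shape
#' @return `grid_centers`: window-centre coordinates in 1-based pixel units.
#' @export
grid_centers <- function(frame_dim, window, overlap) {
  n <- grid_shape(frame_dim, window, overlap)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  step * (seq_len(n) - 1) + (window + 1) / 2
}

#' Zero-mean normalized cross-correlation of two interrogation windows
#'
#' Computed via FFT with zero padding to twice the window size, so there is
#' no circular wraparound within the valid displacement range. The surface
#' is indexed by integer displacement of the second window's content
#' relative to the first, in `[-window + 1, window - 1]` along each axis.
#' The shrinking-overlap taper of the zero-padded estimate is divided out
#' (clamped at half-window overlap), so the peak shape is unbiased where it
#' matters and the subpixel fit is not pulled toward zero.
#'
#' @param win_a,win_b equal-sized square numeric matrices.
#' @return a matrix of class `piv_correlation` of dimension
#'   `(2 * window - 1)^2`, with attributes `window` and `valid` (FALSE when
#'   either window has zero variance, in which case the matrix is empty).
#' @export
cross_correlate <- function(win_a, win_b) {
  stopifnot(is.matrix(win_a), is.matrix(win_b))
  if (!all(dim(win_a) == dim(win_b)) || nrow(win_a) != ncol(win_a))
    stop("windows must be square and of equal size")
  res <- xcorr_core(win_a, win_b)
  structure(res$corr, window = nrow(win_a), valid = res$valid,
            class = c("piv_correlation", "matrix"))
}

#' Subpixel location of the correlation peak
#'
#' Refines the integer peak with a three-point Gaussian fit per axis,
#' `delta = (log c- - log c+) / (2 log c- - 4 log c0 + 2 log c+)`, falling
#' back to a parabolic fit when any of the three samples is non-positive.
#' The signal-to-noise ratio is the peak value over the highest
#' non-adjacent (outside the peak's 8-neighbourhood) value.
#'
#' @param corr correlation surface from [cross_correlate()] (or any matrix
#'   of odd dimension whose centre represents zero displacement).
#' @return list with `drow`, `dcol` (real-valued displacement), `snr`, and
#'   `low_confidence` (TRUE when the peak sits on the surface border, in
#'   which case the integer displacement is returned).
#' @export
subpixel_peak <- function(corr) {
  m <- unclass(corr)
  if (!isTRUE(attr(corr, "valid") %||% TRUE))
    stop("correlation surface is invalid (zero-variance window)")
  stopifnot(is.matrix(m), nrow(m) %% 2 == 1, ncol(m) %% 2 == 1)
  ctr_r <- (nrow(m) + 1) / 2
  ctr_c <- (ncol(m) + 1) / 2
  p <- which(m == max(m), arr.ind = TRUE)[1, ]
  pr <- p[1]; pc <- p[2]
  border <- pr == 1 || pr == nrow(m) || pc == 1 || pc == ncol(m)
  dr <- pr - ctr_r
  dc <- pc - ctr_c
  if (!border) {
    dr <- dr + fit_axis(m[pr - 1, pc], m[pr, pc], m[pr + 1, pc])
    dc <- dc + fit_axis(m[pr, pc - 1], m[pr, pc], m[pr, pc + 1])
  }
  keep <- abs(row(m) - pr) > 2 | abs(col(m) - pc) > 2
  second <- suppressWarnings(max(m[keep]))
  snr <- if (!is.finite(second) || second <= 1e-12) {
    if (m[pr, pc] > 0) 1e6 else 0
  } else m[pr, pc] / second
  list(drow = unname(dr), dcol = unname(dc), snr = unname(snr),
       low_confidence = border)
}

fit_axis <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    lm <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- 2 * lm - 4 * l0 + 2 * lp
    if (abs(den) > 1e-12) {
      d <- (lm - lp) / den
      if (abs(d) <= 1) return(d)
    }
  }
  den <- 2 * cm - 4 * c0 + 2 * cp
  if (abs(den) > 1e-12) {
    d <- (cm - cp) / den
    if (abs(d) <= 1) return(d)
  }
  0
}

# Bilinear interpolation of a predictor component onto new grid centres,
# clamping queries to the predictor's hull (constant extrapolation).
interp_predictor <- function(pred_val, pred_rows, pred_cols, q_rows, q_cols) {
  pred_val[!is.finite(pred_val)] <- 0
  if (length(pred_rows) < 2 || length(pred_cols) < 2) {
    # degenerate predictor grid: nearest neighbour
    ri <- vapply(q_rows, function(r) which.min(abs(pred_rows - r)), 1L)
    ci <- vapply(q_cols, function(cc) which.min(abs(pred_cols - cc)), 1L)
    return(outer(ri, ci, function(i, j) pred_val[cbind(i, j)]))
  }
  qx <- pmin(pmax(rep(q_cols, each = length(q_rows)), min(pred_cols)), max(pred_cols))
  qy <- pmin(pmax(rep(q_rows, times = length(q_cols)), min(pred_rows)), max(pred_rows))
  z <- pracma::interp2(pred_cols, pred_rows, pred_val, qx, qy, method = "linear")
  matrix(z, length(q_rows), length(q_cols))
}

#' Single PIV pass over a pair of frames
#'
#' Correlates each interrogation window of `frame_a` against the window of
#' `frame_b` displaced by the (bilinearly interpolated, integer-rounded)
#' predictor; the total displacement is the offset plus the correlation
#' displacement. Vectors whose correlation peak fails the signal-to-noise
#' threshold, sits on the surface border, or comes from a zero-variance
#' window are marked invalid.
#'
#' @param frame_a,frame_b numeric matrices of equal shape.
#' @param window interrogation window (positive even, px).
#' @param overlap overlap fraction.
#' @param predictor optional `velocity_field` on any grid over the same
#'   frame, used to offset the second window.
#' @param snr_min minimum peak-to-second-peak ratio.
#' @param subpixel subpixel estimator (see [piv_config()]).
#' @return an object of class `velocity_field` with matrices `u`, `v`
#'   (px/frame; +u rightward along columns, +v downward along rows), `snr`,
#'   `valid`, `replaced`, and the grid geometry.
#' @export
piv_pass <- function(frame_a, frame_b, window, overlap = 0.5, predictor = NULL,
                     snr_min = 1.2,
                     subpixel = c("gaussian2d", "gaussian3", "parabolic")) {
  subpixel <- match.arg(subpixel)
  stopifnot(is.matrix(frame_a), is.matrix(frame_b))
  if (!all(dim(frame_a) == dim(frame_b))) stop("frames must share one shape")
  if (window > min(dim(frame_a))) stop("window larger than frame")
  if (window %% 2 != 0 || window <= 0) stop("window must be a positive even integer")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  cr <- grid_centers(nrow(frame_a), window, overlap)
  cc <- grid_centers(ncol(frame_a), window, overlap)
  nr <- length(cr); nc <- length(cc)
  if (is.null(predictor)) {
    off_r <- off_c <- matrix(0, nr, nc)
  } else {
    stopifnot(inherits(predictor, "velocity_field"))
    off_c <- round(interp_predictor(predictor$u, predictor$centers_row,
                                    predictor$centers_col, cr, cc))
    off_r <- round(interp_predictor(predictor$v, predictor$centers_row,
                                    predictor$centers_col, cr, cc))
  }
  res <- piv_pass_core(frame_a, frame_b, as.integer(window), step,
                       off_r, off_c, snr_min,
                       match(subpixel, c("gaussian2d", "gaussian3", "parabolic")) - 1L)
  structure(list(u = res$u, v = res$v, snr = res$snr,
                 valid = matrix(res$valid, nr, nc),
                 replaced = matrix(FALSE, nr, nc),
                 window = as.integer(window), step = step,
                 centers_row = cr, centers_col = cc,
                 frame_shape = dim(frame_a)),
            class = "velocity_field")
}

#' Outlier validation and replacement (normalized median test)
#'
#' Each vector component is compared to the median of its 3 x 3
#' neighbourhood: residual `r = |d - median| / (median(|neighbours -
#' median|) + eps)`; vectors with `r > thresh` in either component (or
#' already invalid from the correlation stage) are replaced by the
#' component-wise median of the passing neighbours. The `replaced` mask
#' records substitutions; `valid` keeps only vectors that passed.
#'
#' @param field a `velocity_field`.
#' @param eps regularization of the neighbourhood median absolute
#'   deviation (px).
#' @param thresh residual acceptance threshold.
#' @return the validated `velocity_field`.
#' @export
validate_and_replace <- function(field, eps = 0.1, thresh = 2.0) {
  stopifnot(inherits(field, "velocity_field"))
  if (nrow(field$u) < 3 || ncol(field$u) < 3)
    stop("validation requires at least a 3 x 3 grid")
  pair <- attr(field, "frame_pair")
  if (!any(field$valid & is.finite(field$u)))
    stop("all vectors invalid",
         if (!is.null(pair)) sprintf(" in frame pair %d -> %d", pair[1], pair[2]) else "")
  res <- nmt_core(field$u, field$v, field$valid, eps, thresh)
  field$u <- res$u
  field$v <- res$v
  field$valid <- matrix(res$pass, nrow(field$u), ncol(field$u))
  field$replaced <- matrix(res$replaced, nrow(field$u), ncol(field$u))
  field
}

# Vectors usable by downstream metrics: measured-and-validated or filled-in.
usable_mask <- function(field) {
  (field$valid | field$replaced) & is.finite(field$u) & is.finite(field$v)
}

#' Run multi-pass PIV over an image sequence
#'
#' For each consecutive frame pair (at the configured stride): a first pass
#' at `initial_window`, validated, serves as predictor for passes at
#' `refine_window`, each validated in turn. The output grid is the
#' refinement-pass grid; velocities stay in px/frame internally (the
#' calibration travels with the series).
#'
#' @param seq an [image_sequence()].
#' @param cfg a [piv_config()].
#' @return an object of class `velocity_field_series`: `fields` (one
#'   validated `velocity_field` per frame pair), calibration, stride and
#'   source frame shape.
#' @export
run_piv <- function(seq, cfg = piv_config()) {
  stopifnot(inherits(seq, "image_sequence"), inherits(cfg, "piv_config"))
  n <- dim(seq$frames)[3]
  stride <- cfg$stride
  if (n <= stride) stop("sequence too short for stride ", stride)
  starts <- seq.int(1L, n - stride, by = stride)
  fields <- vector("list", length(starts))
  for (t in seq_along(starts)) {
    k <- starts[t]
    a <- seq$frames[, , k]
    b <- seq$frames[, , k + stride]
    f <- tryCatch({
      f1 <- piv_pass(a, b, cfg$initial_window, cfg$overlap, NULL, cfg$snr_min,
                     cfg$subpixel)
      attr(f1, "frame_pair") <- c(k, k + stride)
      f1 <- validate_and_replace(f1, cfg$validation_eps, cfg$validation_thresh)
      fcur <- f1
      for (p in seq_len(cfg$n_passes - 1L)) {
        f2 <- piv_pass(a, b, cfg$refine_window, cfg$overlap, fcur, cfg$snr_min,
                       cfg$subpixel)
        attr(f2, "frame_pair") <- c(k, k + stride)
        fcur <- validate_and_replace(f2, cfg$validation_eps, cfg$validation_thresh)
      }
      fcur
    }, error = function(e) {
      stop(sprintf("PIV failed on frame pair %d -> %d: %s", k, k + stride,
                   conditionMessage(e)), call. = FALSE)
    })
    if (stride > 1) {
      f$u <- f$u / stride
      f$v <- f$v / stride
    }
    fields[[t]] <- f
  }
  structure(list(fields = fields, um_per_px = seq$um_per_px,
                 min_per_frame = seq$min_per_frame, stride = stride,
                 source_shape = dim(seq$frames)[1:2]),
            class = "velocity_field_series")
}

#' @export
print.velocity_field_series <- function(x, ...) {
  f <- x$fields[[1]]
  cat(sprintf(paste0("velocity_field_series: %d frame pairs on a %d x %d grid ",
                     "(window %d px, step %d px; %.3g um/px, %.3g min/frame)\n"),
              length(x$fields), nrow(f$u), ncol(f$u), f$window, f$step,
              x$um_per_px, x$min_per_frame))
  invisible(x)
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d grid (window %d px), %.1f%% valid, %.1f%% replaced\n",
              nrow(x$u), ncol(x$u), x$window, 100 * mean(x$valid),
              100 * mean(x$replaced)))
  invisible(x)
}
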
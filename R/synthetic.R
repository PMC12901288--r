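#' Migratory phenotype specification for synthetic wound-healing movies
#'
#' Describes the prescribed kinematics of the two cell sheets flanking a
#' scratch wound. Positive `closure_speed` advects both sheets toward the
#' wound (healing); negative values move them away (wound expansion);
#' `shear_rate` adds a vertical gradient of horizontal velocity, emulating
#' sheets whose rows slide past one another.
#'
#' @param closure_speed signed sheet speed in micrometres per minute;
#'   positive means motion toward the wound on both sides.
#' @param shear_rate vertical gradient of horizontal velocity, in 1/min
#'   (du in um/min per um of vertical distance from the frame midline).
#' @param speed_jitter_sd standard deviation of a per-frame random
#'   perturbation of the closure speed (um/min).
#' @param texture_corr_len correlation length of the synthetic cell texture
#'   in pixels (>= 1); the texture autocorrelation falls to 1/e at this lag.
#' @param noise_sd additive per-pixel Gaussian noise, in intensity units of
#'   the rendered frames (frames are centred at 0.5 with texture amplitude
#'   about 0.18).
#' @param name label carried through reports.
#' @return an object of class `phenotype_spec`.
#' @seealso [phenotype_preset()], [generate_movie()]
#' @export
phenotype_spec <- function(closure_speed, shear_rate = 0, speed_jitter_sd = 0,
                           texture_corr_len = 4, noise_sd = 0.02,
                           name = "custom") {
  stopifnot(is.numeric(closure_speed), length(closure_speed) == 1,
            is.numeric(shear_rate), is.numeric(speed_jitter_sd),
            is.numeric(texture_corr_len), is.numeric(noise_sd))
  if (texture_corr_len < 1) stop("texture_corr_len must be >= 1 pixel")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (speed_jitter_sd < 0) stop("speed_jitter_sd must be >= 0")
  structure(list(closure_speed = closure_speed, shear_rate = shear_rate,
                 speed_jitter_sd = speed_jitter_sd,
                 texture_corr_len = texture_corr_len,
                 noise_sd = noise_sd, name = name),
            class = "phenotype_spec")
}

#' Preset migratory phenotypes
#'
#' Four canonical phenotypes used as study conditions for the synthetic
#' generator: `forward` (net migration toward the wound, as in untreated
#' monolayers that close the scratch), `reversed` (net backward motion, as
#' in cytokine-treated monolayers that occasionally expand the wound),
#' `immotile` (no prescribed motion), and `sheared` (no net closure but a
#' vertical gradient of horizontal velocity, i.e. rows of the sheet sliding
#' past one another).
#'
#' The forward/reversed speed of 0.065 um/min corresponds to roughly 94 um
#' of advance per sheet over 24 h, the scale at which a ~200 um scratch
#' closes within a day.
#'
#' @param name one of `"forward"`, `"immotile"`, `"reversed"`, `"sheared"`.
#' @return a [phenotype_spec()].
#' @export
phenotype_preset <- function(name = c("forward", "immotile", "reversed", "sheared")) {
  name <- match.arg(name)
  switch(name,
    forward  = phenotype_spec(0.065, 0, 0.01, 4, 0.02, "forward"),
    immotile = phenotype_spec(0, 0, 0, 4, 0.02, "immotile"),
    reversed = phenotype_spec(-0.065, 0, 0.01, 4, 0.02, "reversed"),
    sheared  = phenotype_spec(0, 5e-4, 0.01, 4, 0.02, "sheared"))
}

#' Wound geometry for synthetic movies and wound-centric metrics
#'
#' The convention throughout the package is a vertical wound band centred at
#' `wound_center_col`, with cell sheets on its left and right; closure is
#' horizontal.
#'
#' @param frame_shape integer (rows, cols) of each frame in pixels.
#' @param wound_center_col column of the wound midline (defaults to the
#'   frame centre).
#' @param wound_halfwidth half-width of the initial wound band in pixels.
#' @return an object of class `wound_geometry`.
#' @export
wound_geometry <- function(frame_shape = c(600, 800), wound_center_col = NULL,
                           wound_halfwidth = 60) {
  stopifnot(length(frame_shape) == 2, all(frame_shape > 0))
  frame_shape <- as.integer(frame_shape)
  wound_center_col <- wound_center_col %||% (frame_shape[2] / 2)
  if (wound_center_col <= 0 || wound_center_col >= frame_shape[2])
    stop("wound_center_col must lie strictly inside the frame")
  if (wound_halfwidth < 0) stop("wound_halfwidth must be >= 0")
  if (wound_center_col - wound_halfwidth < 1 ||
      wound_center_col + wound_halfwidth > frame_shape[2])
    stop("wound band must lie fully inside the frame at t = 0")
  structure(list(frame_shape = frame_shape,
                 wound_center_col = wound_center_col,
                 wound_halfwidth = wound_halfwidth),
            class = "wound_geometry")
}

#' Calibrated image sequence
#'
#' @param frames numeric array of dimension rows x cols x n_frames
#'   (n_frames >= 2), or a list of equal-sized matrices.
#' @param um_per_px spatial calibration (micrometres per pixel, > 0).
#' @param min_per_frame temporal calibration (minutes per frame, > 0).
#' @return an object of class `image_sequence`.
#' @export
image_sequence <- function(frames, um_per_px, min_per_frame) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1)
      stop("all frames must share one shape (frame ",
           which(!vapply(frames, function(f) identical(dim(f), dim(frames[[1]])), TRUE))[1],
           " differs)")
    frames <- array(unlist(frames), c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] < 2) stop("an image sequence needs at least 2 frames")
  if (!is.numeric(um_per_px) || um_per_px <= 0) stop("um_per_px must be > 0")
  if (!is.numeric(min_per_frame) || min_per_frame <= 0) stop("min_per_frame must be > 0")
  structure(list(frames = frames, um_per_px = um_per_px,
                 min_per_frame = min_per_frame),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_sequence: %d frames of %d x %d px (%.3g um/px, %.3g min/frame)\n",
              d[3], d[1], d[2], x$um_per_px, x$min_per_frame))
  invisible(x)
}

#' Correlated random texture
#'
#' Generates a zero-mean, unit-variance Gaussian random field by low-pass
#' filtering white noise with a periodic Gaussian kernel. The filter scale
#' is chosen so that the field autocorrelation drops to 1/e at lag
#' `corr_len` pixels. This texture carries the local contrast that PIV
#' cross-correlation needs, without modelling cell morphology.
#'
#' @param shape integer (rows, cols).
#' @param corr_len correlation length in pixels (>= 1).
#' @param seed integer seed; the same seed reproduces the field bit for bit.
#' @return numeric matrix of dimension `shape`.
#' @export
generate_texture <- function(shape, corr_len = 4, seed = 1) {
  stopifnot(length(shape) == 2)
  if (any(shape <= 0)) stop("shape must be positive")
  if (corr_len < 1) stop("corr_len must be >= 1")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  w <- withr::with_seed(as.integer(seed), matrix(rnorm(nr * nc), nr, nc))
  sigma <- corr_len / 2
  kr <- 0:(nr - 1); kr[kr > nr / 2] <- kr[kr > nr / 2] - nr
  kc <- 0:(nc - 1); kc[kc > nc / 2] <- kc[kc > nc / 2] - nc
  G <- exp(-2 * pi^2 * sigma^2 * (outer((kr / nr)^2, rep(1, nc)) +
                                  outer(rep(1, nr), (kc / nc)^2)))
  tex <- Re(stats::fft(stats::fft(w) * G, inverse = TRUE)) / (nr * nc)
  (tex - mean(tex)) / stats::sd(tex)
}

#' Generate a synthetic wound-healing movie with exact ground truth
#'
#' Renders a brightfield-like time lapse of two textured cell sheets
#' flanking a central low-texture wound band. Each sheet is a correlated
#' random texture advected every frame by the prescribed per-row
#' displacement (closure speed converted to px/frame, sign folded so both
#' sheets approach the wound when `closure_speed > 0`; `shear_rate` adds a
#' vertical gradient of horizontal velocity). Advection uses periodic
#' subpixel Fourier shifts, so the prescribed field is honoured exactly and
#' is returned as ground truth sampled at the PIV grid.
#'
#' @param phenotype a [phenotype_spec()] or preset name.
#' @param geometry a [wound_geometry()].
#' @param n_frames number of frames (>= 2). The default 30 frames at
#'   48 min/frame spans a 24 h recording.
#' @param um_per_px,min_per_frame calibration.
#' @param seed integer seed; identical (phenotype, geometry, seed)
#'   reproduce the movie bit for bit.
#' @param texture_contrast ratio of sheet to wound-band texture variance
#'   (>= 2 so that the wound is segmentable by local variance).
#' @param grid_window,grid_overlap PIV grid at which the ground-truth field
#'   is sampled (defaults match the default refinement pass).
#' @return list with elements `sequence` (an [image_sequence()]) and
#'   `truth` (a `ground_truth` object holding per-frame-pair `u`, `v`
#'   arrays in px/frame at the PIV grid, sheet side labels, and the wound
#'   edges from which per-frame wound masks are built by [wound_mask()]).
#' @export
generate_movie <- function(phenotype, geometry = wound_geometry(), n_frames = 30,
                           um_per_px = 1.3, min_per_frame = 48, seed = 1,
                           texture_contrast = 8,
                           grid_window = 24, grid_overlap = 0.5) {
  if (is.character(phenotype)) phenotype <- phenotype_preset(phenotype)
  stopifnot(inherits(phenotype, "phenotype_spec"), inherits(geometry, "wound_geometry"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (texture_contrast < 2) stop("texture_contrast must be >= 2")
  rows <- geometry$frame_shape[1]; cols <- geometry$frame_shape[2]
  ctr <- geometry$wound_center_col; hw <- geometry$wound_halfwidth

  to_px <- min_per_frame / um_per_px          # um/min -> px/frame
  base_u <- phenotype$closure_speed * to_px
  gamma_px <- phenotype$shear_rate * min_per_frame  # px/frame per px of row offset
  jit <- withr::with_seed(sub_seed(seed, 1L),
                          rnorm(n_frames - 1, 0, phenotype$speed_jitter_sd)) * to_px

  rowdev <- seq_len(rows) - (rows + 1) / 2
  # left-sheet horizontal speed (px/frame), rows x (n_frames - 1)
  u_int <- outer(gamma_px * rowdev, rep(1, n_frames - 1)) +
    matrix(base_u + jit, rows, n_frames - 1, byrow = TRUE)
  cum <- apply(u_int, 1, cumsum)              # (n-1) x rows; vector when n = 2
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  D <- cbind(0, t(cum))                       # cumulative displacement per frame

  if (max(abs(u_int)) > grid_window / 2)
    warning(sprintf(paste0("per-frame displacement up to %.1f px exceeds half the ",
                           "interrogation window (%d px): PIV dynamic range violated"),
                    max(abs(u_int)), as.integer(grid_window)))

  tex_l <- generate_texture(c(rows, cols), phenotype$texture_corr_len, sub_seed(seed, 2L))
  tex_r <- generate_texture(c(rows, cols), phenotype$texture_corr_len, sub_seed(seed, 3L))
  tex_w <- generate_texture(c(rows, cols), phenotype$texture_corr_len, sub_seed(seed, 4L))

  amp <- 0.18
  amp_w <- amp / sqrt(texture_contrast)
  noise <- withr::with_seed(sub_seed(seed, 5L),
                            array(rnorm(rows * cols * n_frames, 0, phenotype$noise_sd),
                                  c(rows, cols, n_frames)))

  Fl <- stats::mvfft(t(tex_l))
  Fr <- stats::mvfft(t(tex_r))
  colmat <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  frames <- array(0, c(rows, cols, n_frames))
  left_edge <- right_edge <- matrix(0, n_frames, rows)
  for (k in seq_len(n_frames)) {
    d <- D[, k]
    L <- row_shift_fft(Fl, d, cols)
    R <- row_shift_fft(Fr, -d, cols)
    le <- ctr - hw + d
    re <- ctr + hw - d
    left_edge[k, ] <- le
    right_edge[k, ] <- re
    in_left <- colmat <= le
    in_right <- (!in_left) & (colmat >= re)
    in_wound <- !(in_left | in_right)
    frames[, , k] <- 0.5 + amp * (L * in_left + R * in_right) +
      amp_w * tex_w * in_wound + noise[, , k]
  }

  cr <- grid_centers(rows, grid_window, grid_overlap)
  cc <- grid_centers(cols, grid_window, grid_overlap)
  n_gr <- length(cr); n_gc <- length(cc)
  u_true <- array(0, c(n_gr, n_gc, n_frames - 1))
  v_true <- array(0, c(n_gr, n_gc, n_frames - 1))
  side <- array(0L, c(n_gr, n_gc, n_frames - 1))
  rowdev_g <- cr - (rows + 1) / 2
  for (k in seq_len(n_frames - 1)) {
    uk <- base_u + jit[k] + gamma_px * rowdev_g
    le_g <- stats::approx(seq_len(rows), left_edge[k, ], xout = cr, rule = 2)$y
    re_g <- stats::approx(seq_len(rows), right_edge[k, ], xout = cr, rule = 2)$y
    isL <- outer(le_g, cc, function(l, x) x < l)
    isR <- outer(re_g, cc, function(r, x) x > r)
    sgn <- isL - isR                      # +1 left sheet, -1 right sheet, 0 wound
    u_true[, , k] <- sgn * uk
    side[, , k] <- -1L * isL + 1L * isR   # -1 left, +1 right, 0 wound
  }

  seq <- image_sequence(frames, um_per_px, min_per_frame)
  truth <- structure(list(u = u_true, v = v_true, side = side,
                          centers_row = cr, centers_col = cc,
                          left_edge = left_edge, right_edge = right_edge,
                          frame_shape = c(rows, cols),
                          phenotype = phenotype, seed = as.integer(seed),
                          um_per_px = um_per_px, min_per_frame = min_per_frame),
                     class = "ground_truth")
  list(sequence = seq, truth = truth)
}

#' Wound mask of a ground-truth object at one frame
#'
#' @param truth a `ground_truth` from [generate_movie()].
#' @param frame frame index (1-based).
#' @return logical matrix of the frame shape; TRUE inside the wound band.
#' @export
wound_mask <- function(truth, frame) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(truth$left_edge)
  if (frame < 1 || frame > n) stop("frame out of range")
  rows <- truth$frame_shape[1]; cols <- truth$frame_shape[2]
  colmat <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  (colmat > truth$left_edge[frame, ]) & (colmat < truth$right_edge[frame, ])
}

#' Sheet-side labels at the PIV grid for one frame pair
#'
#' Returns -1 for grid points inside the left sheet, +1 inside the right
#' sheet and 0 in the wound band, optionally requiring a margin (px) of
#' clearance from the wound edges (useful to restrict comparisons to grid
#' points whose interrogation windows see only one sheet).
#'
#' @param truth a `ground_truth`.
#' @param k frame-pair index.
#' @param margin clearance from the wound edge in pixels.
#' @return integer matrix on the PIV grid.
#' @export
sheet_side <- function(truth, k, margin = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  le <- stats::approx(seq_len(truth$frame_shape[1]), truth$left_edge[k, ],
                      xout = truth$centers_row, rule = 2)$y
  re <- stats::approx(seq_len(truth$frame_shape[1]), truth$right_edge[k, ],
                      xout = truth$centers_row, rule = 2)$y
  isL <- outer(le, truth$centers_col, function(l, x) x < l - margin)
  isR <- outer(re, truth$centers_col, function(r, x) x > r + margin)
  -1L * isL + 1L * isR
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d frame pairs on a %d x %d PIV grid (phenotype '%s', seed %d)\n",
              dim(x$u)[3], dim(x$u)[1], dim(x$u)[2], x$phenotype$name, x$seed))
  invisible(x)
}
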
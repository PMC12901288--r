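#' Write an image sequence as a multi-page TIFF
#'
#' Intensities are min-max scaled over the whole movie and stored as
#' unsigned integers of the requested bit depth (a common microscopy TIFF
#' dialect). The scaling offset/range are not stored; PIV is invariant to
#' affine intensity rescaling.
#'
#' @param seq an [image_sequence()].
#' @param path output file path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_movie <- function(seq, path, bits = 16) {
  stopifnot(inherits(seq, "image_sequence"))
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
  fr <- seq$frames
  rng <- range(fr)
  if (diff(rng) <= 0) {
    fr[] <- 0.5
  } else {
    fr <- (fr - rng[1]) / diff(rng)
  }
  pages <- lapply(seq_len(dim(fr)[3]), function(k) fr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a calibrated image sequence
#'
#' @param path TIFF file with at least two grayscale pages.
#' @param um_per_px,min_per_frame calibration to attach.
#' @return an [image_sequence()].
#' @export
read_movie <- function(path, um_per_px, min_per_frame) {
  if (!file.exists(path)) stop("cannot read movie: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("corrupt or unreadable TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(seq_along(pages), function(k) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse replicated channels
    if (!is.matrix(p)) stop("frame ", k, " of '", path, "' is not a 2-D grayscale image")
    p
  })
  image_sequence(pages, um_per_px, min_per_frame)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' Stores the PIV-grid coordinates, the per-frame-pair true velocity
#' fields, the wound edges, and the generating phenotype, so that a movie
#' written with [write_movie()] can be re-validated without regenerating it.
#'
#' @param truth a `ground_truth` from [generate_movie()].
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `ground_truth` (reader).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(centers_row = truth$centers_row, centers_col = truth$centers_col,
              frame_shape = truth$frame_shape,
              u = truth$u, v = truth$v, side = truth$side,
              left_edge = truth$left_edge, right_edge = truth$right_edge,
              phenotype = unclass(truth$phenotype), seed = truth$seed,
              um_per_px = truth$um_per_px, min_per_frame = truth$min_per_frame)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("ground-truth sidecar not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- c(length(obj$centers_row), length(obj$centers_col))
  as_arr <- function(x) array(as.numeric(x), dim = dim(x) %||% c(dims, length(x) / prod(dims)))
  ph <- do.call(phenotype_spec, obj$phenotype[c("closure_speed", "shear_rate",
                                                "speed_jitter_sd", "texture_corr_len",
                                                "noise_sd", "name")])
  structure(list(u = as_arr(obj$u), v = as_arr(obj$v), side = as_arr(obj$side),
                 centers_row = as.numeric(obj$centers_row),
                 centers_col = as.numeric(obj$centers_col),
                 left_edge = as.matrix(obj$left_edge),
                 right_edge = as.matrix(obj$right_edge),
                 frame_shape = as.integer(obj$frame_shape),
                 phenotype = ph, seed = as.integer(obj$seed),
                 um_per_px = as.numeric(obj$um_per_px),
                 min_per_frame = as.numeric(obj$min_per_frame)),
            class = "ground_truth")
}

#' Tidy data frame of a velocity-field series
#'
#' One row per (frame pair, grid point): `frame`, `row`, `col` (grid-centre
#' pixel coordinates), `u`, `v` (px/frame), `valid`, `replaced`.
#'
#' @param x a `velocity_field_series` from [run_piv()].
#' @param ... unused.
#' @export
as.data.frame.velocity_field_series <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$fields), function(t) {
    f <- x$fields[[t]]
    data.frame(frame = t,
               row = rep(f$centers_row, times = length(f$centers_col)),
               col = rep(f$centers_col, each = length(f$centers_row)),
               u = as.vector(f$u), v = as.vector(f$v),
               valid = as.vector(f$valid), replaced = as.vector(f$replaced))
  }))
}

#' Write / read a velocity-field series as CSV plus JSON metadata
#'
#' The CSV holds the tidy per-vector table (see
#' [as.data.frame.velocity_field_series()]); grid geometry and calibration
#' go to a `<path>.meta.json` sidecar so the series can be reconstructed.
#'
#' @param series a `velocity_field_series`.
#' @param path CSV file path.
#' @return `path` invisibly (writer); a `velocity_field_series` (reader).
#' @export
write_velocity_series <- function(series, path) {
  stopifnot(inherits(series, "velocity_field_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  f1 <- series$fields[[1]]
  meta <- list(um_per_px = series$um_per_px, min_per_frame = series$min_per_frame,
               stride = series$stride, source_shape = series$source_shape,
               window = f1$window, step = f1$step,
               centers_row = f1$centers_row, centers_col = f1$centers_col,
               n_fields = length(series$fields))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_velocity_series
#' @export
read_velocity_series <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("velocity series CSV or its .meta.json sidecar not found at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  nr <- length(meta$centers_row); nc <- length(meta$centers_col)
  fields <- lapply(seq_len(meta$n_fields), function(t) {
    d <- df[df$frame == t, ]
    structure(list(u = matrix(d$u, nr, nc), v = matrix(d$v, nr, nc),
                   snr = matrix(NA_real_, nr, nc),
                   valid = matrix(d$valid, nr, nc),
                   replaced = matrix(d$replaced, nr, nc),
                   window = meta$window, step = meta$step,
                   centers_row = as.numeric(meta$centers_row),
                   centers_col = as.numeric(meta$centers_col),
                   frame_shape = as.integer(meta$source_shape)),
              class = "velocity_field")
  })
  structure(list(fields = fields, um_per_px = meta$um_per_px,
                 min_per_frame = meta$min_per_frame, stride = meta$stride,
                 source_shape = as.integer(meta$source_shape)),
            class = "velocity_field_series")
}
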
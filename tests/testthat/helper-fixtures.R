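# Shared fixtures: small geometries and PIV configs keep unit tests fast;
# the acceptance suite uses the full study-condition scale.

tiny_geometry <- function(rows = 120, cols = 160, halfwidth = 24) {
  wound_geometry(c(rows, cols), cols / 2, halfwidth)
}

tiny_piv_config <- function(...) {
  piv_config(initial_window = 32, refine_window = 16, ...)
}

# Two-frame sequence of a texture translated by a known subpixel amount.
translation_sequence <- function(drow, dcol, size = 256, corr_len = 4, seed = 7) {
  a <- generate_texture(c(size, size), corr_len, seed)
  b <- shift_image(a, drow, dcol)
  image_sequence(array(c(a, b), c(size, size, 2)), 1, 1)
}

# Hand-rolled field constructor for metric/kymograph oracles.
make_field <- function(u, v = u * 0, valid = NULL, window = 16, step = 8,
                       frame_shape = NULL) {
  nr <- nrow(u); nc <- ncol(u)
  frame_shape <- frame_shape %||% c((nr - 1) * step + window, (nc - 1) * step + window)
  structure(list(u = u, v = v, snr = u * 0 + 10,
                 valid = valid %||% matrix(TRUE, nr, nc),
                 replaced = matrix(FALSE, nr, nc),
                 window = window, step = step,
                 centers_row = step * (seq_len(nr) - 1) + (window + 1) / 2,
                 centers_col = step * (seq_len(nc) - 1) + (window + 1) / 2,
                 frame_shape = frame_shape),
            class = "velocity_field")
}

make_series <- function(fields, um_per_px = 1, min_per_frame = 1) {
  structure(list(fields = fields, um_per_px = um_per_px,
                 min_per_frame = min_per_frame, stride = 1L,
                 source_shape = fields[[1]]$frame_shape),
            class = "velocity_field_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
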
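# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent streams (textures, jitter, pixel noise, per-movie seeds)
# without consecutive seeds sharing a stream. Kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  s <- ((as.double(seed) %% 2147483629) * 48271 + 104729 * as.double(k)) %% 2147483629
  as.integer(s) + 1L
}

# Periodic subpixel shift of a whole image by (drow, dcol) via the Fourier
# shift theorem. Content moves down/right for positive offsets.
#' Shift an image by a (possibly fractional) offset
#'
#' Applies a periodic Fourier-domain translation. Useful for constructing
#' synthetic translation movies with exactly known subpixel displacements.
#'
#' @param img numeric matrix.
#' @param drow,dcol displacement in pixels along rows (down) and columns
#'   (right); may be fractional.
#' @return shifted matrix of the same dimension.
#' @export
shift_image <- function(img, drow = 0, dcol = 0) {
  stopifnot(is.matrix(img), is.numeric(img))
  nr <- nrow(img)
  nc <- ncol(img)
  kr <- 0:(nr - 1); kr[kr > nr / 2] <- kr[kr > nr / 2] - nr
  kc <- 0:(nc - 1); kc[kc > nc / 2] <- kc[kc > nc / 2] - nc
  ph <- exp(-2i * pi * (outer(kr, rep(1, nc)) * drow / nr +
                        outer(rep(1, nr), kc) * dcol / nc))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

# Row-wise periodic horizontal shift: row r of the image moves right by
# d[r] pixels. Takes the precomputed column-wise FFT of t(img) so repeated
# shifts of the same texture reuse one forward transform.
row_shift_fft <- function(Ft, d, ncols) {
  k <- 0:(ncols - 1)
  k[k > ncols / 2] <- k[k > ncols / 2] - ncols
  ph <- exp(-2i * pi * outer(k, d) / ncols)
  Re(t(stats::mvfft(Ft * ph, inverse = TRUE)) / ncols)
}

row_shift <- function(img, d) {
  row_shift_fft(stats::mvfft(t(img)), d, ncol(img))
}

# Sliding-window local mean with border clamping, via integral images.
box_mean <- function(m, w) {
  r <- nrow(m); cl <- ncol(m)
  S <- matrix(0, r + 1, cl + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  h <- w %/% 2
  r1 <- pmax(1L, seq_len(r) - h); r2 <- pmin(r, seq_len(r) + h)
  c1 <- pmax(1L, seq_len(cl) - h); c2 <- pmin(cl, seq_len(cl) + h)
  tot <- S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  tot / outer(r2 - r1 + 1, c2 - c1 + 1)
}

# Central-difference gradient along columns (one-sided at the two edges).
grad_cols <- function(M, h) {
  n <- ncol(M)
  G <- M * NA_real_
  if (n >= 3) G[, 2:(n - 1)] <- (M[, 3:n] - M[, 1:(n - 2)]) / (2 * h)
  G[, 1] <- (M[, 2] - M[, 1]) / h
  G[, n] <- (M[, n] - M[, n - 1]) / h
  G
}

grad_rows <- function(M, h) t(grad_cols(t(M), h))

# Fast median for the small numeric vectors used in kymograph columns.
med <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median.default(x)
}
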
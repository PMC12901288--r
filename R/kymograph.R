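#' Velocity kymograph (distance from the frame edge vs. time)
#'
#' Entry (d, t) is the median over grid rows of the signed closure velocity
#' in grid column d at frame pair t, using usable vectors only. With
#' `fold = TRUE` (default), columns equidistant from the two vertical frame
#' edges are averaged after sign folding, so the distance axis runs from
#' the frame edge toward the wound at the centre. Entries whose column had
#' no usable vector are interpolated from time neighbours and flagged.
#'
#' @param series a `velocity_field_series`.
#' @param wound_center_col wound midline column (px).
#' @param fold average mirror columns (TRUE) or keep the full width (FALSE).
#' @return object of class `kymograph` with `values`
#'   (n_distance x n_time, um/min), `quantity = "velocity"`,
#'   `distance_um`, `time_min`, `fold`, and an `interpolated` flag matrix.
#' @export
velocity_kymograph <- function(series, wound_center_col, fold = TRUE) {
  stopifnot(inherits(series, "velocity_field_series"))
  if (length(series$fields) == 0) stop("empty series")
  build_kymograph(series, fold, quantity = "velocity", function(f) {
    s <- signed_closure_velocity(f, wound_center_col)
    s[!usable_mask(f)] <- NA_real_
    s * series$um_per_px / series$min_per_frame
  })
}

# Shared kymograph assembly: per-field value grid -> column medians ->
# time interpolation of gaps -> optional mirror folding.
build_kymograph <- function(series, fold, quantity, value_fun) {
  f1 <- series$fields[[1]]
  nc <- ncol(f1$u)
  nt <- length(series$fields)
  K <- matrix(NA_real_, nc, nt)
  for (t in seq_len(nt)) {
    vals <- value_fun(series$fields[[t]])
    K[, t] <- vapply(seq_len(nc), function(j) med(vals[, j]), numeric(1))
  }
  interp <- is.na(K)
  if (any(interp)) {
    for (j in seq_len(nc)) {
      miss <- is.na(K[j, ])
      if (any(miss) && any(!miss)) {
        K[j, miss] <- stats::approx(which(!miss), K[j, !miss],
                                    xout = which(miss), rule = 2)$y
      }
    }
    K[is.na(K)] <- 0
  }
  dist_um <- f1$centers_col * series$um_per_px
  if (fold) {
    half <- ceiling(nc / 2)
    Kf <- matrix(NA_real_, half, nt)
    If <- matrix(FALSE, half, nt)
    for (j in seq_len(half)) {
      j2 <- nc + 1 - j
      if (j2 == j) {
        Kf[j, ] <- K[j, ]
        If[j, ] <- interp[j, ]
      } else {
        Kf[j, ] <- (K[j, ] + K[j2, ]) / 2
        If[j, ] <- interp[j, ] | interp[j2, ]
      }
    }
    K <- Kf
    interp <- If
    dist_um <- dist_um[seq_len(half)]
  }
  structure(list(values = K, quantity = quantity, distance_um = dist_um,
                 time_min = seq_len(nt) * series$stride * series$min_per_frame,
                 fold = fold, interpolated = interp),
            class = "kymograph")
}

#' Per-point strain of a velocity field
#'
#' Default mode `"strain"` is the horizontal normal strain rate du/dx by
#' central differences on the PIV grid (one-sided at the edges); mode
#' `"vorticity"` gives dv/dx - du/dy, the curl of the 2-D field, which is
#' the quantity sensitive to rows of the sheet sliding past one another
#' (shear). Units are 1/min after calibration.
#'
#' @param field a `velocity_field` on a grid of at least 3 x 3.
#' @param um_per_px,min_per_frame calibration.
#' @param mode `"strain"` or `"vorticity"`.
#' @return matrix of strain values (1/min); NA where vectors were unusable.
#' @export
strain_field <- function(field, um_per_px, min_per_frame,
                         mode = c("strain", "vorticity")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "velocity_field"))
  if (nrow(field$u) < 3 || ncol(field$u) < 3)
    stop("strain needs a grid of at least 3 x 3")
  conv <- um_per_px / min_per_frame      # px/frame -> um/min
  U <- field$u * conv
  V <- field$v * conv
  bad <- !usable_mask(field)
  U[bad] <- NA_real_
  V[bad] <- NA_real_
  h <- field$step * um_per_px            # grid spacing, um
  if (mode == "strain") {
    grad_cols(U, h)
  } else {
    grad_cols(V, h) - grad_rows(U, h)
  }
}

#' Strain kymograph
#'
#' Entry (d, t) is the median over grid rows of the strain magnitude
#' (absolute value by default; signed optional) in column d at frame pair
#' t. Folding and gap interpolation behave as in [velocity_kymograph()].
#'
#' @param series a `velocity_field_series`.
#' @param mode passed to [strain_field()].
#' @param fold average mirror columns.
#' @param absolute take |strain| before the median (default TRUE).
#' @return a `kymograph` with `quantity = "strain"` (units 1/min).
#' @export
strain_kymograph <- function(series, mode = c("strain", "vorticity"),
                             fold = TRUE, absolute = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "velocity_field_series"))
  if (length(series$fields) == 0) stop("empty series")
  build_kymograph(series, fold, quantity = "strain", function(f) {
    st <- strain_field(f, series$um_per_px, series$min_per_frame, mode)
    if (absolute) abs(st) else st
  })
}

#' Chunk-sum feature vector of a kymograph
#'
#' The time axis is split into `n_chunks` contiguous blocks, as equal as
#' possible (earlier blocks one column larger when the length does not
#' divide evenly); each feature is the sum of all kymograph entries in its
#' block across the full distance axis. The sum of the feature vector
#' equals the sum of the kymograph exactly, for any chunk count. A
#' 32 x 144 kymograph with the default 8 chunks yields blocks of 18 time
#' columns each.
#'
#' @param kymo a `kymograph`, or a plain numeric matrix (distance x time).
#' @param n_chunks number of chunks (1 <= n_chunks <= n_time).
#' @return object of class `feature_vector`: `values` (length `n_chunks`),
#'   `quantity`, `movie` label (if known).
#' @export
chunk_features <- function(kymo, n_chunks = 8) {
  vals <- if (inherits(kymo, "kymograph")) kymo$values else kymo
  stopifnot(is.matrix(vals))
  nt <- ncol(vals)
  if (n_chunks < 1) stop("n_chunks must be >= 1")
  if (n_chunks > nt) stop("n_chunks (", n_chunks, ") exceeds the time length (", nt, ")")
  base <- nt %/% n_chunks
  sizes <- base + (seq_len(n_chunks) <= nt %% n_chunks)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  feats <- vapply(seq_len(n_chunks),
                  function(i) sum(vals[, starts[i]:ends[i]]), numeric(1))
  structure(list(values = feats,
                 quantity = if (inherits(kymo, "kymograph")) kymo$quantity else "unknown",
                 movie = attr(kymo, "movie")),
            class = "feature_vector")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph (%s%s): %d distances x %d time points\n", x$quantity,
              if (x$fold) ", folded" else "", nrow(x$values), ncol(x$values)))
  invisible(x)
}
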
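test_that("grid shape reproduces the published 49 x 65 output grid and brute-force placement counts", {
  expect_identical(grid_shape(600, 24, 0.5), 49L)
  expect_identical(grid_shape(800, 24, 0.5), 65L)
  expect_identical(grid_shape(48, 48, 0.5), 1L)
  expect_identical(grid_shape(600, 48, 0.5), 24L)
  expect_identical(grid_shape(800, 48, 0.5), 32L)
  expect_error(grid_shape(20, 24, 0.5), "exceed")

  # brute-force enumeration of window placements over a parameter sweep
  brute <- function(dim, window, overlap) {
    step <- max(1L, as.integer(round(window * (1 - overlap))))
    sum((0:dim) * step + window <= dim)  # top-left offsets i*step fitting fully
  }
  for (window in c(8, 16, 24, 32, 48, 64)) {
    for (overlap in c(0, 0.25, 0.5, 0.75)) {
      for (dim in c(window, 100, 300, 600, 800)) {
        expect_identical(grid_shape(dim, window, overlap),
                         as.integer(brute(dim, window, overlap)),
                         info = sprintf("dim=%d window=%d overlap=%g",
                                        dim, window, overlap))
      }
    }
  }
  # centres lie fully inside the frame
  ctr <- grid_centers(600, 24, 0.5)
  expect_true(all(ctr - 12 >= 0 & ctr + 12 <= 600 + 1))
})

test_that("cross-correlation peaks at the imposed displacement", {
  tex <- generate_texture(c(64, 64), 3, 5)
  wa <- tex[20:43, 20:43]
  cc <- cross_correlate(wa, wa)
  expect_true(attr(cc, "valid"))
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  expect_identical(unname(p), c(24L, 24L))  # centre = zero displacement

  # content shifted by (3, -2): crop interior windows of a shifted texture
  sh <- shift_image(tex, 3, -2)
  wb <- sh[20:43, 20:43]
  cc2 <- cross_correlate(wa, wb)
  p2 <- which(cc2 == max(cc2), arr.ind = TRUE)[1, ]
  expect_identical(unname(p2 - 24L), c(3L, -2L))

  # constant window: flagged invalid, no exception
  cc3 <- cross_correlate(matrix(1, 16, 16), wa[1:16, 1:16])
  expect_false(attr(cc3, "valid"))
  expect_error(subpixel_peak(cc3), "invalid")
  expect_error(cross_correlate(wa, wa[1:10, 1:10]), "equal size")
})

test_that("subpixel peak fit recovers fractional offsets and degenerate cases", {
  gauss_surface <- function(dr, dc, n = 21, sigma = 2) {
    ctr <- (n + 1) / 2
    outer(seq_len(n), seq_len(n), function(i, j)
      exp(-((i - ctr - dr)^2 + (j - ctr - dc)^2) / (2 * sigma^2)))
  }
  pk <- subpixel_peak(gauss_surface(0.5, -0.25))
  expect_equal(pk$drow, 0.5, tolerance = 0.05)
  expect_equal(pk$dcol, -0.25, tolerance = 0.05)
  expect_false(pk$low_confidence)

  # symmetric peak exactly on an integer
  pk0 <- subpixel_peak(gauss_surface(0, 0))
  expect_equal(pk0$drow, 0, tolerance = 1e-12)
  expect_equal(pk0$dcol, 0, tolerance = 1e-12)

  # single spike on a flat surface: zero offset, huge snr
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  pks <- subpixel_peak(m)
  expect_equal(pks$drow, 0)
  expect_gt(pks$snr, 100)

  # two equal, well-separated spikes: snr = 1, below any sane threshold
  m2 <- matrix(0, 21, 21); m2[11, 11] <- 1; m2[11, 18] <- 1
  expect_equal(subpixel_peak(m2)$snr, 1)

  # peak on the border: integer displacement, low confidence
  m3 <- matrix(0, 21, 21); m3[1, 5] <- 1
  pkb <- subpixel_peak(m3)
  expect_true(pkb$low_confidence)
  expect_equal(pkb$drow, -10)
})

test_that("a single PIV pass recovers uniform translation and zero motion", {
  tex <- generate_texture(c(192, 192), 4, 11)
  sh <- shift_image(tex, 2, 0)
  # a single pass carries the classic loss-of-pairs bias along the motion
  # axis; the multi-pass predictor removes it (tested below via run_piv)
  f <- piv_pass(tex, sh, 32, 0.5)
  ok <- f$valid
  expect_gt(mean(ok), 0.9)
  expect_lt(sqrt(mean((f$v[ok] - 2)^2)), 0.2)
  expect_lt(sqrt(mean(f$u[ok]^2)), 0.1)

  f0 <- piv_pass(tex, tex, 32, 0.5)
  expect_lt(max(abs(f0$u[f0$valid])), 1e-6)
  expect_lt(max(abs(f0$v[f0$valid])), 1e-6)
  expect_error(piv_pass(tex, sh, 256, 0.5), "larger than frame")
  expect_error(piv_pass(tex, sh, 15, 0.5), "even")
})

test_that("multi-pass PIV resolves a shear profile within 5% of the slope", {
  set.seed(1)
  tex <- generate_texture(c(300, 400), 4, 21)
  gamma <- 0.02  # px/frame of u per px of row
  rows <- seq_len(300)
  d <- gamma * (rows - 150.5)
  sh <- sheetflow:::row_shift(tex, d)
  ser <- run_piv(image_sequence(array(c(tex, sh), c(300, 400, 2)), 1, 1),
                 piv_config())
  f <- ser$fields[[1]]
  interior <- 3:(nrow(f$u) - 2)
  prof <- rowMeans(f$u[interior, ], na.rm = TRUE)
  fit <- lm(prof ~ f$centers_row[interior])
  expect_equal(unname(coef(fit)[2]), gamma, tolerance = 0.05)
})

test_that("normalized median test flags and replaces a spurious vector, matching a brute-force oracle", {
  set.seed(42)
  u <- matrix(rnorm(25, 1, 0.05), 5, 5)
  v <- matrix(rnorm(25, 0, 0.05), 5, 5)
  u[3, 3] <- 10  # spurious vector, 10x its neighbours
  f <- make_field(u, v)
  out <- validate_and_replace(f, eps = 0.1, thresh = 2)
  expect_false(out$valid[3, 3])
  expect_true(out$replaced[3, 3])
  nb <- u[2:4, 2:4][-5]
  expect_equal(out$u[3, 3], median(nb), tolerance = 1e-12)

  # brute-force residuals reproduce the pass/fail pattern on the whole grid
  brute_pass <- matrix(NA, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    nbs <- function(m) {
      idx <- expand.grid(ii = (i - 1):(i + 1), jj = (j - 1):(j + 1))
      idx <- idx[!(idx$ii == i & idx$jj == j) & idx$ii >= 1 & idx$jj >= 1 &
                   idx$ii <= 5 & idx$jj <= 5, ]
      m[cbind(idx$ii, idx$jj)]
    }
    res <- function(m) {
      n <- nbs(m); md <- median(n)
      abs(m[i, j] - md) / (median(abs(n - md)) + 0.1)
    }
    brute_pass[i, j] <- res(u) <= 2 && res(v) <= 2
  }
  expect_identical(out$valid, brute_pass == TRUE)

  # a smooth field passes untouched
  smooth <- make_field(matrix(1, 6, 6) + 0.01 * outer(1:6, 1:6))
  outs <- validate_and_replace(smooth)
  expect_true(all(outs$valid))
  expect_false(any(outs$replaced))

  expect_error(validate_and_replace(make_field(matrix(1, 2, 2))), "3 x 3")
  allbad <- make_field(matrix(1, 4, 4), valid = matrix(FALSE, 4, 4))
  expect_error(validate_and_replace(allbad), "all vectors invalid")
})

test_that("full PIV on 600 x 800 frames yields the 49 x 65 grid per frame pair", {
  gm <- generate_movie(phenotype_preset("forward"), wound_geometry(),
                       n_frames = 2, seed = 1)
  ser <- run_piv(gm$sequence, piv_config())
  expect_length(ser$fields, 1)
  expect_identical(dim(ser$fields[[1]]$u), c(49L, 65L))
  expect_identical(dim(ser$fields[[1]]$valid), c(49L, 65L))
})

test_that("recovered fields are shift-equivariant and antisymmetric under frame swap", {
  tex <- generate_texture(c(192, 192), 4, 31)
  mv <- shift_image(tex, 1.5, -1)
  cfg <- tiny_piv_config()
  base <- run_piv(image_sequence(array(c(tex, mv), c(192, 192, 2)), 1, 1), cfg)

  # translate both frames by the same integer vector: interior grid unchanged
  texT <- shift_image(tex, 8, 8)
  mvT <- shift_image(mv, 8, 8)
  trans <- run_piv(image_sequence(array(c(texT, mvT), c(192, 192, 2)), 1, 1), cfg)
  nr <- nrow(base$fields[[1]]$u)
  nc <- ncol(base$fields[[1]]$u)
  ib <- base$fields[[1]]$u[3:(nr - 2), 3:(nc - 2)]
  # frame content moved by (8,8), so grid node (i,j) of the translated pair
  # sees what node (i-1,j-1) saw (step 8)
  it <- trans$fields[[1]]$u[4:(nr - 1), 4:(nc - 1)]
  expect_lt(median(abs(ib - it), na.rm = TRUE), 0.05)

  # swapping the frames negates the displacement: exactly at integer motion,
  # to subpixel tolerance (RMS of the residual) at fractional motion
  mvi <- shift_image(tex, 2, -3)
  fwd_i <- run_piv(image_sequence(array(c(tex, mvi), c(192, 192, 2)), 1, 1), cfg)
  rev_i <- run_piv(image_sequence(array(c(mvi, tex), c(192, 192, 2)), 1, 1), cfg)
  fbi <- fwd_i$fields[[1]]; fri <- rev_i$fields[[1]]
  oki <- fbi$valid & fri$valid
  expect_gt(mean(oki), 0.8)
  expect_lt(sqrt(mean((fbi$u[oki] + fri$u[oki])^2)), 0.1)
  expect_lt(sqrt(mean((fbi$v[oki] + fri$v[oki])^2)), 0.1)
  expect_lt(median(abs(fbi$u[oki] + fri$u[oki])), 0.02)

  rev <- run_piv(image_sequence(array(c(mv, tex), c(192, 192, 2)), 1, 1), cfg)
  fb <- base$fields[[1]]; fr <- rev$fields[[1]]
  ok <- fb$valid & fr$valid
  expect_gt(mean(ok), 0.8)
  expect_lt(sqrt(mean((fb$u[ok] + fr$u[ok])^2)), 0.15)
  expect_lt(sqrt(mean((fb$v[ok] + fr$v[ok])^2)), 0.15)
})

test_that("run_piv matches the generator ground truth inside the sheets", {
  geom <- tiny_geometry(160, 240, 30)
  gm <- generate_movie(phenotype_spec(2 * 1.3 / 48, speed_jitter_sd = 0.01),
                       geom, n_frames = 6, seed = 13,
                       grid_window = 16)
  ser <- run_piv(gm$sequence, tiny_piv_config())
  for (k in seq_along(ser$fields)) {
    f <- ser$fields[[k]]
    side <- sheet_side(gm$truth, k, margin = 10)
    sel <- side != 0 & f$valid
    err <- abs((f$u - gm$truth$u[, , k])[sel])
    expect_gt(mean(f$valid[side != 0]), 0.85)
    expect_lt(median(err), 0.08)
    expect_lt(quantile(err, 0.9, names = FALSE), 0.15)
  }
})

test_that("stride measures displacement across skipped frames and renormalizes per frame", {
  tex <- generate_texture(c(160, 160), 4, 17)
  fr <- array(0, c(160, 160, 3))
  fr[, , 1] <- tex
  fr[, , 2] <- shift_image(tex, 0, 1)
  fr[, , 3] <- shift_image(tex, 0, 2)
  ser <- run_piv(image_sequence(fr, 1, 1), tiny_piv_config(stride = 2))
  expect_length(ser$fields, 1)
  f <- ser$fields[[1]]
  expect_equal(mean(f$u[f$valid]), 1, tolerance = 0.05)
})
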
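test_that("velocity kymograph equals a brute-force column median and handles trivial fields", {
  # field constant along rows -> kymograph column equals that constant
  u <- matrix(rep(c(2, 1, 0, -1, -2), each = 4), 4, 5)
  f <- make_field(u, window = 16, step = 8, frame_shape = c(40, 100))
  ser <- make_series(rep(list(f), 3))
  k <- velocity_kymograph(ser, f$centers_col[3], fold = FALSE)
  s <- signed_closure_velocity(f, f$centers_col[3])
  expect_equal(dim(k$values), c(5L, 3L))
  for (t in 1:3) expect_equal(k$values[, t], apply(s, 2, median), tolerance = 1e-12)

  # median robustness: column values {1, 1, 100} -> 1, as in a sort-and-pick oracle
  u2 <- matrix(1, 3, 3); u2[3, 2] <- 100
  f2 <- make_field(u2, window = 16, step = 8, frame_shape = c(40, 60))
  ser2 <- make_series(list(f2))
  k2 <- velocity_kymograph(ser2, 59, fold = FALSE)  # all columns left of the centre
  expect_equal(k2$values[2, 1], sort(c(1, 1, 100))[2])

  # all-zero series -> zero matrix
  f0 <- make_field(matrix(0, 4, 5), window = 16, step = 8, frame_shape = c(40, 100))
  k0 <- velocity_kymograph(make_series(rep(list(f0), 4)), 25)
  expect_true(all(k0$values == 0))
})

test_that("kymograph entries match an independent median oracle under random validity", {
  set.seed(11)
  fields <- lapply(1:6, function(t)
    make_field(matrix(rnorm(42), 6, 7), valid = matrix(runif(42) > 0.3, 6, 7),
               window = 16, step = 8, frame_shape = c(56, 120)))
  ser <- make_series(fields, um_per_px = 1.3, min_per_frame = 48)
  wcc <- 60
  k <- velocity_kymograph(ser, wcc, fold = FALSE)
  sgn <- sign(wcc - fields[[1]]$centers_col)
  for (t in 1:6) for (j in 1:7) {
    f <- fields[[t]]
    vals <- f$u[f$valid[, j], j] * sgn[j] * 1.3 / 48
    if (length(vals) > 0 && !k$interpolated[j, t])
      expect_equal(k$values[j, t], median(vals), tolerance = 1e-12)
  }
  # folding averages mirror columns after sign folding
  kf <- velocity_kymograph(ser, wcc, fold = TRUE)
  expect_equal(nrow(kf$values), 4L)  # ceil(7/2)
  expect_equal(kf$values[1, ], (k$values[1, ] + k$values[7, ]) / 2, tolerance = 1e-12)
  expect_equal(kf$values[4, ], k$values[4, ], tolerance = 1e-12)  # middle column unpaired
})

test_that("columns with no usable vectors are interpolated from time neighbours and flagged", {
  fields <- lapply(1:3, function(t) {
    val <- matrix(TRUE, 4, 5)
    if (t == 2) val[, 2] <- FALSE
    make_field(matrix(t, 4, 5), valid = val, window = 16, step = 8,
               frame_shape = c(40, 100))
  })
  # replaced mask stays FALSE so column 2 at t=2 is truly unusable
  ser <- make_series(fields)
  k <- velocity_kymograph(ser, 100, fold = FALSE)
  expect_true(k$interpolated[2, 2])
  expect_equal(k$values[2, 2], 2, tolerance = 1e-12)  # linear in time
})

test_that("strain field reproduces analytic gradients and rotation decomposition", {
  # uniform translation: all strain measures vanish
  f <- make_field(matrix(3, 5, 6), matrix(-1, 5, 6), window = 16, step = 8)
  expect_true(all(abs(strain_field(f, 1, 1, "strain")) < 1e-12))
  expect_true(all(abs(strain_field(f, 1, 1, "vorticity")) < 1e-12))

  # u = gamma * x (px): du/dx = gamma at interior points, in 1/min units
  gamma <- 0.03
  cc <- 8 * (0:5) + 8.5
  u <- matrix(rep(gamma * cc, each = 5), 5, 6)
  fx <- make_field(u, window = 16, step = 8)
  st <- strain_field(fx, um_per_px = 2, min_per_frame = 4)
  # u px/frame -> um/min multiplies by 2/4; x px -> um multiplies by 2: net /4
  expect_equal(st[2:4, 2:5], matrix(gamma / 4, 3, 4), tolerance = 1e-10)

  # rigid rotation u = -w*y, v = +w*x: vorticity 2w, normal strain 0
  w <- 0.01
  cr <- 8 * (0:4) + 8.5
  urot <- matrix(rep(-w * cr, times = 6), 5, 6)
  vrot <- matrix(rep(w * cc, each = 5), 5, 6)
  frot <- make_field(urot, vrot, window = 16, step = 8)
  expect_true(all(abs(strain_field(frot, 1, 1, "strain")) < 1e-10))
  expect_equal(strain_field(frot, 1, 1, "vorticity"),
               matrix(2 * w, 5, 6), tolerance = 1e-10)

  expect_error(strain_field(make_field(matrix(1, 2, 2)), 1, 1), "3 x 3")
})

test_that("strain kymograph distinguishes sheared from shear-free synthetic sheets", {
  geom <- wound_geometry(c(300, 400), 200, 40)
  plain <- generate_movie(phenotype_spec(2 * 1.3 / 48, speed_jitter_sd = 0),
                          geom, n_frames = 6, seed = 3)
  shear <- generate_movie(phenotype_spec(0, shear_rate = 5e-4, speed_jitter_sd = 0),
                          geom, n_frames = 6, seed = 3)
  cfg <- piv_config()
  ks_plain <- strain_kymograph(run_piv(plain$sequence, cfg), mode = "vorticity")
  ks_shear <- strain_kymograph(run_piv(shear$sequence, cfg), mode = "vorticity")
  # sheared kymograph entries sit near the prescribed rate
  interior <- 3:(nrow(ks_shear$values) - 2)
  expect_equal(median(ks_shear$values[interior, ]), 5e-4, tolerance = 0.1)
  # shear-free preset is far below: noise floor under 10% of the sheared level
  expect_lt(median(ks_plain$values), 0.1 * median(ks_shear$values))

  # zero series -> zero matrix
  f0 <- make_field(matrix(0, 4, 5), window = 16, step = 8, frame_shape = c(40, 100))
  k0 <- strain_kymograph(make_series(rep(list(f0), 3)))
  expect_true(all(k0$values == 0))
})

test_that("chunk features preserve totals and split the time axis as evenly as possible", {
  # the worked 32 x 144 case: 8 chunks of 18 columns; all-ones sums to 576
  k <- matrix(1, 32, 144)
  fv <- chunk_features(k, 8)
  expect_length(fv$values, 8)
  expect_true(all(fv$values == 32 * 18))

  set.seed(3)
  k2 <- matrix(rnorm(32 * 144), 32, 144)
  for (n in c(1, 5, 8, 13, 144)) {
    f2 <- chunk_features(k2, n)
    expect_length(f2$values, n)
    expect_equal(sum(f2$values), sum(k2), tolerance = 1e-9)
  }
  # remainder goes to the earlier blocks: 10 columns in 3 chunks -> 4, 3, 3
  k3 <- matrix(1, 2, 10)
  expect_equal(chunk_features(k3, 3)$values, c(8, 6, 6))
  expect_error(chunk_features(k3, 11), "exceeds")
  expect_error(chunk_features(k3, 0), ">= 1")
})

test_that("PCA embedding matches an eigen-decomposition oracle with a fixed sign convention", {
  # variance along one axis only: PC1 explains everything
  X1 <- cbind(seq(-2, 2, length.out = 9), 0, 0)
  e1 <- pca_embed(X1, 1)
  expect_equal(e1$explained_variance_ratio[1], 1, tolerance = 1e-12)

  # random matrix: scores equal projection onto covariance eigenvectors
  set.seed(9)
  X <- matrix(rnorm(80), 10, 8)
  emb <- pca_embed(X, 5)
  C <- cov(X)
  ev <- eigen(C, symmetric = TRUE)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  for (i in 1:5) {
    vec <- ev$vectors[, i]
    j <- which.max(abs(vec))
    if (vec[j] < 0) vec <- -vec
    expect_equal(unname(emb$scores[, i]), unname(as.vector(ctr %*% vec)),
                 tolerance = 1e-8)
    expect_equal(emb$explained_variance_ratio[i],
                 ev$values[i] / sum(ev$values), tolerance = 1e-8)
  }
  # reconstruction at full rank
  embf <- pca_embed(X, 8)
  expect_equal(embf$scores %*% t(embf$loadings), unclass(ctr),
               tolerance = 1e-8, ignore_attr = TRUE)

  # explained-variance ratios: non-negative, non-increasing, sum <= 1
  expect_true(all(diff(emb$explained_variance_ratio) <= 1e-12))
  expect_true(all(emb$explained_variance_ratio >= 0))
  expect_lte(sum(emb$explained_variance_ratio), 1 + 1e-12)

  # two duplicated groups far apart separate on PC1 with opposite signs
  G <- rbind(matrix(0, 4, 6), matrix(10, 4, 6))
  eg <- pca_embed(G + matrix(rnorm(48, 0, 0.01), 8, 6), 1)
  expect_true(all(sign(eg$scores[1:4, 1]) == -sign(eg$scores[5:8, 1])))

  # zero-variance feature dropped under standardization
  Z <- cbind(rnorm(6), 1)
  expect_warning(pca_embed(Z, 1, standardize = TRUE), "zero-variance")
  expect_error(pca_embed(X, 10), "n_components")
})

test_that("cluster separation statistic and permutation p behave on constructed embeddings", {
  set.seed(4)
  tight <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 20, 0.1), 10))
  lab <- rep(c("a", "b"), each = 10)
  cs <- cluster_separation(tight, lab, n_permutations = 999, seed = 1)
  expect_gt(cs$statistic, 0.9)
  expect_lte(cs$p_value, 0.001 + 1e-9)

  # random labels on one homogeneous cloud: no significance for a typical draw
  cloud <- matrix(rnorm(40), 20, 2)
  cs2 <- cluster_separation(cloud, lab, n_permutations = 499, seed = 2)
  expect_gt(cs2$p_value, 0.05)

  # identical points in both groups: silhouette 0 without division error
  same <- matrix(1, 8, 2)
  cs3 <- cluster_separation(same, rep(c("a", "b"), 4), n_permutations = 99, seed = 3)
  expect_equal(cs3$statistic, 0)

  expect_error(cluster_separation(tight, c("a", rep("b", 19))), "at least two members")
  expect_error(cluster_separation(tight, rep("a", 20)), "distinct labels")
})
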
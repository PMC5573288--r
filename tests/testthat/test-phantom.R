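test_that("phantom abundances are a stochastic mixture with sum-to-one columns", {
  ph <- small_phantom(seed = 1)
  expect_lt(max(abs(colSums(ph$H_true) - 1)), 1e-12)
  expect_true(all(ph$H_true >= 0))
  expect_true(all(ph$X$data >= 0))
  expect_identical(dim(ph$X), c(24L, 576L))
  expect_identical(length(ph$label_map_true), 576L)
  expect_true(all(lengths(ph$pure_indices) > 0))
})

test_that("phantoms are bit-identical per seed and differ across seeds", {
  a <- small_phantom(seed = 5)
  b <- small_phantom(seed = 5)
  expect_identical(a$X$data, b$X$data)
  expect_identical(a$H_true, b$H_true)
  expect_false(identical(a$X$data, small_phantom(seed = 6)$X$data))
})

test_that("noiseless separable phantoms are exact and SPA-recoverable", {
  ph <- small_phantom(seed = 7, snr_db = Inf, purity = 1)
  expect_identical(ph$X$data, ph$W_true %*% ph$H_true)
  sel <- spa_select_columns(ph$X, 4)
  hits <- vapply(sel$indices, function(i) {
    which(vapply(ph$pure_indices, function(s) i %in% s, TRUE))[1]
  }, 1L)
  expect_setequal(hits, 1:4)
  # pure columns really are one-hot
  for (k in 1:4) {
    expect_true(all(ph$H_true[k, ph$pure_indices[[k]]] == 1))
  }
})

test_that("pure-pixel violation removes a source's pure voxels", {
  ph <- small_phantom(seed = 8, pure_pixel = c(TRUE, TRUE, TRUE, FALSE))
  expect_length(ph$pure_indices[[4]], 0)
  expect_gt(length(ph$pure_indices[[3]]), 0)
  nec <- which(ph$region_map == 4L)
  expect_lt(max(ph$H_true[4, nec]), 1) # no one-hot necrosis voxel remains
})

test_that("ground-truth labels are the dominant tissue everywhere", {
  ph <- small_phantom(seed = 9)
  expect_identical(ph$label_map_true,
                   as.integer(apply(ph$H_true, 2, which.max)))
  # interior voxels also match the geometric region
  interior <- setdiff(seq_along(ph$region_map),
                      which(ph$region_map != ph$label_map_true))
  expect_gt(length(interior) / length(ph$region_map), 0.9)
})

test_that("snr_of measures noise power in dB and the generator calibrates to it", {
  X <- rand_nonneg(5, 10, seed = 10)
  expect_identical(snr_of(X, X), Inf)
  # noise with exactly half the clean power -> 10 log10(2)
  noise <- withr::with_seed(11, matrix(rnorm(50), 5, 10))
  noise <- noise * sqrt(sum(X^2) / 2 / sum(noise^2))
  expect_equal(snr_of(X, X + noise), 10 * log10(2), tolerance = 1e-12)

  ph <- make_phantom(grid_shape = c(40, 40), seed = 12, snr_db = 30) # n = 1600
  expect_lt(abs(ph$snr_db - 30), 0.5)
})

test_that("near-separability certificate on a noiseless phantom", {
  # the convex hull of the columns is spanned by the pure pixels: every
  # non-pure column is a convex combination of one pure representative per
  # source, and no pure representative lies in the hull of the other three
  ph <- make_phantom(grid_shape = c(24, 24), seed = 13, snr_db = Inf, purity = 1)
  X <- ph$X$data
  reps <- vapply(ph$pure_indices, `[`, 1L, 1L)
  V <- X[, reps]
  nonpure <- setdiff(seq_len(ncol(X)), unlist(ph$pure_indices))
  mix <- V %*% ph$H_true[, nonpure, drop = FALSE]
  expect_equal(mix, X[, nonpure, drop = FALSE], tolerance = 1e-12)
  expect_true(all(ph$H_true[, nonpure] >= 0))
  expect_lt(max(abs(colSums(ph$H_true[, nonpure, drop = FALSE]) - 1)), 1e-12)
  for (k in 1:4) {
    # best sum-to-one non-negative fit on the other vertices keeps a
    # positive residual (sum-to-one encoded as a heavily weighted row)
    A <- rbind(V[, -k, drop = FALSE], 1e3)
    b <- matrix(c(V[, k], 1e3), ncol = 1)
    coef <- nnls_abundances(b, A)
    expect_gt(sqrt(sum((V[, k] - V[, -k] %*% coef)^2)), 1e-6)
  }
})
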
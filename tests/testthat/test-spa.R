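test_that("SPA selection matches hand-worked projections", {
  # norms^2 {1, 1, 0.5}: tie broken to column 1; projecting out (1,0) leaves
  # norms^2 {0, 1, 0.25} -> column 2
  X <- matrix(c(1, 0, 0, 1, 0.5, 0.5), nrow = 2)
  sel <- spa_select_columns(X, 2)
  expect_equal(sel$indices, c(1L, 2L))
  expect_equal(sel$projected_norms, c(1, 1))
  expect_equal(sel$vectors, X[, 1:2])

  # norms^2 {4, 1, 1.25}; after projecting out (2,0): {0, 1, 0.25}
  X2 <- matrix(c(2, 0, 0, 1, 1, 0.5), nrow = 2)
  sel2 <- spa_select_columns(X2, 2)
  expect_equal(sel2$indices, c(1L, 2L))
  expect_equal(sel2$projected_norms, c(4, 1))

  # r = 1: plain argmax of squared column norm
  X3 <- rand_nonneg(4, 9, seed = 3)
  expect_equal(spa_select_columns(X3, 1)$indices,
               which.max(colSums(X3^2)))
})

test_that("SPA selection agrees with brute-force enumeration of the greedy rule", {
  # independent oracle: recompute each greedy step by explicit projection
  # matrices over all remaining columns
  for (seed in 1:5) {
    X <- rand_nonneg(5, 12, seed = seed)
    r <- 3
    sel <- spa_select_columns(X, r)
    S <- X
    for (j in seq_len(r)) {
      norms <- apply(S, 2, function(col) sum(col^2))
      i <- which.max(norms)
      expect_identical(sel$indices[[j]], i)
      expect_equal(sel$projected_norms[[j]], norms[[i]])
      s <- S[, i]
      P <- diag(nrow(X)) - outer(s, s) / sum(s^2)
      S <- P %*% S
    }
  }
})

test_that("SPA errors: rank exceeded and rank deficiency", {
  X <- matrix(c(1, 0, 0, 1), 2)
  expect_error(spa_select_columns(X, 3), "exceeds")
  # rank-1 matrix cannot yield 2 columns
  Xr1 <- outer(c(1, 2), c(1, 0.5, 2))
  expect_error(spa_select_columns(Xr1, 2), "rank deficiency at SPA step 2")
})

test_that("SPA invariants: orthogonality, determinism, monotone norms, pure-pixel recovery", {
  ph <- small_phantom(seed = 11, snr_db = Inf)
  X <- ph$X$data
  r <- 4
  sel1 <- spa_select_columns(X, r)
  sel2 <- spa_select_columns(X, r)
  expect_identical(sel1, sel2) # bit-identical reruns
  expect_true(all(diff(sel1$projected_norms) <= 1e-12))

  # projection orthogonality: rebuild internal S and check against selected s_j
  S <- X
  svecs <- list()
  for (j in seq_len(r)) {
    s <- S[, sel1$indices[[j]]]
    svecs[[j]] <- s
    S <- S - s %*% (crossprod(s, S) / sum(s^2))
    for (k in seq_len(j)) {
      expect_lt(max(abs(crossprod(svecs[[k]], S))), 1e-8 * sqrt(sum(X^2)))
    }
  }

  # exact recovery on noiseless separable phantoms: every selected column is a
  # recorded pure pixel and all sources are covered (generator = oracle)
  for (seed in 1:5) {
    ph <- small_phantom(seed = seed, snr_db = Inf)
    sel <- spa_select_columns(ph$X$data, 4)
    src <- vapply(sel$indices, function(i) {
      hits <- which(vapply(ph$pure_indices, function(s) i %in% s, TRUE))
      if (length(hits) == 1L) hits else NA_integer_
    }, 1L)
    expect_false(anyNA(src))
    expect_setequal(src, 1:4)
  }
})

test_that("SPA initialization reconstructs separable data and is deterministic", {
  X <- matrix(c(1, 0, 0, 1, 0.5, 0.5), nrow = 2)
  ini <- init_spa(X, 2)
  expect_equal(ini$W0, matrix(c(1, 0, 0, 1), 2))
  expect_equal(ini$H0, X)
  expect_identical(ini$method, "spa")

  ph <- small_phantom(seed = 21, snr_db = Inf, purity = 1)
  ini <- init_spa(ph$X, 4)
  rel <- nmf_residual(ph$X, ini$W0, ini$H0) / sqrt(sum(ph$X$data^2))
  expect_lt(rel, 1e-8)

  # r = m with coordinate-direction columns: exact basis
  Xb <- cbind(diag(c(2, 3, 4)), rand_nonneg(3, 5, seed = 9))
  ini <- init_spa(Xb, 3)
  expect_lt(nmf_residual(Xb, ini$W0, ini$H0), 1e-10)
})
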
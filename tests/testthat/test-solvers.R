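test_that("residual computes the Frobenius norm of the misfit", {
  X <- diag(2)
  expect_equal(nmf_residual(X, matrix(c(1, 0), 2, 1), matrix(c(1, 0), 1, 2)), 1)
  expect_equal(nmf_residual(X, matrix(0, 2, 1), matrix(0, 1, 2)), sqrt(2))
  gen <- rand_factorizable(4, 6, 2, seed = 1)
  expect_equal(nmf_residual(gen$X, gen$W, gen$H), 0)
  expect_error(nmf_residual(X, matrix(1, 3, 1), matrix(1, 1, 2)), "shape")
})

test_that("every solver recognizes an exact factorization as a fixed point", {
  gen <- rand_factorizable(8, 12, 3, seed = 2)
  ini <- structure(list(W0 = gen$W, H0 = gen$H, method = "oracle", seed = NULL),
                   class = "nmf_init")
  for (fit in list(nmf_ahals(gen$X, ini), nmf_pg(gen$X, ini), nmf_gd(gen$X, ini))) {
    expect_true(fit$converged)
    expect_lte(fit$n_iter, 4)
    expect_lt(fit$residual_trace[[length(fit$residual_trace)]], 1e-8)
  }
})

test_that("aHALS and convex traces are non-increasing; PG and GD descend overall", {
  for (seed in 1:8) {
    X <- rand_nonneg(10, 20, seed = seed)
    ctl <- nmf_control(max_iter = 300)
    ini <- init_random(10, 20, 3, seed = seed + 500)
    fa <- nmf_ahals(X, ini, ctl)
    expect_true(all(diff(fa$residual_trace) <= 1e-9))
    fc <- nmf_convex(X, convex_weights_init(ini$H0), ini$H0, ctl)
    expect_true(all(diff(fc$residual_trace) <= 1e-9))
    fp <- nmf_pg(X, ini, ctl)
    fg <- nmf_gd(X, ini, ctl)
    for (f in list(fp, fg)) {
      tr <- f$residual_trace
      expect_lte(tr[[length(tr)]], tr[[1L]])
    }
  }
})

test_that("solvers honor the common stopping contract", {
  ctl <- nmf_control(tol = 1e-4, max_iter = 50)
  X <- rand_nonneg(8, 15, seed = 9)
  ini <- init_random(8, 15, 3, seed = 10)
  fits <- list(nmf_ahals(X, ini, ctl), nmf_pg(X, ini, ctl), nmf_gd(X, ini, ctl),
               nmf_convex(X, convex_weights_init(ini$H0), ini$H0, ctl))
  for (f in fits) {
    tr <- f$residual_trace
    expect_identical(f$n_iter, length(tr) - 1L)
    expect_lte(f$n_iter, ctl$max_iter)
    if (f$converged && f$n_iter < ctl$max_iter && f$n_iter >= 1L) {
      last_rel <- abs(tr[[f$n_iter + 1L]] - tr[[f$n_iter]]) / tr[[f$n_iter]]
      expect_lt(last_rel, ctl$tol)
    }
    if (!f$converged) expect_identical(f$n_iter, ctl$max_iter)
    expect_true(all(f$W >= 0))
    expect_true(all(f$H >= 0))
  }
})

test_that("PG subproblem for fixed W matches exact per-column NNLS", {
  X <- rand_nonneg(6, 10, seed = 11)
  W <- rand_nonneg(6, 2, seed = 12)
  H_pg <- spanmf:::pg_subproblem(X, W, matrix(0.5, 2, 10),
                                 tol = 1e-10, maxit = 5000,
                                 sigma = 0.01, beta = 0.1)$H
  H_nnls <- nnls_abundances(X, W)
  res_pg <- sqrt(sum((X - W %*% H_pg)^2))
  res_nnls <- sqrt(sum((X - W %*% H_nnls)^2))
  expect_lt(abs(res_pg - res_nnls) / res_nnls, 1e-4)
})

test_that("GD solves an exactly factorizable rank-1 problem", {
  X <- matrix(c(1, 2, 2, 4), 2)
  fit <- nmf_gd(X, init_random(2, 2, 1, seed = 0), nmf_control(max_iter = 5000))
  expect_lt(fit$residual_trace[[length(fit$residual_trace)]], 1e-6)
  # oracle: the leading singular value carries all the mass
  expect_equal(svd(X)$d[[2]], 0, tolerance = 1e-12)
})

test_that("convex NMF keeps its sources in the column space of the data", {
  for (seed in 1:5) {
    X <- rand_nonneg(8, 15, seed = seed)
    # make the column space a strict subspace so the check is non-trivial
    X <- rbind(X, colSums(X))
    ini <- init_random(9, 15, 3, seed = seed + 30)
    fit <- nmf_convex(X, convex_weights_init(ini$H0), ini$H0,
                      nmf_control(max_iter = 200))
    expect_lt(colspace_deviation(X, fit$W), 1e-8)
    expect_equal(fit$W, X %*% fit$A)
  }
})

test_that("restart orchestration returns the best seeded run", {
  X <- rand_nonneg(8, 14, seed = 40)
  ctl <- nmf_control(max_iter = 200, n_restarts = 5)
  best <- run_with_restarts(X, 3, "ahals", "random", ctl, base_seed = 7)
  expect_length(best$restart_residuals, 5)
  finals <- best$restart_residuals
  expect_equal(best$residual_trace[[length(best$residual_trace)]],
               min(finals, na.rm = TRUE))
  # reproducible given base_seed
  again <- run_with_restarts(X, 3, "ahals", "random", ctl, base_seed = 7)
  expect_identical(best$W, again$W)
  # n_restarts = 1 equals a single seeded run
  one <- run_with_restarts(X, 3, "ahals", "random",
                           nmf_control(max_iter = 200, n_restarts = 1),
                           base_seed = 7)
  single <- nmf_ahals(X, init_random(8, 14, 3, seed = 7),
                      nmf_control(max_iter = 200))
  expect_identical(one$W, single$W)
})

test_that("all solvers agree on a noiseless separable phantom with SPA init", {
  ph <- small_phantom(seed = 31, snr_db = Inf)
  X <- ph$X$data
  normX <- sqrt(sum(X^2))
  ini <- init_spa(X, 4)
  ctl <- nmf_control(max_iter = 500)
  fits <- list(ahals = nmf_ahals(X, ini, ctl),
               pg = nmf_pg(X, ini, ctl),
               gd = nmf_gd(X, ini, ctl))
  for (nm in names(fits)) {
    rel <- fits[[nm]]$residual_trace[[length(fits[[nm]]$residual_trace)]] / normX
    expect_lt(rel, 1e-3)
  }
  # the convexity constraint plus the dense weight offset make the
  # multiplicative solver level off above the unconstrained solvers; it
  # still reduces the initial misfit by more than an order of magnitude
  fc <- nmf_convex(X, convex_weights_init(ini$H0), ini$H0,
                   nmf_control(max_iter = 10000))
  rel_c <- fc$residual_trace[[length(fc$residual_trace)]] / normX
  expect_lt(rel_c, 5e-2)
  expect_lt(rel_c * normX, 0.05 * fc$residual_trace[[1L]])
})

test_that("tidy, glance and autoplot expose the fit", {
  X <- rand_nonneg(6, 9, seed = 50)
  fit <- nmf(X, 2, init = "spa", solver = "ahals")
  td <- tidy(fit)
  expect_identical(td$iteration[[1L]], 0L)
  expect_identical(nrow(td), fit$n_iter + 1L)
  gl <- glance(fit)
  expect_identical(gl$n_iter, fit$n_iter)
  expect_s3_class(autoplot(fit), "ggplot")
})
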
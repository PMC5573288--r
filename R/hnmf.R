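#' Two-level hierarchical NMF
#'
#' Hierarchical NMF splits the problem over two levels: (1) a rank-2
#' accelerated-HALS NMF of `X` separates the data into two broad
#' compartments (in brain-tumor data, pathologic vs normal-appearing
#' tissue); (2) every voxel is assigned to the branch of its larger
#' level-1 abundance (ties to branch 1) and each branch is factorized
#' again with aHALS at ranks `r1` and `r - r1`; (3) the branch sources
#' are pooled into `W_pooled = [W_1, W_2]` and the final abundances over
#' all voxels are recomputed by exact non-negative least squares (see
#' [nnls_abundances()]). The chosen initialization method is applied at
#' both levels; with non-deterministic initializers each level uses
#' best-of-`control$n_restarts` restarts.
#'
#' @param X data matrix or [feature_matrix()].
#' @param r total rank, `>= 2`.
#' @param r1 rank given to branch 1 (`1 <= r1 < r`); branch 2 gets
#'   `r - r1`. Default `ceiling(r / 2)`.
#' @param init_method `"spa"`, `"nndsvd"`, `"fcm"` or `"random"`.
#' @param control an [nmf_control()].
#' @param seed base seed for non-deterministic initializers.
#' @return An object of class `hnmf_fit` (also usable like an `nmf_fit`):
#'   `W` (= `W_pooled`), `H` (= final NNLS abundances), `level1`,
#'   `branch_assignment`, `branch_fits`, `converged`, `n_iter` (summed
#'   over the three aHALS runs), `residual_trace` (of the pooled final
#'   factorization: initial and final residual).
#' @export
hnmf <- function(X, r, r1 = ceiling(r / 2), init_method = "spa",
                 control = nmf_control(), seed = 1L) {
  X <- fm_data(X)
  r <- as.integer(r); r1 <- as.integer(r1)
  if (r < 2L) stop("hierarchical NMF needs r >= 2", call. = FALSE)
  if (r1 < 1L || r1 >= r) stop("rank split must satisfy 1 <= r1 < r", call. = FALSE)
  run_level <- function(Xs, rank, seed_offset) {
    if (init_method %in% c("spa", "nndsvd")) {
      solve_with_init(Xs, make_init(Xs, rank, init_method), "ahals", control)
    } else {
      run_with_restarts(Xs, rank, "ahals", init_method, control,
                        base_seed = seed + seed_offset)
    }
  }
  level1 <- run_level(X, 2L, 0L)
  branch <- ifelse(level1$H[1L, ] >= level1$H[2L, ], 1L, 2L)
  ranks <- c(r1, r - r1)
  for (b in 1:2) {
    nb <- sum(branch == b)
    if (nb < ranks[[b]]) {
      stop(sprintf("branch %d received %d columns, fewer than its rank %d",
                   b, nb, ranks[[b]]), call. = FALSE)
    }
  }
  fits <- lapply(1:2, function(b) {
    run_level(X[, branch == b, drop = FALSE], ranks[[b]], b * 1000L)
  })
  W_pooled <- cbind(fits[[1L]]$W, fits[[2L]]$W)
  H_final <- nnls_abundances(X, W_pooled)
  res <- fnorm(X - W_pooled %*% H_final)
  structure(list(W = W_pooled, H = H_final,
                 level1 = level1, branch_assignment = branch,
                 branch_fits = fits,
                 residual_trace = c(level1$residual_trace[[1L]], res),
                 n_iter = level1$n_iter + fits[[1L]]$n_iter + fits[[2L]]$n_iter,
                 converged = level1$converged && fits[[1L]]$converged &&
                   fits[[2L]]$converged,
                 solver = "hnmf", init_method = init_method, seed = seed),
            class = c("hnmf_fit", "nmf_fit"))
}

#' @export
print.hnmf_fit <- function(x, ...) {
  cat(sprintf(
    "<hnmf_fit> init = %s, ranks = %d + %d\n  branch sizes: %d / %d, final ||X - WH||_F = %.6g\n",
    x$init_method, ncol(x$branch_fits[[1L]]$W), ncol(x$branch_fits[[2L]]$W),
    sum(x$branch_assignment == 1L), sum(x$branch_assignment == 2L),
    x$residual_trace[[length(x$residual_trace)]]))
  invisible(x)
}
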
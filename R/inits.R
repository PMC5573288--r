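#' Random NMF initialization
#'
#' `W0` and `H0` filled with i.i.d. Uniform(0, 1) draws from a seeded
#' generator; the benchmark initializer, used inside the repeated-restart
#' strategy (see [run_with_restarts()]).
#'
#' @param m,n,r problem dimensions (features, voxels, rank).
#' @param seed integer seed; the same seed reproduces the factors exactly.
#' @return An `nmf_init` (see [init_spa()]) with `method = "random"`.
#' @export
init_random <- function(m, n, r, seed = NULL) {
  with_seed(seed, {
    W0 <- matrix(stats::runif(m * r), m, r)
    H0 <- matrix(stats::runif(r * n), r, n)
    new_nmf_init(W0, H0, method = "random", seed = seed)
  })
}

#' Non-negative double SVD (NNDSVD) initialization
#'
#' Deterministic initialization from the truncated SVD
#' `X ~ sum_i sigma_i u_i v_i'`. The leading singular pair of a
#' non-negative matrix can be chosen non-negative, giving
#' `W0[, 1] = sqrt(sigma_1) |u_1|`, `H0[1, ] = sqrt(sigma_1) |v_1|`. For
#' `i >= 2` each singular pair is split into positive and negative parts
#' `u = u+ - u-`, `v = v+ - v-`; of the two non-negative rank-1 candidates
#' `u+ v+'` and `u- v-'` the one with the larger product of factor norms
#' is the dominant singular triplet of the positive part of
#' `sigma_i u_i v_i'` and is kept, scaled so the term carries weight
#' `sigma_i * mu` with `mu` the norm product. Exact zeros left by the
#' positive-part construction would stay zero under multiplicative and
#' squared-variable solvers, so every zero of `W0` (resp. `H0`) is
#' replaced by 1% of the mean of its positive entries.
#'
#' Singular-vector signs are fixed (largest-magnitude entry of each `u_i`
#' made positive) so repeated runs are bit-identical.
#'
#' @inheritParams spa_select_columns
#' @return An `nmf_init` with `method = "nndsvd"` and strictly positive
#'   factors.
#' @export
init_nndsvd <- function(X, r) {
  X <- fm_data(X)
  m <- nrow(X); n <- ncol(X)
  r <- as.integer(r)
  if (r > min(m, n)) stop("r exceeds min(m, n)", call. = FALSE)
  sv <- svd(X, nu = r, nv = r)
  d <- sv$d[seq_len(r)]
  if (any(d < .Machine$double.eps * max(sv$d) * max(m, n))) {
    warning("r exceeds the numerical rank of X; trailing NNDSVD components are near zero")
  }
  W0 <- matrix(0, m, r)
  H0 <- matrix(0, r, n)
  for (i in seq_len(r)) {
    u <- sv$u[, i]
    v <- sv$v[, i]
    # deterministic sign convention
    s <- sign(u[which.max(abs(u))])
    if (s < 0) { u <- -u; v <- -v }
    if (i == 1L) {
      W0[, 1L] <- sqrt(d[[1L]]) * abs(u)
      H0[1L, ] <- sqrt(d[[1L]]) * abs(v)
      next
    }
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    mp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    mn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (mp >= mn) {
      mu <- mp
      uu <- if (mp > 0) up / sqrt(sum(up^2)) else up
      vv <- if (mp > 0) vp / sqrt(sum(vp^2)) else vp
    } else {
      mu <- mn
      uu <- un / sqrt(sum(un^2))
      vv <- vn / sqrt(sum(vn^2))
    }
    W0[, i] <- sqrt(d[[i]] * mu) * uu
    H0[i, ] <- sqrt(d[[i]] * mu) * vv
  }
  # zero-fix: zeros -> 1% of the mean positive entry, per factor
  fix <- function(M) {
    pos <- M > 0
    if (!all(pos)) {
      repl <- if (any(pos)) 0.01 * mean(M[pos]) else .Machine$double.eps
      M[!pos] <- repl
    }
    M
  }
  new_nmf_init(fix(W0), fix(H0), method = "nndsvd")
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distances: memberships
#' `w_kj = d_kj^{-2/(f-1)} / sum_l d_lj^{-2/(f-1)}` and centroids the
#' `w^f`-weighted means, alternated from random initial memberships until
#' the largest membership change drops below `tol` or `max_iter` sweeps.
#' A point coincident with a centroid receives the indicator membership
#' of its nearest centroid (standard singularity handling).
#'
#' @param points n x d numeric matrix, one data point per row.
#' @param c number of clusters, `c <= n`.
#' @param fuzzifier fuzziness exponent, > 1 (default 2).
#' @param tol stopping tolerance on the max absolute membership change.
#' @param max_iter maximum number of update sweeps.
#' @param seed integer seed for the random initial memberships.
#' @return A list of class `fcm_result`: `centroids` (c x d),
#'   `memberships` (c x n, columns sum to 1), `objective_trace`
#'   (non-increasing), `n_iter`.
#' @export
fcm_cluster <- function(points, c, fuzzifier = 2, tol = 1e-5,
                        max_iter = 300L, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (c > n) stop("more clusters than points", call. = FALSE)
  if (fuzzifier <= 1) stop("fuzzifier must exceed 1", call. = FALSE)
  with_seed(seed, {
    U <- matrix(stats::runif(c * n), c, n)
    U <- sweep(U, 2L, colSums(U), "/")
    trace <- numeric(0)
    iter <- 0L
    expo <- 2 / (fuzzifier - 1)
    pts2 <- rowSums(points^2)
    repeat {
      iter <- iter + 1L
      Um <- U^fuzzifier
      V <- (Um %*% points) / rowSums(Um)                  # c x d centroids
      # squared Euclidean distances, c x n
      D2 <- outer(rowSums(V^2), pts2, "+") - 2 * V %*% t(points)
      D2 <- pmax(D2, 0)
      Unew <- D2^(-1 / (fuzzifier - 1))                    # = d^{-2/(f-1)}
      sing <- !is.finite(Unew)
      if (any(sing)) { # point on a centroid: indicator membership
        cols <- unique(which(sing, arr.ind = TRUE)[, 2L])
        for (j in cols) {
          Unew[, j] <- 0
          Unew[which.min(D2[, j]), j] <- 1
        }
      }
      Unew <- sweep(Unew, 2L, colSums(Unew), "/")
      trace <- c(trace, sum(Unew^fuzzifier * D2))
      delta <- max(abs(Unew - U))
      U <- Unew
      if (delta < tol || iter >= max_iter) break
    }
    structure(list(centroids = V, memberships = U,
                   objective_trace = trace, n_iter = iter),
              class = "fcm_result")
  })
}

#' Fuzzy c-means NMF initialization
#'
#' Clusters the voxel columns of `X` with [fcm_cluster()] (`c = r`);
#' cluster centroids become the columns of `W0` and the membership rows
#' become `H0`. Non-deterministic: wrap in [run_with_restarts()] for
#' reproducible best-of-k results.
#'
#' @inheritParams spa_select_columns
#' @param seed integer seed passed to [fcm_cluster()].
#' @param ... further arguments (`fuzzifier`, `tol`, `max_iter`) for
#'   [fcm_cluster()].
#' @return An `nmf_init` with `method = "fcm"`.
#' @export
init_fcm <- function(X, r, seed = NULL, ...) {
  X <- fm_data(X)
  res <- fcm_cluster(t(X), c = r, seed = seed, ...)
  new_nmf_init(t(res$centroids), res$memberships, method = "fcm",
               seed = seed, fcm = res)
}
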
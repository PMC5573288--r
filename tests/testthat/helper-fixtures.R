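# deterministic random non-negative matrix
rand_nonneg <- function(m, n, seed) {
  withr::with_seed(seed, matrix(runif(m * n), m, n))
}

# random exactly factorizable instance X = W H*
rand_factorizable <- function(m, n, r, seed) {
  withr::with_seed(seed, {
    W <- matrix(runif(m * r), m, r)
    H <- matrix(runif(r * n), r, n)
    list(W = W, H = H, X = W %*% H)
  })
}

# small phantom for unit tests (fast)
small_phantom <- function(seed = 1, ...) {
  suppressMessages(make_phantom(grid_shape = c(24L, 24L), seed = seed, ...))
}

# deviation of W from the column space of X
colspace_deviation <- function(X, W) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  sqrt(sum((W - Q %*% crossprod(Q, W))^2))
}

# brute-force one-sided signed-rank p-value over all 2^n sign patterns
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% rk)
  mean(W_all >= W_obs - 1e-12)
}
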
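#' Solver control parameters
#'
#' Common stopping contract for all NMF solvers: iterate until the
#' relative change of the unsquared Frobenius residual `||X - WH||_F`
#' between successive outer iterations falls below `tol`, or `max_iter`
#' outer iterations are reached. The defaults (`tol = 1e-5`,
#' `max_iter = 10000`, `n_restarts = 30`) are the study settings used
#' throughout the package.
#'
#' @param tol relative-residual-change convergence tolerance.
#' @param max_iter maximum number of outer iterations.
#' @param n_restarts restarts for non-deterministic initializers
#'   ([run_with_restarts()]).
#' @param ahals_alpha acceleration parameter bounding the number of inner
#'   HALS passes (`1 + floor(alpha * flop_ratio)`).
#' @param ahals_inner_eps early-exit threshold for inner HALS passes
#'   (stop when a pass changes the factor by less than this fraction of
#'   the first pass's change).
#' @param gd_delta0 initial trust-region radius of the Gauss-Newton solver.
#' @param gd_cg_maxit cap on conjugate-gradient iterations per
#'   trust-region subproblem.
#' @param pg_sigma,pg_beta Armijo sufficient-decrease parameter and
#'   backtracking ratio of the projected-gradient subproblem solver.
#' @param pg_subprob_tol initial subproblem tolerance as a fraction of the
#'   initial projected-gradient norm (shrinks by 0.1 whenever a
#'   subproblem converges immediately).
#' @param pg_subprob_maxit cap on projected-gradient steps per subproblem.
#' @return A list of class `nmf_control`.
#' @export
nmf_control <- function(tol = 1e-5, max_iter = 10000L, n_restarts = 30L,
                        ahals_alpha = 0.5, ahals_inner_eps = 0.01,
                        gd_delta0 = 1.0, gd_cg_maxit = 100L,
                        pg_sigma = 0.01, pg_beta = 0.1,
                        pg_subprob_tol = 1e-3, pg_subprob_maxit = 1000L) {
  stopifnot(tol > 0, max_iter >= 1L, n_restarts >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 ahals_alpha = ahals_alpha, ahals_inner_eps = ahals_inner_eps,
                 gd_delta0 = gd_delta0, gd_cg_maxit = as.integer(gd_cg_maxit),
                 pg_sigma = pg_sigma, pg_beta = pg_beta,
                 pg_subprob_tol = pg_subprob_tol,
                 pg_subprob_maxit = as.integer(pg_subprob_maxit)),
            class = "nmf_control")
}

#' Frobenius residual of a factorization
#'
#' `||X - W H||_F`, the residual tracked by every solver trace and used
#' for best-restart selection. (The optimization objective is its square
#' halved; both orderings agree.)
#'
#' @param X data matrix or [feature_matrix()].
#' @param W,H factor matrices.
#' @return A non-negative scalar.
#' @export
nmf_residual <- function(X, W, H) {
  X <- fm_data(X)
  W <- as.matrix(W); H <- as.matrix(H)
  if (nrow(W) != nrow(X) || ncol(H) != ncol(X) || ncol(W) != nrow(H)) {
    stop("shape mismatch between X, W and H", call. = FALSE)
  }
  fnorm(X - W %*% H)
}

new_nmf_fit <- function(W, H, residual_trace, converged, init_method,
                        seed = NULL, A = NULL, solver, ...) {
  structure(list(W = W, H = H, A = A,
                 residual_trace = residual_trace,
                 n_iter = length(residual_trace) - 1L,
                 converged = converged,
                 solver = solver, init_method = init_method, seed = seed, ...),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "<nmf_fit> solver = %s, init = %s, rank = %d\n  %d iterations, converged = %s, ||X - WH||_F = %.6g\n",
    x$solver, x$init_method, ncol(x$W), x$n_iter, x$converged,
    x$residual_trace[[length(x$residual_trace)]]))
  invisible(x)
}

# one cyclic pass block of exact HALS coordinate updates for H given
# precomputed WtW and WtX; `ratio` bounds the accelerated inner passes
hals_update <- function(H, WtW, WtX, alpha, inner_eps, ratio) {
  r <- nrow(H)
  max_pass <- 1L + floor(alpha * ratio)
  delta0 <- NA_real_
  for (pass in seq_len(max_pass)) {
    H_in <- H
    for (k in seq_len(r)) {
      hk <- H[k, ] + (WtX[k, ] - WtW[k, ] %*% H) / WtW[k, k]
      H[k, ] <- pmax(1e-16, hk)
    }
    change <- fnorm(H - H_in)
    if (pass == 1L) {
      delta0 <- change
      if (delta0 == 0) break
    } else if (change <= inner_eps * delta0) {
      break
    }
  }
  H
}

# reset degenerate (numerically zero) columns of W / rows of H
reset_degenerate <- function(M, margin, scale) {
  sums <- if (margin == 2L) colSums(M) else rowSums(M)
  bad <- which(sums < 1e-300)
  if (length(bad)) {
    warning("degenerate HALS block reset to small random values", call. = FALSE)
    for (b in bad) {
      if (margin == 2L) M[, b] <- stats::runif(nrow(M)) * scale
      else M[b, ] <- stats::runif(ncol(M)) * scale
    }
  }
  M
}

#' Accelerated HALS NMF
#'
#' Alternating exact rank-one (coordinate) block updates: with `W` fixed,
#' each row of `H` is updated in closed form
#' `H[k, ] <- max(eps, H[k, ] + (W[, k]'X - W[, k]'WH) / ||W[, k]||^2)`,
#' and symmetrically for the columns of `W`. The acceleration repeats the
#' cheap inner passes several times per outer iteration (the precomputed
#' Gram matrices dominate the cost), bounded by
#' `1 + floor(alpha * flop_ratio)` with an early exit once a pass moves
#' the factor by less than 1% of the first pass.
#'
#' @param X data matrix or [feature_matrix()].
#' @param init an `nmf_init` (e.g. from [init_spa()]).
#' @param control an [nmf_control()].
#' @return An `nmf_fit`: `W`, `H`, `residual_trace` (starting at the
#'   initial residual, non-increasing), `n_iter`, `converged`.
#' @export
nmf_ahals <- function(X, init, control = nmf_control()) {
  X <- fm_data(X)
  W <- as.matrix(init$W0); H <- as.matrix(init$H0)
  m <- nrow(X); n <- ncol(X); r <- ncol(W)
  stopifnot(nrow(W) == m, ncol(H) == n, nrow(H) == r)
  ratio_H <- (m * n + n * r) / (n * r + r * r)
  ratio_W <- (m * n + m * r) / (m * r + r * r)
  res <- nmf_residual(X, W, H)
  trace <- res
  converged <- FALSE
  scaleX <- mean(X)
  for (t in seq_len(control$max_iter)) {
    W <- reset_degenerate(W, 2L, scaleX)
    H <- hals_update(H, crossprod(W), crossprod(W, X),
                     control$ahals_alpha, control$ahals_inner_eps, ratio_H)
    H <- reset_degenerate(H, 1L, scaleX)
    Wt <- hals_update(t(W), tcrossprod(H), tcrossprod(H, X),
                      control$ahals_alpha, control$ahals_inner_eps, ratio_W)
    W <- t(Wt)
    res_new <- nmf_residual(X, W, H)
    trace <- c(trace, res_new)
    if (rel_change(res_new, res) < control$tol) { converged <- TRUE; res <- res_new; break }
    res <- res_new
  }
  new_nmf_fit(W, H, trace, converged, init$method, init$seed, solver = "ahals")
}

# ---- Gauss-Newton trust-region solver (squared-variable parametrization) ----

# Steihaug-Toint truncated CG for the Gauss-Newton model
#   m(p) = f + g'p + 1/2 p'(J'J)p   subject to ||p|| <= Delta
# Hv() applies J'J to a step; g is the gradient (list of U- and V-blocks).
steihaug_cg <- function(g, Hv, Delta, cg_tol, maxit) {
  p <- lapply(g, function(x) x * 0)
  rvec <- lapply(g, function(x) -x)
  d <- rvec
  rr <- sum(vapply(rvec, function(x) sum(x^2), 0))
  rr0 <- sqrt(rr)
  if (rr0 == 0) return(list(p = p, boundary = FALSE))
  dot <- function(a, b) sum(mapply(function(x, y) sum(x * y), a, b))
  axpy <- function(a, x, y) mapply(function(xi, yi) yi + a * xi, x, y, SIMPLIFY = FALSE)
  nrm <- function(a) sqrt(sum(vapply(a, function(x) sum(x^2), 0)))
  boundary <- FALSE
  for (i in seq_len(maxit)) {
    Hd <- Hv(d)
    dHd <- dot(d, Hd)
    if (dHd <= 0) { # zero-curvature direction: go to the boundary
      tau <- boundary_tau(p, d, Delta)
      p <- axpy(tau, d, p)
      boundary <- TRUE
      break
    }
    alpha <- rr / dHd
    p_try <- axpy(alpha, d, p)
    if (nrm(p_try) >= Delta) {
      tau <- boundary_tau(p, d, Delta)
      p <- axpy(tau, d, p)
      boundary <- TRUE
      break
    }
    p <- p_try
    rvec <- axpy(-alpha, Hd, rvec)
    rr_new <- sum(vapply(rvec, function(x) sum(x^2), 0))
    if (sqrt(rr_new) <= cg_tol * rr0) { rr <- rr_new; break }
    beta <- rr_new / rr
    d <- mapply(function(ri, di) ri + beta * di, rvec, d, SIMPLIFY = FALSE)
    rr <- rr_new
  }
  list(p = p, boundary = boundary)
}

# positive tau with ||p + tau d|| = Delta
boundary_tau <- function(p, d, Delta) {
  dd <- sum(vapply(d, function(x) sum(x^2), 0))
  pd <- sum(mapply(function(x, y) sum(x * y), p, d))
  pp <- sum(vapply(p, function(x) sum(x^2), 0))
  disc <- pd^2 + dd * (Delta^2 - pp)
  (-pd + sqrt(max(disc, 0))) / dd
}

#' Gauss-Newton trust-region NMF (squared variables)
#'
#' Removes the non-negativity constraints by the change of variables
#' `W = U*U`, `H = V*V` (element-wise squares) and minimizes the
#' resulting unconstrained nonlinear least-squares objective
#' `1/2 ||X - (U*U)(V*V)||_F^2` by Gauss-Newton steps globalized with a
#' trust region. The linearized subproblem is solved by truncated
#' conjugate gradients using Jacobian-vector products only (the Jacobian
#' is never formed). Entries initialized at zero have zero gradient and
#' stay zero, so strictly positive initializations (e.g. NNDSVD after its
#' zero fix) are recommended.
#'
#' A rejected trust-region step shrinks the radius and retries within the
#' same outer iteration, so the residual trace decreases at every
#' recorded step; if the radius collapses below 1e-14 the solver declares
#' convergence to tolerance.
#'
#' @inheritParams nmf_ahals
#' @return An `nmf_fit`.
#' @export
nmf_gd <- function(X, init, control = nmf_control()) {
  X <- fm_data(X)
  U <- sqrt(as.matrix(init$W0)); V <- sqrt(as.matrix(init$H0))
  res <- nmf_residual(X, U^2, V^2)
  trace <- res
  converged <- FALSE
  Delta <- control$gd_delta0
  for (t in seq_len(control$max_iter)) {
    W <- U^2; H <- V^2
    R <- W %*% H - X                       # residual matrix of 1/2||.||^2
    f_old <- 0.5 * sum(R^2)
    gU <- 2 * U * (R %*% t(H))
    gV <- 2 * V * crossprod(W, R)
    g <- list(U = gU, V = gV)
    gnorm <- sqrt(sum(gU^2) + sum(gV^2))
    if (!is.finite(f_old)) stop("non-finite residual in Gauss-Newton solver", call. = FALSE)
    if (gnorm == 0) { converged <- TRUE; break }
    Hv <- function(p) {
      Y <- (2 * U * p$U) %*% H + W %*% (2 * V * p$V)   # J p
      list(U = 2 * U * (Y %*% t(H)), V = 2 * V * crossprod(W, Y)) # J'(Jp)
    }
    cg_tol <- min(0.1, sqrt(gnorm))
    accepted <- FALSE
    collapsed <- FALSE
    while (!accepted) {
      sol <- steihaug_cg(g, Hv, Delta, cg_tol, control$gd_cg_maxit)
      p <- sol$p
      U_new <- U + p$U; V_new <- V + p$V
      f_new <- 0.5 * sum((X - (U_new^2) %*% (V_new^2))^2)
      Hp <- Hv(p)
      pred <- -(sum(g$U * p$U) + sum(g$V * p$V) +
                  0.5 * (sum(p$U * Hp$U) + sum(p$V * Hp$V)))
      rho <- if (pred > 0) (f_old - f_new) / pred else -Inf
      if (is.finite(f_new) && rho > 0 && f_new <= f_old) {
        accepted <- TRUE
        U <- U_new; V <- V_new
        if (rho < 0.25) Delta <- Delta * 0.25
        else if (rho > 0.75 && sol$boundary) Delta <- Delta * 2
      } else {
        Delta <- Delta * 0.25
        if (Delta < 1e-14) { collapsed <- TRUE; break }
      }
    }
    if (collapsed) { converged <- TRUE; break } # trust region exhausted
    res_new <- nmf_residual(X, U^2, V^2)
    trace <- c(trace, res_new)
    if (rel_change(res_new, res) < control$tol) { converged <- TRUE; res <- res_new; break }
    res <- res_new
  }
  new_nmf_fit(U^2, V^2, trace, converged, init$method, init$seed, solver = "gd")
}

# ---- Projected-gradient solver (alternating NNLS subproblems) ----

# Solve min_{H >= 0} 1/2||V - W H||_F^2 by projected gradient with the
# Armijo rule along the projection arc; returns H, its projected-gradient
# norm and the number of iterations used.
pg_subproblem <- function(V, W, H, tol, maxit, sigma, beta) {
  WtV <- crossprod(W, V)
  WtW <- crossprod(W)
  alpha <- 1
  used <- 0L
  for (it in seq_len(maxit)) {
    used <- it
    grad <- WtW %*% H - WtV
    pg <- fnorm(grad[grad < 0 | H > 0])
    if (pg < tol) break
    # Armijo along the projection arc with adaptive initial step
    decr <- FALSE
    H_new <- H
    for (inner in seq_len(30L)) {
      Hn <- pmax(H - alpha * grad, 0)
      d <- Hn - H
      gd <- sum(grad * d)
      dQd <- sum((WtW %*% d) * d)
      suff <- (1 - sigma) * gd + 0.5 * dQd <= 0
      if (inner == 1L) decr <- !suff
      if (decr) {        # step too long: shrink until sufficient decrease
        if (suff) { H_new <- Hn; break }
        alpha <- alpha * beta
      } else {           # step acceptable: grow while it stays acceptable
        if (!suff || identical(Hn, H_new)) break
        H_new <- Hn
        alpha <- alpha / beta
      }
    }
    H <- H_new
  }
  list(H = H, pg = pg, iter = used)
}

#' Projected-gradient NMF
#'
#' Alternates the two convex non-negative least-squares subproblems (for
#' `H` with `W` fixed, and for `W` with `H` fixed), each solved by
#' projected gradient descent: step along the negative gradient, project
#' negative entries back to zero, with the step size chosen by the Armijo
#' rule along the projection arc. Subproblem tolerances start at
#' `pg_subprob_tol * ||grad f(W0, H0)||_F` and shrink by a factor 10
#' whenever a subproblem converges immediately.
#'
#' @inheritParams nmf_ahals
#' @return An `nmf_fit`.
#' @export
nmf_pg <- function(X, init, control = nmf_control()) {
  X <- fm_data(X)
  W <- as.matrix(init$W0); H <- as.matrix(init$H0)
  gradW <- W %*% tcrossprod(H) - X %*% t(H)
  gradH <- crossprod(W) %*% H - crossprod(W, X)
  initgrad <- sqrt(sum(gradW^2) + sum(gradH^2))
  tolW <- max(control$pg_subprob_tol, control$tol) * initgrad
  tolH <- tolW
  res <- nmf_residual(X, W, H)
  trace <- res
  converged <- FALSE
  for (t in seq_len(control$max_iter)) {
    sw <- pg_subproblem(t(X), t(H), t(W), tolW, control$pg_subprob_maxit,
                        control$pg_sigma, control$pg_beta)
    W <- t(sw$H)
    if (sw$iter == 1L) tolW <- 0.1 * tolW
    sh <- pg_subproblem(X, W, H, tolH, control$pg_subprob_maxit,
                        control$pg_sigma, control$pg_beta)
    H <- sh$H
    if (sh$iter == 1L) tolH <- 0.1 * tolH
    res_new <- nmf_residual(X, W, H)
    if (!is.finite(res_new)) stop("non-finite residual in projected-gradient solver", call. = FALSE)
    trace <- c(trace, res_new)
    if (rel_change(res_new, res) < control$tol) { converged <- TRUE; res <- res_new; break }
    res <- res_new
  }
  new_nmf_fit(W, H, trace, converged, init$method, init$seed, solver = "pg")
}

#' Convex NMF by multiplicative updates
#'
#' Convex NMF constrains the sources to the column space of the data,
#' `W = X A` with `A >= 0`, so each source is a weighted sum of observed
#' voxels, and factorizes `X ~ X A H`. `A` and `H` are updated by the
#' standard multiplicative square-root rules derived from the splitting
#' of `K = X'X` into positive and negative parts; for non-negative input
#' (guaranteed by the [feature_matrix()] contract) the negative part
#' vanishes and the updates reduce to
#' `H <- H * sqrt(W'X / (W'W H))` and
#' `A <- A * sqrt(X'(X H') / (X'(W (H H'))))` with `W = X A`, computed
#' without forming the n x n Gram matrix. Denominators are floored at
#' 1e-16.
#'
#' @inheritParams nmf_ahals
#' @param A0 non-negative n x r starting weight matrix (see
#'   [convex_weights_init()]).
#' @param H0 non-negative r x n starting abundances.
#' @return An `nmf_fit` whose `A` element holds the final weights and
#'   whose `W = X A`.
#' @export
nmf_convex <- function(X, A0, H0, control = nmf_control(),
                       init_method = "unknown", seed = NULL) {
  X <- fm_data(X)
  A <- as.matrix(A0); H <- as.matrix(H0)
  stopifnot(nrow(A) == ncol(X), nrow(H) == ncol(A), ncol(H) == ncol(X))
  eps <- 1e-16
  W <- X %*% A
  res <- nmf_residual(X, W, H)
  trace <- res
  converged <- FALSE
  for (t in seq_len(control$max_iter)) {
    # H update: K+ = K = X'X (X >= 0), K- = 0
    num_H <- crossprod(W, X)               # A'K
    den_H <- pmax(crossprod(W) %*% H, eps) # A'K A H
    H <- H * sqrt(num_H / den_H)
    # A update
    num_A <- crossprod(X, X %*% t(H))          # K H'
    den_A <- pmax(crossprod(X, W %*% tcrossprod(H)), eps) # K A H H'
    A <- A * sqrt(num_A / den_A)
    W <- X %*% A
    if (any(!is.finite(A)) || any(!is.finite(H))) {
      stop("non-finite multiplicative update in convex NMF", call. = FALSE)
    }
    res_new <- nmf_residual(X, W, H)
    trace <- c(trace, res_new)
    if (rel_change(res_new, res) < control$tol) { converged <- TRUE; res <- res_new; break }
    res <- res_new
  }
  new_nmf_fit(W, H, trace, converged, init_method, seed, A = A, solver = "convex")
}

# dispatch a single solver run from an nmf_init
solve_with_init <- function(X, init, solver, control) {
  switch(solver,
         ahals = nmf_ahals(X, init, control),
         gd = nmf_gd(X, init, control),
         pg = nmf_pg(X, init, control),
         convex = {
           A0 <- if (!is.null(init$A0)) init$A0 else convex_weights_init(init$H0)
           nmf_convex(X, A0, init$H0, control,
                      init_method = init$method, seed = init$seed)
         },
         stop("unknown solver: ", solver, call. = FALSE))
}

make_init <- function(X, r, method, seed = NULL) {
  switch(method,
         spa = init_spa(X, r),
         nndsvd = init_nndsvd(X, r),
         fcm = init_fcm(X, r, seed = seed),
         random = init_random(nrow(fm_data(X)), ncol(fm_data(X)), r, seed = seed),
         stop("unknown initialization method: ", method, call. = FALSE))
}

#' Best-of-k restarts for non-deterministic initializers
#'
#' Runs `init -> solve` with seeds `base_seed, base_seed + 1, ...,
#' base_seed + n_restarts - 1` and returns the run with the lowest final
#' Frobenius residual (ties broken by the smallest seed), making random
#' and fuzzy-c-means initialization reproducible given `base_seed`. The
#' fuzzy clustering is re-run with a fresh seed for every restart.
#'
#' @param X data matrix or [feature_matrix()].
#' @param r factorization rank.
#' @param solver one of `"ahals"`, `"gd"`, `"pg"`, `"convex"`.
#' @param init_method `"random"` or `"fcm"`.
#' @param control an [nmf_control()]; `control$n_restarts` sets the
#'   number of runs.
#' @param base_seed integer seed of the first restart.
#' @return The winning `nmf_fit`, with an extra element
#'   `restart_residuals` (named by seed) recording every run's final
#'   residual.
#' @export
run_with_restarts <- function(X, r, solver, init_method, control = nmf_control(),
                              base_seed = 1L) {
  stopifnot(init_method %in% c("random", "fcm"))
  seeds <- base_seed + seq_len(control$n_restarts) - 1L
  best <- NULL
  best_res <- Inf
  all_res <- stats::setNames(rep(NA_real_, length(seeds)), seeds)
  for (s in seeds) {
    fit <- tryCatch({
      init <- make_init(X, r, init_method, seed = s)
      solve_with_init(X, init, solver, control)
    }, error = function(e) {
      warning(sprintf("restart with seed %d failed: %s", s, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(fit)) next
    final <- fit$residual_trace[[length(fit$residual_trace)]]
    all_res[[as.character(s)]] <- final
    if (final < best_res) { best_res <- final; best <- fit }
  }
  if (is.null(best)) stop("all restarts failed", call. = FALSE)
  best$restart_residuals <- all_res
  best
}

#' Fit an NMF model
#'
#' High-level entry point tying an initializer to a solver. Deterministic
#' initializers (`"spa"`, `"nndsvd"`) run the solver once; random and
#' fuzzy-c-means initializers are repeated `control$n_restarts` times and
#' the lowest-residual run is returned (see [run_with_restarts()]). The
#' hierarchical solver is available as `solver = "hnmf"` (see [hnmf()]).
#'
#' @param X data matrix or [feature_matrix()].
#' @param r factorization rank.
#' @param init `"spa"`, `"nndsvd"`, `"fcm"` or `"random"`.
#' @param solver `"ahals"`, `"gd"`, `"pg"`, `"convex"` or `"hnmf"`.
#' @param control an [nmf_control()].
#' @param seed base seed for non-deterministic initializers.
#' @param rank_split level-2 rank split for `solver = "hnmf"`.
#' @return An `nmf_fit` (or `hnmf_fit` for the hierarchical solver).
#' @export
#' @examples
#' X <- matrix(runif(60), 6, 10)
#' fit <- nmf(X, 2, init = "spa", solver = "ahals")
#' fit$converged
nmf <- function(X, r, init = c("spa", "nndsvd", "fcm", "random"),
                solver = c("ahals", "gd", "pg", "convex", "hnmf"),
                control = nmf_control(), seed = 1L,
                rank_split = ceiling(r / 2)) {
  init <- match.arg(init)
  solver <- match.arg(solver)
  if (solver == "hnmf") {
    return(hnmf(X, r, r1 = rank_split, init_method = init,
                control = control, seed = seed))
  }
  if (init %in% c("spa", "nndsvd")) {
    solve_with_init(X, make_init(X, r, init), solver, control)
  } else {
    run_with_restarts(X, r, solver, init, control, base_seed = seed)
  }
}
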
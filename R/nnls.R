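# Multi-right-hand-side non-negative least squares.
#
# All abundance fits in the package (SPA H0, hierarchical recombination,
# oracle checks against the projected-gradient subproblem) reduce to
#   min_{h >= 0} || b_j - W h ||_2   for thousands of columns b_j sharing W.
# The grouped active-set scheme of Van Benthem & Keenan (fast combinatorial
# NNLS) solves all columns simultaneously: columns with identical passive
# sets share one normal-equations solve, and the Lawson-Hanson inner/outer
# loops guarantee an exact KKT point per column.

# Solve the passive-set-restricted least squares for every column.
# WtW: r x r, WtB: r x k, P: r x k logical passive sets (NULL = all passive).
cssls <- function(WtW, WtB, P = NULL) {
  r <- nrow(WtB)
  K <- matrix(0, r, ncol(WtB))
  if (is.null(P)) {
    K[] <- solve(WtW, WtB)
    return(K)
  }
  codes <- apply(P, 2L, function(p) paste(as.integer(p), collapse = ""))
  for (code in unique(codes)) {
    cols <- which(codes == code)
    pass <- P[, cols[[1L]]]
    if (!any(pass)) next
    sub <- WtW[pass, pass, drop = FALSE]
    sol <- tryCatch(solve(sub, WtB[pass, cols, drop = FALSE]),
                    error = function(e) {
                      # numerically singular passive block: tiny ridge
                      ridge <- sum(diag(sub)) / nrow(sub) * 1e-12 + 1e-300
                      solve(sub + diag(ridge, nrow(sub)),
                            WtB[pass, cols, drop = FALSE])
                    })
    K[pass, cols] <- sol
  }
  K
}

# Fast combinatorial NNLS: returns the r x k matrix H >= 0 minimizing
# ||B - W H||_F column-wise. Exact active-set solution (KKT per column).
fcnnls <- function(W, B) {
  W <- as.matrix(W); B <- as.matrix(B)
  r <- ncol(W); k <- ncol(B)
  WtW <- crossprod(W)
  WtB <- crossprod(W, B)
  tol <- 10 * .Machine$double.eps * norm(W, "2")^2 * r

  K <- cssls(WtW, WtB)          # unconstrained start
  P <- K > 0
  K[!P] <- 0
  D <- K
  Fset <- which(colSums(P) < r) # columns not yet proven optimal
  iter <- 0L
  maxiter <- 30L * r

  while (length(Fset) > 0L) {
    K[, Fset] <- cssls(WtW, WtB[, Fset, drop = FALSE], P[, Fset, drop = FALSE])

    # infeasible columns: back-track along the segment D -> K (inner loop)
    Hset <- Fset[colSums(K[, Fset, drop = FALSE] < -tol) > 0L]
    while (length(Hset) > 0L && iter < maxiter) {
      iter <- iter + 1L
      for (j in Hset) {
        neg <- which(P[, j] & K[, j] < -tol)
        alpha <- D[neg, j] / (D[neg, j] - K[neg, j])
        a <- which.min(alpha)
        D[, j] <- D[, j] + alpha[a] * (K[, j] - D[, j])
        D[neg[a], j] <- 0
        P[neg[a], j] <- FALSE
      }
      K[, Hset] <- cssls(WtW, WtB[, Hset, drop = FALSE], P[, Hset, drop = FALSE])
      K[, Hset][!P[, Hset, drop = FALSE] & K[, Hset, drop = FALSE] < 0] <- 0
      Hset <- Fset[colSums(K[, Fset, drop = FALSE] < -tol) > 0L]
    }
    K[K < 0] <- 0

    # optimality: gradient of 1/2||b - Wh||^2 is WtW h - Wtb; at a KKT point
    # the (negated) gradient on the active set must be <= 0
    Wgrad <- WtB[, Fset, drop = FALSE] - WtW %*% K[, Fset, drop = FALSE]
    act <- !P[, Fset, drop = FALSE]
    viol <- Wgrad * act
    ok <- colSums(viol > tol) == 0L
    Jset <- Fset[ok]
    Fset <- Fset[!ok]
    if (length(Fset) > 0L) {
      viol <- viol[, !ok, drop = FALSE]
      for (idx in seq_along(Fset)) {
        j <- Fset[[idx]]
        i <- which.max(viol[, idx])
        P[i, j] <- TRUE
      }
      D[, Fset] <- K[, Fset]
    }
  }
  dimnames(K) <- NULL
  K
}

#' Non-negative least-squares abundances
#'
#' Given a source matrix `W` (m x r) and data `X` (m x n), returns the
#' r x n abundance matrix `H` whose column `j` minimizes
#' `||X[, j] - W h||_2` subject to `h >= 0`, each column solved to an
#' exact KKT point by a combinatorial active-set method. This is the fit
#' used to derive `H0` from SPA-selected sources and to recombine pooled
#' sources in hierarchical NMF.
#'
#' @param X a [feature_matrix()] or non-negative numeric matrix (m x n).
#' @param W non-negative m x r source matrix with no zero column.
#' @return An r x n non-negative matrix.
#' @export
#' @examples
#' X <- matrix(c(1, 0, 0, 1, 0.5, 0.5), nrow = 2)
#' nnls_abundances(X, diag(2))
nnls_abundances <- function(X, W) {
  X <- fm_data(X)
  W <- as.matrix(W)
  if (nrow(W) != nrow(X)) stop("W and X have incompatible row counts", call. = FALSE)
  if (any(colSums(abs(W)) == 0)) {
    stop("degenerate basis: W has a zero column", call. = FALSE)
  }
  fcnnls(W, X)
}
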
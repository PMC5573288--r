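#' Successive projection algorithm (SPA) column selection
#'
#' Greedy selection of `r` columns of a non-negative matrix `X` by
#' successive orthogonal projections. At each step the column of the
#' working matrix `S` with the largest squared l2 norm is selected; under
#' the near-separability assumptions (every source appears pure in at
#' least one column and abundances sum to at most one) the selected
#' columns are vertices of the convex hull of the data, i.e. pure-source
#' columns. After each selection `S` is projected onto the orthogonal
#' complement of the selected (projected) column, so subsequent picks are
#' maximally independent of the earlier ones.
#'
#' Ties in the argmax are broken by the smallest column index, making the
#' selection fully deterministic. Indices are 1-based, as everywhere in R.
#'
#' @param X a [feature_matrix()] or non-negative numeric matrix (m x n).
#' @param r number of columns to select; must satisfy `r <= min(m, n)`.
#' @param norm_floor relative floor for the maximal projected squared norm:
#'   selection aborts with a rank-deficiency error when the best remaining
#'   column has squared norm below `norm_floor * ||X||_F^2` (default 1e-12),
#'   meaning `X` has numerical rank below `r`.
#' @return An object of class `spa_selection`: list with `indices`
#'   (selected column indices, in selection order), `vectors` (the
#'   corresponding original, unprojected columns of `X`, m x r), and
#'   `projected_norms` (the maximal squared projected norm at each step,
#'   non-increasing).
#' @export
#' @examples
#' X <- matrix(c(1, 0, 0, 1, 0.5, 0.5), nrow = 2)
#' spa_select_columns(X, 2)$indices
spa_select_columns <- function(X, r, norm_floor = 1e-12) {
  X <- fm_data(X)
  m <- nrow(X); n <- ncol(X)
  r <- as.integer(r)
  if (r < 1L) stop("r must be a positive integer", call. = FALSE)
  if (r > min(m, n)) {
    stop(sprintf("r = %d exceeds min(m, n) = %d", r, min(m, n)), call. = FALSE)
  }
  if (any(X < 0)) stop("X must be non-negative", call. = FALSE)
  normX2 <- sum(X^2)
  S <- X
  indices <- integer(r)
  norms <- numeric(r)
  for (j in seq_len(r)) {
    cn <- colSums(S^2)
    i_star <- which.max(cn) # first max -> smallest-index tie break
    if (cn[[i_star]] < norm_floor * normX2) {
      stop(sprintf(
        "rank deficiency at SPA step %d: maximal projected squared norm %.3e below floor",
        j, cn[[i_star]]), call. = FALSE)
    }
    indices[[j]] <- i_star
    norms[[j]] <- cn[[i_star]]
    s <- S[, i_star]
    S <- S - s %*% (crossprod(s, S) / sum(s^2))
  }
  structure(list(indices = indices,
                 vectors = X[, indices, drop = FALSE],
                 projected_norms = norms),
            class = "spa_selection")
}

#' @export
print.spa_selection <- function(x, ...) {
  cat("<spa_selection>\n  indices:", x$indices,
      "\n  projected norms^2:", signif(x$projected_norms, 4), "\n")
  invisible(x)
}

#' SPA initialization for NMF
#'
#' Builds a full `(W0, H0)` initialization from SPA: the columns of `W0`
#' are the SPA-selected original columns of `X` (in selection order) and
#' `H0` is the exact non-negative least-squares abundance fit of `X` on
#' `W0` (see [nnls_abundances()]). The construction is fully
#' deterministic.
#'
#' @inheritParams spa_select_columns
#' @return An object of class `nmf_init`: list with `W0` (m x r), `H0`
#'   (r x n), `A0 = NULL` (see [convex_weights_init()]), `method = "spa"`,
#'   `seed = NULL`, and the underlying `selection`.
#' @export
init_spa <- function(X, r) {
  X <- fm_data(X)
  sel <- spa_select_columns(X, r)
  W0 <- sel$vectors
  H0 <- nnls_abundances(X, W0)
  new_nmf_init(W0, H0, method = "spa", selection = sel)
}

new_nmf_init <- function(W0, H0, A0 = NULL, method, seed = NULL, ...) {
  structure(list(W0 = W0, H0 = H0, A0 = A0, method = method, seed = seed, ...),
            class = "nmf_init")
}

#' @export
print.nmf_init <- function(x, ...) {
  cat(sprintf("<nmf_init> method = %s, W0: %d x %d, H0: %d x %d%s\n",
              x$method, nrow(x$W0), ncol(x$W0), nrow(x$H0), ncol(x$H0),
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' Convex-NMF weight initialization from an abundance matrix
#'
#' Convex NMF writes the sources as weighted sums of data columns,
#' `W = X A`, and needs a non-negative starting value for the n x r
#' weight matrix `A`. Solving `X ~ X A H0` for `A` in the least-squares
#' sense gives `A ~ H0' (H0 H0')^{-1}`; non-negativity is then restored
#' as `A0 = A^+ + 0.2 * E * <A^+>`, where `A^+` is the element-wise
#' positive part, `E` the all-ones matrix, and `<A^+>` the mean absolute
#' value of the nonzero entries of `A^+`. The same construction is
#' applied to the `H0` of every initialization method.
#'
#' @param H0 non-negative r x n abundance matrix of full row rank.
#' @return An n x r non-negative matrix `A0`.
#' @export
#' @examples
#' convex_weights_init(diag(2)) # = [[1.2, 0.2], [0.2, 1.2]]
convex_weights_init <- function(H0) {
  H0 <- as.matrix(H0)
  G <- tcrossprod(H0) # H0 H0', r x r
  A <- tryCatch(t(solve(G, H0)), error = function(e) {
    # numerically singular Gram matrix: regularize with a tiny ridge
    ridge <- 1e-10 * sum(diag(G)) / nrow(G)
    if (ridge == 0) {
      stop("H0 H0' is singular and has zero trace; cannot derive A0", call. = FALSE)
    }
    t(solve(G + diag(ridge, nrow(G)), H0))
  })
  Apos <- pmax(A, 0)
  nz <- Apos > 0
  if (!any(nz)) stop("positive part of A is identically zero", call. = FALSE)
  offset <- 0.2 * sum(Apos) / sum(nz)
  Apos + offset
}
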
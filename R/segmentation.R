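#' Segment voxels from an abundance matrix
#'
#' Turns the r x n abundance matrix of a factorization into a hard tissue
#' segmentation by k-means (`k = r`) on the abundance columns, with the
#' cluster centroids initialized at the one-hot vectors `e_1, ..., e_r` so
#' that cluster `k` inherits the identity of source `k`. Columns are
#' optionally normalized to unit sum first, which makes mixed voxels
#' commensurate with the one-hot centroids. Lloyd iterations run until
#' the maximal centroid shift falls below 1e-6 or 300 iterations; a
#' cluster that empties keeps its previous centroid.
#'
#' All-zero abundance columns cannot be assigned and receive label 0.
#'
#' @param H non-negative r x n abundance matrix, `r >= 2`.
#' @param normalize normalize each column to unit sum before clustering
#'   (default `TRUE`).
#' @param grid_shape optional grid layout carried to the result.
#' @param class_of_source optional character vector mapping source index
#'   to a tissue name in `normal`, `edema`, `active`, `necrosis`, `other`.
#' @return An object of class `label_map`: list with `labels` (integer
#'   n-vector in `0:r`), `grid_shape`, `class_of_source`, `centroids`.
#' @export
#' @examples
#' H <- matrix(c(0.9, 0.1, 0.1, 0.9), nrow = 2)
#' segment_abundances(H)$labels # 1, 2
segment_abundances <- function(H, normalize = TRUE, grid_shape = NULL,
                               class_of_source = NULL) {
  H <- as.matrix(H)
  r <- nrow(H); n <- ncol(H)
  if (r < 2L) stop("segmentation needs at least 2 sources", call. = FALSE)
  zero <- colSums(H) == 0
  if (any(zero)) {
    message(sprintf("%d all-zero abundance column(s) labeled 0 (unassigned)", sum(zero)))
  }
  Hn <- H[, !zero, drop = FALSE]
  if (normalize) Hn <- sweep(Hn, 2L, colSums(Hn), "/")
  centers <- diag(r)            # one-hot centroid per source
  pts2 <- colSums(Hn^2)
  assign_lab <- NULL
  for (it in seq_len(300L)) {
    D2 <- outer(rowSums(centers^2), pts2, "+") - 2 * centers %*% Hn
    assign_lab <- max.col(t(-D2), ties.method = "first")
    new_centers <- centers
    for (k in seq_len(r)) {
      members <- assign_lab == k
      if (any(members)) new_centers[k, ] <- rowMeans(Hn[, members, drop = FALSE])
      # empty cluster: centroid retained
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < 1e-6) break
  }
  labels <- integer(n)
  labels[!zero] <- assign_lab
  structure(list(labels = labels, grid_shape = grid_shape,
                 class_of_source = class_of_source, centroids = centers),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map>", length(x$labels), "voxels; counts:\n")
  print(table(x$labels))
  invisible(x)
}

#' Match estimated sources to reference sources
#'
#' NMF returns its sources in arbitrary order; this resolves the
#' permutation by maximizing the summed cosine similarity between matched
#' columns, solved exactly as an assignment problem by dynamic
#' programming over reference subsets (cosine similarity is invariant to
#' the per-source scale ambiguity of NMF).
#'
#' @param W_est,W_ref m x r matrices with no zero columns.
#' @return An integer permutation `p` of `1:r` such that estimated source
#'   `p[k]` corresponds to reference source `k`
#'   (`W_est[, p]` aligns column-wise with `W_ref`).
#' @export
#' @examples
#' W <- matrix(runif(12), 4, 3)
#' match_sources(W[, c(2, 3, 1)], W) # c(3, 1, 2)
match_sources <- function(W_est, W_ref) {
  W_est <- as.matrix(W_est); W_ref <- as.matrix(W_ref)
  r <- ncol(W_ref)
  stopifnot(ncol(W_est) == r, nrow(W_est) == nrow(W_ref))
  ne <- sqrt(colSums(W_est^2)); nr <- sqrt(colSums(W_ref^2))
  if (any(ne == 0) || any(nr == 0)) stop("zero column in source matrix", call. = FALSE)
  C <- crossprod(W_est, W_ref) / outer(ne, nr) # C[i, j] = cos(est_i, ref_j)
  assignment_max(C)
}

# exact max-weight assignment by bitmask DP: rows of C assigned to columns.
# Returns p with p[j] = row matched to column j.
assignment_max <- function(C) {
  r <- nrow(C)
  nstates <- bitwShiftL(1L, r)
  best <- rep(-Inf, nstates)   # best[mask + 1]: columns 1..popcount(mask) done, rows in mask used
  choice <- matrix(0L, nstates, 1L)
  best[[1L]] <- 0
  pop <- integer(nstates)
  for (s in seq_len(nstates - 1L)) pop[[s + 1L]] <- pop[[bitwShiftR(s, 1L) + 1L]] + bitwAnd(s, 1L)
  from <- integer(nstates)
  for (s in 0:(nstates - 1L)) {
    if (!is.finite(best[[s + 1L]])) next
    j <- pop[[s + 1L]] + 1L      # next column to assign
    if (j > r) next
    for (i in seq_len(r)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(s, bit) > 0L) next
      s2 <- bitwOr(s, bit)
      val <- best[[s + 1L]] + C[i, j]
      if (val > best[[s2 + 1L]]) {
        best[[s2 + 1L]] <- val
        from[[s2 + 1L]] <- i
      }
    }
  }
  # backtrack
  p <- integer(r)
  s <- nstates - 1L
  for (j in rev(seq_len(r))) {
    i <- from[[s + 1L]]
    p[[j]] <- i
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L)))
  }
  p
}

#' Dice similarity coefficient
#'
#' `2 |A ∩ B| / (|A| + |B|)`: the overlap of two binary masks normalized
#' to their average size. Two empty masks agree perfectly on absence and
#' score 1; empty against non-empty scores 0.
#'
#' @param mask_a,mask_b logical vectors over a common voxel index set.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' dice_score(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)) # 2/3
dice_score <- function(mask_a, mask_b) {
  stopifnot(length(mask_a) == length(mask_b))
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0L) {
    message("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(mask_a & mask_b) / (a + b)
}

#' Nested tumor tissue-class masks
#'
#' The three standard nested evaluation classes for glioma segmentation:
#' active tumor; tumor core = active + necrosis; whole tumor = core +
#' edema.
#'
#' @param labels integer vector of per-voxel source labels (0 allowed for
#'   unassigned voxels, which belong to no class).
#' @param class_of_source character vector mapping source index to a
#'   tissue name among `normal`, `edema`, `active`, `necrosis`, `other`.
#' @return A named list of three logical masks: `active`, `core`, `whole`.
#' @export
tissue_class_masks <- function(labels, class_of_source) {
  present <- setdiff(unique(labels), 0L)
  if (any(present > length(class_of_source)) || any(present < 0L)) {
    stop("label present without a class mapping", call. = FALSE)
  }
  bad <- setdiff(class_of_source, c("normal", "edema", "active", "necrosis", "other"))
  if (length(bad)) stop("unknown tissue class: ", paste(bad, collapse = ", "), call. = FALSE)
  cls <- c("none", class_of_source)[labels + 1L] # label 0 -> none
  active <- cls == "active"
  core <- active | cls == "necrosis"
  whole <- core | cls == "edema"
  list(active = active, core = core, whole = whole)
}

#' Dice report over the nested tumor classes
#'
#' Compares two segmentations class-by-class for active tumor, tumor core
#' and whole tumor.
#'
#' @param labels_est,labels_ref integer label vectors over the same
#'   voxels.
#' @param class_est,class_ref the `class_of_source` mappings of the two
#'   segmentations.
#' @return A tibble with one row per tissue class: `class`, `dice`,
#'   `n_est`, `n_ref`, `n_intersect`.
#' @export
dice_report <- function(labels_est, class_est, labels_ref, class_ref) {
  m_est <- tissue_class_masks(labels_est, class_est)
  m_ref <- tissue_class_masks(labels_ref, class_ref)
  cls <- c("active", "core", "whole")
  tibble::tibble(
    class = cls,
    dice = vapply(cls, function(k) {
      suppressMessages(dice_score(m_est[[k]], m_ref[[k]]))
    }, 0, USE.NAMES = FALSE),
    n_est = vapply(m_est, sum, 0L, USE.NAMES = FALSE),
    n_ref = vapply(m_ref, sum, 0L, USE.NAMES = FALSE),
    n_intersect = vapply(cls, function(k) sum(m_est[[k]] & m_ref[[k]]), 0L,
                         USE.NAMES = FALSE)
  )
}

#' One-tailed Wilcoxon signed-rank test
#'
#' Paired one-sided test of `H1: x > y` (or `x < y`) by signed midranks
#' of the nonzero differences. For up to 25 nonzero pairs the p-value is
#' exact, computed by enumerating the null distribution of the positive
#' rank sum with a generating-function convolution (valid under ties,
#' where midranks make the support non-integer); beyond that a normal
#' approximation with tie correction and continuity correction is used.
#' Zero differences are dropped, the common signed-rank convention.
#'
#' @param x,y paired numeric vectors of equal length (>= 5 pairs).
#' @param alternative `"greater"` (default) tests `x > y`.
#' @param exact_limit maximal number of nonzero pairs for the exact
#'   enumeration (default 25).
#' @return A list with `statistic` (positive rank sum W+), `p.value`,
#'   `n` (nonzero pairs) and `exact` (logical).
#' @export
#' @examples
#' wilcoxon_one_tailed(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))$p.value # 1/32
wilcoxon_one_tailed <- function(x, y, alternative = c("greater", "less"),
                                exact_limit = 25L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- x - y
  if (alternative == "less") d <- -d
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = 0L, exact = TRUE))
  }
  rk <- rank(abs(d)) # midranks under ties
  W <- sum(rk[d > 0])
  if (n <= exact_limit) {
    # exact null: signs i.i.d. +/- with prob 1/2; W+ support on multiples of
    # 1/2 under midranks -> work with doubled ranks as integers
    r2 <- as.integer(round(2 * rk))
    total <- sum(r2)
    f <- numeric(total + 1L) # f[s + 1] = #sign patterns with doubled sum s
    f[[1L]] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
      f <- f + shifted
    }
    W2 <- as.integer(round(2 * W))
    p <- sum(f[(W2 + 1L):(total + 1L)]) / 2^n
    list(statistic = W, p.value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5) / sqrt(sigma2)
    list(statistic = W, p.value = stats::pnorm(z, lower.tail = FALSE),
         n = n, exact = FALSE)
  }
}
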
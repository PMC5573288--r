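#' Synthetic multi-parametric tumor phantom
#'
#' Generates a near-separable non-negative mixture with the statistical
#' structure the factorization pipeline assumes: `r` tissue sources with
#' distinct non-negative feature signatures, spatially coherent abundance
#' maps on a 2-D grid with a concentric tumor geometry (necrotic center
#' inside an active-tumor rim inside an edema halo inside normal brain),
#' sum-to-one mixing, pure voxels for most tissues, and additive
#' truncated Gaussian noise at a target SNR.
#'
#' Interior voxels of each region are pure (one-hot abundance) with
#' probability `purity`, otherwise Dirichlet-mixed with the concentration
#' mass on the region's own tissue; voxels on region boundaries are
#' two-tissue Dirichlet mixtures of the adjacent tissues. Setting
#' `pure_pixel[k] = FALSE` replaces all of tissue `k`'s pure voxels with
#' 0.9/0.1 mixtures, emulating the partial-volume violation of the
#' pure-pixel assumption seen in low-resolution spectroscopic channels.
#'
#' @param grid_shape integer pair, the voxel grid (default 64 x 64).
#' @param m number of features per voxel (default 24).
#' @param r number of tissue sources (default 4: normal, edema, active,
#'   necrosis).
#' @param purity per-source fraction of interior voxels that are pure
#'   (recycled to length `r`; default 0.6).
#' @param snr_db target signal-to-noise ratio in dB (power ratio over the
#'   noiseless matrix); `Inf` for noiseless data. Default 30.
#' @param mixing_sharpness Dirichlet concentration of the dominant tissue
#'   in mixed voxels (default 8).
#' @param pure_pixel logical vector (recycled to `r`): sources whose pure
#'   voxels are kept. Default all `TRUE`.
#' @param seed integer seed; the same seed reproduces the phantom
#'   bit-identically.
#' @return An object of class `phantom`: `X` (a [feature_matrix()]),
#'   `W_true` (m x r), `H_true` (r x n, columns summing to 1),
#'   `label_map_true` (integer vector), `pure_indices` (list per source),
#'   `class_of_source`, `source_names`, `grid_shape`, `snr_db`
#'   (realized), `config`.
#' @export
#' @examples
#' ph <- make_phantom(grid_shape = c(16, 16), seed = 1)
#' table(ph$label_map_true)
make_phantom <- function(grid_shape = c(64L, 64L), m = 24L, r = 4L,
                         purity = 0.6, snr_db = 30,
                         mixing_sharpness = 8,
                         pure_pixel = TRUE, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  m <- as.integer(m); r <- as.integer(r)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 8L),
            r >= 2L, r <= m, all(purity >= 0), all(purity <= 1))
  purity <- rep_len(purity, r)
  pure_pixel <- rep_len(pure_pixel, r)
  source_names <- if (r == 4L) c("normal", "edema", "active", "necrosis")
                  else paste0("source", seq_len(r))
  class_of_source <- if (r == 4L) c("normal", "edema", "active", "necrosis")
                     else rep("other", r)
  with_seed(seed, {
    h <- grid_shape[[1L]]; w <- grid_shape[[2L]]
    n <- h * w
    # ---- tissue regions: concentric tumor geometry ----
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    R <- min(h, w) / 2
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    dist <- sqrt((rows - ctr[[1L]])^2 + (cols - ctr[[2L]])^2)
    if (r == 4L) {
      region <- matrix(1L, h, w)                    # normal background
      region[dist < 0.75 * R] <- 2L                 # edema halo
      region[dist < 0.48 * R] <- 3L                 # active rim
      region[dist < 0.28 * R] <- 4L                 # necrotic center
    } else {
      # general r: annuli of equal radial width inside R, background = 1
      region <- matrix(1L, h, w)
      for (k in 2:r) {
        region[dist < R * (1 - (k - 2) / (r - 1)) * 0.85] <- k
      }
    }
    counts <- tabulate(region, r)
    if (any(counts < 4L)) {
      stop("grid too small: some tissue regions host fewer than 4 voxels", call. = FALSE)
    }
    # boundary voxels: any 4-neighbor in a different region
    shift <- function(M, dr, dc) {
      out <- M
      ri <- pmin(pmax(rows + dr, 1L), h)
      ci <- pmin(pmax(cols + dc, 1L), w)
      matrix(M[cbind(as.vector(ri), as.vector(ci))], h, w)
    }
    nb_diff <- (shift(region, 1L, 0L) != region) | (shift(region, -1L, 0L) != region) |
      (shift(region, 0L, 1L) != region) | (shift(region, 0L, -1L) != region)
    # the dominant neighboring tissue for boundary mixing
    nb_region <- region
    for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      cand <- shift(region, s[[1L]], s[[2L]])
      pick <- nb_diff & (nb_region == region) & (cand != region)
      nb_region[pick] <- cand[pick]
    }

    # ---- source signatures: log-uniform profiles, limited collinearity ----
    draw_W <- function() matrix(10^stats::runif(m * r, -1, 1), m, r)
    W_true <- draw_W()
    for (attempt in seq_len(200L)) {
      nrm <- sqrt(colSums(W_true^2))
      cs <- crossprod(W_true) / outer(nrm, nrm)
      diag(cs) <- 0
      if (max(cs) <= 0.97) break
      W_true <- draw_W()
    }

    # ---- abundances ----
    rdirichlet <- function(alpha) {
      g <- stats::rgamma(length(alpha), shape = alpha)
      g / sum(g)
    }
    H_true <- matrix(0, r, n)
    reg_vec <- as.integer(region)       # column-major voxel order
    nb_vec <- as.integer(nb_region)
    bnd_vec <- as.vector(nb_diff)
    pure <- logical(n)
    for (j in seq_len(n)) {
      k <- reg_vec[[j]]
      if (bnd_vec[[j]]) {
        ab <- numeric(r)
        mix <- rdirichlet(c(mixing_sharpness, mixing_sharpness / 2))
        ab[[k]] <- mix[[1L]]
        ab[[nb_vec[[j]]]] <- mix[[2L]]
        H_true[, j] <- ab
      } else if (stats::runif(1L) < purity[[k]]) {
        H_true[k, j] <- 1
        pure[[j]] <- TRUE
      } else {
        alpha <- rep(0.3, r)
        alpha[[k]] <- mixing_sharpness
        ab <- rdirichlet(alpha)
        i <- which.max(ab)
        if (i != k) { # keep the region's tissue dominant in interior voxels
          tmp <- ab[[k]]; ab[[k]] <- ab[[i]]; ab[[i]] <- tmp
        }
        H_true[, j] <- ab
      }
    }
    # pure-pixel violation: demote this tissue's pure voxels to 0.9/0.1
    for (k in which(!pure_pixel)) {
      idx <- which(pure & reg_vec == k)
      for (j in idx) {
        other <- if (k == reg_vec[[j]]) {
          # mix with the spatially adjacent tissue (next region outward)
          if (r == 4L) c(2L, 1L, 2L, 3L)[[k]] else max(1L, k - 1L)
        } else 1L
        H_true[, j] <- 0
        H_true[k, j] <- 0.9
        H_true[other, j] <- 0.1
      }
      pure[reg_vec == k] <- FALSE
    }
    pure_indices <- lapply(seq_len(r), function(k) which(pure & reg_vec == k))

    # ---- data matrix with truncated Gaussian noise at target SNR ----
    X_clean <- W_true %*% H_true
    if (is.finite(snr_db)) {
      sd_noise <- sqrt(sum(X_clean^2) / (m * n * 10^(snr_db / 10)))
      X <- pmax(X_clean + matrix(stats::rnorm(m * n, sd = sd_noise), m, n), 0)
    } else {
      X <- X_clean
    }
    # ground truth label = dominant tissue of the generated abundance; this
    # coincides with the region stencil at every interior voxel and resolves
    # boundary voxels by their actual mixture
    lab_true <- apply(H_true, 2L, which.max)
    structure(list(
      X = feature_matrix(X, grid_shape = grid_shape),
      W_true = W_true, H_true = H_true,
      label_map_true = as.integer(lab_true),
      region_map = reg_vec,
      pure_indices = pure_indices,
      class_of_source = class_of_source,
      source_names = source_names,
      grid_shape = grid_shape,
      snr_db = snr_of(X_clean, X),
      config = list(grid_shape = grid_shape, m = m, r = r, purity = purity,
                    snr_db = snr_db, mixing_sharpness = mixing_sharpness,
                    pure_pixel = pure_pixel, seed = seed)
    ), class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d features x %d voxels (%d x %d grid), %d sources\n",
              nrow(x$W_true), ncol(x$H_true), x$grid_shape[[1L]],
              x$grid_shape[[2L]], ncol(x$W_true)))
  cat(sprintf("  realized SNR: %.2f dB; pure voxels per source: %s\n",
              x$snr_db, paste(lengths(x$pure_indices), collapse = ", ")))
  invisible(x)
}

#' Realized signal-to-noise ratio
#'
#' `10 log10(||clean||_F^2 / ||noisy - clean||_F^2)` in dB; identical
#' inputs give `+Inf`.
#'
#' @param X_clean,X_noisy matrices of identical shape.
#' @return SNR in dB.
#' @export
snr_of <- function(X_clean, X_noisy) {
  X_clean <- fm_data(X_clean); X_noisy <- fm_data(X_noisy)
  stopifnot(all(dim(X_clean) == dim(X_noisy)))
  noise <- sum((X_noisy - X_clean)^2)
  if (noise == 0) return(Inf)
  10 * log10(sum(X_clean^2) / noise)
}
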
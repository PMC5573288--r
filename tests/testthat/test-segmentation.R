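test_that("segmentation of one-hot and near-one-hot abundances", {
  H <- diag(3)[, c(1, 2, 3, 2, 1)]
  seg <- segment_abundances(H)
  expect_identical(seg$labels, c(1L, 2L, 3L, 2L, 1L))

  H2 <- matrix(c(0.9, 0.1, 0.1, 0.9), nrow = 2)
  expect_identical(segment_abundances(H2)$labels, c(1L, 2L))

  expect_error(segment_abundances(matrix(1, 1, 4)), "at least 2")
  expect_message(seg0 <- segment_abundances(cbind(diag(2), c(0, 0))), "labeled 0")
  expect_identical(seg0$labels, c(1L, 2L, 0L))
})

test_that("segmentation Lloyd iterations agree with stats::kmeans on separated data", {
  H <- withr::with_seed(70, {
    H <- matrix(0.05 * runif(3 * 60), 3, 60)
    for (j in seq_len(60)) H[(j %% 3) + 1L, j] <- H[(j %% 3) + 1L, j] + 1
    H
  })
  seg <- segment_abundances(H, normalize = TRUE)
  Hn <- sweep(H, 2, colSums(H), "/")
  km <- stats::kmeans(t(Hn), centers = diag(3), algorithm = "Lloyd")
  expect_identical(seg$labels, unname(km$cluster))
})

test_that("phantom abundances segment to the ground-truth labels", {
  ph <- small_phantom(seed = 71, mixing_sharpness = 30)
  seg <- segment_abundances(ph$H_true)
  expect_gte(mean(seg$labels == ph$label_map_true), 0.99)
})

test_that("source matching recovers permutations, scalings ignored", {
  W <- rand_nonneg(6, 4, seed = 72) + 0.05
  expect_identical(match_sources(W, W), 1:4)
  perm <- c(3L, 1L, 4L, 2L)
  expect_identical(match_sources(W[, perm], W), order(perm))

  # scaled and permuted: brute-force over all assignments as oracle
  D <- diag(c(2, 0.5, 3, 1.2))
  W_est <- (W %*% D)[, perm]
  got <- match_sources(W_est, W)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4L), ]
  cosm <- crossprod(W_est, W) /
    outer(sqrt(colSums(W_est^2)), sqrt(colSums(W^2)))
  scores <- apply(perms, 1, function(p) sum(cosm[cbind(p, 1:4)]))
  best <- perms[which.max(scores), ]
  expect_identical(got, as.integer(best))
})

test_that("Dice score arithmetic, symmetry and empty-mask conventions", {
  a <- c(rep(TRUE, 6), rep(FALSE, 4))
  b <- c(rep(TRUE, 3), rep(FALSE, 3), TRUE, rep(FALSE, 2), TRUE)
  # |A| = 6, |B| = 5, |A n B| = 3 -> 6/11; rebuild with |B| = 4
  b4 <- c(rep(TRUE, 3), rep(FALSE, 3), TRUE, rep(FALSE, 3))
  expect_equal(dice_score(a, b4), 2 * 3 / (6 + 4))
  expect_equal(dice_score(b4, a), dice_score(a, b4))
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, !a), 0)
  expect_message(d <- dice_score(logical(5), logical(5)), "both masks empty")
  expect_equal(d, 1)
  expect_equal(dice_score(logical(5), c(TRUE, logical(4))), 0)
})

test_that("nested tumor class masks: counts and nesting", {
  cls <- c("normal", "edema", "active", "necrosis")
  labels <- c(rep(3L, 10), rep(4L, 5), rep(2L, 20), rep(1L, 7))
  masks <- tissue_class_masks(labels, cls)
  expect_identical(sum(masks$active), 10L)
  expect_identical(sum(masks$core), 15L)
  expect_identical(sum(masks$whole), 35L)
  expect_true(all(masks$core[masks$active]))
  expect_true(all(masks$whole[masks$core]))

  only_normal <- rep(1L, 5)
  m2 <- tissue_class_masks(only_normal, cls)
  expect_identical(vapply(m2, sum, 1L), c(active = 0L, core = 0L, whole = 0L))

  expect_error(tissue_class_masks(c(1L, 5L), cls), "without a class")
  expect_error(tissue_class_masks(1L, c("tumor")), "unknown tissue class")
})

test_that("dice_report scores all three classes against a reference", {
  cls <- c("normal", "edema", "active", "necrosis")
  ref <- c(rep(1L, 10), rep(2L, 6), rep(3L, 4), rep(4L, 2))
  est <- ref; est[11] <- 1L # one edema voxel missed
  rep_tab <- dice_report(est, cls, ref, cls)
  expect_identical(rep_tab$class, c("active", "core", "whole"))
  expect_equal(rep_tab$dice[rep_tab$class == "active"], 1)
  expect_equal(rep_tab$dice[rep_tab$class == "core"], 1)
  expect_equal(rep_tab$dice[rep_tab$class == "whole"], 2 * 11 / (11 + 12))
})
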
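test_that("PCA recovers rank-1 structure with the sign convention", {
  set.seed(12)
  dir <- c(3, -1, 2, 0.5) / sqrt(sum(c(3, -1, 2, 0.5)^2))
  X <- outer(rnorm(40), dir) + 5
  fit <- fit_pca(X)
  expect_equal(fit$explained_variance[1], 1, tolerance = 1e-9)
  expect_equal(abs(sum(fit$loadings[, 1] * dir)), 1, tolerance = 1e-9)
  expect_gt(fit$loadings[which.max(abs(fit$loadings[, 1])), 1], 0)
  expect_lt(abs(mean(fit$scores[, 1])), 1e-9)
})

test_that("PCA is permutation-invariant and reconstructs its input", {
  set.seed(13)
  X <- matrix(rnorm(500), 50, 10)
  fit <- fit_pca(X)
  perm <- sample(50)
  fit_p <- fit_pca(X[perm, ])
  expect_equal(fit_p$loadings, fit$loadings, tolerance = 1e-8)
  expect_equal(fit_p$scores, fit$scores[perm, ], tolerance = 1e-8)
  recon <- fit$scores %*% t(fit$loadings) +
    matrix(fit$center, 50, 10, byrow = TRUE)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  expect_lte(sum(fit$explained_variance), 1 + 1e-9)
})

test_that("zero-variance input yields zero scores with a warning", {
  X <- matrix(1, 10, 4)
  expect_warning(fit <- fit_pca(X), "zero-variance")
  expect_true(all(fit$scores == 0))
})

test_that("loading spans are read off the bin edges", {
  v <- numeric(560)
  v[4:26] <- 0.5  # hydrogen-bond bins 3..25, zero-based
  fake <- structure(list(loadings = cbind(v), explained_variance = 1,
                         center = numeric(560),
                         scores = matrix(0, 2, 1)),
                    class = "pca_model")
  lp <- loading_profile(fake, 1)
  hb <- lp$spans[lp$spans$category == "hbond", ]
  expect_equal(hb$d_lo, 2.225)
  expect_equal(hb$d_hi, 3.875)
  expect_equal(hb$sign, 1)
  expect_true(all(is.na(
    lp$spans$d_lo[lp$spans$category != "hbond"])))

  zero <- fake
  zero$loadings <- cbind(numeric(560))
  expect_true(all(is.na(loading_profile(zero, 1)$spans$d_lo)))

  short <- fake
  short$loadings <- cbind(numeric(100))
  expect_error(loading_profile(short, 1), "fingerprint-shaped")
})

test_that("per-cluster ligand means follow a group-by oracle", {
  expect_equal(
    cluster_mean_pc(c(1, 3), c(1, 1), c("a", "a"), min_poses = 1)$mean_pc1,
    2)
  set.seed(14)
  n <- 300
  s <- rnorm(n)
  cl <- sample(1:3, n, replace = TRUE)
  lig <- sample(letters[1:6], n, replace = TRUE)
  got <- cluster_mean_pc(s, cl, lig, min_poses = 3)
  ref <- aggregate(s, list(cluster_id = cl, ligand_id = lig),
                   function(v) c(mean(v), length(v)))
  for (r in seq_len(nrow(ref))) {
    row <- got[got$cluster_id == ref$cluster_id[r] &
                 got$ligand_id == ref$ligand_id[r], ]
    expect_equal(row$n, ref$x[r, 2])
    if (ref$x[r, 2] >= 3) {
      expect_equal(row$mean_pc1, ref$x[r, 1])
    } else {
      expect_true(is.na(row$mean_pc1))
    }
  }
  # a ligand absent from a cluster has no row at all
  sub <- cluster_mean_pc(c(0, 0, 0), c(1, 1, 1), c("a", "a", "b"),
                         min_poses = 1)
  expect_equal(nrow(sub), 2)
})

test_that("affinity regression handles scales, exclusions and R^2", {
  aff <- affinity_table(letters[1:6],
                        c("1", "10", "100", "1000", ">500", "31.6"))
  means <- data.frame(ligand_id = letters[1:6],
                      mean_pc1 = c(3, 2, 1, 0, 9, 1.5))
  tr <- affinity_regression(means, aff)
  expect_equal(tr$r_squared, 1, tolerance = 1e-6)  # collinear by design
  expect_equal(tr$n_ligands, 5)                      # ">500" excluded
  expect_equal(tr$slope, -1, tolerance = 1e-9)
  capped <- affinity_regression(means, aff, oor = "cap")
  expect_equal(capped$n_ligands, 6)
  expect_lt(capped$r_squared, 1)
  raw <- affinity_regression(means, aff, scale = "raw_cd50")
  expect_lt(raw$r_squared, tr$r_squared)

  expect_error(affinity_regression(means[1:2, ], aff), "fewer than 3")
  const_x <- data.frame(ligand_id = letters[1:4], mean_pc1 = 1)
  expect_error(affinity_regression(const_x, aff), "zero-variance")
  const_y <- affinity_table(letters[1:4], rep("10", 4))
  expect_warning(
    z <- affinity_regression(means[1:4, ], const_y), "constant response")
  expect_equal(z$r_squared, 0)
})

test_that("R^2 is invariant under affine maps of the predictor", {
  set.seed(15)
  aff <- affinity_table(letters[1:10],
                        format(10^runif(10, 0, 2.5), digits = 8))
  means <- data.frame(ligand_id = letters[1:10], mean_pc1 = rnorm(10))
  r0 <- affinity_regression(means, aff)$r_squared
  for (k in 1:5) {
    a <- runif(1, 0.1, 4) * sample(c(-1, 1), 1)
    b <- rnorm(1, 0, 10)
    m2 <- means
    m2$mean_pc1 <- a * means$mean_pc1 + b
    expect_equal(affinity_regression(m2, aff)$r_squared, r0,
                 tolerance = 1e-9)
  }
})

test_that("cluster ranking sorts by R^2 and names the top cluster", {
  mk <- function(r2) structure(list(slope = 1, intercept = 0,
                                    r_squared = r2, n_ligands = 5L,
                                    affinity_scale = "log10_cd50"),
                               class = "trend_result")
  rk <- rank_clusters(list(`S1/1` = mk(0.2), `S2/3` = mk(0.6)))
  expect_equal(rk$cluster[1], "S2/3")
  expect_equal(rk$r_squared, c(0.6, 0.2))
  single <- rank_clusters(list(only = mk(0.4)))
  expect_equal(single$cluster[1], "only")
  expect_error(rank_clusters(list()), "no trend")
})
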
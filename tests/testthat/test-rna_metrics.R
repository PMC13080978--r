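planar_base_model <- function() {
  rna_model(data.frame(
    residue_index = 1L, residue_name = "A",
    atom_name = c("C2", "C4", "C6"), element = "C",
    x = c(1, -0.5, -0.5), y = c(0, 0.866, -0.866), z = c(0, 0, 0)))
}

test_that("base frames follow the planar C2/C4/C6 construction", {
  fr <- compute_base_frames(planar_base_model())
  expect_equal(fr$origins[1, ], c(0, 0, 0), tolerance = 1e-6)
  expect_equal(fr$axes[1, , 1], c(1, 0, 0), tolerance = 1e-6)
  expect_equal(abs(fr$axes[3, 3, 1]), 1, tolerance = 1e-6)
})

test_that("frames are equivariant under rigid rotation", {
  set.seed(11)
  R <- random_rotation_matrix()
  m2 <- transform_model(fx_model, R, c(1, -2, 3))
  f1 <- compute_base_frames(fx_model)
  f2 <- compute_base_frames(m2)
  for (i in c(1, 7, 20)) {
    expect_equal(f2$axes[, , i], f1$axes[, , i] %*% t(R),
                 tolerance = 1e-9)
    expect_equal(f2$origins[i, ],
                 as.vector(R %*% f1$origins[i, ]) + c(1, -2, 3),
                 tolerance = 1e-9)
  }
})

test_that("frames match an independent Gram-Schmidt oracle", {
  fr <- compute_base_frames(fx_model)
  a <- fx_model$atoms
  for (ri in c(2, 9, 15)) {
    pick <- function(nm) {
      r <- a[a$residue_index == ri & a$atom_name == nm, ][1, ]
      c(r$x, r$y, r$z)
    }
    orc <- oracle_frame(pick("C2"), pick("C4"), pick("C6"))
    expect_equal(fr$origins[ri, ], orc$origin, tolerance = 1e-12)
    expect_equal(fr$axes[1, , ri], orc$x, tolerance = 1e-12)
    expect_equal(fr$axes[2, , ri], orc$y, tolerance = 1e-12)
    expect_equal(fr$axes[3, , ri], orc$z, tolerance = 1e-12)
  }
})

test_that("collinear ring atoms are rejected with the residue named", {
  bad <- rna_model(data.frame(
    residue_index = 1L, residue_name = "A",
    atom_name = c("C2", "C4", "C6"), element = "C",
    x = c(0, 1, 2), y = 0, z = 0))
  expect_error(compute_base_frames(bad), "residue 1")
})

test_that("g-vectors vanish beyond the cutoff and obey the rho -> 0 limit", {
  mk_frames <- function(origin_k) {
    structure(list(
      residue_index = 1:2,
      origins = rbind(c(0, 0, 0), origin_k),
      axes = array(rep(diag(3), 2), c(3, 3, 2))), class = "base_frames")
  }
  far <- compute_gvectors(mk_frames(c(30, 0, 0)))
  expect_equal(far$G[1, 2, ], c(0, 0, 0, 0))
  expect_equal(far$G[2, 1, ], c(0, 0, 0, 0))
  near <- compute_gvectors(mk_frames(c(5e-6, 0, 0)))
  expect_equal(near$G[1, 2, 4], 2, tolerance = 1e-9)
  g <- pi / 2.4
  expect_equal(near$G[1, 2, 1], g * 1e-6, tolerance = 1e-3)
})

test_that("a hand-placed pair matches the standalone scalar oracle", {
  frames <- structure(list(
    residue_index = 1:2,
    origins = rbind(c(0, 0, 0), c(2.5, 0, 1.5)),
    axes = array(rep(diag(3), 2), c(3, 3, 2))), class = "base_frames")
  gv <- compute_gvectors(frames)
  expect_equal(gv$G[1, 2, ], oracle_gvector(c(2.5, 0, 1.5)),
               tolerance = 1e-12)
})

test_that("eRMSD is zero on identity and invariant under rigid motion", {
  g1 <- compute_gvectors(compute_base_frames(fx_model))
  expect_equal(as.numeric(ermsd(g1, g1)), 0)
  set.seed(21)
  for (k in 1:5) {
    R <- random_rotation_matrix()
    m2 <- transform_model(fx_model, R, rnorm(3, 0, 10))
    g2 <- compute_gvectors(compute_base_frames(m2))
    expect_lt(abs(ermsd(g1, g2)), 1e-9)
  }
})

test_that("eRMSD is symmetric and matches the monolithic oracle", {
  set.seed(31)
  for (k in 1:10) {
    es <- ensemble_spec(n_models = 2, rotation_sd = runif(1, 2, 25),
                        translation_sd = runif(1, 0, 0.6),
                        seed = 1000 + k)
    pair <- perturb_ensemble(fx_model, es)
    ga <- compute_gvectors(compute_base_frames(pair$models[[1]]))
    gb <- compute_gvectors(compute_base_frames(pair$models[[2]]))
    expect_identical(as.numeric(ermsd(ga, gb)),
                     as.numeric(ermsd(gb, ga)))
    expect_equal(as.numeric(ermsd(ga, gb)),
                 oracle_ermsd(pair$models[[1]], pair$models[[2]]),
                 tolerance = 1e-9)
  }
})

test_that("eRMSD refuses mismatched residue sets", {
  g_full <- gvectors_for <- compute_gvectors(compute_base_frames(fx_model))
  sub <- rnapose:::subset_residues(fx_model, 1:10)
  g_sub <- compute_gvectors(compute_base_frames(sub))
  expect_error(ermsd(g_full, g_sub), "mismatch")
})

test_that("heavy-atom RMSD superposes optimally (quaternion oracle)", {
  expect_equal(heavy_atom_rmsd(fx_model, fx_model), 0)
  set.seed(41)
  R <- random_rotation_matrix()
  moved <- transform_model(fx_model, R, c(5, 5, -5))
  expect_lt(heavy_atom_rmsd(fx_model, moved), 1e-9)
  for (k in 1:5) {
    pair <- perturb_ensemble(
      fx_model, ensemble_spec(n_models = 2, rotation_sd = 15,
                              translation_sd = 0.5, seed = 500 + k))
    A <- as.matrix(pair$models[[1]]$atoms[, c("x", "y", "z")])
    B <- as.matrix(pair$models[[2]]$atoms[, c("x", "y", "z")])
    expect_equal(heavy_atom_rmsd(pair$models[[1]], pair$models[[2]]),
                 oracle_quaternion_rmsd(B, A), tolerance = 1e-6)
  }
})

test_that("heavy-atom RMSD validates its selection", {
  expect_error(heavy_atom_rmsd(fx_model, fx_model, residues = 999),
               "different atom lists|fewer than 3")
})

test_that("site feature vectors have the fixed pair layout", {
  g <- compute_gvectors(compute_base_frames(fx_model))
  expect_length(site_feature_vector(g, c(3, 7)), 8)
  expect_error(site_feature_vector(g, integer(0)), "empty site")
  # identical conformations give identical vectors
  expect_identical(site_feature_vector(g, c(2, 5, 9)),
                   site_feature_vector(g, c(2, 5, 9)))
  # a 76-residue model with the upper-site residue list (8 residues)
  big <- make_idealized_helix(76)$models[[1]]
  gb <- compute_gvectors(compute_base_frames(big))
  v <- site_feature_vector(gb, c(11, 12, 13, 41, 42, 70, 71, 72))
  expect_length(v, 4 * 8 * 7)
})

test_that("mean eRMSD grows with the generator's perturbation magnitude", {
  mags <- c(0.5, 1, 2, 4, 8)
  mean_e <- vapply(seq_along(mags), function(i) {
    ens <- perturb_ensemble(
      fx_model, ensemble_spec(n_models = 8, rotation_sd = 3 * mags[i],
                              translation_sd = 0.08 * mags[i],
                              seed = 900 + i))
    g0 <- compute_gvectors(compute_base_frames(fx_model))
    mean(vapply(ens$models, function(m) {
      as.numeric(ermsd(g0, compute_gvectors(compute_base_frames(m))))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(mags, mean_e, method = "spearman"), 0.9)
})
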
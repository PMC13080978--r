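test_that("the idealized helix is frame-ready and deterministic", {
  h <- make_idealized_helix(10)
  m <- h$models[[1]]
  expect_length(unique(m$atoms$residue_index), 10)
  expect_s3_class(compute_base_frames(m), "base_frames")  # C2/C4/C6 ok
  h2 <- make_idealized_helix(10)
  expect_identical(h$models[[1]]$atoms, h2$models[[1]]$atoms)
  expect_error(make_idealized_helix(3), ">= 4")

  # consecutive base origins rise 2.8 A along the axis
  fr <- compute_base_frames(m)
  expect_equal(diff(fr$origins[, 3]), rep(2.8, 9), tolerance = 1e-9)
})

test_that("zero perturbation reproduces the reference exactly", {
  ens <- perturb_ensemble(fx_model,
                          ensemble_spec(n_models = 3, rotation_sd = 0,
                                        translation_sd = 0, seed = 1))
  g0 <- compute_gvectors(compute_base_frames(fx_model))
  for (m in ens$models) {
    expect_equal(as.matrix(m$atoms[, c("x", "y", "z")]),
                 as.matrix(fx_model$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-12)
    expect_equal(
      as.numeric(ermsd(g0, compute_gvectors(compute_base_frames(m)))), 0)
  }
})

test_that("perturbation is seeded and ordered by magnitude", {
  e1 <- perturb_ensemble(fx_model,
                         ensemble_spec(n_models = 4, seed = 77))
  e2 <- perturb_ensemble(fx_model,
                         ensemble_spec(n_models = 4, seed = 77))
  expect_identical(e1$models[[4]]$atoms, e2$models[[4]]$atoms)
  expect_error(ensemble_spec(n_models = 2), "seed")

  mean_to_ref <- function(rot_sd, seed) {
    ens <- perturb_ensemble(
      fx_model, ensemble_spec(n_models = 20, rotation_sd = rot_sd,
                              translation_sd = 0.1, seed = seed))
    g0 <- compute_gvectors(compute_base_frames(fx_model))
    mean(vapply(ens$models, function(m) {
      as.numeric(ermsd(g0, compute_gvectors(compute_base_frames(m))))
    }, numeric(1)))
  }
  expect_gt(mean_to_ref(20, 88), mean_to_ref(2, 89))
})

test_that("the congeneric series shares an ordered two-fold scaffold", {
  expect_length(fx_scaffold_group, 2)
  s2 <- make_congeneric_series(6, seed = 7)
  expect_identical(s2$ligands, fx_series$ligands)
  for (lig in fx_series$ligands) {
    expect_identical(lig$elements[1:21], fx_series$scaffold$elements)
    expect_identical(lig$formal_charges[1:21],
                     fx_series$scaffold$formal_charges)
    expect_true(all(lig$bonds[1:nrow(fx_series$scaffold$bonds), ] ==
                      fx_series$scaffold$bonds))
  }
  expect_error(make_congeneric_series(2), ">= 3")
})

test_that("planted pose modes are separated far beyond the threshold", {
  truth <- fx_planted$truth
  poses <- fx_planted$poses
  grp <- fx_scaffold_group
  by_mode <- split(seq_along(poses), truth$cluster_of_pose)
  for (a in 1:(length(by_mode) - 1)) {
    for (b in (a + 1):length(by_mode)) {
      r <- min_symmetry_rmsd(poses[[by_mode[[a]][1]]],
                             poses[[by_mode[[b]][1]]], grp)
      expect_gt(r, 5)
    }
  }
  # intra-mode spread stays below the threshold
  i <- by_mode[[1]]
  expect_lt(min_symmetry_rmsd(poses[[i[1]]], poses[[i[2]]], grp), 5)
})

test_that("planted counts rise with affinity within the signal cluster", {
  sc <- planted_scenario(n_ligands = 12, poses_per_ligand = 80, seed = 29)
  pl <- plant_pose_set(fx_model, make_congeneric_series(12, seed = 29), sc)
  truth <- pl$truth
  sig <- truth$counts[truth$counts$cluster == truth$signal_cluster, ]
  per_lig <- aggregate(cbind(n_hb, n_ca, n_lip) ~ ligand_id, sig, mean)
  x <- truth$x[match(per_lig$ligand_id, truth$ligand_id)]
  expect_gt(cor(x, per_lig$n_hb, method = "spearman"), 0.8)
  expect_gt(cor(x, per_lig$n_ca, method = "spearman"), 0.8)
  expect_lt(cor(x, per_lig$n_lip, method = "spearman"), -0.8)
})

test_that("out-of-range entries mark the weakest planted binders", {
  sc <- planted_scenario(n_ligands = 10, poses_per_ligand = 5,
                         fraction_out_of_range = 0.2, seed = 3)
  pl <- plant_pose_set(fx_model, make_congeneric_series(10, seed = 3), sc)
  expect_equal(sum(pl$affinities$out_of_range), 2)
  expect_true(all(pl$affinities$out_of_range[1:2]))  # lowest latent first
  expect_true(all(is.na(pl$affinities$cd50_uM[1:2])))
  expect_true(all(pl$affinities$cd50_uM[-(1:2)] > 0))
})

test_that("a noiseless one-cluster scenario recovers R^2 near 1", {
  sc <- planted_scenario(n_ligands = 8, poses_per_ligand = 40,
                         n_clusters = 1, signal_cluster = 1,
                         target_r2 = 1.0, fraction_out_of_range = 0,
                         cluster_weights = 1, seed = 17)
  pl <- plant_pose_set(fx_model, make_congeneric_series(8, seed = 17), sc)
  FP <- fingerprint_matrix(pl$poses, fx_model)
  fit <- fit_pca(FP, 2)
  tags <- attr(FP, "tags")
  means <- cluster_mean_pc(fit$scores[, 1], rep(1, nrow(FP)),
                           tags$ligand_id)
  tr <- affinity_regression(means, pl$affinities)
  expect_gte(tr$r_squared, 0.95)
})

test_that("scenario fixtures round-trip through the external formats", {
  dir <- withr::local_tempdir()
  sc <- planted_scenario(n_ligands = 5, poses_per_ligand = 8, seed = 19)
  es <- ensemble_spec(n_residues = 16, n_models = 3, seed = 20)
  fx <- write_scenario_fixtures(dir, seed = 19, scenario = sc, espec = es)
  expect_true(all(file.exists(unlist(fx$paths))))
  ens <- read_rna_models(fx$paths$rna)
  expect_length(ens$models, 3)
  sm <- read_scaffold_map(fx$paths$scaffold)
  poses <- read_ligand_poses(fx$paths$poses, sm)
  expect_length(poses, 5 * 8)
  expect_equal(validate_counts(poses,
                               read_docking_manifest(fx$paths$manifest))$
                 difference, rep(0L, 5))
  truth <- jsonlite::read_json(fx$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$signal_cluster, 1)
  expect_length(truth$cluster_of_pose, 40)
})
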
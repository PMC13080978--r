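# Shared fixtures, built once per test run. Kept deliberately small;
# the acceptance suite builds the full-size scenario itself.

fx_helix <- make_idealized_helix(20, seed = 1)
fx_model <- fx_helix$models[[1]]

fx_ensemble <- perturb_ensemble(
  fx_model,
  ensemble_spec(n_residues = 20, n_models = 6, rotation_sd = 8,
                translation_sd = 0.3, seed = 42))

fx_series <- make_congeneric_series(6, seed = 7)

fx_small_scenario <- planted_scenario(
  n_ligands = 6, poses_per_ligand = 30, target_r2 = 0.9,
  fraction_out_of_range = 0, seed = 5)

fx_planted <- plant_pose_set(fx_model, fx_series, fx_small_scenario)

fx_scaffold_group <- scaffold_automorphisms(
  fx_series$scaffold$bonds, fx_series$scaffold$elements)

# A miniature rigid "pose" builder: scaffold-only ligand on a ring of
# carbons, for geometry-level tests that do not need chemistry.
make_simple_pose <- function(coords, elements = NULL, charges = NULL,
                             bonds = NULL, ligand_id = "T1",
                             scaffold = seq_len(nrow(coords))) {
  n <- nrow(coords)
  elements <- elements %||% rep("C", n)
  charges <- charges %||% rep(0L, n)
  bonds <- bonds %||% cbind(seq_len(n - 1), 2:n, 1)
  ligand_pose(ligand_id, "S1", "m1", "test",
              atoms = data.frame(element = elements,
                                 x = coords[, 1], y = coords[, 2],
                                 z = coords[, 3],
                                 formal_charge = charges),
              bonds = bonds, scaffold_atoms = scaffold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rigidly transform an rna_model (rotation matrix R, translation t).
transform_model <- function(model, R, t) {
  a <- model$atoms
  P <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  P <- sweep(P, 2, t, `+`)
  a$x <- P[, 1]; a$y <- P[, 2]; a$z <- P[, 3]
  rna_model(a, model$model_id)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
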
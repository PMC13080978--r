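# Seeded generators for every fixture the pipeline needs: idealized RNA
# helices, perturbed conformational ensembles, a congeneric symmetric-
# scaffold ligand series, and pose sets with planted interaction-affinity
# structure.

#' Idealized RNA helix
#'
#' A single-model A-form-like stacked geometry: base origins on a helix
#' (rise 2.8 A, twist 32.7 deg/residue, radius 4 A), the three ring
#' carbons C2/C4/C6 on a 1.4 A ring around each base origin, plus the
#' dictionary donor/acceptor base atoms, the sugar O2' and the two
#' non-bridging phosphate oxygens. Sequence alternates A/U with a G-C
#' pair inserted mid-helix. Fully deterministic given the arguments.
#'
#' @param n_residues number of residues (>= 4).
#' @param seed RNG seed (kept for interface symmetry; the construction is
#'   deterministic).
#' @return an [rna_model_set()] with one model.
#' @export
make_idealized_helix <- function(n_residues, seed = 1L) {
  if (n_residues < 4) stop("n_residues must be >= 4")
  set.seed(seed)
  twist <- 32.7 * pi / 180
  rise <- 2.8
  base_r <- 4
  seqn <- rep(c("A", "U"), length.out = n_residues)
  mid <- floor(n_residues / 2)
  seqn[mid] <- "G"; seqn[mid + 1] <- "C"
  # fixed in-plane angles (deg) for the dictionary base atoms
  base_angles <- c(N1 = 30, N2 = 90, N3 = 60, N4 = 80, N6 = 100,
                   N7 = 160, O2 = 200, O4 = 230, O6 = 260)
  rows <- list()
  for (i in seq_len(n_residues)) {
    th <- (i - 1) * twist
    zi <- (i - 1) * rise
    e1 <- c(cos(th), sin(th), 0)
    e2 <- c(-sin(th), cos(th), 0)
    o <- base_r * e1 + c(0, 0, zi)
    put <- function(name, elem, pos) {
      rows[[length(rows) + 1L]] <<- data.frame(
        residue_index = i, residue_name = seqn[i], atom_name = name,
        element = elem, x = pos[1], y = pos[2], z = pos[3])
    }
    for (k in seq_along(c(0, 120, 240))) {
      phi <- c(0, 120, 240)[k] * pi / 180
      put(c("C2", "C4", "C6")[k], "C",
          o + 1.4 * (cos(phi) * e1 + sin(phi) * e2))
    }
    dict <- RNA_TYPING[[seqn[i]]]
    for (nm in c(dict$donors, dict$acceptors)) {
      phi <- base_angles[[nm]] * pi / 180
      put(nm, substr(nm, 1, 1), o + 2.4 * (cos(phi) * e1 + sin(phi) * e2))
    }
    # sugar
    ths <- th - 10 * pi / 180
    put("O2'", "O", c(5.5 * cos(ths), 5.5 * sin(ths), zi - 1.0))
    # phosphate
    thp <- th + 25 * pi / 180
    ep <- c(cos(thp), sin(thp), 0)
    P <- 7 * ep + c(0, 0, zi + 1.4)
    put("P", "P", P)
    put("O1P", "O", P + 1.3 * ep)
    put("O2P", "O", P + c(0, 0, 1.3))
  }
  rna_model_set(list(rna_model(do.call(rbind, rows), model_id = 1L)))
}

#' Ensemble perturbation specification
#'
#' @param n_residues,n_models ensemble dimensions.
#' @param rotation_sd per-base random rotation SD, degrees.
#' @param translation_sd per-base random translation SD, Angstrom.
#' @param seed mandatory RNG seed.
#' @export
ensemble_spec <- function(n_residues = 36L, n_models = 10L,
                          rotation_sd = 10, translation_sd = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(rotation_sd >= 0, translation_sd >= 0, n_models >= 1)
  structure(list(n_residues = as.integer(n_residues),
                 n_models = as.integer(n_models),
                 rotation_sd = rotation_sd,
                 translation_sd = translation_sd, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Perturbed conformational ensemble
#'
#' `n_models` copies of the reference in which every residue is rigidly
#' rotated about its base-frame origin (random axis, angle ~ N(0,
#' rotation_sd)) and translated (componentwise N(0, translation_sd)),
#' emulating the base-frame variability of a sampled trajectory. Seeded
#' and fully reproducible.
#'
#' @param reference an [rna_model()].
#' @param spec an [ensemble_spec()].
#' @return an [rna_model_set()] with `n_models` models.
#' @export
perturb_ensemble <- function(reference, spec) {
  stopifnot(inherits(reference, "rna_model"),
            inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  res <- residue_indices(reference)
  models <- vector("list", spec$n_models)
  for (m in seq_len(spec$n_models)) {
    a <- reference$atoms
    for (ri in res) {
      sel <- which(a$residue_index == ri)
      nm <- a$atom_name[sel]
      ring <- sel[nm %in% c("C2", "C4", "C6")]
      o <- c(mean(a$x[ring]), mean(a$y[ring]), mean(a$z[ring]))
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- rnorm(1, 0, spec$rotation_sd) * pi / 180
      R <- rotation_about_axis(ax, ang)
      tr <- rnorm(3, 0, spec$translation_sd)
      P <- as.matrix(a[sel, c("x", "y", "z")])
      P <- sweep(P, 2, o)
      P <- P %*% t(R)
      P <- sweep(P, 2, o + tr, `+`)
      a$x[sel] <- P[, 1]; a$y[sel] <- P[, 2]; a$z[sel] <- P[, 3]
    }
    models[[m]] <- rna_model(a, model_id = m)
  }
  rna_model_set(models)
}

#' Congeneric ligand series on a two-fold symmetric scaffold
#'
#' A 21-atom common scaffold - two identical pyridine-like rings, each
#' carrying an amidine-like head (C=N / C-N+), bridged by a symmetric
#' N-C-N linker - whose colored bond graph has exactly two automorphisms
#' (identity and arm swap). Each ligand decorates the scaffold with
#' substituent pools used by the pose generator as interaction contact
#' atoms: a chain of neutral donor nitrogens, a chain of amidinium-like
#' (C, N+) dyads, and a lipophilic carbon chain, with a per-ligand class
#' ("charged", "polar" or "lipophilic") adding a few extra atoms of the
#' matching kind. Ligands are abstract topologies with valid elements,
#' charges and bonds, not real chemistry.
#'
#' @param n_ligands series size (>= 3).
#' @param seed RNG seed (drives the class draw).
#' @return object of class `congeneric_series`: list with `scaffold`
#'   (elements, bonds, template coords), `scaffold_atoms` (1:21), and
#'   `ligands` (named list of topologies with pool index bookkeeping).
#' @export
make_congeneric_series <- function(n_ligands, seed = 1L) {
  if (n_ligands < 3) stop("n_ligands must be >= 3")
  set.seed(seed)
  deg <- function(d) d * pi / 180
  # scaffold: linker N1-C2-N3; arms = ring(6) + amidine(3)
  sc_el <- c("N", "C", "N",
             c("C", "N", "C", "C", "C", "C"),   # arm A ring, atoms 4-9
             "C", "N", "N",                     # arm A amidine 10-12
             c("C", "N", "C", "C", "C", "C"),   # arm B ring 13-18
             "C", "N", "N")                     # arm B amidine 19-21
  sc_chg <- integer(21); sc_chg[c(12, 21)] <- 1L
  sc_bonds <- rbind(
    c(1, 2, 1), c(2, 3, 1), c(1, 4, 1), c(3, 13, 1),
    c(4, 5, 1), c(5, 6, 1), c(6, 7, 1), c(7, 8, 1), c(8, 9, 1), c(9, 4, 1),
    c(7, 10, 1), c(10, 11, 2), c(10, 12, 1),
    c(13, 14, 1), c(14, 15, 1), c(15, 16, 1), c(16, 17, 1), c(17, 18, 1),
    c(18, 13, 1),
    c(16, 19, 1), c(19, 20, 2), c(19, 21, 1))
  ring_xy <- function(center, start_angle) {
    t(vapply(0:5, function(j) {
      center + 1.4 * c(cos(start_angle + deg(60 * j)),
                       sin(start_angle + deg(60 * j)), 0)
    }, numeric(3)))
  }
  co <- matrix(0, 21, 3)
  co[1, ] <- c(-1.4, 0, 0); co[2, ] <- c(0, 0.6, 0); co[3, ] <- c(1.4, 0, 0)
  co[4:9, ] <- ring_xy(c(-4.2, 0, 0), 0)        # atom 4 faces the linker
  co[10, ] <- c(-4.2 - 2.8, 0, 0)
  co[11, ] <- co[10, ] + 1.2 * c(-cos(deg(30)), sin(deg(30)), 0)
  co[12, ] <- co[10, ] + 1.2 * c(-cos(deg(30)), -sin(deg(30)), 0)
  co[13:18, ] <- ring_xy(c(4.2, 0, 0), deg(180))  # mirrored arm
  co[19, ] <- c(4.2 + 2.8, 0, 0)
  co[20, ] <- co[19, ] + 1.2 * c(cos(deg(30)), sin(deg(30)), 0)
  co[21, ] <- co[19, ] + 1.2 * c(cos(deg(30)), -sin(deg(30)), 0)
  classes <- sample(c("charged", "polar", "lipophilic"), n_ligands,
                    replace = TRUE)
  ligands <- list()
  for (i in seq_len(n_ligands)) {
    n_neutral <- 12L + if (classes[i] == "polar") 3L else 0L
    n_dyads <- 16L + if (classes[i] == "charged") 2L else 0L
    n_lipo <- 14L + if (classes[i] == "lipophilic") 3L else 0L
    el <- sc_el; chg <- sc_chg; bonds <- sc_bonds
    add_atom <- function(elem, charge) {
      el <<- c(el, elem); chg <<- c(chg, charge)
      length(el)
    }
    # neutral donor N chain rooted at arm-A ring atom 8
    neutral_idx <- integer(n_neutral)
    prev <- 8L
    for (k in seq_len(n_neutral)) {
      idx <- add_atom("N", 0L)
      bonds <- rbind(bonds, c(prev, idx, 1))
      neutral_idx[k] <- idx
      prev <- idx
    }
    # amidinium-like dyads: C chain rooted at arm-B ring atom 17, each C
    # carrying one pendant N+
    dyad_c <- dyad_n <- integer(n_dyads)
    prev <- 17L
    for (k in seq_len(n_dyads)) {
      ci <- add_atom("C", 0L)
      bonds <- rbind(bonds, c(prev, ci, 1))
      ni <- add_atom("N", 1L)
      bonds <- rbind(bonds, c(ci, ni, 1))
      dyad_c[k] <- ci; dyad_n[k] <- ni
      prev <- ci
    }
    # lipophilic C chain rooted at arm-A ring atom 6
    lipo_idx <- integer(n_lipo)
    prev <- 6L
    for (k in seq_len(n_lipo)) {
      idx <- add_atom("C", 0L)
      bonds <- rbind(bonds, c(prev, idx, 1))
      lipo_idx[k] <- idx
      prev <- idx
    }
    ligands[[sprintf("L%02d", i)]] <- list(
      elements = el, formal_charges = chg, bonds = bonds,
      substituent_class = classes[i],
      pools = list(neutral_N = neutral_idx, dyad_C = dyad_c,
                   dyad_N = dyad_n, lipo_C = lipo_idx))
  }
  structure(list(
    scaffold = list(elements = sc_el, formal_charges = sc_chg,
                    bonds = sc_bonds, template = co),
    scaffold_atoms = 1:21,
    ligands = ligands), class = "congeneric_series")
}

#' Planted benchmark scenario
#'
#' Parameters of the planted interaction-affinity benchmark: poses fall in
#' `n_clusters` spatial modes (inter-mode scaffold RMSD far above the 5 A
#' clustering threshold, intra-mode far below); within the signal cluster,
#' per-pose hydrogen-bond and cation-anion contact counts increase
#' linearly with a per-ligand affinity latent while lipophilic contacts
#' decrease; other clusters carry affinity-independent contact rates
#' pinned at the signal cluster's mid-level. CD50 values are log-linear in
#' the latent with Gaussian noise whose variance is budgeted in closed
#' form on the regression-eligible ligands so the pipeline's expected
#' recovered R^2 equals `target_r2`.
#'
#' @param n_ligands,poses_per_ligand series and sampling size.
#' @param n_clusters number of spatial pose modes.
#' @param signal_cluster index (in size order; cluster 1 is largest) of
#'   the mode carrying the affinity signal.
#' @param target_r2 target regression R^2 in (0, 1].
#' @param affinity_range CD50 range in micromolar (log-uniform signal).
#' @param fraction_out_of_range fraction of ligands reported as ">500".
#' @param cluster_weights per-ligand pose fractions per mode
#'   (renormalized over `n_clusters`).
#' @param hb_rate,ca_rate,lip_rate c(base, slope) of the per-pose Poisson
#'   contact-count means, linear in the affinity latent x in [0, 1].
#' @param jitter_translation_sd,jitter_rotation_sd intra-mode rigid pose
#'   jitter (Angstrom / degrees).
#' @param seed mandatory RNG seed.
#' @export
planted_scenario <- function(n_ligands = 15L, poses_per_ligand = 200L,
                             n_clusters = 3L, signal_cluster = 1L,
                             target_r2 = 0.85,
                             affinity_range = c(1, 500),
                             fraction_out_of_range = 0.15,
                             cluster_weights = c(0.45, 0.30, 0.25),
                             hb_rate = c(2, 5), ca_rate = c(2, 8),
                             lip_rate = c(9, -6),
                             jitter_translation_sd = 0.3,
                             jitter_rotation_sd = 2,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(target_r2 > 0, target_r2 <= 1,
            fraction_out_of_range >= 0, fraction_out_of_range < 1,
            signal_cluster >= 1, signal_cluster <= n_clusters,
            n_ligands >= 3, poses_per_ligand >= 1)
  w <- cluster_weights[seq_len(n_clusters)]
  structure(list(n_ligands = as.integer(n_ligands),
                 poses_per_ligand = as.integer(poses_per_ligand),
                 n_clusters = as.integer(n_clusters),
                 signal_cluster = as.integer(signal_cluster),
                 target_r2 = target_r2,
                 affinity_range = affinity_range,
                 fraction_out_of_range = fraction_out_of_range,
                 cluster_weights = w / sum(w),
                 hb_rate = hb_rate, ca_rate = ca_rate, lip_rate = lip_rate,
                 jitter_translation_sd = jitter_translation_sd,
                 jitter_rotation_sd = jitter_rotation_sd,
                 seed = as.integer(seed)),
            class = "planted_scenario")
}

#' Plant a pose set with known interaction-affinity structure
#'
#' Places poses of a congeneric series in well-separated spatial modes
#' near an RNA model and decorates each pose's substituent pools with
#' geometric contacts (see [planted_scenario()]) that the interaction
#' module will detect, so that the full pipeline's recovered trend is
#' known by construction. Ground truth (per-pose cluster, planted latent,
#' contact counts) is returned for assertions.
#'
#' @param rna an [rna_model()] (helix along z, as built by
#'   [make_idealized_helix()] / [perturb_ensemble()]).
#' @param series a [make_congeneric_series()] result with at least
#'   `scenario$n_ligands` ligands.
#' @param scenario a [planted_scenario()].
#' @param conformation_tag tag stamped on every pose (default "m1").
#' @return list with `poses` (list of [ligand_pose()]), `affinities`
#'   (an [affinity_table()]) and `truth` (list).
#' @export
plant_pose_set <- function(rna, series, scenario,
                           conformation_tag = "m1") {
  stopifnot(inherits(rna, "rna_model"),
            inherits(series, "congeneric_series"),
            inherits(scenario, "planted_scenario"))
  n <- scenario$n_ligands
  lig_ids <- names(series$ligands)
  if (length(lig_ids) < n) stop("series smaller than scenario n_ligands")
  lig_ids <- lig_ids[seq_len(n)]
  set.seed(scenario$seed)

  # planted affinity latent and CD50 values
  x <- seq(0, 1, length.out = n)
  k_oor <- round(scenario$fraction_out_of_range * n)
  oor <- seq_len(n) <= k_oor           # weakest binders are out of range
  lo <- log10(scenario$affinity_range[1])
  hi <- log10(scenario$affinity_range[2])
  signal <- hi - (hi - lo) * x
  kept <- !oor
  sd_eps <- sqrt(stats::var(signal[kept]) *
                   (1 - scenario$target_r2) / scenario$target_r2)
  log_cd50 <- signal + rnorm(n, 0, sd_eps)
  cd50_str <- ifelse(oor, ">500",
                     format(10^log_cd50, trim = TRUE, digits = 6))
  affinities <- affinity_table(lig_ids, cd50_str)

  # spatial modes: scaffold centroids well outside the RNA envelope,
  # separated along the helix axis by far more than the 5 A threshold
  XYZ <- model_coords(rna)
  rad_max <- max(sqrt(XYZ[, 1]^2 + XYZ[, 2]^2))
  d0 <- rad_max + 11
  zmid <- mean(range(XYZ[, 3]))
  zc <- zmid + 12 * (seq_len(scenario$n_clusters) -
                       (scenario$n_clusters + 1) / 2)
  mode_rot <- lapply(seq_len(scenario$n_clusters), function(k)
    rotation_about_axis(c(0, 0, 1), (k - 1) * 40 * pi / 180))
  template <- sweep(series$scaffold$template, 2,
                    colMeans(series$scaffold$template))
  mode_scaffold <- lapply(seq_len(scenario$n_clusters), function(k)
    sweep(template %*% t(mode_rot[[k]]), 2, c(d0, 0, zc[k]), `+`))
  for (att in 1:10) {
    sep <- TRUE
    if (scenario$n_clusters > 1) {
      for (a in 1:(scenario$n_clusters - 1)) {
        for (b in (a + 1):scenario$n_clusters) {
          r <- sqrt(mean(rowSums(
            (mode_scaffold[[a]] - mode_scaffold[[b]])^2)))
          if (r <= 5) sep <- FALSE
        }
      }
    }
    if (sep) break
    if (att == 10) stop("could not place non-overlapping pose modes")
    zc <- zc * 1.5
    mode_scaffold <- lapply(seq_len(scenario$n_clusters), function(k)
      sweep(template %*% t(mode_rot[[k]]), 2, c(d0, 0, zc[k]), `+`))
  }

  # RNA target atoms per mode
  rna_centers <- assign_centers(rna)
  targets_near <- function(df, zck) {
    df[abs(df$z - zck) <= 9, , drop = FALSE]
  }
  hb_targets <- lapply(zc, function(z)
    targets_near(rna_centers$acceptors[
      rna_centers$acceptors$moiety == "base", ], z))
  ca_targets <- lapply(zc, function(z) targets_near(rna_centers$anions, z))
  lip_targets <- lapply(zc, function(z)
    targets_near(rna_centers$lipophilic, z))

  # per-ligand pose counts per mode (deterministic split)
  counts_per_mode <- round(scenario$poses_per_ligand *
                             scenario$cluster_weights)
  counts_per_mode[scenario$n_clusters] <-
    scenario$poses_per_ligand - sum(counts_per_mode[-scenario$n_clusters])

  rate_at <- function(rate, xv) max(rate[1] + rate[2] * xv, 0)
  poses <- list()
  truth_rows <- list()
  for (li in seq_len(n)) {
    lig <- series$ligands[[lig_ids[li]]]
    n_atoms <- length(lig$elements)
    pools <- lig$pools
    for (k in seq_len(scenario$n_clusters)) {
      in_signal <- k == scenario$signal_cluster
      xv <- if (in_signal) x[li] else 0.5
      l_hb <- rate_at(scenario$hb_rate, xv)
      l_ca <- rate_at(scenario$ca_rate, xv)
      l_lip <- rate_at(scenario$lip_rate, xv)
      for (pp in seq_len(counts_per_mode[k])) {
        # rigid intra-mode jitter of the scaffold
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        R <- rotation_about_axis(
          ax, rnorm(1, 0, scenario$jitter_rotation_sd) * pi / 180)
        tr <- rnorm(3, 0, scenario$jitter_translation_sd)
        sc0 <- mode_scaffold[[k]]
        ctr <- colMeans(sc0)
        sc <- sweep(sweep(sc0, 2, ctr) %*% t(R), 2, ctr + tr, `+`)
        co <- matrix(NA_real_, n_atoms, 3)
        co[series$scaffold_atoms, ] <- sc
        out_dir <- c(ctr[1], ctr[2], 0)
        out_dir <- out_dir / sqrt(sum(out_dir^2))
        park <- function(idx) {
          # unused pool atoms: staggered outward, away from the RNA
          for (q in seq_along(idx)) {
            co[idx[q], ] <<- ctr + out_dir * (6 + 1.1 * q) +
              c(0, 0, 0.37 * q %% 3)
          }
        }
        n_hb <- min(rpois(1, l_hb), length(pools$neutral_N),
                    nrow(hb_targets[[k]]))
        n_ca <- min(rpois(1, l_ca), length(pools$dyad_N),
                    nrow(ca_targets[[k]]))
        n_lip <- min(rpois(1, l_lip), length(pools$lipo_C),
                     nrow(lip_targets[[k]]))
        place_near <- function(tdf, n_place, d_lo, d_hi) {
          if (n_place == 0) return(NULL)
          rows <- sample(nrow(tdf), n_place)
          t(vapply(seq_len(n_place), function(q) {
            tg <- as.numeric(tdf[rows[q], c("x", "y", "z")])
            u <- c(tg[1], tg[2], 0)
            u <- u / max(sqrt(sum(u^2)), 1e-9)
            u <- u + rnorm(3, 0, 0.15)
            u <- u / sqrt(sum(u^2))
            tg + runif(1, d_lo, d_hi) * u
          }, numeric(3)))
        }
        hb_pos <- place_near(hb_targets[[k]], n_hb, 2.8, 3.7)
        ca_cen <- place_near(ca_targets[[k]], n_ca, 3.0, 4.2)
        lip_pos <- place_near(lip_targets[[k]], n_lip, 3.3, 4.4)
        if (n_hb) co[pools$neutral_N[seq_len(n_hb)], ] <- hb_pos
        park(pools$neutral_N[seq_len(length(pools$neutral_N)) > n_hb])
        if (n_ca) {
          # place the (C, N+) dyad with its axis perpendicular to the
          # contact direction, so the charged-group centroid sits at the
          # sampled distance from the phosphate oxygen
          for (q in seq_len(n_ca)) {
            cen <- ca_cen[q, ]
            co[pools$dyad_N[q], ] <- cen + c(0, 0, 0.65)
            co[pools$dyad_C[q], ] <- cen - c(0, 0, 0.65)
          }
        }
        park(pools$dyad_N[seq_len(length(pools$dyad_N)) > n_ca])
        park(pools$dyad_C[seq_len(length(pools$dyad_C)) > n_ca])
        if (n_lip) co[pools$lipo_C[seq_len(n_lip)], ] <- lip_pos
        park(pools$lipo_C[seq_len(length(pools$lipo_C)) > n_lip])
        atoms <- data.frame(element = lig$elements,
                            x = co[, 1], y = co[, 2], z = co[, 3],
                            formal_charge = lig$formal_charges)
        poses[[length(poses) + 1L]] <- ligand_pose(
          ligand_id = lig_ids[li], site_tag = "S1",
          conformation_tag = conformation_tag,
          program_tag = "synthdock",
          atoms = atoms, bonds = lig$bonds,
          scaffold_atoms = series$scaffold_atoms)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          ligand_id = lig_ids[li], cluster = k, n_hb = n_hb,
          n_ca = n_ca, n_lip = n_lip)
      }
    }
  }
  truth <- list(
    ligand_id = lig_ids, x = x, log_cd50 = log_cd50,
    out_of_range = oor,
    signal_cluster = scenario$signal_cluster,
    cluster_of_pose = vapply(truth_rows, function(r) r$cluster,
                             numeric(1)),
    counts = do.call(rbind, truth_rows),
    mode_z = zc, mode_offset = d0)
  list(poses = poses, affinities = affinities, truth = truth)
}

#' Write a complete synthetic benchmark scenario to disk
#'
#' Generates the perturbed RNA ensemble, the congeneric series, the
#' planted pose set and the affinity table, and writes them in the
#' pipeline's external formats: `models.pdb`, `poses.sdf`, `cd50.csv`,
#' `scaffold.yaml`, `manifest.yaml` and `truth.json`. Poses are planted
#' against model 1 of the ensemble (conformation tag `m1`).
#'
#' @param dir output directory (created if missing).
#' @param seed master seed; sub-generator seeds are derived from it.
#' @param scenario a [planted_scenario()] (default: the standard planted
#'   benchmark with this `seed`).
#' @param espec an [ensemble_spec()] (default: 36 residues, 10 models).
#' @return invisibly, a list of the in-memory objects and file paths.
#' @export
write_scenario_fixtures <- function(dir, seed,
                                    scenario = NULL, espec = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- as.integer(seed)
  scenario <- scenario %||% planted_scenario(seed = seed)
  espec <- espec %||% ensemble_spec(seed = seed + 1000L)
  helix <- make_idealized_helix(espec$n_residues, seed = seed)
  ens <- perturb_ensemble(helix$models[[1]], espec)
  series <- make_congeneric_series(scenario$n_ligands, seed = seed + 2000L)
  planted <- plant_pose_set(ens$models[[1]], series, scenario,
                            conformation_tag = "m1")
  paths <- list(
    rna = file.path(dir, "models.pdb"),
    poses = file.path(dir, "poses.sdf"),
    affinities = file.path(dir, "cd50.csv"),
    scaffold = file.path(dir, "scaffold.yaml"),
    manifest = file.path(dir, "manifest.yaml"),
    truth = file.path(dir, "truth.json"))
  write_rna_models(ens, paths$rna)
  write_ligand_poses(planted$poses, paths$poses)
  write_affinities(planted$affinities, paths$affinities)
  write_scaffold_map(
    setNames(rep(list(series$scaffold_atoms), scenario$n_ligands),
             names(series$ligands)[seq_len(scenario$n_ligands)]),
    paths$scaffold)
  manifest <- docking_manifest(
    sites = data.frame(site_tag = "S1", n_conformations = 1L),
    programs = "synthdock",
    poses_per_program = scenario$poses_per_ligand,
    ligand_ids = names(series$ligands)[seq_len(scenario$n_ligands)])
  write_docking_manifest(manifest, paths$manifest)
  jsonlite::write_json(planted$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, ensemble = ens, series = series,
                 planted = planted, manifest = manifest,
                 scenario = scenario))
}
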
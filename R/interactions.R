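# Geometric typing of RNA and ligand interaction centers and detection of
# seven noncovalent interaction categories, histogrammed by distance.

#' Frozen fingerprint category order
#'
#' Hydrogen bonds, halogen bonds, lipophilic contacts, cation-anion,
#' pi-stacking, pi-cation, pi-anion. This order is fixed: flattened
#' fingerprint features and loading profiles rely on it.
#' @export
FP_CATEGORIES <- c("hbond", "halogen", "lipophilic", "cation_anion",
                   "pi_stacking", "pi_cation", "pi_anion")

#' Fingerprint histogram configuration
#'
#' @param d_min,d_max distance range in Angstrom (defaults 2 and 8).
#' @param n_bins number of equal-width bins (default 80, width 0.075 A).
#' @export
fingerprint_config <- function(d_min = 2, d_max = 8, n_bins = 80L) {
  stopifnot(d_max > d_min, n_bins >= 1)
  structure(list(d_min = d_min, d_max = d_max, n_bins = as.integer(n_bins),
                 width = (d_max - d_min) / n_bins),
            class = "fingerprint_config")
}

#' Geometric interaction rules
#'
#' Config-overridable distance/angle cutoffs for the seven categories.
#' Distances in Angstrom, angles in degrees. When a molecule carries no
#' explicit hydrogens, angle criteria that need them are skipped and
#' distance-only rules apply. For pi-stacking, the centroid-offset bound
#' applies to the parallel branch; the T-shaped branch (interplanar angle
#' 60-90 degrees) is distance/angle only.
#'
#' @param ... named overrides of the defaults listed in the source.
#' @export
interaction_rules <- function(...) {
  r <- list(
    hbond_dist = 3.9, hbond_angle = 100,
    halogen_dist = 4.0, halogen_angle = 140,
    lipophilic_detect = 8.0, lipophilic_core = 4.5,
    cation_anion_dist = 5.5,
    pistack_dist = 5.5, pistack_planar = 30,
    pistack_tshape = c(60, 90), pistack_offset = 2.5,
    pication_dist = 6.0, pication_angle = 40,
    pianion_dist = 5.5, pianion_angle = 40)
  ov <- list(...)
  bad <- setdiff(names(ov), names(r))
  if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "))
  r[names(ov)] <- ov
  structure(r, class = "interaction_rules")
}

# Per-nucleotide typing dictionary: base donors/acceptors, the sugar O2'
# (donor and acceptor), and the non-bridging phosphate oxygens as anion
# centers (and hydrogen-bond acceptors).
RNA_TYPING <- list(
  A = list(donors = "N6", acceptors = c("N1", "N7")),
  U = list(donors = "N3", acceptors = c("O2", "O4")),
  G = list(donors = c("N1", "N2"), acceptors = c("O6", "N7")),
  C = list(donors = "N4", acceptors = c("O2", "N3"))
)
RNA_SUGAR_DONOR_ACCEPTOR <- "O2'"
RNA_PHOSPHATE_ANIONS <- c("O1P", "O2P")
RNA_BASE_CARBONS <- c("C2", "C4", "C6")

moiety_of_atom <- function(atom_name) {
  ifelse(atom_name %in% c("P", "O1P", "O2P", "O5'", "O3'"), "phosphate",
         ifelse(grepl("'", atom_name), "sugar", "base"))
}

#' Assign interaction centers
#'
#' Deterministic typing of the hydrogen-bond donors and acceptors, halogen
#' donors (C-X, X in Cl/Br/I), formal-charge-derived cation and anion
#' centers (centroid of the charged atom and its bonded heavy neighbors),
#' lipophilic carbons, and aromatic rings (5/6-membered C/N cycles that are
#' near-planar) of a molecule. RNA typing comes from a built-in
#' per-nucleotide dictionary; ligand typing from elements, bonds and formal
#' charges, in both explicit- and implicit-hydrogen regimes.
#'
#' @param mol an [rna_model()] or [ligand_pose()].
#' @return object of class `interaction_centers`.
#' @export
assign_centers <- function(mol) UseMethod("assign_centers")

empty_centers <- function() {
  xyz <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    ref = character(0), residue_index = integer(0),
                    moiety = character(0))
  structure(list(donors = cbind(xyz, has_h = logical(0)),
                 donor_h = list(),
                 acceptors = xyz, halogens = cbind(xyz, cx = numeric(0),
                                                   cy = numeric(0),
                                                   cz = numeric(0)),
                 cations = xyz, anions = xyz, lipophilic = xyz,
                 rings = cbind(xyz, nx = numeric(0), ny = numeric(0),
                               nz = numeric(0))),
            class = "interaction_centers")
}

center_row <- function(co, ref, residue_index = NA_integer_,
                       moiety = NA_character_) {
  data.frame(x = co[1], y = co[2], z = co[3], ref = ref,
             residue_index = residue_index, moiety = moiety,
             stringsAsFactors = FALSE)
}

#' @export
assign_centers.rna_model <- function(mol) {
  cn <- empty_centers()
  a <- mol$atoms
  add <- function(df, rows) if (nrow(rows)) rbind(df, rows) else df
  for (ri in residue_indices(mol)) {
    sel <- which(a$residue_index == ri)
    nm <- a$atom_name[sel]
    resn <- a$residue_name[sel][1]
    dict <- RNA_TYPING[[resn]]
    co <- function(atom) {
      row <- sel[nm == atom][1]
      c(a$x[row], a$y[row], a$z[row])
    }
    present <- function(atoms) atoms[atoms %in% nm]
    for (d in present(c(dict$donors, RNA_SUGAR_DONOR_ACCEPTOR))) {
      cn$donors <- add(cn$donors,
                       cbind(center_row(co(d), d, ri, moiety_of_atom(d)),
                             has_h = FALSE))
      cn$donor_h <- c(cn$donor_h, list(NULL))
    }
    for (ac in present(c(dict$acceptors, RNA_SUGAR_DONOR_ACCEPTOR,
                         RNA_PHOSPHATE_ANIONS))) {
      cn$acceptors <- add(cn$acceptors,
                          center_row(co(ac), ac, ri, moiety_of_atom(ac)))
    }
    for (an in present(RNA_PHOSPHATE_ANIONS)) {
      cn$anions <- add(cn$anions, center_row(co(an), an, ri, "phosphate"))
    }
    for (cc in present(RNA_BASE_CARBONS)) {
      cn$lipophilic <- add(cn$lipophilic, center_row(co(cc), cc, ri, "base"))
    }
    ring <- vapply(RNA_BASE_CARBONS, co, numeric(3))
    cen <- rowMeans(ring)
    nrm <- pracma_cross(ring[, 2] - ring[, 1], ring[, 3] - ring[, 1])
    nn <- sqrt(sum(nrm^2))
    if (nn > 1e-9) {
      cn$rings <- add(cn$rings,
                      cbind(center_row(cen, "base_ring", ri, "base"),
                            nx = nrm[1] / nn, ny = nrm[2] / nn,
                            nz = nrm[3] / nn))
    }
  }
  cn
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @export
assign_centers.ligand_pose <- function(mol) {
  cn <- empty_centers()
  a <- mol$atoms
  n <- nrow(a)
  el <- a$element
  chg <- a$formal_charge
  co <- as.matrix(a[, c("x", "y", "z")])
  known <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H", "D")
  unknown <- !(el %in% known)
  if (any(unknown)) {
    warning("skipping atom(s) with unknown element: ",
            paste(unique(el[unknown]), collapse = ", "))
  }
  bi <- c(mol$bonds[, 1], mol$bonds[, 2])
  bj <- c(mol$bonds[, 2], mol$bonds[, 1])
  adj <- split(bj, factor(bi, levels = seq_len(n)))
  is_h <- el %in% c("H", "D")
  n_h_nb <- vapply(adj, function(v) sum(is_h[v]), integer(1))
  heavy_deg <- vapply(adj, function(v) sum(!is_h[v]), integer(1))
  polar_nb <- vapply(adj, function(v) {
    hv <- v[!is_h[v]]
    any(el[hv] %in% c("N", "O")) || any(chg[hv] != 0)
  }, logical(1))
  valid <- !unknown & !is_h
  explicit_h <- any(el == "H")
  mk <- function(idx, extra = NULL) {
    df <- list(x = co[idx, 1], y = co[idx, 2], z = co[idx, 3],
               ref = paste0(el[idx], idx),
               residue_index = rep(NA_integer_, length(idx)),
               moiety = rep(NA_character_, length(idx)))
    quickdf(c(df, extra))
  }
  # hydrogen-bond donors
  don <- which(valid & el %in% c("N", "O") &
                 (if (explicit_h) n_h_nb > 0
                  else (el == "N" | (el == "O" & heavy_deg <= 1))))
  if (length(don)) {
    cn$donors <- mk(don, list(has_h = n_h_nb[don] > 0))
    cn$donor_h <- lapply(don, function(i) {
      h <- adj[[i]][is_h[adj[[i]]]]
      if (length(h)) co[h, , drop = FALSE] else NULL
    })
  }
  # acceptors
  acc <- which(valid & (el == "O" | (el == "N" & chg <= 0)))
  if (length(acc)) cn$acceptors <- mk(acc)
  # halogen donors (C-X)
  hal <- which(valid & el %in% c("Cl", "Br", "I"))
  hal <- hal[vapply(hal, function(i) {
    any(el[adj[[i]]] == "C")
  }, logical(1))]
  if (length(hal)) {
    cc <- t(vapply(hal, function(i) {
      co[adj[[i]][el[adj[[i]]] == "C"][1], ]
    }, numeric(3)))
    cn$halogens <- mk(hal, list(cx = cc[, 1], cy = cc[, 2], cz = cc[, 3]))
  }
  # charged-group centers: charged atom + bonded heavy neighbors
  ci <- which(valid & chg != 0)
  if (length(ci)) {
    cen <- t(vapply(ci, function(i) {
      colMeans(co[c(i, adj[[i]][!is_h[adj[[i]]]]), , drop = FALSE])
    }, numeric(3)))
    df <- quickdf(list(x = cen[, 1], y = cen[, 2], z = cen[, 3],
                       ref = paste0(el[ci], ci,
                                    ifelse(chg[ci] > 0, "+", "-")),
                       residue_index = rep(NA_integer_, length(ci)),
                       moiety = rep(NA_character_, length(ci))))
    cn$cations <- df[chg[ci] > 0, , drop = FALSE]
    cn$anions <- df[chg[ci] < 0, , drop = FALSE]
  }
  # lipophilic: carbon not bonded to N/O/charged atoms
  lip <- which(valid & el == "C" & chg == 0 & !polar_nb)
  if (length(lip)) cn$lipophilic <- mk(lip)
  # aromatic rings: 5/6-cycles of C/N, near-planar
  ring_rows <- list()
  for (cyc in find_rings(n, mol$bonds)) {
    if (!all(el[cyc] %in% c("C", "N"))) next
    P <- co[cyc, , drop = FALSE]
    cen <- colMeans(P)
    Pc <- sweep(P, 2, cen)
    sv <- svd(Pc)
    nrm <- sv$v[, 3]
    if (max(abs(Pc %*% nrm)) > 0.2) next  # not planar
    ring_rows[[length(ring_rows) + 1L]] <-
      cbind(center_row(cen, paste0("ring_", paste(cyc, collapse = "."))),
            nx = nrm[1], ny = nrm[2], nz = nrm[3])
  }
  if (length(ring_rows)) {
    cn$rings <- do.call(rbind, c(list(cn$rings), ring_rows))
  }
  cn
}

# Simple 5/6-membered cycles of a bond graph, deduplicated by member set.
# Acyclic branches are stripped (iterative leaf pruning) before the
# bounded DFS, so only the 2-core is searched.
find_rings <- function(n, bonds) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  alive <- vapply(adj, length, integer(1)) > 0
  repeat {
    deg <- vapply(seq_len(n), function(i)
      sum(alive[adj[[i]]]), integer(1))
    leaves <- which(alive & deg <= 1)
    if (!length(leaves)) break
    alive[leaves] <- FALSE
  }
  if (!any(alive)) return(list())
  found <- list()
  keys <- character(0)
  dfs <- function(start, path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (!alive[nb]) next
      if (nb == start && length(path) >= 5) {
        key <- paste(sort(path), collapse = ".")
        if (!(key %in% keys)) {
          keys <<- c(keys, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && nb > start && length(path) < 6) {
        dfs(start, c(path, nb))
      }
    }
  }
  for (s in which(alive)) dfs(s, s)
  found
}

#' Detect RNA-ligand interactions of the seven categories
#'
#' Every RNA-ligand center pair satisfying its category's geometric
#' predicate yields one interaction carrying the category's characteristic
#' distance: donor-acceptor distance for hydrogen bonds, X...acceptor for
#' halogen bonds, C...C for lipophilic contacts, charge-center distance
#' for cation-anion, centroid-centroid for pi-stacking, and charge-to-
#' centroid for pi-cation / pi-anion.
#'
#' @param pose a [ligand_pose()] (or precomputed centers via `lig_centers`).
#' @param rna an [rna_model()] (or precomputed centers via `rna_centers`).
#' @param rules an [interaction_rules()] object.
#' @param lig_centers,rna_centers optional precomputed
#'   [assign_centers()] results (caching hook for large pose sets).
#' @return data.frame with `category`, `distance`, `rna_residue`,
#'   `rna_moiety` (one row per interaction instance).
#' @export
detect_interactions <- function(pose, rna, rules = interaction_rules(),
                                lig_centers = NULL, rna_centers = NULL) {
  L <- lig_centers %||% assign_centers(pose)
  R <- rna_centers %||% assign_centers(rna)
  mx <- function(df) {
    if (nrow(df)) unname(as.matrix(df[, c("x", "y", "z")]))
    else matrix(0, 0, 3)
  }
  nm3 <- function(df, cols) {
    if (nrow(df)) unname(as.matrix(df[, cols])) else matrix(0, 0, 3)
  }
  cats <- character(0); dist <- numeric(0)
  rres <- integer(0); rmoi <- character(0)
  emit <- function(category, distance, rna_residue, rna_moiety) {
    if (!length(distance)) return()
    cats <<- c(cats, rep(category, length(distance)))
    dist <<- c(dist, distance)
    rres <<- c(rres, rna_residue)
    rmoi <<- c(rmoi, rna_moiety)
  }

  # hydrogen bonds: ligand donor -> RNA acceptor (the D-H...A angle
  # criterion applies only to donors with explicit hydrogens)
  if (nrow(L$donors) && nrow(R$acceptors)) {
    LD <- mx(L$donors); RA <- mx(R$acceptors)
    dm <- cross_dist(LD, RA)
    hit <- which(dm <= rules$hbond_dist, arr.ind = TRUE)
    if (nrow(hit) && any(L$donors$has_h)) {
      ok <- vapply(seq_len(nrow(hit)), function(k) {
        i <- hit[k, 1]; j <- hit[k, 2]
        H <- L$donor_h[[i]]
        if (is.null(H) || !L$donors$has_h[i]) return(TRUE)
        don <- LD[i, ]; acc <- RA[j, ]
        any(vapply(seq_len(nrow(H)), function(hh) {
          ang <- vec_angle(don - H[hh, ], acc - H[hh, ])
          !is.na(ang) && ang >= rules$hbond_angle
        }, logical(1)))
      }, logical(1))
      hit <- hit[ok, , drop = FALSE]
    }
    emit("hbond", dm[hit], R$acceptors$residue_index[hit[, 2]],
         R$acceptors$moiety[hit[, 2]])
  }
  # hydrogen bonds: RNA donor -> ligand acceptor (dictionary donors carry
  # no explicit hydrogens, so the distance rule applies)
  if (nrow(R$donors) && nrow(L$acceptors)) {
    dm <- cross_dist(mx(R$donors), mx(L$acceptors))
    hit <- which(dm <= rules$hbond_dist, arr.ind = TRUE)
    emit("hbond", dm[hit], R$donors$residue_index[hit[, 1]],
         R$donors$moiety[hit[, 1]])
  }
  # halogen bonds: C-X...A angle at the halogen
  if (nrow(L$halogens) && nrow(R$acceptors)) {
    LX <- mx(L$halogens); RA <- mx(R$acceptors)
    LC <- nm3(L$halogens, c("cx", "cy", "cz"))
    dm <- cross_dist(LX, RA)
    hit <- which(dm <= rules$halogen_dist, arr.ind = TRUE)
    if (nrow(hit)) {
      U <- LC[hit[, 1], , drop = FALSE] - LX[hit[, 1], , drop = FALSE]
      V <- RA[hit[, 2], , drop = FALSE] - LX[hit[, 1], , drop = FALSE]
      cosang <- rowSums(U * V) /
        pmax(sqrt(rowSums(U^2)) * sqrt(rowSums(V^2)), 1e-12)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      hit <- hit[ang >= rules$halogen_angle, , drop = FALSE]
      emit("halogen", dm[hit], R$acceptors$residue_index[hit[, 2]],
           R$acceptors$moiety[hit[, 2]])
    }
  }
  # lipophilic contacts: all ligand-C / base-C pairs within the detection
  # range enter the histogram (the distance structure is the signal)
  if (nrow(L$lipophilic) && nrow(R$lipophilic)) {
    dm <- cross_dist(mx(L$lipophilic), mx(R$lipophilic))
    hit <- which(dm <= rules$lipophilic_detect, arr.ind = TRUE)
    emit("lipophilic", dm[hit], R$lipophilic$residue_index[hit[, 2]],
         R$lipophilic$moiety[hit[, 2]])
  }
  # cation-anion
  if (nrow(L$cations) && nrow(R$anions)) {
    dm <- cross_dist(mx(L$cations), mx(R$anions))
    hit <- which(dm <= rules$cation_anion_dist, arr.ind = TRUE)
    emit("cation_anion", dm[hit], R$anions$residue_index[hit[, 2]],
         R$anions$moiety[hit[, 2]])
  }
  if (nrow(L$anions) && nrow(R$cations)) {
    dm <- cross_dist(mx(L$anions), mx(R$cations))
    hit <- which(dm <= rules$cation_anion_dist, arr.ind = TRUE)
    emit("cation_anion", dm[hit], R$cations$residue_index[hit[, 2]],
         R$cations$moiety[hit[, 2]])
  }
  # pi-stacking: parallel (interplanar angle and centroid offset) or
  # T-shaped (interplanar angle only)
  if (nrow(L$rings) && nrow(R$rings)) {
    LR <- mx(L$rings); RR <- mx(R$rings)
    LN <- nm3(L$rings, c("nx", "ny", "nz"))
    RN <- nm3(R$rings, c("nx", "ny", "nz"))
    dm <- cross_dist(LR, RR)
    hit <- which(dm <= rules$pistack_dist, arr.ind = TRUE)
    if (nrow(hit)) {
      N1 <- LN[hit[, 1], , drop = FALSE]
      N2 <- RN[hit[, 2], , drop = FALSE]
      th <- acos(pmin(1, abs(rowSums(N1 * N2)))) * 180 / pi  # [0, 90]
      D <- RR[hit[, 2], , drop = FALSE] - LR[hit[, 1], , drop = FALSE]
      d2 <- rowSums(D^2)
      off <- pmin(sqrt(pmax(d2 - rowSums(D * N1)^2, 0)),
                  sqrt(pmax(d2 - rowSums(D * N2)^2, 0)))
      ok <- (th <= rules$pistack_planar & off <= rules$pistack_offset) |
        (th >= rules$pistack_tshape[1] & th <= rules$pistack_tshape[2])
      hit <- hit[ok, , drop = FALSE]
      emit("pi_stacking", dm[hit], R$rings$residue_index[hit[, 2]],
           R$rings$moiety[hit[, 2]])
    }
  }
  # pi-cation / pi-anion: charge center over a ring face, within an
  # axial cone around the ring normal
  axial_hits <- function(ch_xyz, ring_xyz, ring_n, dmax, amax) {
    dm <- cross_dist(ch_xyz, ring_xyz)
    hit <- which(dm <= dmax, arr.ind = TRUE)
    if (!nrow(hit)) return(list(hit = hit, dm = dm))
    V <- ch_xyz[hit[, 1], , drop = FALSE] -
      ring_xyz[hit[, 2], , drop = FALSE]
    N <- ring_n[hit[, 2], , drop = FALSE]
    cosang <- abs(rowSums(V * N)) / pmax(sqrt(rowSums(V^2)), 1e-12)
    ang <- acos(pmin(1, cosang)) * 180 / pi
    list(hit = hit[ang <= amax, , drop = FALSE], dm = dm)
  }
  if (nrow(L$cations) && nrow(R$rings)) {
    h <- axial_hits(mx(L$cations), mx(R$rings),
                    nm3(R$rings, c("nx", "ny", "nz")),
                    rules$pication_dist, rules$pication_angle)
    emit("pi_cation", h$dm[h$hit], R$rings$residue_index[h$hit[, 2]],
         R$rings$moiety[h$hit[, 2]])
  }
  if (nrow(R$anions) && nrow(L$rings)) {
    h <- axial_hits(mx(R$anions), mx(L$rings),
                    nm3(L$rings, c("nx", "ny", "nz")),
                    rules$pianion_dist, rules$pianion_angle)
    emit("pi_anion", h$dm[h$hit], R$anions$residue_index[h$hit[, 1]],
         R$anions$moiety[h$hit[, 1]])
  }
  if (nrow(L$anions) && nrow(R$rings)) {
    h <- axial_hits(mx(L$anions), mx(R$rings),
                    nm3(R$rings, c("nx", "ny", "nz")),
                    rules$pianion_dist, rules$pianion_angle)
    emit("pi_anion", h$dm[h$hit], R$rings$residue_index[h$hit[, 2]],
         R$rings$moiety[h$hit[, 2]])
  }
  data.frame(category = cats, distance = dist, rna_residue = rres,
             rna_moiety = rmoi, stringsAsFactors = FALSE)
}

#' Distance-binned fingerprint histogram of one pose
#'
#' Each interaction with `d_min <= distance < d_max` increments bin
#' `floor((distance - d_min) / width)` of its category row; out-of-range
#' interactions are dropped (their count is kept in attribute `dropped`).
#'
#' @param interactions a [detect_interactions()] result.
#' @param config a [fingerprint_config()].
#' @return 7 x n_bins integer matrix (rows in [FP_CATEGORIES] order,
#'   columns labeled by bin lower edge), with attribute `dropped`.
#' @export
fingerprint_histogram <- function(interactions,
                                  config = fingerprint_config()) {
  stopifnot(inherits(config, "fingerprint_config"))
  edges <- config$d_min + config$width * (seq_len(config$n_bins) - 1)
  H <- matrix(0L, length(FP_CATEGORIES), config$n_bins,
              dimnames = list(FP_CATEGORIES, format(edges, trim = TRUE)))
  d <- interactions$distance
  keep <- d >= config$d_min & d < config$d_max
  dropped <- sum(!keep)
  if (any(keep)) {
    bin <- floor((d[keep] - config$d_min) / config$width) + 1L
    bin <- pmin(bin, config$n_bins)
    cat_i <- match(interactions$category[keep], FP_CATEGORIES)
    for (k in seq_along(bin)) {
      H[cat_i[k], bin[k]] <- H[cat_i[k], bin[k]] + 1L
    }
  }
  attr(H, "dropped") <- dropped
  H
}

#' Fingerprint matrix of a pose set
#'
#' One flattened 7 x n_bins histogram row per pose. RNA interaction
#' centers are computed once per conformation and cached; each pose is
#' evaluated against the model named by its `conformation_tag` (models of
#' an [rna_model_set()] are named `m1`, `m2`, ... in model order; a single
#' [rna_model()] serves all poses).
#'
#' @param poses list of [ligand_pose()] objects.
#' @param rna an [rna_model()] or [rna_model_set()].
#' @param rules [interaction_rules()].
#' @param config [fingerprint_config()].
#' @return numeric matrix poses x (7 * n_bins) with attribute `tags`
#'   (data.frame of pose metadata).
#' @export
fingerprint_matrix <- function(poses, rna, rules = interaction_rules(),
                               config = fingerprint_config()) {
  stopifnot(length(poses) > 0)
  if (inherits(rna, "rna_model")) {
    models <- list(m1 = rna)
    centers <- list(m1 = assign_centers(rna))
    center_for <- function(tag) centers[[1]]
  } else if (inherits(rna, "rna_model_set")) {
    models <- setNames(rna$models, paste0("m", seq_along(rna$models)))
    cache <- new.env(parent = emptyenv())
    center_for <- function(tag) {
      if (is.null(models[[tag]])) {
        stop("pose conformation_tag '", tag,
             "' matches no model (expected m1..m", length(models), ")")
      }
      if (is.null(cache[[tag]])) {
        cache[[tag]] <- assign_centers(models[[tag]])
      }
      cache[[tag]]
    }
  } else stop("rna must be an rna_model or rna_model_set")
  # direct binned tabulation (equivalent to flattening
  # fingerprint_histogram(), asserted in the test suite)
  nb <- config$n_bins
  edges <- format(config$d_min + config$width * (0:(nb - 1)), trim = TRUE)
  rows <- lapply(poses, function(p) {
    inter <- detect_interactions(
      p, NULL, rules,
      lig_centers = assign_centers(p),
      rna_centers = center_for(p$conformation_tag))
    d <- inter$distance
    keep <- d >= config$d_min & d < config$d_max
    idx <- (match(inter$category[keep], FP_CATEGORIES) - 1L) * nb +
      pmin(floor((d[keep] - config$d_min) / config$width) + 1L, nb)
    tabulate(idx, nbins = length(FP_CATEGORIES) * nb)
  })
  M <- do.call(rbind, rows)
  colnames(M) <- as.vector(t(outer(FP_CATEGORIES, edges, paste,
                                   sep = "_")))
  attr(M, "tags") <- data.frame(
    pose = seq_along(poses),
    ligand_id = vapply(poses, `[[`, character(1), "ligand_id"),
    site_tag = vapply(poses, `[[`, character(1), "site_tag"),
    conformation_tag = vapply(poses, `[[`, character(1),
                              "conformation_tag"),
    program_tag = vapply(poses, `[[`, character(1), "program_tag"))
  M
}

#' Average interaction profile per group
#'
#' Arithmetic per-bin mean of fingerprint rows within each group (e.g. per
#' site or per ligand), for site-profile comparisons.
#'
#' @param rows fingerprint matrix ([fingerprint_matrix()] output or any
#'   poses x bins matrix).
#' @param grouping factor/character of length `nrow(rows)`.
#' @return matrix groups x bins of per-group means.
#' @export
average_profile <- function(rows, grouping) {
  grouping <- as.factor(grouping)
  if (any(table(grouping) == 0) || !nrow(rows)) stop("empty group")
  stopifnot(length(grouping) == nrow(rows))
  counts <- as.vector(table(grouping))
  sums <- rowsum(rows, grouping)
  sweep(sums, 1, counts, `/`)
}
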
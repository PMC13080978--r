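#' Element- and bond-preserving scaffold automorphisms
#'
#' Enumerates all permutations of the scaffold atoms that preserve element
#' labels and the bond graph including bond orders (colored-graph
#' automorphisms), by deterministic backtracking with element/degree
#' pruning. The identity is always first. Symmetric scaffolds (e.g. a
#' two-fold symmetric diamidine) yield the extra permutations under which
#' pose RMSD must be minimized.
#'
#' @param bonds integer matrix with columns `i`, `j`, `order`, indices into
#'   the scaffold atom list.
#' @param elements character vector of scaffold element labels.
#' @param cap maximum number of automorphisms before erroring (guards
#'   against pathological highly symmetric graphs).
#' @return object of class `symmetry_group`: list of integer permutations
#'   (each `p` maps scaffold position `k` to position `p[k]`).
#' @export
scaffold_automorphisms <- function(bonds, elements, cap = 10000L) {
  n <- length(elements)
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3)
  if (!graph_connected(n, cbind(bonds[, 1:2, drop = FALSE], 1L))) {
    stop("scaffold graph is not connected")
  }
  # adjacency with bond-order colors
  A <- matrix(0L, n, n)
  for (r in seq_len(nrow(bonds))) {
    A[bonds[r, 1], bonds[r, 2]] <- bonds[r, 3]
    A[bonds[r, 2], bonds[r, 1]] <- bonds[r, 3]
  }
  deg <- rowSums(A > 0)
  # refinement color: element + degree + sorted incident bond orders
  colr <- vapply(seq_len(n), function(i) {
    paste(elements[i], deg[i],
          paste(sort(A[i, A[i, ] > 0]), collapse = ","))
  }, character(1))
  perms <- list()
  p <- integer(n)
  used <- logical(n)
  backtrack <- function(k) {
    if (k > n) {
      perms[[length(perms) + 1L]] <<- p
      if (length(perms) > cap) {
        stop("more than ", cap, " automorphisms; supply a manual ",
             "permutation list instead")
      }
      return(invisible())
    }
    for (cand in seq_len(n)) {
      if (used[cand] || colr[cand] != colr[k]) next
      ok <- TRUE
      for (prev in seq_len(k - 1L)) {
        if (A[k, prev] != A[cand, p[prev]]) { ok <- FALSE; break }
      }
      if (!ok) next
      p[k] <<- cand
      used[cand] <<- TRUE
      backtrack(k + 1L)
      used[cand] <<- FALSE
    }
    invisible()
  }
  backtrack(1L)
  idx <- which(vapply(perms, function(q) all(q == seq_len(n)), logical(1)))
  perms <- c(perms[idx], perms[-idx])
  structure(perms, class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat("<symmetry_group>", length(x), "automorphism(s) on",
      length(x[[1]]), "scaffold atoms\n")
  invisible(x)
}

#' Symmetry-corrected minimum RMSD between two poses
#'
#' RMSD over the common scaffold atoms, minimized over the scaffold's
#' automorphisms, computed WITHOUT superposition: docked poses live in the
#' shared receptor coordinate frame, and superposing them would erase
#' binding-site placement. A superposed variant (`superpose = TRUE`) is
#' available for sensitivity analysis only.
#'
#' @param pose_a,pose_b [ligand_pose()] objects sharing the scaffold
#'   correspondence.
#' @param group a [scaffold_automorphisms()] result.
#' @param superpose if TRUE, optimally superpose before measuring
#'   (non-default; see above).
#' @return nonnegative RMSD in Angstrom.
#' @export
min_symmetry_rmsd <- function(pose_a, pose_b, group,
                              superpose = FALSE) {
  A <- scaffold_coords(pose_a)
  B <- scaffold_coords(pose_b)
  if (nrow(A) != nrow(B)) stop("scaffold size mismatch")
  stopifnot(inherits(group, "symmetry_group"),
            length(group[[1]]) == nrow(A))
  best <- Inf
  for (p in group) {
    Bp <- B[p, , drop = FALSE]
    if (superpose) Bp <- kabsch(Bp, A)$coords
    r <- sqrt(mean(rowSums((A - Bp)^2)))
    if (r < best) best <- r
  }
  best
}

#' Symmetry-corrected pose distance matrix
#'
#' All-pairs [min_symmetry_rmsd()] over a pose set (across ligands: the
#' scaffold is common to the series). Vectorized over poses per
#' automorphism, so large campaigns stay tractable.
#'
#' @param poses list of [ligand_pose()] objects.
#' @param group shared [scaffold_automorphisms()] result.
#' @return a [dist_matrix()] with metric tag `"pose_min_rmsd"` and
#'   attribute `pose_ids` (data.frame ligand_id / pose index).
#' @export
pose_distance_matrix <- function(poses, group) {
  stopifnot(length(poses) >= 1)
  m <- length(poses[[1]]$scaffold_atoms)
  X <- t(vapply(poses, function(p) {
    sc <- scaffold_coords(p)
    if (nrow(sc) != m) stop("scaffold size mismatch across poses")
    as.vector(t(sc))  # x1 y1 z1 x2 y2 z2 ...
  }, numeric(3 * m)))
  s <- rowSums(X^2)
  best <- NULL
  for (p in group) {
    cols <- as.vector(t(cbind(3 * p - 2, 3 * p - 1, 3 * p)))
    Xp <- X[, cols, drop = FALSE]
    D2 <- outer(s, s, `+`) - 2 * tcrossprod(X, Xp)
    best <- if (is.null(best)) D2 else pmin(best, D2)
  }
  D <- sqrt(pmax(best, 0) / m)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  out <- dist_matrix(D, metric_tag = "pose_min_rmsd")
  attr(out, "pose_ids") <- data.frame(
    pose = seq_along(poses),
    ligand_id = vapply(poses, `[[`, character(1), "ligand_id"),
    site_tag = vapply(poses, `[[`, character(1), "site_tag"))
  out
}

#' PCA on pose scaffold coordinates
#'
#' Mean-centered PCA on the flattened scaffold coordinates (3m features
#' per pose), tagging scores with program and conformation for
#' binding-mode maps that contrast docking programs.
#'
#' @param poses list of [ligand_pose()] objects on a common scaffold.
#' @return list with `scores` (poses x components), `explained_variance`
#'   (ratios), `loadings`, and `tags` (data.frame of pose metadata).
#' @export
pose_coordinate_pca <- function(poses) {
  if (length(poses) < 2) stop("need at least 2 poses")
  m <- length(poses[[1]]$scaffold_atoms)
  X <- t(vapply(poses, function(p) as.vector(t(scaffold_coords(p))),
                numeric(3 * m)))
  fit <- fit_pca(X)
  list(scores = fit$scores,
       explained_variance = fit$explained_variance,
       loadings = fit$loadings,
       tags = data.frame(
         pose = seq_along(poses),
         ligand_id = vapply(poses, `[[`, character(1), "ligand_id"),
         site_tag = vapply(poses, `[[`, character(1), "site_tag"),
         conformation_tag = vapply(poses, `[[`, character(1),
                                   "conformation_tag"),
         program_tag = vapply(poses, `[[`, character(1), "program_tag")))
}
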
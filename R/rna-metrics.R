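#' Parameters of the g-vector metric
#'
#' The base-pair-sensitive distance between RNA conformations rescales each
#' base-to-base separation anisotropically: in-plane components by `a`,
#' the out-of-plane component by `b`. Pairs beyond the dimensionless cutoff
#' `r_cut` contribute nothing. `gamma` is fixed at `pi / r_cut` so the
#' smoothing factor `sin(gamma * rho)` vanishes continuously at the cutoff.
#'
#' @param a in-plane rescaling length, Angstrom (default 5).
#' @param b normal rescaling length, Angstrom (default 3).
#' @param r_cut rescaled-distance cutoff, dimensionless (default 2.4).
#' @return an object of class `ermsd_parameters`.
#' @export
ermsd_parameters <- function(a = 5, b = 3, r_cut = 2.4) {
  stopifnot(a > 0, b > 0, r_cut > 0)
  structure(list(a = a, b = b, r_cut = r_cut, gamma = pi / r_cut),
            class = "ermsd_parameters")
}

#' Nucleotide base reference frames
#'
#' One orthonormal frame per residue, built identically for purines and
#' pyrimidines from the three six-membered-ring carbons: origin at the
#' centroid of C2/C4/C6, local x along origin to C2, y the component of
#' origin to C4 orthogonal to x, z their cross product.
#'
#' @param model an [rna_model()].
#' @return object of class `base_frames`: list with `residue_index`,
#'   `origins` (n x 3) and `axes` (3 x 3 x n; rows of each slice are the
#'   local x, y, z axes).
#' @export
compute_base_frames <- function(model) {
  stopifnot(inherits(model, "rna_model"))
  res <- residue_indices(model)
  n <- length(res)
  origins <- matrix(NA_real_, n, 3)
  axes <- array(NA_real_, c(3, 3, n))
  a <- model$atoms
  for (i in seq_len(n)) {
    sel <- a$residue_index == res[i]
    pick <- function(nm) {
      row <- which(sel & a$atom_name == nm)[1]
      c(a$x[row], a$y[row], a$z[row])
    }
    c2 <- pick("C2"); c4 <- pick("C4"); c6 <- pick("C6")
    o <- (c2 + c4 + c6) / 3
    x <- c2 - o
    nx <- sqrt(sum(x^2))
    if (nx < 1e-9) stop("degenerate ring geometry at residue ", res[i])
    x <- x / nx
    y <- (c4 - o) - sum((c4 - o) * x) * x
    ny <- sqrt(sum(y^2))
    if (ny < 1e-9) {
      stop("collinear C2/C4/C6 at residue ", res[i])
    }
    y <- y / ny
    z <- c(x[2] * y[3] - x[3] * y[2],
           x[3] * y[1] - x[1] * y[3],
           x[1] * y[2] - x[2] * y[1])
    origins[i, ] <- o
    axes[, , i] <- rbind(x, y, z)
  }
  structure(list(residue_index = res, origins = origins, axes = axes),
            class = "base_frames")
}

#' Pairwise g-vectors of a set of base frames
#'
#' For every ordered residue pair (j, k) the position of frame k's origin is
#' expressed in frame j's axes, rescaled anisotropically, and mapped to a
#' smooth 4-component descriptor that decays to zero at the cutoff:
#' with rescaled separation `rt = (rx/a, ry/a, rz/b)` and `rho = |rt|`,
#' `G = (sin(g rho) rt / rho, 1 + cos(g rho))` when `rho < r_cut`, else 0.
#'
#' @param frames a `base_frames` object from [compute_base_frames()].
#' @param params an [ermsd_parameters()] object.
#' @return object of class `gvector_field`: list with `residue_index` and
#'   `G`, an n x n x 4 array (diagonal slices zero).
#' @export
compute_gvectors <- function(frames, params = ermsd_parameters()) {
  stopifnot(inherits(frames, "base_frames"),
            inherits(params, "ermsd_parameters"))
  n <- nrow(frames$origins)
  if (n < 2) stop("need at least 2 frames")
  G <- array(0, c(n, n, 4))
  scl <- c(params$a, params$a, params$b)
  for (j in seq_len(n)) {
    d <- sweep(frames$origins, 2, frames$origins[j, ])   # origins_k - o_j
    loc <- d %*% t(frames$axes[, , j])                   # in frame j
    rt <- sweep(loc, 2, scl, `/`)
    rho <- sqrt(rowSums(rt^2))
    if (any(rho[-j] < 1e-12)) {
      stop("coincident base origins for residue pair involving index ", j)
    }
    inside <- rho < params$r_cut & seq_len(n) != j
    if (any(inside)) {
      s <- sin(params$gamma * rho[inside]) / rho[inside]
      G[j, inside, 1] <- s * rt[inside, 1]
      G[j, inside, 2] <- s * rt[inside, 2]
      G[j, inside, 3] <- s * rt[inside, 3]
      G[j, inside, 4] <- 1 + cos(params$gamma * rho[inside])
    }
  }
  structure(list(residue_index = frames$residue_index, G = G),
            class = "gvector_field")
}

#' eRMSD between two g-vector fields
#'
#' Root-mean-square deviation of the pairwise g-vectors, normalized by the
#' residue count N (not the pair count): this is the convention under which
#' values above about 0.7-0.8 indicate a changed base-pairing pattern.
#'
#' @param field_a,field_b `gvector_field` objects over the same residues.
#' @return nonnegative scalar with attribute `n_residues`.
#' @export
ermsd <- function(field_a, field_b) {
  stopifnot(inherits(field_a, "gvector_field"),
            inherits(field_b, "gvector_field"))
  if (!identical(field_a$residue_index, field_b$residue_index)) {
    stop("mismatched residue sets")
  }
  n <- length(field_a$residue_index)
  v <- sqrt(sum((field_a$G - field_b$G)^2) / n)
  attr(v, "n_residues") <- n
  v
}

#' eRMSD for models, with an optional residue selection
#'
#' Convenience wrapper: builds frames and g-vectors for the selected
#' residues of both models and returns their [ermsd()].
#'
#' @param model_a,model_b [rna_model()] objects.
#' @param residues residue indices to use (default: all shared residues).
#' @param params [ermsd_parameters()].
#' @export
ermsd_models <- function(model_a, model_b, residues = NULL,
                         params = ermsd_parameters()) {
  fa <- gvectors_for(model_a, residues, params)
  fb <- gvectors_for(model_b, residues, params)
  ermsd(fa, fb)
}

gvectors_for <- function(model, residues = NULL,
                         params = ermsd_parameters()) {
  if (!is.null(residues)) model <- subset_residues(model, residues)
  compute_gvectors(compute_base_frames(model), params)
}

subset_residues <- function(model, residues) {
  miss <- setdiff(residues, residue_indices(model))
  if (length(miss)) {
    stop("residue selection outside model: ", paste(miss, collapse = ", "))
  }
  keep <- model$atoms$residue_index %in% residues
  rna_model(model$atoms[keep, , drop = FALSE], model$model_id)
}

#' Pairwise eRMSD matrix of an ensemble
#'
#' @param set an [rna_model_set()].
#' @param residues optional residue-index selection (e.g. a binding site).
#' @param params [ermsd_parameters()].
#' @return a [dist_matrix()] with metric tag `"ermsd"`.
#' @export
ermsd_matrix <- function(set, residues = NULL,
                         params = ermsd_parameters()) {
  stopifnot(inherits(set, "rna_model_set"))
  fields <- lapply(set$models, gvectors_for, residues = residues,
                   params = params)
  n <- length(fields)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- as.numeric(ermsd(fields[[i]], fields[[j]]))
    }
  }
  dist_matrix(D, metric_tag = "ermsd")
}

#' Heavy-atom RMSD after optimal superposition
#'
#' Least-squares rigid superposition (rotation + translation) of the
#' selected atoms of `model_b` onto `model_a`, then RMSD over the same
#' selection. By default all non-hydrogen atoms of the selected residues
#' enter both the fit and the measure.
#'
#' @param model_a,model_b [rna_model()] objects with identical atom layout.
#' @param residues optional residue-index selection.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(model_a, model_b, residues = NULL) {
  sel_rows <- function(m) {
    keep <- !(m$atoms$element %in% c("H", "D"))
    if (!is.null(residues)) keep <- keep & m$atoms$residue_index %in% residues
    which(keep)
  }
  ra <- sel_rows(model_a); rb <- sel_rows(model_b)
  if (!identical(
        paste(model_a$atoms$residue_index[ra], model_a$atoms$atom_name[ra]),
        paste(model_b$atoms$residue_index[rb], model_b$atoms$atom_name[rb]))) {
    stop("selections map to different atom lists in the two models")
  }
  if (length(ra) < 3) stop("fewer than 3 selected atoms")
  A <- model_coords(model_a, ra)
  B <- model_coords(model_b, rb)
  fit <- kabsch(B, A)
  sqrt(mean(rowSums((fit$coords - A)^2)))
}

#' Site-restricted g-vector feature vector
#'
#' Flattens the g-vectors of all ordered residue pairs within a site into a
#' fixed-order numeric vector (lexicographic in (j, k), 4 components per
#' pair), suitable as PCA input for site-specific conformational analysis.
#' Length is `4 * m * (m - 1)` for `m` site residues.
#'
#' @param field a `gvector_field`.
#' @param site_residues residue indices of the site (subset of the field's).
#' @return named numeric vector.
#' @export
site_feature_vector <- function(field, site_residues) {
  stopifnot(inherits(field, "gvector_field"))
  if (!length(site_residues)) stop("empty site")
  site <- sort(unique(site_residues))
  pos <- match(site, field$residue_index)
  if (anyNA(pos)) {
    stop("site residues not in field: ",
         paste(site[is.na(pos)], collapse = ", "))
  }
  out <- numeric(0)
  nms <- character(0)
  for (j in seq_along(pos)) {
    for (k in seq_along(pos)) {
      if (j == k) next
      out <- c(out, field$G[pos[j], pos[k], ])
      nms <- c(nms, paste0("g", site[j], "_", site[k], "_", 1:4))
    }
  }
  setNames(out, nms)
}
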
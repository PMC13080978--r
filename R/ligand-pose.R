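#' Docked ligand pose
#'
#' One docked pose of a ligand: elements, coordinates and formal charges,
#' the bond graph, the campaign tags that tie the pose to the docking
#' design, and the ordered scaffold atom indices shared by the whole
#' congeneric series (atom k of the scaffold is the same chemical atom in
#' every pose of every ligand).
#'
#' @param ligand_id,site_tag,conformation_tag,program_tag character tags.
#' @param atoms data.frame with `element`, `x`, `y`, `z`, `formal_charge`.
#' @param bonds integer matrix with columns `i`, `j`, `order`.
#' @param scaffold_atoms ordered integer vector of scaffold atom indices.
#' @return object of class `ligand_pose`.
#' @export
ligand_pose <- function(ligand_id, site_tag, conformation_tag, program_tag,
                        atoms, bonds, scaffold_atoms) {
  stopifnot(all(c("element", "x", "y", "z", "formal_charge") %in%
                names(atoms)))
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  n <- nrow(atoms)
  if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n)) {
    stop("bond indices out of range")
  }
  if (any(atoms$formal_charge != round(atoms$formal_charge))) {
    stop("formal charges must be integers")
  }
  scaffold_atoms <- as.integer(scaffold_atoms)
  if (any(scaffold_atoms < 1L) || any(scaffold_atoms > n) ||
      anyDuplicated(scaffold_atoms)) {
    stop("invalid scaffold atom indices")
  }
  obj <- structure(list(
    ligand_id = ligand_id, site_tag = site_tag,
    conformation_tag = conformation_tag, program_tag = program_tag,
    atoms = atoms, bonds = bonds, scaffold_atoms = scaffold_atoms),
    class = "ligand_pose")
  if (!graph_connected(n, bonds)) {
    stop("bond graph of pose (ligand ", ligand_id, ") is not connected")
  }
  obj
}

graph_connected <- function(n, bonds) {
  if (n <= 1L) return(TRUE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose>", x$ligand_id,
      sprintf("[site=%s conf=%s prog=%s]", x$site_tag, x$conformation_tag,
              x$program_tag),
      nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
      length(x$scaffold_atoms), "scaffold atoms\n")
  invisible(x)
}

# Scaffold coordinates of a pose, in scaffold order (m x 3).
scaffold_coords <- function(pose) {
  as.matrix(pose$atoms[pose$scaffold_atoms, c("x", "y", "z")])
}

pose_atom_coords <- function(pose) {
  as.matrix(pose$atoms[, c("x", "y", "z")])
}
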
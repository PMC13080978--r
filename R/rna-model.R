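#' RNA model containers
#'
#' An `rna_model` holds one conformation of an RNA as an ordered atom table;
#' an `rna_model_set` holds a conformational ensemble in which every model
#' shares identical residue indexing and atom naming (as in a multi-MODEL
#' PDB file). Every retained residue must carry the three six-membered-ring
#' carbons C2, C4 and C6 from which nucleotide base reference frames are
#' built.
#'
#' @param atoms data.frame with columns `residue_index`, `residue_name`
#'   (one of A/U/G/C), `atom_name`, `element`, `x`, `y`, `z`.
#' @param model_id integer model identifier.
#' @return `rna_model()` returns an object of class `rna_model`;
#'   `rna_model_set()` an object of class `rna_model_set`.
#' @export
rna_model <- function(atoms, model_id = 1L) {
  need <- c("residue_index", "residue_name", "atom_name", "element",
            "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  atoms <- atoms[order(atoms$residue_index), , drop = FALSE]
  rownames(atoms) <- NULL
  obj <- structure(list(model_id = as.integer(model_id), atoms = atoms),
                   class = "rna_model")
  validate_rna_model(obj)
  obj
}

validate_rna_model <- function(m) {
  a <- m$atoms
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in model ", m$model_id)
  }
  bad <- setdiff(unique(a$residue_name), c("A", "U", "G", "C"))
  if (length(bad)) {
    stop("non-nucleotide residue names in model ", m$model_id, ": ",
         paste(bad, collapse = ", "))
  }
  for (ri in unique(a$residue_index)) {
    nm <- a$atom_name[a$residue_index == ri]
    miss <- setdiff(c("C2", "C4", "C6"), nm)
    if (length(miss)) {
      stop("model ", m$model_id, ", residue ", ri,
           ": missing base ring atom(s) ", paste(miss, collapse = ", "))
    }
  }
  invisible(m)
}

#' @param models list of `rna_model` objects.
#' @rdname rna_model
#' @export
rna_model_set <- function(models) {
  if (!length(models)) stop("empty model set")
  stopifnot(all(vapply(models, inherits, logical(1), "rna_model")))
  key <- function(m) paste(m$atoms$residue_index, m$atoms$atom_name,
                           collapse = "|")
  k1 <- key(models[[1]])
  for (i in seq_along(models)) {
    if (key(models[[i]]) != k1) {
      stop("inconsistent residue/atom sets across models (model ",
           models[[i]]$model_id, " differs from model ",
           models[[1]]$model_id, ")")
    }
  }
  structure(list(models = models), class = "rna_model_set")
}

#' @export
print.rna_model <- function(x, ...) {
  cat("<rna_model>", "model", x$model_id, "-",
      length(unique(x$atoms$residue_index)), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' @export
print.rna_model_set <- function(x, ...) {
  cat("<rna_model_set>", length(x$models), "models,",
      length(unique(x$models[[1]]$atoms$residue_index)),
      "residues each\n")
  invisible(x)
}

#' @export
length.rna_model_set <- function(x) length(x$models)

# Residue indices of a model (sorted, unique).
residue_indices <- function(model) sort(unique(model$atoms$residue_index))

# n x 3 coordinate matrix of (a subset of) a model's atoms.
model_coords <- function(model, rows = seq_len(nrow(model$atoms))) {
  as.matrix(model$atoms[rows, c("x", "y", "z")])
}
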
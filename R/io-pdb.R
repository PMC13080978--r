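#' Read a (multi-MODEL) PDB file into an RNA model set
#'
#' Parses ATOM records via \pkg{bio3d}. Only standard ribonucleotide
#' residues (A, U, G, C) are retained; other residues are skipped with a
#' warning. Alternate locations other than blank or 'A' are dropped so each
#' model carries a single deterministic conformer. Every retained residue
#' must contain the base ring atoms C2, C4 and C6, and all models must share
#' an identical residue/atom layout.
#'
#' @param path PDB file with one or more MODEL records (a file without
#'   MODEL records is read as a single implicit model).
#' @return an [rna_model_set()].
#' @export
read_rna_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_model_consistency(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep_alt <- is.na(at$alt) | at$alt == "" | at$alt == "A"
  resname <- normalize_resname(at$resid)
  is_nuc <- !is.na(resname)
  if (any(!is_nuc)) {
    skipped <- unique(at$resid[!is_nuc])
    warning("skipping non-nucleotide residue(s): ",
            paste(skipped, collapse = ", "))
  }
  keep <- keep_alt & is_nuc & at$type %in% c("ATOM", "HETATM")
  if (!any(keep)) stop("no nucleotide atoms found in ", path)
  at <- at[keep, , drop = FALSE]
  resname <- resname[keep]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  col_idx <- which(rep(keep, each = 3))
  n_models <- nrow(xyz)
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    co <- matrix(xyz[m, col_idx], ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      residue_index = at$resno,
      residue_name = resname,
      atom_name = at$elety,
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(at$elety, 1, 1), at$elesy),
      x = co[, 1], y = co[, 2], z = co[, 3],
      stringsAsFactors = FALSE
    )
    models[[m]] <- rna_model(atoms, model_id = m)
  }
  rna_model_set(models)
}

# Multi-MODEL files must carry an identical nucleotide atom layout in
# every model; a light record scan verifies this before parsing, naming
# the first offending model and residue.
check_model_consistency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  keys <- lapply(seq_along(starts), function(m) {
    blk <- lines[starts[m]:ends[m]]
    at <- blk[grepl("^(ATOM  |HETATM)", blk)]
    resn <- normalize_resname(substr(at, 18, 20))
    at <- at[!is.na(resn)]
    paste(trimws(substr(at, 23, 26)), trimws(substr(at, 13, 16)))
  })
  for (m in seq_along(keys)[-1]) {
    if (identical(keys[[m]], keys[[1]])) next
    missing <- setdiff(keys[[1]], keys[[m]])
    extra <- setdiff(keys[[m]], keys[[1]])
    bad <- c(missing, extra)[1]
    stop("inconsistent atom records across models: model ", m,
         ", residue ", sub(" .*$", "", bad), " differs from model 1 (",
         if (length(missing)) "missing " else "extra ",
         sub("^[^ ]+ ", "", bad), ")")
  }
  invisible(TRUE)
}

normalize_resname <- function(resid) {
  r <- toupper(trimws(resid))
  map <- c(A = "A", U = "U", G = "G", C = "C",
           RA = "A", RU = "U", RG = "G", RC = "C",
           ADE = "A", URA = "U", GUA = "G", CYT = "C")
  out <- unname(map[r])
  out
}

#' Write an RNA model set as a multi-MODEL PDB file
#'
#' Emits standard fixed-width ATOM records wrapped in MODEL/ENDMDL pairs
#' (coordinates at PDB precision, 3 decimals), readable by
#' [read_rna_models()] and any PDB-aware tool.
#'
#' @param set an [rna_model_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rna_models <- function(set, path) {
  stopifnot(inherits(set, "rna_model_set"))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(set$models) > 1L
  for (m in set$models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m$model_id), con)
    a <- m$atoms
    nm <- ifelse(nchar(a$atom_name) < 4L,
                 sprintf(" %-3s", a$atom_name), a$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), nm, paste0("  ", a$residue_name), a$residue_index,
      a$x, a$y, a$z, 1, 0, substr(a$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
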
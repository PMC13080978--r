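# SDF (V2000) pose I/O via ChemmineR. Formal charges travel in the
# atom-block charge-code column (codes 1:7 = +3..-3 around 0 = neutral),
# which ChemmineR preserves in both directions; campaign tags travel as
# data-block properties.

CHG_CODE <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L,
              `-1` = 5L, `-2` = 6L, `-3` = 7L)
CODE_CHG <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
              `5` = -1L, `6` = -2L, `7` = -3L)

REQUIRED_TAGS <- c("ligand_id", "site_tag", "conformation_tag",
                   "program_tag")

#' Read docked ligand poses from an SDF file
#'
#' Every record must carry the data-block properties `ligand_id`,
#' `site_tag`, `conformation_tag` and `program_tag`, plus connectivity.
#' The scaffold correspondence is chemical, not inferable from coordinates,
#' so it is supplied explicitly: either one ordered atom-index vector
#' applied to every record, or a named list mapping each `ligand_id` to its
#' ordered scaffold atom indices (e.g. from [read_scaffold_map()]).
#'
#' @param path SDF (V2000) file.
#' @param scaffold_spec integer vector, or named list of integer vectors
#'   keyed by ligand_id.
#' @return list of [ligand_pose()] objects, in file order.
#' @export
read_ligand_poses <- function(path, scaffold_spec) {
  if (!file.exists(path)) stop("no such file: ", path)
  sdfs <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfs))
  for (i in seq_along(out)) {
    sdf <- sdfs[[i]]
    db <- ChemmineR::datablock(sdf)
    miss <- setdiff(REQUIRED_TAGS, names(db))
    if (length(miss)) {
      stop("SDF record ", i, " missing property tag(s): ",
           paste(miss, collapse = ", "))
    }
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    charges <- CODE_CHG[as.character(as.integer(ab[, "C6"]))]
    charges[is.na(charges)] <- 0L
    atoms <- data.frame(
      element = elements,
      x = ab[, "C1"], y = ab[, "C2"], z = ab[, "C3"],
      formal_charge = as.integer(charges),
      stringsAsFactors = FALSE
    )
    rownames(atoms) <- NULL
    bonds <- cbind(i = as.integer(bb[, "C1"]),
                   j = as.integer(bb[, "C2"]),
                   order = as.integer(bb[, "C3"]))
    lig <- unname(db[["ligand_id"]])
    sc <- if (is.list(scaffold_spec)) {
      if (is.null(scaffold_spec[[lig]])) {
        stop("SDF record ", i, " (ligand ", lig,
             "): no scaffold definition found")
      }
      scaffold_spec[[lig]]
    } else {
      scaffold_spec
    }
    if (any(sc > nrow(atoms))) {
      stop("SDF record ", i, " (ligand ", lig,
           "): scaffold atoms not found in record")
    }
    out[[i]] <- ligand_pose(
      ligand_id = lig,
      site_tag = unname(db[["site_tag"]]),
      conformation_tag = unname(db[["conformation_tag"]]),
      program_tag = unname(db[["program_tag"]]),
      atoms = atoms, bonds = bonds, scaffold_atoms = sc)
  }
  out
}

#' Write ligand poses to an SDF file
#'
#' @param poses list of [ligand_pose()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ligand_poses <- function(poses, path) {
  stopifnot(length(poses) > 0,
            all(vapply(poses, inherits, logical(1), "ligand_pose")))
  sdfs <- lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    n <- nrow(p$atoms); nb <- nrow(p$bonds)
    ab <- matrix(0, n, 15,
                 dimnames = list(
                   paste0(p$atoms$element, "_", seq_len(n)),
                   paste0("C", c(1:3, 5:16))))
    ab[, "C1"] <- p$atoms$x
    ab[, "C2"] <- p$atoms$y
    ab[, "C3"] <- p$atoms$z
    code <- CHG_CODE[as.character(p$atoms$formal_charge)]
    if (anyNA(code)) stop("formal charge outside -3..+3 in pose ", i)
    ab[, "C6"] <- code
    bb <- matrix(0L, nb, 4,
                 dimnames = list(seq_len(nb), paste0("C", 1:4)))
    bb[, 1:3] <- p$bonds
    header <- c(
      Molecule_Name = paste0(p$ligand_id, "_pose", i),
      Source = "  rnapose", Comment = "",
      Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                            n, nb))
    db <- c(ligand_id = p$ligand_id, site_tag = p$site_tag,
            conformation_tag = p$conformation_tag,
            program_tag = p$program_tag)
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = header, atomblock = ab, bondblock = bb,
                 datablock = db)
  })
  set <- methods::new(
    methods::getClass("SDFset", where = asNamespace("ChemmineR")),
    SDF = sdfs,
                      ID = vapply(sdfs, function(s)
                        ChemmineR::header(s)[["Molecule_Name"]],
                        character(1)))
  ChemmineR::write.SDF(set, file = path)
  invisible(path)
}
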
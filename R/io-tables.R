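#' Read a ligand affinity table
#'
#' CSV with columns `ligand_id` and `cd50_uM`, where `cd50_uM` is either a
#' positive number (the CD50 in micromolar: the compound concentration
#' achieving 50\% competitive dye displacement) or the literal token
#' `">500"` marking a compound outside the assay range.
#'
#' @param path CSV file.
#' @return data.frame of class `affinity_table` with columns `ligand_id`,
#'   `cd50_uM` (NA when out of range), `out_of_range`, `bound_uM`.
#' @export
read_affinities <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  if (!all(c("ligand_id", "cd50_uM") %in% names(raw))) {
    stop("affinity CSV must have columns ligand_id, cd50_uM")
  }
  affinity_table(raw$ligand_id, raw$cd50_uM)
}

#' @param ligand_id character vector of ligand identifiers.
#' @param cd50 numeric or character vector; `">500"` flags out-of-range.
#' @rdname read_affinities
#' @export
affinity_table <- function(ligand_id, cd50) {
  if (anyDuplicated(ligand_id)) {
    stop("duplicate ligand_id: ",
         paste(unique(ligand_id[duplicated(ligand_id)]), collapse = ", "))
  }
  cd50 <- trimws(as.character(cd50))
  oor <- grepl("^>\\s*500$", cd50)
  val <- suppressWarnings(as.numeric(cd50))
  if (any(!oor & is.na(val))) {
    stop("unparseable cd50_uM value(s): ",
         paste(cd50[!oor & is.na(val)], collapse = ", "))
  }
  if (any(!oor & val <= 0)) {
    stop("non-positive cd50_uM for ligand(s): ",
         paste(ligand_id[!oor & val <= 0], collapse = ", "))
  }
  out <- data.frame(ligand_id = ligand_id,
                    cd50_uM = ifelse(oor, NA_real_, val),
                    out_of_range = oor,
                    bound_uM = 500,
                    stringsAsFactors = FALSE)
  class(out) <- c("affinity_table", "data.frame")
  out
}

#' @param tab an `affinity_table`.
#' @rdname read_affinities
#' @export
write_affinities <- function(tab, path) {
  stopifnot(inherits(tab, "affinity_table"))
  df <- data.frame(ligand_id = tab$ligand_id,
                   cd50_uM = ifelse(tab$out_of_range, ">500",
                                    format(tab$cd50_uM, trim = TRUE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Docking-design manifest
#'
#' Records the combinatorial design of an ensemble docking campaign: the
#' binding sites with their number of receptor conformations (including the
#' crystal conformation when it was docked against), the docking programs,
#' the poses requested per program, and the ligand series.
#'
#' @param sites data.frame with `site_tag`, `n_conformations`.
#' @param programs character vector of program tags.
#' @param poses_per_program positive integer.
#' @param ligand_ids character vector.
#' @return object of class `docking_manifest`.
#' @export
docking_manifest <- function(sites, programs, poses_per_program,
                             ligand_ids) {
  stopifnot(all(c("site_tag", "n_conformations") %in% names(sites)),
            all(sites$n_conformations > 0),
            length(programs) > 0, poses_per_program > 0,
            length(ligand_ids) > 0)
  structure(list(sites = as.data.frame(sites), programs = programs,
                 poses_per_program = as.integer(poses_per_program),
                 ligand_ids = ligand_ids),
            class = "docking_manifest")
}

#' @param path YAML file.
#' @rdname docking_manifest
#' @export
read_docking_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- do.call(rbind, lapply(y$sites, function(s)
    data.frame(site_tag = s$site_tag,
               n_conformations = as.integer(s$n_conformations))))
  docking_manifest(sites, unlist(y$programs),
                   y$poses_per_program, unlist(y$ligand_ids))
}

#' @param manifest a `docking_manifest`.
#' @rdname docking_manifest
#' @export
write_docking_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "docking_manifest"))
  y <- list(
    sites = lapply(seq_len(nrow(manifest$sites)), function(i)
      list(site_tag = manifest$sites$site_tag[i],
           n_conformations = manifest$sites$n_conformations[i])),
    programs = as.list(manifest$programs),
    poses_per_program = manifest$poses_per_program,
    ligand_ids = as.list(manifest$ligand_ids))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Expected pose counts from a docking manifest
#'
#' For each site, a ligand receives `n_conformations x n_programs x
#' poses_per_program` poses; the per-ligand total sums over sites. These
#' are the design totals used to validate ingested pose sets.
#'
#' @param manifest a [docking_manifest()].
#' @return list with `per_site` (named integer vector: poses per ligand at
#'   each site), `per_ligand_total`, `per_conformation` (poses per ligand
#'   per conformation, all programs), and `grand_total` (all ligands).
#' @export
expected_pose_counts <- function(manifest) {
  stopifnot(inherits(manifest, "docking_manifest"))
  per_site <- setNames(
    manifest$sites$n_conformations * length(manifest$programs) *
      manifest$poses_per_program,
    manifest$sites$site_tag)
  total <- sum(per_site)
  list(per_site = per_site,
       per_ligand_total = total,
       per_conformation = length(manifest$programs) *
         manifest$poses_per_program,
       grand_total = total * length(manifest$ligand_ids))
}

#' Scaffold map sidecar
#'
#' YAML mapping each ligand_id to the ordered atom indices of the common
#' scaffold within that ligand's atom numbering. Explicit ordered lists are
#' the canonical (and only chemically well-defined) way to state the
#' scaffold correspondence across a congeneric series.
#'
#' @param path YAML file.
#' @return named list of integer vectors.
#' @export
read_scaffold_map <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(v) as.integer(unlist(v)))
}

#' @param map named list of integer vectors.
#' @rdname read_scaffold_map
#' @export
write_scaffold_map <- function(map, path) {
  yaml::write_yaml(lapply(map, as.integer), path)
  invisible(path)
}
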
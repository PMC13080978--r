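#' Pipeline configuration
#'
#' Paths and thresholds for the full post-docking analysis: ensemble
#' curation (QT on site-restricted eRMSD, cutoff 0.7; centroid retention
#' above 0.7), pose clustering (QT on symmetry-corrected scaffold RMSD,
#' threshold 5 A; top clusters covering 50\% of poses), distance-binned
#' interaction fingerprints (2-8 A, 80 bins), per-site fingerprint PCA
#' and per-cluster affinity regression.
#'
#' @param rna,poses,affinities,manifest,scaffold input file paths (PDB,
#'   SDF, CSV, YAML, YAML).
#' @param out_dir directory for persisted intermediates and the report.
#' @param sites named list mapping site_tag to the residue indices of the
#'   binding region (used for site-restricted eRMSD); NULL = all residues.
#' @param qt_threshold_ensemble,qt_threshold_pose QT diameter cutoffs.
#' @param retain_cutoff centroid retention distance cutoff (eRMSD units).
#' @param coverage pose-cluster coverage fraction for the trend stage.
#' @param fp_config a [fingerprint_config()].
#' @param rules an [interaction_rules()].
#' @param scale,oor affinity regression options (see
#'   [affinity_regression()]).
#' @param min_poses per-(cluster, ligand) floor for mean-PC1 cells.
#' @export
pipeline_config <- function(rna, poses, affinities, manifest, scaffold,
                            out_dir,
                            sites = NULL,
                            qt_threshold_ensemble = 0.7,
                            qt_threshold_pose = 5.0,
                            retain_cutoff = 0.7,
                            coverage = 0.5,
                            fp_config = fingerprint_config(),
                            rules = interaction_rules(),
                            scale = "log10_cd50",
                            oor = "exclude",
                            min_poses = 3L) {
  stopifnot(qt_threshold_ensemble > 0, qt_threshold_pose > 0,
            retain_cutoff > 0, coverage > 0, coverage <= 1)
  structure(list(rna = rna, poses = poses, affinities = affinities,
                 manifest = manifest, scaffold = scaffold,
                 out_dir = out_dir, sites = sites,
                 qt_threshold_ensemble = qt_threshold_ensemble,
                 qt_threshold_pose = qt_threshold_pose,
                 retain_cutoff = retain_cutoff, coverage = coverage,
                 fp_config = fp_config, rules = rules, scale = scale,
                 oor = oor, min_poses = as.integer(min_poses)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Scaffold bond graph of a pose, remapped to scaffold-local indices.
scaffold_graph <- function(pose) {
  sc <- pose$scaffold_atoms
  b <- pose$bonds
  keep <- b[, 1] %in% sc & b[, 2] %in% sc
  bonds <- cbind(match(b[keep, 1], sc), match(b[keep, 2], sc),
                 b[keep, 3])
  list(bonds = bonds, elements = pose$atoms$element[sc])
}

#' Run the full post-docking analysis pipeline
#'
#' Ensemble curation per site, symmetry-corrected pose clustering per
#' site, interaction fingerprints, per-site fingerprint PCA on the
#' retained clusters, per-cluster affinity regression and cluster
#' ranking. All intermediates are persisted under `config$out_dir` so any
#' stage can be inspected or rerun; rerunning with identical config and
#' inputs reproduces identical outputs (the only non-deterministic report
#' field is the timestamp).
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  out <- function(...) file.path(config$out_dir, ...)

  rna <- stage("ingest-rna", read_rna_models(config$rna))
  scaffold_map <- stage("ingest-scaffold",
                        read_scaffold_map(config$scaffold))
  poses <- stage("ingest-poses",
                 read_ligand_poses(config$poses, scaffold_map))
  affinities <- stage("ingest-affinities",
                      read_affinities(config$affinities))
  manifest <- stage("ingest-manifest",
                    read_docking_manifest(config$manifest))
  count_check <- validate_counts(poses, manifest)

  site_tags <- sort(unique(vapply(poses, `[[`, character(1), "site_tag")))
  all_res <- residue_indices(rna$models[[1]])

  # --- ensemble curation per site -----------------------------------
  ensembles <- list()
  for (s in site_tags) {
    res_sel <- config$sites[[s]] %||% all_res
    D <- stage(paste0("curation-", s),
               ermsd_matrix(rna, residues = res_sel))
    cl <- qt_cluster(D, config$qt_threshold_ensemble)
    cents <- select_diverse_centroids(cluster_medoids(cl, D), D,
                                      config$retain_cutoff)
    utils::write.csv(cents, out(paste0("ensemble_", s, ".csv")),
                     row.names = FALSE)
    retained_models <- cents$medoid[cents$retained]
    write_rna_models(rna_model_set(rna$models[retained_models]),
                     out(paste0("ensemble_", s, ".pdb")))
    ensembles[[s]] <- list(clustering = cl, centroids = cents,
                           retained_models = retained_models)
  }

  # --- pose clustering per site -------------------------------------
  pose_clusters <- list()
  for (s in site_tags) {
    idx <- which(vapply(poses, `[[`, character(1), "site_tag") == s)
    sg <- scaffold_graph(poses[[idx[1]]])
    group <- stage(paste0("pose-symmetry-", s),
                   scaffold_automorphisms(sg$bonds, sg$elements))
    D <- stage(paste0("pose-distance-", s),
               pose_distance_matrix(poses[idx], group))
    cl <- stage(paste0("pose-clustering-", s),
                qt_cluster(D, config$qt_threshold_pose))
    top <- select_top_clusters(cl, config$coverage)
    lab_df <- data.frame(
      pose = idx,
      ligand_id = vapply(poses[idx], `[[`, character(1), "ligand_id"),
      cluster = cl$labels,
      in_top = cl$labels %in% top)
    data.table::fwrite(lab_df, out(paste0("pose_clusters_", s, ".csv")))
    pose_clusters[[s]] <- list(pose_index = idx, clustering = cl,
                               top_clusters = top, labels = lab_df,
                               n_automorphisms = length(group))
  }

  # --- interaction fingerprints -------------------------------------
  FP <- stage("fingerprints",
              fingerprint_matrix(poses, rna, config$rules,
                                 config$fp_config))
  data.table::fwrite(
    cbind(attr(FP, "tags"), as.data.frame(FP)), out("fingerprints.csv"))

  # --- per-site PCA, trends, ranking --------------------------------
  trends <- list()
  pca_reports <- list()
  for (s in site_tags) {
    pc_s <- pose_clusters[[s]]
    idx <- pc_s$pose_index
    full_fit <- stage(paste0("pca-full-", s),
                      fit_pca(FP[idx, , drop = FALSE], 2))
    ret_rows <- idx[pc_s$labels$in_top]
    fit <- stage(paste0("pca-", s),
                 fit_pca(FP[ret_rows, , drop = FALSE], 2))
    prof <- loading_profile(fit, 1L, config$fp_config)
    ligs <- vapply(poses[ret_rows], `[[`, character(1), "ligand_id")
    labs <- pc_s$labels$cluster[pc_s$labels$in_top]
    means <- cluster_mean_pc(fit$scores[, 1], labs, ligs,
                             config$min_poses)
    data.table::fwrite(cbind(
      data.frame(pose = ret_rows, ligand_id = ligs, cluster = labs),
      data.frame(pc1 = fit$scores[, 1], pc2 = fit$scores[, 2])),
      out(paste0("pca_scores_", s, ".csv")))
    data.table::fwrite(prof$spans, out(paste0("loading_spans_", s, ".csv")))
    for (cid in pc_s$top_clusters) {
      mm <- means[means$cluster_id == cid, , drop = FALSE]
      tr <- tryCatch(
        affinity_regression(mm, affinities, scale = config$scale,
                            oor = config$oor),
        error = function(e) NULL)
      if (!is.null(tr)) trends[[paste0(s, "/", cid)]] <- tr
    }
    pca_reports[[s]] <- list(
      explained_variance_full = full_fit$explained_variance,
      explained_variance_retained = fit$explained_variance,
      loading_spans = prof$spans,
      cluster_means = means)
  }
  if (!length(trends)) {
    stop("pipeline stage 'trends' failed: no cluster produced a usable ",
         "affinity regression", call. = FALSE)
  }
  ranking <- rank_clusters(trends)
  data.table::fwrite(ranking, out("cluster_ranking.csv"))

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  tf <- tempfile()
  saveRDS(cfg_for_hash, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  report <- structure(list(
    counts = list(
      n_models = length(rna$models),
      n_residues = length(all_res),
      n_poses = length(poses),
      n_ligands = nrow(affinities),
      poses_per_site = vapply(pose_clusters, function(p)
        length(p$pose_index), integer(1)),
      ensemble_clusters = vapply(ensembles, function(e)
        length(e$clustering$clusters), integer(1)),
      retained_centroids = vapply(ensembles, function(e)
        length(e$retained_models), integer(1)),
      pose_cluster_sizes = lapply(pose_clusters, function(p)
        lengths(p$clustering$clusters)),
      top_cluster_coverage = vapply(pose_clusters, function(p) {
        sz <- lengths(p$clustering$clusters)
        sum(sz[p$top_clusters]) / sum(sz)
      }, numeric(1)),
      count_discrepancies = sum(count_check$difference != 0)),
    ensembles = ensembles,
    pose_clusters = pose_clusters,
    pca = pca_reports,
    trends = trends,
    ranking = ranking,
    top_cluster = ranking$cluster[1],
    count_check = count_check,
    provenance = list(
      package_version = as.character(utils::packageVersion("rnapose")),
      config_hash = cfg_hash,
      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")
  json <- report_to_json(report)
  writeLines(json, out("report.json"))
  report
}

report_to_json <- function(report) {
  slim <- list(
    counts = report$counts,
    ranking = report$ranking,
    top_cluster = report$top_cluster,
    trends = lapply(report$trends, function(t)
      t[c("slope", "intercept", "r_squared", "n_ligands",
          "affinity_scale")]),
    pca = lapply(report$pca, function(p)
      list(explained_variance_full = p$explained_variance_full,
           explained_variance_retained = p$explained_variance_retained,
           loading_spans = p$loading_spans)),
    provenance = report$provenance)
  jsonlite::toJSON(slim, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   dataframe = "rows")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  models:", x$counts$n_models, " poses:", x$counts$n_poses,
      " ligands:", x$counts$n_ligands, "\n")
  cat("  retained centroids:",
      paste(names(x$counts$retained_centroids),
            x$counts$retained_centroids, sep = "=", collapse = ", "), "\n")
  cat("  top cluster:", x$top_cluster, sprintf(
    "(R^2 = %.3f)", x$ranking$r_squared[1]), "\n")
  invisible(x)
}

#' Validate ingested pose counts against the docking design
#'
#' Compares per-(ligand, site) pose counts with [expected_pose_counts()];
#' discrepancies are reported (with a warning), never fatal.
#'
#' @param poses list of [ligand_pose()] objects.
#' @param manifest a [docking_manifest()].
#' @return data.frame with `ligand_id`, `site_tag`, `expected`,
#'   `observed`, `difference`.
#' @export
validate_counts <- function(poses, manifest) {
  exp_counts <- expected_pose_counts(manifest)
  grid <- expand.grid(ligand_id = manifest$ligand_ids,
                      site_tag = manifest$sites$site_tag,
                      stringsAsFactors = FALSE)
  grid$expected <- exp_counts$per_site[grid$site_tag]
  obs <- table(
    paste(vapply(poses, `[[`, character(1), "ligand_id"),
          vapply(poses, `[[`, character(1), "site_tag"), sep = "\r"))
  key <- paste(grid$ligand_id, grid$site_tag, sep = "\r")
  grid$observed <- as.integer(ifelse(key %in% names(obs), obs[key], 0L))
  grid$difference <- grid$observed - grid$expected
  if (any(grid$difference != 0)) {
    warning(sum(grid$difference != 0),
            " (ligand, site) cell(s) deviate from the design counts")
  }
  grid
}
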
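#' Mean-centered PCA with a deterministic sign convention
#'
#' PCA via singular value decomposition on mean-centered (unscaled)
#' features. Each component is oriented so that its largest-magnitude
#' loading is positive, making score signs reproducible across runs.
#' Zero-variance input yields all-zero scores with a warning.
#'
#' @param features items x d numeric matrix.
#' @param n_components number of components to keep (default all).
#' @return object of class `pca_model`: list with `loadings` (d x k),
#'   `explained_variance` (ratios, non-increasing), `center` (feature
#'   means), `scores` (items x k).
#' @export
fit_pca <- function(features, n_components = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 items")
  k_max <- min(nrow(features) - 1L, ncol(features))
  k <- min(n_components %||% k_max, k_max)
  ctr <- colMeans(features)
  X <- sweep(features, 2, ctr)
  tot <- sum(X^2)
  if (tot < 1e-12) {
    warning("zero-variance input: all scores set to 0")
    return(structure(list(
      loadings = matrix(0, ncol(features), k),
      explained_variance = rep(0, k), center = ctr,
      scores = matrix(0, nrow(features), k)), class = "pca_model"))
  }
  sv <- svd(X, nu = k, nv = k)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  # sign convention: largest |loading| positive, per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- sv$d^2 / tot
  structure(list(loadings = loadings,
                 explained_variance = evr[seq_len(k)],
                 center = ctr, scores = scores),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", nrow(x$scores), "items,", ncol(x$scores),
      "components; explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-category loading profile of a fingerprint PCA component
#'
#' Reshapes a component's loadings back to the 7 x n_bins fingerprint
#' layout and reports, per category, the contiguous distance span (the run
#' of consecutive bins around the category's absolute-loading maximum)
#' where |loading| exceeds `threshold_frac` of the component's global
#' maximum. Distances are labeled by bin lower edge.
#'
#' @param model a [fit_pca()] result fitted on fingerprint bins.
#' @param component component index (default 1).
#' @param config the [fingerprint_config()] the fingerprints used.
#' @param threshold_frac fraction of the global max |loading| (default
#'   0.1) a bin must exceed to enter a span.
#' @return list with `profile` (7 x n_bins loading matrix) and `spans`
#'   (data.frame: category, d_lo, d_hi, sign, peak_loading; NA rows for
#'   categories with no bins above threshold).
#' @export
loading_profile <- function(model, component = 1L,
                            config = fingerprint_config(),
                            threshold_frac = 0.1) {
  stopifnot(inherits(model, "pca_model"))
  v <- model$loadings[, component]
  nb <- config$n_bins
  if (length(v) != length(FP_CATEGORIES) * nb) {
    stop("loadings are not fingerprint-shaped (expected ",
         length(FP_CATEGORIES) * nb, " features, got ", length(v), ")")
  }
  edges <- config$d_min + config$width * (0:(nb - 1))
  P <- matrix(v, nrow = length(FP_CATEGORIES), byrow = TRUE,
              dimnames = list(FP_CATEGORIES, format(edges, trim = TRUE)))
  thr <- threshold_frac * max(abs(v))
  spans <- do.call(rbind, lapply(FP_CATEGORIES, function(cat) {
    w <- abs(P[cat, ])
    above <- w > thr
    if (!any(above) || thr == 0) {
      return(data.frame(category = cat, d_lo = NA_real_, d_hi = NA_real_,
                        sign = NA_real_, peak_loading = NA_real_))
    }
    peak <- which.max(w)
    lo <- peak
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- peak
    while (hi < nb && above[hi + 1]) hi <- hi + 1
    data.frame(category = cat, d_lo = edges[lo], d_hi = edges[hi],
               sign = sign(P[cat, peak]), peak_loading = P[cat, peak])
  }))
  list(profile = P, spans = spans)
}

#' Per-cluster, per-ligand mean PC scores
#'
#' Arithmetic mean of PC1 over each ligand's poses within each cluster;
#' (cluster, ligand) cells with fewer than `min_poses` poses are reported
#' as missing (NA).
#'
#' @param scores numeric vector (PC1 score per pose) or matrix whose first
#'   column is used.
#' @param clusters integer cluster label per pose.
#' @param ligands ligand id per pose.
#' @param min_poses minimum poses per cell for a reported mean (default 3).
#' @return data.frame with `cluster_id`, `ligand_id`, `mean_pc1`, `n`.
#' @export
cluster_mean_pc <- function(scores, clusters, ligands, min_poses = 3L) {
  if (is.matrix(scores)) scores <- scores[, 1]
  stopifnot(length(scores) == length(clusters),
            length(scores) == length(ligands))
  df <- data.frame(cluster_id = clusters, ligand_id = ligands, s = scores)
  agg <- stats::aggregate(s ~ cluster_id + ligand_id, df,
                          function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(cluster_id = agg$cluster_id,
                    ligand_id = agg$ligand_id,
                    mean_pc1 = agg$s[, "mean"],
                    n = as.integer(agg$s[, "n"]))
  out$mean_pc1[out$n < min_poses] <- NA_real_
  out[order(out$cluster_id, out$ligand_id), , drop = FALSE]
}

#' Regression of affinity on mean PC1 score
#'
#' Ordinary least squares of the experimental affinity (CD50, raw or
#' log10) on the per-ligand mean PC1 score of one cluster. R^2 is the
#' squared Pearson correlation. Out-of-range ligands (">500 uM") are
#' excluded by default; `oor = "cap"` instead enters them at the 500 uM
#' bound (sensitivity analysis).
#'
#' @param means data.frame with `ligand_id` and `mean_pc1` (one cluster's
#'   rows of [cluster_mean_pc()]).
#' @param affinities an [affinity_table()].
#' @param scale `"log10_cd50"` (default: affinities span orders of
#'   magnitude) or `"raw_cd50"`.
#' @param oor `"exclude"` (default) or `"cap"`.
#' @return object of class `trend_result`: list with `slope`, `intercept`,
#'   `r_squared`, `n_ligands`, `affinity_scale`, `data`.
#' @export
affinity_regression <- function(means, affinities,
                                scale = c("log10_cd50", "raw_cd50"),
                                oor = c("exclude", "cap")) {
  scale <- match.arg(scale)
  oor <- match.arg(oor)
  stopifnot(inherits(affinities, "affinity_table"))
  aff <- affinities
  y_raw <- ifelse(aff$out_of_range,
                  if (oor == "cap") aff$bound_uM else NA_real_,
                  aff$cd50_uM)
  idx <- match(means$ligand_id, aff$ligand_id)
  df <- data.frame(ligand_id = means$ligand_id,
                   x = means$mean_pc1,
                   y = y_raw[idx])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3) stop("fewer than 3 ligands with both a mean PC1 ",
                         "and a usable affinity")
  if (scale == "log10_cd50") df$y <- log10(df$y)
  if (stats::sd(df$x) < 1e-12) stop("zero-variance predictor")
  if (stats::sd(df$y) < 1e-12) {
    warning("constant response; R^2 reported as 0")
    r2 <- 0
    fit <- stats::lm(y ~ x, df)
  } else {
    fit <- stats::lm(y ~ x, df)
    r2 <- stats::cor(df$x, df$y)^2
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_ligands = nrow(df),
                 affinity_scale = scale,
                 data = df),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> R^2 = %.3f (slope %.3g, n = %d, %s)\n",
              x$r_squared, x$slope, x$n_ligands, x$affinity_scale))
  invisible(x)
}

#' Rank clusters by affinity-trend strength
#'
#' Descending sort of per-cluster trend results by R^2; the top entry is
#' the cluster whose binding mode best rationalizes the affinity series.
#'
#' @param trends named list of [affinity_regression()] results (names =
#'   cluster identifiers, e.g. "S1/3").
#' @return data.frame with `cluster`, `r_squared`, `slope`, `n_ligands`,
#'   ordered by decreasing `r_squared`.
#' @export
rank_clusters <- function(trends) {
  if (!length(trends)) stop("no trend results to rank")
  out <- data.frame(
    cluster = names(trends) %||% as.character(seq_along(trends)),
    r_squared = vapply(trends, `[[`, numeric(1), "r_squared"),
    slope = vapply(trends, `[[`, numeric(1), "slope"),
    n_ligands = vapply(trends, `[[`, integer(1), "n_ligands"),
    row.names = NULL)
  out[order(-out$r_squared), , drop = FALSE]
}
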
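# Pipeline orchestration: configuration, the snc() fit object, artifact
# writing and provenance.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the Select-and-Cluster pipeline with
#' the stock defaults: significance level 0.05 with Bonferroni correction at
#' both correlation scales, at least 4 significant connections per coarse
#' voxel, 20 interior samples per path segment and a hard-margin sphere.
#'
#' @param alpha_select significance level of the voxel-selection passes.
#' @param alpha_network significance level of the ROI-network pass.
#' @param min_connections coarse-scale minimum significant-edge count.
#' @param correction `"bonferroni"` or `"fdr"`.
#' @param fwhm_mm length-3 smoothness in mm, or `"estimate"` to measure it
#'   from the data.
#' @param n_components number of functional components P, or `"auto"` for
#'   the MDL order of the selected-voxel series.
#' @param soft_margin_c SVC box constraint in (0, 1].
#' @param n_path_samples interior samples for the SVC segment test.
#' @param seed integer seed recorded in the provenance block.
#' @param parcellation_path optional path to an integer NIfTI label volume
#'   used to pre-partition the selected voxels before clustering.
#' @param parcel_block_mm optional physical size (mm) of a built-in
#'   axis-aligned block parcellation (used when no label volume is given;
#'   `NULL` disables parcellation).
#' @return a list of class `"snc_config"`.
#' @export
snc_config <- function(alpha_select = 0.05, alpha_network = 0.05,
                       min_connections = 4L,
                       correction = c("bonferroni", "fdr"),
                       fwhm_mm = "estimate", n_components = "auto",
                       soft_margin_c = 1, n_path_samples = 20L, seed = 1L,
                       parcellation_path = NULL, parcel_block_mm = NULL) {
  correction <- match.arg(correction)
  stopifnot(alpha_select > 0, alpha_select < 1,
            alpha_network > 0, alpha_network < 1,
            soft_margin_c > 0, soft_margin_c <= 1, n_path_samples >= 1)
  structure(list(alpha_select = alpha_select, alpha_network = alpha_network,
                 min_connections = as.integer(min_connections),
                 correction = correction, fwhm_mm = fwhm_mm,
                 n_components = n_components, soft_margin_c = soft_margin_c,
                 n_path_samples = as.integer(n_path_samples),
                 seed = as.integer(seed),
                 parcellation_path = parcellation_path,
                 parcel_block_mm = parcel_block_mm),
            class = "snc_config")
}

# axis-aligned super-block parcellation of selected voxel coordinates
block_parcellation <- function(ijk, voxel_size_mm, block_mm) {
  b <- pmax(1L, round(block_mm / voxel_size_mm))
  key <- (ijk[, 1] - 1L) %/% b[1] + 4096L * ((ijk[, 2] - 1L) %/% b[2]) +
    4096L^2 * ((ijk[, 3] - 1L) %/% b[3])
  match(key, unique(key))
}

#' Fit the Select-and-Cluster model to a 4D volume
#'
#' Runs the full pipeline: multiscale correlation voxel selection, SVD
#' feature extraction with MDL model-order selection, spatiofunctional
#' Support Vector Clustering of the selected voxels, and the ROI-level
#' Bonferroni correlation network.
#'
#' @param vs a [volume_series()].
#' @param config a [snc_config()].
#' @param select if `FALSE`, skip the selection step and cluster every
#'   in-mask voxel (the configuration used for the hybrid benchmark, where
#'   the clustering itself is under evaluation).
#' @return object of class `"snc"`: list with `selection`, `features`,
#'   `clusters`, `graph` (NULL when fewer than 2 ROIs), `fwhm_mm`,
#'   `n_components`, `config`, `call`.
#' @examples
#' \donttest{
#' ph <- default_network_phantom(seed = 2)
#' fit <- snc(ph$vs, snc_config(seed = 2))
#' print(fit)
#' }
#' @export
snc <- function(vs, config = snc_config(), select = TRUE) {
  stopifnot(inherits(vs, "volume_series"))
  set.seed(config$seed)
  fwhm <- if (identical(config$fwhm_mm, "estimate"))
    estimate_fwhm(vs) else as.numeric(config$fwhm_mm)

  if (select) {
    selection <- select_voxels(vs, alpha = config$alpha_select,
                               correction = config$correction,
                               min_connections = config$min_connections,
                               fwhm_mm = fwhm)
    if (!any(selection$mask))
      stop("empty selection: no voxel shows significant connectivity at ",
           "alpha = ", config$alpha_select)
    sel_mask <- selection$mask
  } else {
    selection <- NULL
    sel_mask <- vs$mask
  }
  d <- dim(vs$data)
  keep <- which(sel_mask)
  flat <- matrix(vs$data, prod(d[1:3]), d[4])
  series <- flat[keep, , drop = FALSE]
  ijk <- mask_coords(sel_mask)
  coords <- voxel_to_mm(ijk, vs$voxel_size_mm)

  P <- config$n_components
  if (identical(P, "auto")) {
    ev <- temporal_eigenvalues(series)
    ev <- ev[ev > max(ev) * 1e-12]
    P <- model_order(ev, n_samples = nrow(series))
  }
  feats <- svd_features(series, coords, P)
  kp <- estimate_gammas(fwhm, feats, soft_margin_c = config$soft_margin_c)

  parcel <- NULL
  if (!is.null(config$parcellation_path)) {
    lab <- as.array(RNifti::readNifti(config$parcellation_path))
    parcel <- as.integer(lab[keep])
  } else if (!is.null(config$parcel_block_mm)) {
    parcel <- block_parcellation(ijk, vs$voxel_size_mm,
                                 config$parcel_block_mm)
  }
  clusters <- svc_cluster(feats, kp = kp, parcellation = parcel,
                          n_path_samples = config$n_path_samples,
                          series = series)
  graph <- if (nrow(clusters$roi_table) >= 2L)
    roi_graph(clusters, alpha = config$alpha_network) else NULL

  structure(list(selection = selection, features = feats,
                 clusters = clusters, graph = graph, fwhm_mm = fwhm,
                 n_components = P, ijk = ijk, dim = d,
                 voxel_size_mm = vs$voxel_size_mm, config = config,
                 call = match.call()),
            class = "snc")
}

#' @export
print.snc <- function(x, ...) {
  cat("Select-and-Cluster fit\n")
  cat(sprintf("  smoothness (FWHM): %s mm\n",
              paste(signif(x$fwhm_mm, 3), collapse = ", ")))
  if (!is.null(x$selection))
    cat(sprintf("  selected voxels: %d\n", sum(x$selection$mask)))
  cat(sprintf("  functional components: %d\n", x$n_components))
  cat(sprintf("  ROIs: %d\n", nrow(x$clusters$roi_table)))
  if (!is.null(x$graph))
    cat(sprintf("  significant ROI-ROI connections: %d\n",
                sum(x$graph$adjacency) / 2))
  invisible(x)
}

#' @export
summary.snc <- function(object, ...) {
  tab <- object$clusters$roi_table
  cat("Select-and-Cluster fit\n\n")
  print.snc(object)
  cat("\nROI table (largest 10):\n")
  print(utils::head(tab[order(-tab$n_voxels), ], 10), row.names = FALSE)
  invisible(object)
}

#' Cluster label volume of an snc fit
#'
#' @param object an `"snc"` fit.
#' @param ... unused.
#' @return 3D integer array of ROI ids (0 outside the clustered set).
#' @export
labels.snc <- function(object, ...) {
  lab <- array(0L, object$dim[1:3])
  lin <- object$ijk[, 1] + (object$ijk[, 2] - 1L) * object$dim[1] +
    (object$ijk[, 3] - 1L) * object$dim[1] * object$dim[2]
  lab[lin] <- object$clusters$labels
  lab
}

#' Plot the ROI label map of an snc fit
#'
#' Displays one axial slice of the cluster label volume.
#'
#' @param x an `"snc"` fit.
#' @param z slice index (default: the slice containing most labelled
#'   voxels).
#' @param ... passed to [graphics::image()].
#' @export
plot.snc <- function(x, z = NULL, ...) {
  lab <- labels.snc(x)
  if (is.null(z)) z <- which.max(apply(lab > 0, 3, sum))
  m <- max(lab)
  graphics::image(lab[, , z], col = c("grey95", grDevices::hcl.colors(max(m, 2), "Dark 3")),
                  axes = FALSE, asp = 1, ...)
  graphics::title(sprintf("ROI labels, slice z = %d (%d ROIs)", z, m))
  invisible(x)
}

#' Run the pipeline and write all artifacts to a directory
#'
#' Executes [snc()] and writes: the selection mask and ROI label volume as
#' NIfTI, fine-scale and ROI-level edge lists as TSV, the ROI graph as
#' GraphML, the ROI table as TSV, and a JSON provenance block (configuration,
#' its MD5 hash, seed, package version). Reruns with identical data,
#' configuration and seed produce identical outputs.
#'
#' @param config a [snc_config()].
#' @param vs a [volume_series()].
#' @param out_dir output directory (created if missing).
#' @param select passed to [snc()].
#' @return the `"snc"` fit, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, vs, out_dir, select = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- snc(vs, config, select = select)
  if (!is.null(fit$selection)) {
    write_label_volume(array(as.integer(fit$selection$mask),
                             fit$dim[1:3]), vs$voxel_size_mm,
                       file.path(out_dir, "selection_mask.nii.gz"))
    if (!is.null(fit$selection$fine_graph))
      write_edges_tsv(fit$selection$fine_graph, fit$selection$fine_ijk,
                      file.path(out_dir, "fine_edges.tsv"))
  }
  write_label_volume(labels.snc(fit), vs$voxel_size_mm,
                     file.path(out_dir, "roi_labels.nii.gz"))
  utils::write.table(fit$clusters$roi_table,
                     file.path(out_dir, "roi_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_features_tsv(fit$features, file.path(out_dir, "features.tsv"))
  if (!is.null(fit$graph))
    write_roi_graph(fit$graph, file.path(out_dir, "roi_graph"))
  cfg_json <- jsonlite::toJSON(unclass(fit$config), auto_unbox = TRUE,
                               null = "null", digits = NA)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  prov <- list(config = unclass(fit$config),
               config_md5 = unname(tools::md5sum(tf)),
               seed = fit$config$seed,
               fwhm_mm = fit$fwhm_mm,
               n_components = fit$n_components,
               package_version = as.character(utils::packageVersion("snclust")))
  unlink(tf)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(fit)
}

#' Evaluate a predicted label volume against a binary truth volume
#'
#' Convenience wrapper comparing two NIfTI label images with
#' [weighted_jaccard()] and [fowlkes_mallows()].
#'
#' @param pred_path NIfTI with predicted integer labels.
#' @param truth_path NIfTI with truth labels (0 background).
#' @param json_path optional output path for the metrics as JSON.
#' @return list with `weighted_jaccard`, `fowlkes_mallows` and the pair
#'   confusion counts.
#' @export
evaluate_labels <- function(pred_path, truth_path, json_path = NULL) {
  pred <- as.integer(as.array(RNifti::readNifti(pred_path)))
  truth <- as.integer(as.array(RNifti::readNifti(truth_path)))
  wjc <- weighted_jaccard(pred, truth)
  pc <- pair_confusion(pred, truth)
  out <- list(weighted_jaccard = as.numeric(wjc),
              activation_cluster = attr(wjc, "activation_cluster"),
              tp = attr(wjc, "a"), fn = attr(wjc, "b"), fp = attr(wjc, "c"),
              fowlkes_mallows = fowlkes_mallows(pc),
              pair_confusion = unclass(pc))
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  out
}
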
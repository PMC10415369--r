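#' Aggregate per-iteration model weights into voxel maps
#'
#' Feature-importance maps are a reconstruction built from the stored
#' per-iteration models: for every mask voxel, the mean weight across
#' iterations and the *sign consistency* — the fraction of iterations whose
#' weight sign agrees with the sign of the mean. Voxels outside the mask are
#' exactly zero. Mean weight and sign consistency jointly flag voxels that
#' contribute strongly and stably; they are descriptive, not a statistical
#' thresholding, and a feature's contribution always depends on the other
#' features in the model.
#'
#' @param x an iterations-by-voxels weight matrix, or a fitted
#'   [gmd_rsplit()] object (with `keep_weights = TRUE`).
#' @param mask the `gmd_mask` defining voxel placement (taken from the fit
#'   when `x` is a `gmd_rsplit`).
#' @param model for a `gmd_rsplit`, which model's weights to aggregate.
#' @param ... passed between methods.
#' @return An object of class `gmd_weight_maps`: `mean_weight` and
#'   `sign_consistency` (3D arrays), `n_iterations`, `model`, `mask`.
#' @export
aggregate_weights <- function(x, ...) UseMethod("aggregate_weights")

#' @rdname aggregate_weights
#' @export
aggregate_weights.matrix <- function(x, mask, model = "", ...) {
  stopifnot(inherits(mask, "gmd_mask"))
  idx <- mask_indices(mask)
  if (ncol(x) != length(idx))
    stop(sprintf("weight length %d does not match mask population %d",
                 ncol(x), length(idx)))
  mw <- colMeans(x)
  cons <- colMeans(sign(x) == rep(sign(mw), each = nrow(x)))
  dims <- dim(mask$volume)
  mean_vol <- array(0, dims); mean_vol[idx] <- mw
  cons_vol <- array(0, dims); cons_vol[idx] <- cons
  structure(list(mean_weight = mean_vol, sign_consistency = cons_vol,
                 n_iterations = nrow(x), model = model, mask = mask),
            class = "gmd_weight_maps")
}

#' @rdname aggregate_weights
#' @export
aggregate_weights.gmd_rsplit <- function(x, mask = x$mask,
                                         model = x$groups[1L], ...) {
  if (is.null(x$weights)) stop("fit was run with keep_weights = FALSE")
  if (is.null(mask)) stop("no mask stored in the fit; pass one explicitly")
  aggregate_weights(x$weights[[model]], mask, model = model)
}

#' @export
print.gmd_weight_maps <- function(x, ...) {
  idx <- mask_indices(x$mask)
  cat(sprintf("Weight maps (%s model, %d iterations): %d mask voxels\n",
              x$model, x$n_iterations, length(idx)))
  cat(sprintf("  mean weight range [%.2e, %.2e]; median consistency %.2f\n",
              min(x$mean_weight[idx]), max(x$mean_weight[idx]),
              stats::median(x$sign_consistency[idx])))
  invisible(x)
}

#' Write weight maps as NIfTI volumes
#'
#' One file per map (`<prefix>_mean.nii.gz`, `<prefix>_consistency.nii.gz`),
#' with the affine copied from the mask.
#'
#' @param map_set a `gmd_weight_maps`.
#' @param path_prefix output path prefix (directories created as needed).
#' @return Invisibly, the two file paths.
#' @export
write_map_nifti <- function(map_set, path_prefix) {
  stopifnot(inherits(map_set, "gmd_weight_maps"))
  dir.create(dirname(path_prefix), showWarnings = FALSE, recursive = TRUE)
  f1 <- paste0(path_prefix, "_mean.nii.gz")
  f2 <- paste0(path_prefix, "_consistency.nii.gz")
  write_volume(map_set$mean_weight, map_set$mask$affine, f1)
  write_volume(map_set$sign_consistency, map_set$mask$affine, f2)
  invisible(c(f1, f2))
}

#' Count of high-consistency, high-magnitude voxels
#'
#' A simple summary used to compare the spatial extent of stable features
#' across models: voxels whose sign consistency exceeds
#' `consistency_threshold` and whose absolute mean weight lies above the
#' `magnitude_quantile` of the in-mask absolute mean weights.
#'
#' @param map_set a `gmd_weight_maps`.
#' @param consistency_threshold minimum sign consistency (default 0.9).
#' @param magnitude_quantile quantile of |mean weight| (default 0.95).
#' @param magnitude_threshold absolute |mean weight| cutoff; overrides the
#'   quantile when given (use a common value to compare models).
#' @return Integer count.
#' @export
count_consistent_voxels <- function(map_set, consistency_threshold = 0.9,
                                    magnitude_quantile = 0.95,
                                    magnitude_threshold = NULL) {
  idx <- mask_indices(map_set$mask)
  aw <- abs(map_set$mean_weight[idx])
  thr <- magnitude_threshold %||%
    stats::quantile(aw, magnitude_quantile, names = FALSE)
  sum(map_set$sign_consistency[idx] > consistency_threshold & aw > thr)
}
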
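#' Mask configuration
#'
#' Thresholds for the grey-matter voxel mask and the smoothing kernel width.
#' A voxel enters the mask iff its grey-matter probability is strictly above
#' `gm_threshold` and its white-matter probability strictly below
#' `wm_threshold`; the defaults (0.40 / 0.60) restrict analysis to grey
#' matter while limiting partial-volume and white-matter contamination.
#'
#' @param gm_threshold lower bound on grey-matter probability (strict).
#' @param wm_threshold upper bound on white-matter probability (strict).
#' @param fwhm_mm Gaussian smoothing full width at half maximum, mm.
#' @return An object of class `mask_config`.
#' @export
mask_config <- function(gm_threshold = 0.40, wm_threshold = 0.60, fwhm_mm = 8) {
  if (gm_threshold < 0 || gm_threshold > 1 || wm_threshold < 0 || wm_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  structure(list(gm_threshold = gm_threshold, wm_threshold = wm_threshold,
                 fwhm_mm = fwhm_mm), class = "mask_config")
}

#' Build the grey-matter voxel mask
#'
#' Applies the two-criterion rule to a pair of template tissue-probability
#' volumes: include voxel \eqn{v} iff \eqn{gm(v) >} `gm_threshold` and
#' \eqn{wm(v) <} `wm_threshold`, both strict. The mask fixes the voxel
#' linearization used by every downstream feature matrix: included voxels
#' are ordered by ascending linear index in the column-major storage order
#' of the volume.
#'
#' @param gm_prob,wm_prob 3D arrays (or `RNifti` images) of grey-/white-
#'   matter tissue probability; must share shape (and affine, if images).
#' @param config a [mask_config()].
#' @param affine optional 4x4 voxel-to-mm transform; taken from `gm_prob`
#'   when it is a NIfTI image, identity-scaled otherwise.
#' @return An object of class `gmd_mask`: `volume` (logical 3D array),
#'   `affine`, `voxel_order` (description of the linearization rule),
#'   `n_voxels`.
#' @export
build_gm_mask <- function(gm_prob, wm_prob, config = mask_config(),
                          affine = NULL) {
  ga <- volume_affine(gm_prob)
  wa <- volume_affine(wm_prob)
  gm <- as.array(gm_prob); wm <- as.array(wm_prob)
  if (!identical(dim(gm), dim(wm)))
    stop("gm and wm volumes have different shapes")
  if (!is.null(ga) && !is.null(wa) && max(abs(ga - wa)) > 1e-4)
    stop("gm and wm volumes have different affines")
  affine <- affine %||% ga %||% diag(4)
  vol <- (gm > config$gm_threshold) & (wm < config$wm_threshold)
  if (!any(vol))
    stop(sprintf(paste0("empty mask: no voxel satisfies gm > %g and ",
                        "wm < %g"), config$gm_threshold, config$wm_threshold))
  structure(list(volume = vol, affine = affine,
                 voxel_order = "ascending linear index (column-major)",
                 n_voxels = sum(vol)), class = "gmd_mask")
}

volume_affine <- function(x) {
  if (inherits(x, "niftiImage")) structure(RNifti::xform(x), class = NULL)
  else attr(x, "affine", exact = TRUE)
}

#' @export
print.gmd_mask <- function(x, ...) {
  cat(sprintf("Grey-matter mask: %d of %d voxels (%s)\n", x$n_voxels,
              length(x$volume), paste(dim(x$volume), collapse = " x ")))
  invisible(x)
}

#' Voxel indices of a mask
#'
#' Linear indices (column-major) of the included voxels, in the order that
#' defines the feature-matrix columns.
#' @param mask a `gmd_mask`.
#' @return Integer vector of length `mask$n_voxels`.
#' @export
mask_indices <- function(mask) {
  stopifnot(inherits(mask, "gmd_mask"))
  which(mask$volume)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian smoothing with \eqn{\sigma = \mathrm{FWHM} /
#' (2\sqrt{2\ln 2})} per axis, converted to voxel units. The kernel is
#' truncated at 4 sigma and renormalized at the edges (normalized
#' convolution), so constants are preserved everywhere and mass is preserved
#' on the interior.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_size_mm isotropic voxel edge length, > 0.
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm) {
  if (!(voxel_size_mm > 0)) stop("`voxel_size_mm` must be positive")
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  vol <- as.array(vol)
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  for (ax in 1:3) vol <- convolve_axis(vol, kern, ax)
  vol
}

# 1D convolution along one axis via a row-renormalized band matrix.
convolve_axis <- function(vol, kern, axis) {
  d <- dim(vol)
  r <- (length(kern) - 1L) / 2L
  n <- d[axis]
  K <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    i <- seq_len(n)
    keep <- i + j >= 1L & i + j <= n
    K[cbind(i[keep], (i + j)[keep])] <- kern[j + r + 1L]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  v <- K %*% matrix(v, nrow = n)
  v <- array(v, d[perm])
  aperm(v, order(perm))
}

#' Extract the subjects-by-voxels GMD feature matrix
#'
#' Reads each subject's volume at the mask coordinates. Rows follow the
#' order of `subject_ids`; columns follow the mask's voxel order.
#'
#' @param images a `gmd_cohort`, a 4D array (x-y-z-subject), or a named list
#'   of 3D arrays / NIfTI file paths.
#' @param mask a `gmd_mask` whose shape the images must match.
#' @param subject_ids row names; required for a 4D array, defaults to the
#'   cohort table or list names otherwise.
#' @return An object of class `gmd_features`: `values` (numeric matrix with
#'   subject-id rownames), `subject_ids`, `mask`.
#' @export
extract_features <- function(images, mask, subject_ids = NULL) {
  stopifnot(inherits(mask, "gmd_mask"))
  idx <- mask_indices(mask)
  dm <- dim(mask$volume)
  if (inherits(images, "gmd_cohort")) {
    subject_ids <- subject_ids %||% images$subjects$id
    images <- images$gmd
  }
  if (is.array(images) && length(dim(images)) == 4L) {
    if (!identical(dim(images)[1:3], dm))
      stop("image shape does not match the mask")
    if (is.null(subject_ids)) stop("`subject_ids` required for array input")
    n <- dim(images)[4L]
    if (length(subject_ids) != n) stop("one id per subject required")
    flat <- matrix(images, nrow = prod(dm), ncol = n)
    vals <- t(flat[idx, , drop = FALSE])
  } else if (is.list(images)) {
    subject_ids <- subject_ids %||% names(images)
    if (is.null(subject_ids)) stop("`subject_ids` required for list input")
    missing <- subject_ids[!subject_ids %in% names(images)]
    if (length(missing))
      stop("missing image(s) for subject(s): ", paste(missing, collapse = ", "))
    vals <- matrix(NA_real_, length(subject_ids), length(idx))
    for (i in seq_along(subject_ids)) {
      im <- images[[subject_ids[i]]]
      if (is.character(im)) im <- as.array(RNifti::readNifti(im))
      im <- as.array(im)
      if (!identical(dim(im), dm))
        stop("image for ", subject_ids[i], " does not match the mask shape")
      vals[i, ] <- im[idx]
    }
  } else stop("unsupported `images` type")
  rownames(vals) <- subject_ids
  structure(list(values = vals, subject_ids = subject_ids, mask = mask),
            class = "gmd_features")
}

#' @export
print.gmd_features <- function(x, ...) {
  cat(sprintf("GMD feature matrix: %d subjects x %d voxels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write / read NIfTI volumes and masks
#'
#' `write_volume()` writes a plain array with a given affine; `write_mask()`
#' serializes a `gmd_mask` as a uint8 NIfTI whose header description records
#' the voxel linearization rule; `read_mask()` restores it.
#'
#' @param vol 3D array. @param affine 4x4 transform. @param path output file.
#' @return The path, invisibly (`read_mask` returns a `gmd_mask`).
#' @export
write_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(as.array(vol))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param mask a `gmd_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "gmd_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$volume), dim(mask$volume)),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  img$descrip <- paste0("gmd mask; voxel order: ", mask$voxel_order)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(volume = array(as.array(img) > 0, dim(img)),
                 affine = structure(RNifti::xform(img), class = NULL),
                 voxel_order = "ascending linear index (column-major)",
                 n_voxels = sum(as.array(img) > 0)), class = "gmd_mask")
}

#' Persist / restore a feature matrix
#'
#' The matrix is stored as a gzip-compressed CSV plus a `subjects.csv`
#' sidecar, so a saved matrix round-trips losslessly (full double precision)
#' and is readable outside R.
#'
#' @param features a `gmd_features`. @param dir directory to write into.
#' @param subjects optional subject table to store alongside.
#' @return `write_features()` the directory, invisibly; `read_features()` a
#'   list with `values` and `subjects`.
#' @export
write_features <- function(features, dir, subjects = NULL) {
  stopifnot(inherits(features, "gmd_features"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- gzfile(file.path(dir, "features.csv.gz"), "w")
  df <- data.frame(id = features$subject_ids,
                   format(features$values, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("id", paste0("v", seq_len(ncol(features$values))))
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  if (!is.null(subjects))
    utils::write.csv(subjects, file.path(dir, "subjects.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_features
#' @export
read_features <- function(dir) {
  df <- utils::read.csv(gzfile(file.path(dir, "features.csv.gz")),
                        check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$id
  subj_path <- file.path(dir, "subjects.csv")
  subjects <- if (file.exists(subj_path)) utils::read.csv(subj_path) else NULL
  list(values = vals, subjects = subjects)
}
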
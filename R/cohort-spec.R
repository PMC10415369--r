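#' Specify a synthetic GMD cohort
#'
#' A `cohort_spec` fixes everything the synthetic cohort generator needs:
#' grid geometry, group sizes under the biotype scheme, the spatial effect
#' patterns of grey-matter-density (GMD) reduction, noise levels, and the
#' clinical outcome model. Group sizes default to the B-SNIP study sample
#' (B1 = 150, B2 = 185, B3 = 222, CON = 251, with DSM diagnoses SZ = 242,
#' SAD = 138, BD = 177 distributed at random across the biotypes).
#'
#' The generative model for subject \eqn{i} in group \eqn{g} at voxel
#' \eqn{v} is
#' \deqn{y_i(v) = \mathrm{clip}(\mu - g_i\,\delta_g(v) + a_i + e_i(v),\ 0,\ 1)}
#' where \eqn{\mu} is `baseline_mean`, \eqn{\delta_g} is the group's combined
#' deficit map (shared pattern, if the group expresses it, plus the
#' group-specific pattern), \eqn{g_i \sim N(1, \mathrm{expression\_sd}^2)}
#' is the subject's expression gain (1 for CON and when `expression_sd` is
#' 0), \eqn{a_i \sim N(0, \mathrm{subject\_sd}^2)} is a subject-level offset
#' and \eqn{e_i(v) \sim N(0, \mathrm{voxel\_sd}^2)} is independent voxel
#' noise.
#'
#' @param grid_dims integer vector of length 3, voxels per axis.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param group_sizes named integer vector of biotype group sizes; must
#'   include `CON` and at least one psychosis group, all counts >= 1.
#' @param diagnosis_sizes named integer vector of DSM diagnosis sizes for the
#'   psychosis subjects; rescaled proportionally if its total differs from
#'   the psychosis total.
#' @param baseline_mean mean GMD of unaffected tissue, in (0, 1).
#' @param subject_sd standard deviation of the per-subject global GMD offset.
#' @param voxel_sd standard deviation of independent voxel noise.
#' @param expression_sd standard deviation of the per-subject expression
#'   gain: each psychosis subject expresses its group's deficit map scaled
#'   by \eqn{g_i \sim N(1, \mathrm{expression\_sd}^2)}. This is the
#'   between-subject anatomical heterogeneity that keeps classification
#'   accuracy away from ceiling — with `expression_sd = 0` every group
#'   member expresses the pattern identically and independent voxel noise
#'   averages out over the support, so accuracy saturates.
#' @param shared_effect an [effect_pattern()] expressed by the groups in
#'   `shared_groups`, or `NULL`.
#' @param specific_effects named list of [effect_pattern()]s, one per
#'   psychosis group that has a group-specific pattern.
#' @param shared_groups character vector of groups expressing `shared_effect`.
#' @param clinical_spec a [clinical_spec()] describing outcome columns.
#' @param seed master seed for the generator.
#' @return An object of class `cohort_spec`.
#' @seealso [cohort_preset()] for ready-made configurations,
#'   [generate_cohort()] to draw a cohort.
#' @export
cohort_spec <- function(grid_dims = c(20L, 20L, 20L),
                        voxel_size_mm = 2,
                        group_sizes = c(B1 = 150L, B2 = 185L, B3 = 222L, CON = 251L),
                        diagnosis_sizes = c(SZ = 242L, SAD = 138L, BD = 177L),
                        baseline_mean = 0.5,
                        subject_sd = 0.01,
                        voxel_sd = 0.05,
                        expression_sd = 0,
                        shared_effect = NULL,
                        specific_effects = list(),
                        shared_groups = c("B1", "B2"),
                        clinical_spec = default_clinical_spec(),
                        seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stop("`grid_dims` must be 3 positive integers")
  if (!(voxel_size_mm > 0)) stop("`voxel_size_mm` must be positive")
  if (is.null(names(group_sizes)) || !"CON" %in% names(group_sizes))
    stop("`group_sizes` must be named and include CON")
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1")
  if (!(baseline_mean > 0 && baseline_mean < 1))
    stop("`baseline_mean` must lie in (0, 1)")
  if (subject_sd < 0 || voxel_sd < 0 || expression_sd < 0)
    stop("noise sds must be >= 0")
  n_vox <- prod(grid_dims)
  check_pattern <- function(p, who) {
    if (is.null(p)) return(invisible(NULL))
    if (!inherits(p, "effect_pattern")) stop(who, " must be an effect_pattern")
    if (length(p$support) && max(p$support) > n_vox)
      stop(who, ": support exceeds the grid (", n_vox, " voxels)")
  }
  check_pattern(shared_effect, "shared_effect")
  for (g in names(specific_effects)) check_pattern(specific_effects[[g]], g)
  structure(list(
    grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
    group_sizes = group_sizes, diagnosis_sizes = diagnosis_sizes,
    baseline_mean = baseline_mean, subject_sd = subject_sd,
    voxel_sd = voxel_sd, expression_sd = expression_sd,
    shared_effect = shared_effect,
    specific_effects = specific_effects, shared_groups = shared_groups,
    clinical_spec = clinical_spec, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Define a spatial pattern of GMD reduction
#'
#' A pattern is a set of voxels (its support) together with a per-voxel
#' reduction depth. `uniform` profiles subtract `magnitude` at every support
#' voxel; `gaussian-bump` profiles subtract `magnitude` at the sphere centre,
#' decaying with distance.
#'
#' @param support integer voxel indices (ascending linear index in the
#'   column-major order of the stored volume).
#' @param magnitude peak GMD reduction, >= 0.
#' @param profile `"uniform"` or `"gaussian-bump"`.
#' @param delta optional explicit per-voxel reductions (overrides `profile`);
#'   must match `length(support)`.
#' @param center,sigma centre voxel coordinates and decay scale (in voxels)
#'   for the `gaussian-bump` profile; required only for that profile when
#'   `delta` is not given (and `dims` must then be supplied to locate
#'   support voxels).
#' @param dims grid dimensions, needed to resolve coordinates for the
#'   gaussian-bump profile.
#' @return An object of class `effect_pattern` with fields `support`,
#'   `delta` (per-voxel reduction), `magnitude` and `profile`.
#' @export
effect_pattern <- function(support, magnitude, profile = c("uniform", "gaussian-bump"),
                           delta = NULL, center = NULL, sigma = NULL, dims = NULL) {
  profile <- match.arg(profile)
  support <- as.integer(support)
  if (magnitude < 0) stop("`magnitude` must be >= 0")
  if (is.null(delta)) {
    if (profile == "uniform") {
      delta <- rep(magnitude, length(support))
    } else {
      if (is.null(center) || is.null(sigma) || is.null(dims))
        stop("gaussian-bump profile needs `center`, `sigma` and `dims`")
      xyz <- arrayInd(support, .dim = dims)
      d2 <- rowSums(sweep(xyz, 2L, center)^2)
      delta <- magnitude * exp(-d2 / (2 * sigma^2))
    }
  }
  if (length(delta) != length(support)) stop("`delta` must match `support`")
  structure(list(support = support, delta = as.numeric(delta),
                 magnitude = magnitude, profile = profile),
            class = "effect_pattern")
}

# Voxel indices of a sphere, in ascending linear index order.
sphere_support <- function(dims, center, radius) {
  xyz <- arrayInd(seq_len(prod(dims)), .dim = dims)
  which(rowSums(sweep(xyz, 2L, center)^2) <= radius^2)
}

#' Ready-made cohort configurations
#'
#' Three presets cover the study conditions exercised by the pipeline tests:
#' \describe{
#'   \item{`paper_like`}{A stepwise gradient of GMD loss across biotypes:
#'     B1 expresses a strong, spatially extensive specific pattern plus a
#'     modest pattern shared with B2; B2 expresses only the shared pattern;
#'     B3 a weak, small, purely specific pattern. This is the configuration
#'     under which the B1-vs-CON model is expected to be the only specific
#'     one, with mean accuracies ordered B1 > B2 > B3.}
#'   \item{`null`}{All effect magnitudes zero: no group signal at all. Used
#'     to calibrate the chance level of the accuracy interval test.}
#'   \item{`shared_only`}{A single pattern expressed identically by all three
#'     psychosis groups and no group-specific patterns: pure common psychosis
#'     signal, so no model should be specific.}
#' }
#' Pattern geometry is deterministic: spheres placed inside the region where
#' the synthetic grey-matter probability map exceeds the mask threshold, with
#' radii scaled to the grid.
#'
#' @param preset one of `"paper_like"`, `"null"`, `"shared_only"`.
#' @param grid_dims,seed,... passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_preset <- function(preset = c("paper_like", "null", "shared_only"),
                          grid_dims = c(20L, 20L, 20L), seed = 1L, ...) {
  preset <- match.arg(preset)
  grid_dims <- as.integer(grid_dims)
  ctr <- (grid_dims + 1) / 2
  R <- min(grid_dims) / 2
  # Shared sphere sits inside B1's large sphere; B3's small sphere overlaps
  # B1's (so B1 cases express B3-model features, as the transfer results
  # require) but stays clear of the shared sphere (so B2 cases do not).
  shared_sup <- sphere_support(grid_dims, ctr + c(0.20 * R, 0, 0), 0.28 * R)
  b1_sup <- sphere_support(grid_dims, ctr + c(-0.15 * R, 0, 0), 0.45 * R)
  b3_sup <- sphere_support(grid_dims, ctr + c(-0.20 * R, 0.30 * R, 0), 0.20 * R)
  args <- switch(preset,
    paper_like = list(
      shared_effect = effect_pattern(shared_sup, 0.012),
      specific_effects = list(
        B1 = effect_pattern(b1_sup, 0.010),
        B3 = effect_pattern(b3_sup, 0.008)),
      shared_groups = c("B1", "B2"),
      expression_sd = 0.95),
    null = list(
      shared_effect = NULL,
      specific_effects = list(),
      shared_groups = character(0)),
    shared_only = list(
      shared_effect = effect_pattern(shared_sup, 0.012),
      specific_effects = list(),
      shared_groups = c("B1", "B2", "B3"),
      expression_sd = 0.95))
  spec <- do.call(cohort_spec,
                  c(list(grid_dims = grid_dims, seed = seed), args, list(...)))
  spec$preset <- preset
  spec
}

#' Per-group combined effect patterns
#'
#' Resolves the shared and group-specific patterns of a [cohort_spec()] into
#' one combined deficit map per psychosis group (per-voxel reductions summed
#' where patterns overlap). Groups with no applicable pattern get an empty
#' pattern. Deterministic: pattern geometry carries no randomness.
#'
#' @param spec a `cohort_spec`.
#' @return Named list of `effect_pattern`s, one per psychosis group.
#' @export
make_effect_patterns <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_vox <- prod(spec$grid_dims)
  groups <- setdiff(names(spec$group_sizes), "CON")
  out <- list()
  for (g in groups) {
    delta <- numeric(n_vox)
    if (!is.null(spec$shared_effect) && g %in% spec$shared_groups) {
      p <- spec$shared_effect
      delta[p$support] <- delta[p$support] + p$delta
    }
    if (!is.null(spec$specific_effects[[g]])) {
      p <- spec$specific_effects[[g]]
      if (length(p$support) && max(p$support) > n_vox)
        stop("support of the ", g, " pattern exceeds the grid")
      delta[p$support] <- delta[p$support] + p$delta
    }
    sup <- which(delta > 0)
    out[[g]] <- effect_pattern(sup, if (length(sup)) max(delta[sup]) else 0,
                               delta = delta[sup])
  }
  out
}

#' Specify synthetic clinical outcomes
#'
#' Each outcome is generated as
#' `intercept + slope * expression + group_offset + noise`, where
#' `expression` is the subject's z-scored expression of the B1 deficit
#' pattern (see [pattern_expression()]). The slope is identical across
#' groups, so associations are group-invariant by construction; entries are
#' then masked completely at random at `missing_rate`.
#'
#' @param outcomes a data frame with columns `name`, `intercept`, `slope`,
#'   `offset_B1`, `offset_B2`, `offset_B3`, `noise_sd`, `missing_rate`
#'   (offsets are relative to CON, the reference group).
#' @return An object of class `clinical_spec`.
#' @export
clinical_spec <- function(outcomes) {
  need <- c("name", "intercept", "slope", "offset_B1", "offset_B2",
            "offset_B3", "noise_sd", "missing_rate")
  if (!all(need %in% names(outcomes)))
    stop("`outcomes` must have columns: ", paste(need, collapse = ", "))
  if (any(outcomes$missing_rate < 0 | outcomes$missing_rate >= 1))
    stop("missing_rate must lie in [0, 1)")
  if (any(outcomes$noise_sd < 0)) stop("noise_sd must be >= 0")
  structure(list(outcomes = outcomes), class = "clinical_spec")
}

#' @rdname clinical_spec
#' @details `default_clinical_spec()` emulates the six outcome variables of
#'   the association analysis: a WRAT-like premorbid-ability estimate with a
#'   genuine negative, group-invariant dependence on B1-pattern expression
#'   (slope -0.4, noise sd 1), GAF/SFS-like functioning scores with group
#'   offsets but no dependence on the pattern, and three null biomarker
#'   components (IEA PCA1, SPEM PCA1/PCA2) that are noise or group offsets
#'   only. Missingness rates loosely follow the magnitudes reported for the
#'   real measures.
#' @export
default_clinical_spec <- function() {
  clinical_spec(data.frame(
    name = c("WRAT", "GAF", "SFS", "IEA_PCA1", "SPEM_PCA1", "SPEM_PCA2"),
    intercept = c(0.25, 86.6, 157.7, 0, 0.33, 0.1),
    slope = c(-0.4, 0, 0, 0, 0, 0),
    offset_B1 = c(-1.2, -37.7, -40.3, 0, -1.1, -0.1),
    offset_B2 = c(-0.1, -33.5, -33.3, 0, -0.67, -0.26),
    offset_B3 = c(-0.3, -30.8, -25.7, 0, -0.24, -0.09),
    noise_sd = c(1, 13, 23, 1, 1, 1),
    missing_rate = c(0.02, 0.01, 0.20, 0.15, 0.10, 0.10)
  ))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic GMD cohort specification",
      if (!is.null(x$preset)) sprintf("(preset: %s)", x$preset), "\n")
  cat("  grid:", paste(x$grid_dims, collapse = " x "),
      sprintf("voxels @ %g mm\n", x$voxel_size_mm))
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                         collapse = ", "), "\n")
  cat(sprintf("  baseline %g, subject sd %g, voxel sd %g, seed %d\n",
              x$baseline_mean, x$subject_sd, x$voxel_sd, x$seed))
  pats <- make_effect_patterns(x)
  for (g in names(pats))
    cat(sprintf("  %s pattern: %d voxels, peak reduction %.3f\n",
                g, length(pats[[g]]$support), pats[[g]]$magnitude))
  invisible(x)
}
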
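#' Generate a synthetic GMD cohort
#'
#' Draws per-subject 3D grey-matter-density volumes under the generative
#' model of [cohort_spec()], together with template grey- and white-matter
#' tissue-probability volumes shaped so the standard mask rule
#' (gm > 0.40, wm < 0.60) selects a contiguous interior region with voxels
#' excluded by each criterion. Subject noise is drawn from per-subject
#' substreams spawned from the master seed, so the same seed reproduces the
#' cohort bit for bit and a subject's volume does not depend on how many
#' other subjects are generated before it.
#'
#' DSM diagnosis labels are assigned to the psychosis subjects by a random
#' permutation respecting `diagnosis_sizes`, independent of biotype — the two
#' categorization schemes cut across each other, as in the study sample.
#' Clinical outcome columns are generated by [generate_clinical()] from the
#' subjects' B1-pattern expression.
#'
#' @param spec a [cohort_spec()] (or preset from [cohort_preset()]).
#' @return An object of class `gmd_cohort`: list with `gmd` (4D array,
#'   x-y-z-subject), `gm_prob`/`wm_prob` (3D arrays), `subjects` (data frame:
#'   `id`, `biotype`, `diagnosis`, outcome columns), `affine`, `patterns`
#'   (per-group combined deficit maps) and `truth` (the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$group_sizes < 1)) stop("zero-size group in `group_sizes`")
  dims <- spec$grid_dims
  n_vox <- prod(dims)
  groups <- names(spec$group_sizes)
  n <- sum(spec$group_sizes)

  patterns <- make_effect_patterns(spec)
  deficit <- lapply(patterns, function(p) {
    d <- numeric(n_vox); d[p$support] <- p$delta; d
  })
  deficit$CON <- numeric(n_vox)

  tp <- tissue_probability_volumes(dims)
  baseline <- rep(spec$baseline_mean, n_vox)

  biotype <- rep(groups, times = spec$group_sizes)
  ids <- sprintf("S%04d", seq_len(n))

  # seed table: 1..n per-subject noise, n+1 diagnosis permutation, n+2 clinical
  seeds <- derive_seeds(spec$seed, n + 2L)
  gmd <- array(NA_real_, c(dims, n))
  for (i in seq_len(n)) {
    vol <- with_seed(seeds[i], {
      gain <- if (spec$expression_sd > 0 && biotype[i] != "CON")
        stats::rnorm(1L, 1, spec$expression_sd) else 1
      offset <- stats::rnorm(1L, 0, spec$subject_sd)
      noise <- stats::rnorm(n_vox, 0, spec$voxel_sd)
      baseline - gain * deficit[[biotype[i]]] + offset + noise
    })
    gmd[, , , i] <- pmin(1, pmax(0, vol))
  }

  diagnosis <- rep("CON", n)
  psych <- which(biotype != "CON")
  dcounts <- scale_counts(spec$diagnosis_sizes, length(psych))
  dlabels <- rep(names(dcounts), times = dcounts)
  diagnosis[psych] <- with_seed(seeds[n + 1L], sample(dlabels))

  subjects <- data.frame(id = ids, biotype = biotype, diagnosis = diagnosis,
                         stringsAsFactors = FALSE)
  cohort <- structure(list(
    gmd = gmd, gm_prob = tp$gm, wm_prob = tp$wm, subjects = subjects,
    affine = iso_affine(spec$voxel_size_mm), patterns = patterns,
    truth = spec
  ), class = "gmd_cohort")

  # Under a no-effect configuration there is no pattern to express; the
  # clinical latent is identically zero and outcomes are offsets + noise.
  expr <- if (length(patterns[["B1"]]$support)) pattern_expression(cohort)
          else numeric(n)
  clin <- generate_clinical(cohort, spec$clinical_spec, expr,
                            seed = seeds[n + 2L])
  cohort$subjects <- cbind(subjects, clin[, -1L, drop = FALSE])
  cohort
}

# Rescale named counts to sum to n, largest-remainder rounding.
scale_counts <- function(counts, n) {
  if (sum(counts) == n) return(counts)
  raw <- counts * n / sum(counts)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    extra <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[extra] <- out[extra] + 1
  }
  structure(as.integer(out), names = names(counts))
}

# Smooth synthetic tissue-probability templates: a central grey-matter bump
# and a white-matter sheath rising towards the periphery, so that both the
# gm > threshold and wm < threshold criteria exclude some voxels.
tissue_probability_volumes <- function(dims) {
  ctr <- (dims + 1) / 2
  R <- min(dims) / 2
  xyz <- arrayInd(seq_len(prod(dims)), .dim = dims)
  r2 <- rowSums(sweep(xyz, 2L, ctr)^2)
  gm <- 0.85 * exp(-r2 / (2 * (0.60 * R)^2))
  wm <- 0.75 * (1 - exp(-r2 / (2 * (0.36 * R)^2)))
  list(gm = array(gm, dims), wm = array(wm, dims))
}

#' B1 deficit-pattern expression score
#'
#' The latent the clinical outcomes are tied to: each subject's mean GMD
#' shortfall relative to the baseline over the B1 pattern support, z-scored
#' across the cohort. Higher values mean stronger expression of the B1-like
#' pattern of grey matter loss. The real-data analogue is classifier
#' evidence; the generator needs an explicit latent, and this one makes
#' slope recovery analytically checkable.
#'
#' @param cohort a `gmd_cohort`.
#' @param group group whose pattern defines the score (default `"B1"`).
#' @return Numeric vector, one z-score per subject.
#' @export
pattern_expression <- function(cohort, group = "B1") {
  stopifnot(inherits(cohort, "gmd_cohort"))
  p <- cohort$patterns[[group]]
  if (is.null(p) || !length(p$support))
    stop("no ", group, " pattern support in this cohort")
  n <- dim(cohort$gmd)[4L]
  flat <- matrix(cohort$gmd, nrow = prod(cohort$truth$grid_dims), ncol = n)
  shortfall <- cohort$truth$baseline_mean - colMeans(flat[p$support, , drop = FALSE])
  as.numeric(scale(shortfall))
}

#' Generate clinical outcome columns
#'
#' Applies the linear outcome model of [clinical_spec()] to a per-subject
#' pattern-expression score: `intercept + slope * expression + group_offset
#' + N(0, noise_sd)`, with entries deleted completely at random at each
#' outcome's `missing_rate`. The slope does not vary by group, so any
#' brain-behaviour association is group-invariant by construction.
#'
#' @param cohort a `gmd_cohort` (supplies group labels).
#' @param spec a `clinical_spec`.
#' @param expression per-subject expression score, e.g.
#'   [pattern_expression()].
#' @param seed RNG seed for noise and missingness.
#' @return Data frame: `id` plus one column per outcome.
#' @export
generate_clinical <- function(cohort, spec = cohort$truth$clinical_spec,
                              expression = pattern_expression(cohort),
                              seed = cohort$truth$seed) {
  stopifnot(inherits(cohort, "gmd_cohort"), inherits(spec, "clinical_spec"))
  subj <- cohort$subjects
  if (length(expression) != nrow(subj))
    stop("`expression` must give one value per subject")
  known <- c("B1", "B2", "B3", "CON")
  if (!all(subj$biotype %in% known))
    stop("unknown group label(s): ",
         paste(unique(setdiff(subj$biotype, known)), collapse = ", "))
  n <- nrow(subj)
  out <- data.frame(id = subj$id, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (k in seq_len(nrow(spec$outcomes))) {
      o <- spec$outcomes[k, ]
      offs <- c(B1 = o$offset_B1, B2 = o$offset_B2, B3 = o$offset_B3, CON = 0)
      y <- o$intercept + o$slope * expression + offs[subj$biotype] +
        stats::rnorm(n, 0, o$noise_sd)
      if (o$missing_rate > 0)
        y[stats::runif(n) < o$missing_rate] <- NA_real_
      out[[o$name]] <- as.numeric(y)
    }
  })
  out
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI volume per subject (`<id>.nii.gz`), the tissue-probability
#' templates (`gm_prob.nii.gz`, `wm_prob.nii.gz`) and the subject table
#' (`subjects.csv`).
#'
#' @param cohort a `gmd_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gmd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(cohort$gmd)[4L]
  files <- character(0)
  for (i in seq_len(n)) {
    f <- file.path(dir, paste0(cohort$subjects$id[i], ".nii.gz"))
    write_volume(cohort$gmd[, , , i], cohort$affine, f)
    files <- c(files, f)
  }
  fg <- file.path(dir, "gm_prob.nii.gz")
  fw <- file.path(dir, "wm_prob.nii.gz")
  write_volume(cohort$gm_prob, cohort$affine, fg)
  write_volume(cohort$wm_prob, cohort$affine, fw)
  fs <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$subjects, fs, row.names = FALSE)
  invisible(c(files, fg, fw, fs))
}

#' @export
print.gmd_cohort <- function(x, ...) {
  n <- dim(x$gmd)[4L]
  cat(sprintf("Synthetic GMD cohort: %d subjects, %s grid\n",
              n, paste(dim(x$gmd)[1:3], collapse = " x ")))
  print(table(biotype = x$subjects$biotype))
  invisible(x)
}
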
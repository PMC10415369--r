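#' PCA reduction of multi-measure inputs
#'
#' Principal components of the correlation matrix: measures are z-scored,
#' rows with any missing value are excluded before fitting, components are
#' ordered by decreasing eigenvalue, and each component's sign is fixed so
#' that its largest-|loading| measure loads positively. Scores are returned
#' for complete rows and `NA` elsewhere.
#'
#' @param x numeric matrix or data frame (subjects x measures).
#' @param n_components number of components to keep.
#' @return List: `scores` (n x k, `NA` for incomplete rows), `loadings`
#'   (measures x k), `sdev`, `explained` (proportion of variance).
#' @export
reduce_pca <- function(x, n_components) {
  x <- as.matrix(x)
  if (n_components > ncol(x))
    stop("`n_components` exceeds the number of measures")
  complete <- stats::complete.cases(x)
  xc <- x[complete, , drop = FALSE]
  if (nrow(xc) <= ncol(x)) stop("too few complete rows for a PCA")
  pc <- stats::prcomp(xc, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-8)
  if (n_components > rank)
    stop("`n_components` (", n_components, ") exceeds the rank (", rank, ")")
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  z <- scale(xc, center = pc$center, scale = pc$scale)
  scores <- matrix(NA_real_, nrow(x), n_components,
                   dimnames = list(rownames(x),
                                   paste0("PC", seq_len(n_components))))
  scores[complete, ] <- z %*% rot
  list(scores = scores, loadings = rot,
       sdev = pc$sdev[seq_len(n_components)],
       explained = pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2))
}

#' Design matrix for the evidence-by-group interaction regression
#'
#' Columns: intercept, mean-centered classifier evidence, one dummy per
#' psychosis group (CON is the reference: all its dummy and interaction
#' entries are zero), and the dummy-by-centered-evidence interactions —
#' 7 predictors besides the intercept for a three-group scheme. Evidence is
#' centered on the mean over the rows entering this regression (i.e. after
#' any listwise deletion), which is what keeps the interaction terms and the
#' main effect interpretable together.
#'
#' @param evidence per-subject classifier evidence in \[0, 1\].
#' @param groups per-subject group labels.
#' @param reference reference group (default `"CON"`).
#' @param group_levels order of the psychosis dummies; defaults to the
#'   sorted non-reference labels present.
#' @return Numeric matrix with named columns.
#' @export
build_design <- function(evidence, groups, reference = "CON",
                         group_levels = NULL) {
  groups <- as.character(groups)
  if (length(evidence) != length(groups))
    stop("evidence and groups must have the same length")
  group_levels <- group_levels %||% sort(setdiff(unique(groups), reference))
  known <- c(reference, group_levels)
  if (!all(groups %in% known))
    stop("unknown group label(s): ",
         paste(unique(setdiff(groups, known)), collapse = ", "))
  ev <- evidence - mean(evidence)
  X <- cbind("(Intercept)" = 1, evidence = ev)
  for (g in group_levels) {
    d <- as.numeric(groups == g)
    X <- cbind(X, d, d * ev)
    colnames(X)[ncol(X) - 1:0] <- c(g, paste0("evidence:", g))
  }
  X
}

#' Ordinary least squares on an explicit design matrix
#'
#' Least-squares solution of the normal equations via the QR decomposition
#' (`lm.fit`). Errors on rank deficiency, e.g. when evidence has no variance
#' within a group.
#'
#' @param design numeric design matrix (rows already listwise-complete).
#' @param outcome numeric response.
#' @return Named coefficient vector.
#' @export
fit_ols <- function(design, outcome) {
  if (anyNA(outcome) || anyNA(design))
    stop("fit_ols expects complete cases; delete missing rows first")
  fit <- stats::lm.fit(design, outcome)
  if (fit$rank < ncol(design))
    stop("design matrix is rank deficient (rank ", fit$rank, " < ",
         ncol(design), " columns)")
  fit$coefficients
}

#' Brain-behaviour association analysis across iterations
#'
#' For every iteration of a fitted [gmd_rsplit()] and every outcome, fits
#' the 7-predictor interaction regression of [build_design()] on the
#' iteration's entire test sample (all groups), with listwise deletion of
#' missing outcomes and evidence re-centered after deletion. Per-term
#' coefficients are collected across iterations and summarised by their mean
#' and equal-tail percentile interval; a term is flagged significant when
#' the interval excludes zero. Note the interval reflects variability across
#' resampled splits of one cohort — subjects recur across iterations, so it
#' is not an independent-replicates confidence interval; it is reported the
#' way the classification intervals are.
#'
#' @param object a fitted `gmd_rsplit` (evidence available per iteration).
#' @param clinical data frame with `id` and outcome columns (missingness
#'   allowed); defaults to the subject table stored in the fit.
#' @param model which model's evidence to use (default `"B1"`, the model
#'   with specificity; any model is accepted for synthetic experiments).
#' @param outcomes outcome column names (default: all non-id, non-label
#'   columns of `clinical`).
#' @param level interval level (default 0.95).
#' @param z_outcomes z-score each outcome before fitting (default FALSE:
#'   raw scale).
#' @return An object of class `gmd_assoc`: data frame with columns
#'   `outcome`, `term`, `mean`, `lo`, `hi`, `significant`,
#'   `n_iterations_used`.
#' @export
run_associations <- function(object, clinical = object$subjects,
                             model = "B1", outcomes = NULL, level = 0.95,
                             z_outcomes = FALSE) {
  stopifnot(inherits(object, "gmd_rsplit"))
  if (!model %in% names(object$evidence))
    stop("no evidence stored for model ", model)
  scheme_col <- object$scheme
  subj <- object$subjects
  if (!identical(clinical$id, subj$id)) {
    m <- match(subj$id, clinical$id)
    if (anyNA(m)) stop("clinical table missing subjects: ",
                       paste(utils::head(subj$id[is.na(m)]), collapse = ", "))
    clinical <- clinical[m, , drop = FALSE]
  }
  groups <- as.character(subj[[scheme_col]])
  outcomes <- outcomes %||%
    setdiff(names(clinical), c("id", "biotype", "diagnosis"))
  for (oc in outcomes) {
    ok <- tapply(!is.na(clinical[[oc]]), groups, any)
    if (!all(ok))
      stop("outcome ", oc, " is missing for entire group(s): ",
           paste(names(ok)[!ok], collapse = ", "))
  }
  E <- object$evidence[[model]]
  n_iter <- nrow(E)
  glv <- sort(setdiff(unique(groups), "CON"))
  terms <- c("(Intercept)", "evidence", as.vector(rbind(glv,
             paste0("evidence:", glv))))
  rows <- list()
  for (oc in outcomes) {
    y0 <- clinical[[oc]]
    if (z_outcomes) y0 <- as.numeric(scale(y0))
    B <- matrix(NA_real_, n_iter, length(terms),
                dimnames = list(NULL, terms))
    for (i in seq_len(n_iter)) {
      in_test <- !is.na(E[i, ])
      use <- in_test & !is.na(y0)
      X <- build_design(E[i, use], groups[use], group_levels = glv)
      B[i, colnames(X)] <- fit_ols(X, y0[use])
    }
    for (tm in terms) {
      ci <- percentile_interval(B[, tm], level)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, term = tm, mean = mean(B[, tm]),
        lo = ci[1L], hi = ci[2L],
        significant = ci[1L] > 0 || ci[2L] < 0,
        n_iterations_used = n_iter, stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), model = model,
                 level = level, z_outcomes = z_outcomes),
            class = "gmd_assoc")
}

#' @export
print.gmd_assoc <- function(x, digits = 2, ...) {
  cat(sprintf("Evidence associations (%s model, %g%% intervals across iterations)\n",
              x$model, 100 * x$level))
  s <- x$summary
  for (oc in unique(s$outcome)) {
    cat("\n", oc, "\n", sep = "")
    d <- s[s$outcome == oc, ]
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-18s %9s (%s; %s)%s\n", d$term[i],
                  formatC(d$mean[i], digits = digits, format = "f"),
                  formatC(d$lo[i], digits = digits, format = "f"),
                  formatC(d$hi[i], digits = digits, format = "f"),
                  if (d$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' @rdname run_associations
#' @param x a `gmd_assoc`. @param path CSV output path.
#' @export
write_associations <- function(x, path) {
  stopifnot(inherits(x, "gmd_assoc"))
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}
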
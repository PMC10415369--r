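#' Plan repeated stratified train/test splits
#'
#' For each iteration, draws `n_train_per_group` training subjects without
#' replacement from every in-scheme group (the three psychosis groups and
#' CON); each group's test set is its full complement. One CON draw is made
#' per iteration, so the CON training subset is identical across the three
#' binary models of that iteration. The other scheme's labels play no role
#' in case selection. Per-iteration RNG streams are spawned from the master
#' seed (the first `n_iterations` draws of `sample.int` under the master
#' seed, one substream seed per iteration), so any iteration can be
#' reproduced independently.
#'
#' @param subjects data frame with a column named after `scheme`
#'   (`"biotype"` or `"diagnosis"`) holding group labels including `"CON"`.
#' @param scheme categorization scheme column to use.
#' @param n_train_per_group training cases drawn per group (default 88).
#' @param n_iterations number of repeated splits (default 1000).
#' @param master_seed seed for the whole plan.
#' @return An object of class `gmd_splits`: `scheme`, `groups` (psychosis
#'   groups), `iterations` (per iteration, `train` and `test` index lists
#'   keyed by group).
#' @export
plan_splits <- function(subjects, scheme = c("biotype", "diagnosis"),
                        n_train_per_group = 88L, n_iterations = 1000L,
                        master_seed = 1L) {
  scheme <- match.arg(scheme)
  if (!scheme %in% names(subjects))
    stop("`subjects` has no '", scheme, "' column")
  labels <- as.character(subjects[[scheme]])
  groups <- setdiff(unique(labels), "CON")
  if (!"CON" %in% labels) stop("no CON subjects in the table")
  all_groups <- c("CON", sort(groups))
  idx_by_group <- lapply(all_groups, function(g) which(labels == g))
  names(idx_by_group) <- all_groups
  sizes <- lengths(idx_by_group)
  short <- all_groups[sizes < n_train_per_group + 1L]
  if (length(short))
    stop("group(s) too small for ", n_train_per_group,
         " training cases plus at least one test case: ",
         paste(sprintf("%s (n = %d)", short, sizes[short]), collapse = ", "))
  seeds <- derive_seeds(master_seed, n_iterations)
  iterations <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    iterations[[i]] <- with_seed(seeds[i], {
      train <- lapply(idx_by_group, function(ix)
        sort(sample(ix, n_train_per_group)))
      test <- Map(setdiff, idx_by_group, train)
      list(train = train, test = test)
    })
  }
  structure(list(scheme = scheme, groups = sort(groups),
                 n_train_per_group = as.integer(n_train_per_group),
                 n_iterations = as.integer(n_iterations),
                 master_seed = as.integer(master_seed),
                 group_sizes = sizes, iterations = iterations),
            class = "gmd_splits")
}

#' @export
print.gmd_splits <- function(x, ...) {
  cat(sprintf("Split plan (%s): %d iterations, %d train/group\n", x$scheme,
              x$n_iterations, x$n_train_per_group))
  cat("  test counts:",
      paste(sprintf("%s=%d", names(x$group_sizes),
                    x$group_sizes - x$n_train_per_group), collapse = ", "),
      "\n")
  invisible(x)
}

#' Repeated-split GMD classification of psychosis groups versus controls
#'
#' The core fitting routine. For each iteration of a stratified split plan
#' and each psychosis group in the scheme, an L2-penalized logistic model
#' (group vs CON, shared CON training subset, cost `l2_cost`, no feature
#' standardization) is trained on the iteration's training subjects and
#' evaluated on the held-out data: sensitivity, specificity, balanced and
#' pooled accuracy on the model's own test groups, transfer
#' (psychosis-labelling) rates on the other two psychosis groups' test
#' cases, and per-subject classifier evidence on the entire test sample.
#'
#' `summary()` aggregates the iterations into a specificity report:
#' equal-tail percentile intervals at `ci_level` for every rate, flags
#' `above_chance` where the interval's lower bound exceeds `chance_level`,
#' and calls a model *specific* when its own group is classified above
#' chance while neither out-group transfer rate is (see
#' [assess_specificity()]).
#'
#' @param features a `gmd_features` from [extract_features()], or a numeric
#'   matrix with subject-id rownames.
#' @param subjects subject table aligned with the feature rows (matched by
#'   `id` when present, otherwise by position).
#' @param scheme `"biotype"` or `"diagnosis"`.
#' @param n_train_per_group,n_iterations,master_seed split-plan parameters
#'   (defaults 88 / 1000).
#' @param ci_level percentile-interval level for the report (default 0.9917,
#'   a Bonferroni-style tightening of 95% for the three models per scheme).
#' @param chance_level nominal chance (default 0.5).
#' @param l2_cost cost C of the logistic objective (default 1).
#' @param decision_threshold evidence threshold for labelling (default 0.5;
#'   ties go to CON).
#' @param models optionally restrict to a subset of psychosis groups.
#' @param keep_weights store per-iteration weight vectors (needed for
#'   [aggregate_weights()] and `coef()`).
#' @param verbose print per-iteration progress.
#' @return An object of class `gmd_rsplit` with elements `iterations` (data
#'   frame of per-iteration, per-model rates), `evidence` (per model, an
#'   iterations x subjects matrix, `NA` for subjects in any training set),
#'   `weights`/`intercepts` (per model) and the configuration. Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`.
#' @export
gmd_rsplit <- function(features, subjects, scheme = c("biotype", "diagnosis"),
                       n_train_per_group = 88L, n_iterations = 1000L,
                       ci_level = 0.9917, chance_level = 0.5, l2_cost = 1,
                       decision_threshold = 0.5, master_seed = 1L,
                       models = NULL, keep_weights = TRUE, verbose = FALSE) {
  scheme <- match.arg(scheme)
  if (!(ci_level > 0 && ci_level < 1)) stop("`ci_level` must lie in (0, 1)")
  x <- if (inherits(features, "gmd_features")) features$values else
    as.matrix(features)
  if ("id" %in% names(subjects) && !is.null(rownames(x))) {
    if (!all(subjects$id %in% rownames(x)))
      stop("subjects missing from the feature matrix: ",
           paste(utils::head(setdiff(subjects$id, rownames(x))), collapse = ", "))
    x <- x[subjects$id, , drop = FALSE]
  } else if (nrow(x) != nrow(subjects))
    stop("feature rows and subject table do not align")

  plan <- plan_splits(subjects, scheme, n_train_per_group, n_iterations,
                      master_seed)
  groups <- models %||% plan$groups
  if (!all(groups %in% plan$groups))
    stop("unknown model group(s): ",
         paste(setdiff(groups, plan$groups), collapse = ", "))
  labels <- as.character(subjects[[scheme]])
  n <- nrow(x)
  p <- ncol(x)

  evidence <- lapply(groups, function(g)
    matrix(NA_real_, n_iterations, n,
           dimnames = list(NULL, subjects$id %||% rownames(x))))
  names(evidence) <- groups
  weights <- if (keep_weights)
    stats::setNames(lapply(groups, function(g)
      matrix(NA_real_, n_iterations, p)), groups) else NULL
  intercepts <- stats::setNames(lapply(groups, function(g)
    numeric(n_iterations)), groups)

  rec <- vector("list", n_iterations * length(groups))
  k <- 0L
  for (i in seq_len(n_iterations)) {
    it <- plan$iterations[[i]]
    test_all <- sort(unlist(it$test, use.names = FALSE))
    for (g in groups) {
      tr_idx <- c(it$train[[g]], it$train[["CON"]])
      fit <- train_binary_model(x[tr_idx, , drop = FALSE],
                                labels[tr_idx], positive_class = g,
                                cost = l2_cost)
      ev <- predict_evidence(fit, x[test_all, , drop = FALSE])
      evidence[[g]][i, test_all] <- ev
      if (keep_weights) weights[[g]][i, ] <- fit$weights
      intercepts[[g]][i] <- fit$intercept

      own <- it$test[[g]]; con <- it$test[["CON"]]
      ev_by <- function(ix) evidence[[g]][i, ix]
      sens <- mean(ev_by(own) > decision_threshold)
      spc <- mean(ev_by(con) <= decision_threshold)
      pooled <- (sens * length(own) + spc * length(con)) /
        (length(own) + length(con))
      out <- setdiff(plan$groups, g)
      out_rates <- vapply(out, function(h)
        mean(ev_by(it$test[[h]]) > decision_threshold), 0)
      k <- k + 1L
      rec[[k]] <- data.frame(
        iteration = i, model = g, sensitivity = sens, specificity = spc,
        balanced_accuracy = (sens + spc) / 2, pooled_accuracy = pooled,
        outgroup = paste(out, collapse = ","),
        rate_out1 = if (length(out_rates) >= 1L) unname(out_rates[1L])
                    else NA_real_,
        rate_out2 = if (length(out_rates) >= 2L) unname(out_rates[2L])
                    else NA_real_,
        stringsAsFactors = FALSE)
    }
    if (verbose && i %% 25L == 0L)
      message("iteration ", i, "/", n_iterations)
  }
  structure(list(
    iterations = do.call(rbind, rec), evidence = evidence,
    weights = weights, intercepts = intercepts,
    scheme = scheme, groups = groups, all_groups = plan$groups,
    subjects = subjects, mask = if (inherits(features, "gmd_features"))
      features$mask else NULL,
    config = list(n_train_per_group = n_train_per_group,
                  n_iterations = n_iterations, ci_level = ci_level,
                  chance_level = chance_level, l2_cost = l2_cost,
                  decision_threshold = decision_threshold,
                  master_seed = master_seed)
  ), class = "gmd_rsplit")
}

#' @export
print.gmd_rsplit <- function(x, ...) {
  cat(sprintf("Repeated-split GMD classification (%s scheme)\n", x$scheme))
  cat(sprintf("  %d iterations, %d train/group, models: %s\n",
              x$config$n_iterations, x$config$n_train_per_group,
              paste(x$groups, collapse = ", ")))
  ba <- tapply(x$iterations$balanced_accuracy, x$iterations$model, mean)
  cat("  mean balanced accuracy:",
      paste(sprintf("%s = %.3f", names(ba), ba), collapse = ", "), "\n")
  invisible(x)
}

#' Specificity report for a fitted repeated-split object
#'
#' @param object a `gmd_rsplit`.
#' @param ci_level override the interval level stored in the fit.
#' @param ... ignored.
#' @return An object of class `gmd_specificity`: a data frame with one row
#'   per model and quantity (`overall` balanced accuracy, `pooled` raw
#'   accuracy, own-group and CON accuracy, each out-group transfer rate),
#'   columns `mean`, `lo`, `hi`, `above_chance`; plus a `specific` logical
#'   vector per model.
#' @export
summary.gmd_rsplit <- function(object, ci_level = object$config$ci_level, ...) {
  ch <- object$config$chance_level
  rows <- list()
  for (g in object$groups) {
    d <- object$iterations[object$iterations$model == g, ]
    out <- strsplit(d$outgroup[1L], ",")[[1L]]
    quants <- list(overall = d$balanced_accuracy, pooled = d$pooled_accuracy,
                   own = d$sensitivity, CON = d$specificity)
    if (length(out) >= 1L && nzchar(out[1L]))
      quants[[paste0("transfer_", out[1L])]] <- d$rate_out1
    if (length(out) > 1L) quants[[paste0("transfer_", out[2L])]] <- d$rate_out2
    for (q in names(quants)) {
      ci <- percentile_interval(quants[[q]], ci_level)
      rows[[length(rows) + 1L]] <- data.frame(
        model = g, quantity = q, mean = mean(quants[[q]]),
        lo = ci[1L], hi = ci[2L], above_chance = ci[1L] > ch,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  specific <- vapply(object$groups, function(g) {
    rows <- report[report$model == g, ]
    if (!any(startsWith(rows$quantity, "transfer_"))) return(NA)
    assess_specificity(rows)
  }, NA)
  structure(list(report = report, specific = specific, ci_level = ci_level,
                 chance_level = ch, scheme = object$scheme),
            class = "gmd_specificity")
}

#' Specificity verdict for one model
#'
#' A model is *specific* when it classifies its own group above chance while
#' labelling neither out-group as psychosis at an above-chance rate — i.e.
#' it has captured features particular to its group rather than features of
#' psychosis as a whole.
#'
#' @param report_rows the rows of a specificity report for one model
#'   (columns `quantity`, `above_chance`; must include `own` and at least
#'   one `transfer_*` row).
#' @return Logical.
#' @export
assess_specificity <- function(report_rows) {
  qs <- report_rows$quantity
  if (!"own" %in% qs || !any(startsWith(qs, "transfer_")))
    stop("report rows must include own-group and out-group entries")
  own_above <- report_rows$above_chance[qs == "own"]
  out_above <- report_rows$above_chance[startsWith(qs, "transfer_")]
  isTRUE(own_above) && !any(out_above)
}

#' @export
print.gmd_specificity <- function(x, digits = 3, ...) {
  cat(sprintf("Specificity report (%s scheme, %.2f%% intervals vs chance %g)\n",
              x$scheme, 100 * x$ci_level, x$chance_level))
  r <- x$report
  for (g in unique(r$model)) {
    cat(sprintf("\nModel %s vs CON%s\n", g,
                if (isTRUE(x$specific[[g]])) "  [specific]" else ""))
    d <- r[r$model == g, ]
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-14s %.*f  (%.*f, %.*f)%s\n", d$quantity[i],
                  digits, d$mean[i], digits, d$lo[i], digits, d$hi[i],
                  if (d$above_chance[i]) "  *above chance" else ""))
  }
  invisible(x)
}

#' @export
coef.gmd_rsplit <- function(object, model = NULL, ...) {
  if (is.null(object$weights))
    stop("fit was run with keep_weights = FALSE")
  model <- model %||% object$groups
  out <- vapply(model, function(g) colMeans(object$weights[[g]]),
                numeric(ncol(object$weights[[model[1L]]])))
  if (length(model) == 1L) drop(out) else out
}

#' @export
predict.gmd_rsplit <- function(object, newdata, model = object$groups[1L],
                               type = c("evidence", "label"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "gmd_features")) newdata$values else
    as.matrix(newdata)
  w <- coef(object, model)
  b <- mean(object$intercepts[[model]])
  ev <- stats::plogis(drop(x %*% w) + b)
  if (type == "evidence") ev
  else ifelse(ev > object$config$decision_threshold, model, "CON")
}

#' @export
plot.gmd_rsplit <- function(x, ...) {
  d <- x$iterations
  graphics::boxplot(balanced_accuracy ~ model, data = d,
                    ylab = "balanced accuracy", xlab = "model",
                    main = sprintf("Accuracy across %d iterations (%s)",
                                   x$config$n_iterations, x$scheme), ...)
  graphics::abline(h = x$config$chance_level, lty = 2)
  invisible(x)
}

#' Export per-iteration records and evidence
#'
#' Writes the classify outputs in portable form: a long-format CSV of
#' per-iteration metrics (`iteration, model, metric, value`), the
#' specificity report as JSON (if `jsonlite` is available), and a long CSV
#' of per-subject evidence (`iteration, subject_id, model, evidence`).
#'
#' @param object a `gmd_rsplit`. @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_rsplit <- function(object, dir) {
  stopifnot(inherits(object, "gmd_rsplit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- object$iterations
  long <- list()
  for (m in c("sensitivity", "specificity", "balanced_accuracy",
              "pooled_accuracy", "rate_out1", "rate_out2"))
    long[[m]] <- data.frame(iteration = d$iteration, model = d$model,
                            metric = m, value = d[[m]])
  f1 <- file.path(dir, "iteration_records.csv")
  utils::write.csv(do.call(rbind, long), f1, row.names = FALSE)
  files <- f1
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    s <- summary(object)
    f2 <- file.path(dir, "specificity_report.json")
    jsonlite::write_json(list(report = s$report,
                              specific = as.list(s$specific),
                              ci_level = s$ci_level), f2,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f2)
  }
  ev_rows <- list()
  for (g in names(object$evidence)) {
    E <- object$evidence[[g]]
    nz <- which(!is.na(E), arr.ind = TRUE)
    ev_rows[[g]] <- data.frame(iteration = nz[, 1L],
                               subject_id = colnames(E)[nz[, 2L]],
                               model = g, evidence = E[nz])
  }
  f3 <- file.path(dir, "evidence.csv")
  utils::write.csv(do.call(rbind, ev_rows), f3, row.names = FALSE)
  invisible(c(files, f3))
}
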
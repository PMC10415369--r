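#' L2-penalized logistic regression (liblinear-style objective)
#'
#' Fits the binary classifier used throughout the pipeline: minimize
#' \deqn{\tfrac12 \|w\|^2 + C \sum_i \log(1 + e^{-y_i (w^\top x_i + b)})}
#' with cost `C` and an unpenalized intercept `b`. Features enter on their
#' native \[0, 1\] GMD scale — no standardization, mirroring a pipeline with
#' no feature reduction or selection. The minimizer is a deterministic
#' quasi-Newton solve (L-BFGS with analytic gradient); the fit is accepted
#' when the objective gradient's max-norm falls below `tol`.
#'
#' @param x numeric matrix, training subjects in rows.
#' @param y class labels (two classes).
#' @param positive_class label of the psychosis class; the model's evidence
#'   is the probability of this class. Defaults to the non-`CON` label.
#' @param cost C parameter of the objective (default 1).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param maxit iteration cap per solver run.
#' @return An object of class `gmd_logit`: `weights`, `intercept`,
#'   `positive_class`, `negative_class`, `cost`, `grad_norm`, `converged`.
#' @export
train_binary_model <- function(x, y, positive_class = NULL, cost = 1,
                               tol = 1e-6, maxit = 1000L) {
  x <- as.matrix(x)
  labs <- unique(as.character(y))
  if (length(labs) != 2L)
    stop("exactly two classes required, got: ", paste(labs, collapse = ", "))
  if (all(apply(x, 2L, function(col) diff(range(col)) == 0)))
    stop("degenerate features: every column is constant")
  positive_class <- positive_class %||%
    (if ("CON" %in% labs) setdiff(labs, "CON") else labs[1L])
  if (!positive_class %in% labs) stop("positive_class not present in labels")
  negative_class <- setdiff(labs, positive_class)
  ypm <- ifelse(as.character(y) == positive_class, 1, -1)

  p <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- ypm * (drop(x %*% w) + b)
    0.5 * sum(w^2) + cost * sum(log1p(exp(-abs(m))) + pmax(-m, 0))
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- ypm * (drop(x %*% w) + b)
    s <- ypm * stats::plogis(-m)          # y * sigma(-y f)
    c(w - cost * drop(crossprod(x, s)), -cost * sum(s))
  }
  # Hessian-vector product for the Newton-CG polish.
  hessvec <- function(par, v) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    f <- drop(x %*% w) + b
    d <- cost * stats::plogis(f) * stats::plogis(-f)  # sigma(1-sigma)
    u <- drop(x %*% v[seq_len(p)]) + v[p + 1L]
    c(v[seq_len(p)] + drop(crossprod(x, d * u)), sum(d * u))
  }
  par <- numeric(p + 1L)
  fit <- stats::optim(par, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e5, pgtol = 0))
  par <- fit$par
  # Newton-CG refinement: L-BFGS stops on function decrease, which can leave
  # the gradient just above tol; a few damped Newton steps (CG solve of the
  # convex Hessian system) push it to convergence.
  gnorm <- max(abs(grad(par)))
  for (newton in seq_len(20L)) {
    if (gnorm < tol) break
    g <- grad(par)
    step <- cg_solve(function(v) hessvec(par, v), -g, rel_tol = 0.01)
    f0 <- obj(par); alpha <- 1
    while (obj(par + alpha * step) > f0 + 1e-4 * alpha * sum(g * step) &&
           alpha > 1e-8) alpha <- alpha / 2
    par <- par + alpha * step
    gnorm <- max(abs(grad(par)))
  }
  if (gnorm >= tol)
    warning(sprintf("logistic fit: gradient max-norm %.2e above tol %.1e",
                    gnorm, tol))
  structure(list(weights = par[seq_len(p)], intercept = par[p + 1L],
                 positive_class = positive_class,
                 negative_class = negative_class, cost = cost,
                 grad_norm = gnorm, converged = gnorm < tol),
            class = "gmd_logit")
}

# Conjugate-gradient solve of A v = b for a symmetric positive-definite
# operator given as a function.
cg_solve <- function(Afun, b, rel_tol = 0.01, maxit = length(b)) {
  v <- numeric(length(b))
  r <- b
  d <- r
  rs <- sum(r^2)
  thresh <- rel_tol^2 * rs
  for (i in seq_len(maxit)) {
    if (rs <= thresh) break
    Ad <- Afun(d)
    alpha <- rs / sum(d * Ad)
    v <- v + alpha * d
    r <- r - alpha * Ad
    rs_new <- sum(r^2)
    d <- r + (rs_new / rs) * d
    rs <- rs_new
  }
  v
}

#' Classifier evidence
#'
#' The logistic of the model's linear score: the predicted probability that
#' a subject belongs to the positive (psychosis) class.
#'
#' @param model a `gmd_logit`.
#' @param x numeric matrix with as many columns as the model has weights.
#' @return Numeric vector of probabilities.
#' @export
predict_evidence <- function(model, x) {
  stopifnot(inherits(model, "gmd_logit"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$weights))
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 length(model$weights), ncol(x)))
  stats::plogis(drop(x %*% model$weights) + model$intercept)
}

#' @export
print.gmd_logit <- function(x, ...) {
  cat(sprintf("L2 logistic model %s vs %s: %d features, cost %g, |grad| %.1e\n",
              x$positive_class, x$negative_class, length(x$weights), x$cost,
              x$grad_norm))
  invisible(x)
}

#' Balanced accuracy
#'
#' The unweighted mean of sensitivity and specificity — the per-class
#' accuracies averaged without regard to class size, so unequal test groups
#' do not bias the metric.
#'
#' @param truth true class labels (exactly two classes present).
#' @param predicted predicted class labels.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  labs <- unique(truth)
  if (length(labs) != 2L)
    stop("`truth` must contain exactly two classes, got ", length(labs))
  mean(vapply(labs, function(l) mean(predicted[truth == l] == l), 0))
}

#' Out-group psychosis-labelling rate
#'
#' The transfer test: apply a trained model to subjects from a psychosis
#' group it was not trained on, and report the fraction labelled as the
#' model's psychosis class. Evidence exactly at the threshold is labelled
#' CON (deterministic tie rule) and so does not count.
#'
#' @param model a `gmd_logit`.
#' @param x out-group feature matrix (must be non-empty).
#' @param threshold decision threshold on evidence (default 0.5).
#' @return Fraction in \[0, 1\].
#' @export
outgroup_rate <- function(model, x, threshold = 0.5) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty out-group")
  mean(predict_evidence(model, x) > threshold)
}

#' Equal-tail empirical percentile interval
#'
#' Quantiles at `(1 - level)/2` and `1 - (1 - level)/2` of the empirical
#' distribution, with linear interpolation between order statistics — the
#' interval used for accuracy and coefficient summaries across iterations.
#'
#' @param values numeric vector (length >= 2).
#' @param level interval level in (0, 1), e.g. 0.9917.
#' @return Numeric vector `c(lo, hi)`.
#' @export
percentile_interval <- function(values, level) {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("`level` must lie strictly inside (0, 1)")
  if (length(values) < 2L) stop("need at least 2 values")
  a <- (1 - level) / 2
  stats::quantile(values, probs = c(a, 1 - a), names = FALSE, type = 7)
}
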
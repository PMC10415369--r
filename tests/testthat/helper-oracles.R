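# Independent oracles used to cross-check package computations.

# Brute-force equal-tail quantile with linear interpolation between order
# statistics (independent of stats::quantile).
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(s[n])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }, 0)
}

oracle_interval <- function(x, level) {
  a <- (1 - level) / 2
  oracle_quantile(x, c(a, 1 - a))
}

# Direct evaluation of the truncated, per-axis-normalized 3D Gaussian kernel:
# what smoothing a centred unit impulse must produce away from the edges.
oracle_gaussian_kernel <- function(fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(outer(k1, k1), k1)
}

# Normal-equations OLS by explicit matrix inversion.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# Reference L2-logistic fit via glmnet's ridge path (lambda matched to the
# cost-C objective: lambda = 1 / (n * C)), used only as a cross-check.
oracle_logistic <- function(x, y_pm, cost = 1) {
  n <- nrow(x)
  fit <- glmnet::glmnet(x, factor(y_pm, levels = c(-1, 1)),
                        family = "binomial", alpha = 0,
                        lambda = 1 / (n * cost), standardize = FALSE,
                        thresh = 1e-14, maxit = 1e6)
  list(weights = as.numeric(fit$beta), intercept = as.numeric(fit$a0))
}
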
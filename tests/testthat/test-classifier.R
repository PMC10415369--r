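test_that("the logistic fit matches an independent ridge-logistic solver", {
  set.seed(20)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- rep(c("G", "CON"), each = 10)
  x[y == "G", 1] <- x[y == "G", 1] + 1.5
  fit <- train_binary_model(x, y, positive_class = "G")
  expect_true(fit$converged)
  orc <- oracle_logistic(x, ifelse(y == "G", 1, -1))
  expect_lt(max(abs(fit$weights - orc$weights)), 1e-4)
  expect_lt(abs(fit$intercept - orc$intercept), 1e-4)
})

test_that("separable clusters order evidence by membership; permuted labels give chance", {
  set.seed(7)
  x <- rbind(matrix(rnorm(30 * 3, 2), 30, 3), matrix(rnorm(30 * 3, -2), 30, 3))
  y <- rep(c("P", "CON"), each = 30)
  fit <- train_binary_model(x, y, positive_class = "P")
  ev <- predict_evidence(fit, x)
  expect_true(min(ev[1:30]) > max(ev[31:60]))

  yp <- sample(y)                       # no signal left
  xtr <- x[1:40, ]; xte <- x[41:60, ]
  f2 <- train_binary_model(xtr, yp[1:40], positive_class = "P")
  pred <- ifelse(predict_evidence(f2, xte) > 0.5, "P", "CON")
  expect_lt(abs(balanced_accuracy(yp[41:60], pred) - 0.5), 0.25)

  expect_error(train_binary_model(matrix(1, 10, 3), rep(c("P", "CON"), 5)),
               "degenerate")
  expect_error(train_binary_model(x, rep("P", 60)), "two classes")
})

test_that("evidence is the logistic of the linear score", {
  m <- structure(list(weights = c(0.5, -1), intercept = 0.25,
                      positive_class = "P", negative_class = "CON"),
                 class = "gmd_logit")
  x <- rbind(c(1, 2), c(-3, 0.5))
  expect_equal(predict_evidence(m, x),
               stats::plogis(c(0.5 * 1 - 1 * 2 + 0.25, 0.5 * -3 - 0.5 + 0.25)))
  m0 <- structure(list(weights = c(0, 0), intercept = 0), class = "gmd_logit")
  expect_equal(predict_evidence(m0, x), c(0.5, 0.5))
  mbig <- structure(list(weights = c(0, 0), intercept = 50), class = "gmd_logit")
  expect_gt(min(predict_evidence(mbig, x)), 1 - 1e-9)
  expect_error(predict_evidence(m, matrix(1, 2, 3)), "mismatch")
})

test_that("balanced accuracy is the mean of the per-class accuracies", {
  expect_equal(balanced_accuracy(c("P", "C"), c("P", "C")), 1)
  expect_equal(balanced_accuracy(c("P", "P", "C"), c("P", "P", "P")), 0.5)
  expect_equal(balanced_accuracy(c("P", "P", "P", "C", "C"),
                                 c("P", "P", "C", "C", "C")),
               (2 / 3 + 1) / 2)
  expect_error(balanced_accuracy(c("P", "P"), c("P", "C")), "two classes")
})

test_that("balanced accuracy is robust to majority-class subsampling", {
  set.seed(99)
  truth <- rep(c("P", "C"), c(60, 300))
  pred <- ifelse(stats::runif(360) < ifelse(truth == "P", 0.7, 0.2), "P", "C")
  full <- balanced_accuracy(truth, pred)
  sub <- replicate(300, {
    keep <- c(which(truth == "P"), sample(which(truth == "C"), 60))
    balanced_accuracy(truth[keep], pred[keep])
  })
  expect_lt(abs(mean(sub) - full), 0.02)
})

test_that("out-group rate counts evidence strictly above the threshold", {
  # one-feature model: evidence = plogis(x), so x = qlogis(target evidence)
  m <- structure(list(weights = 1, intercept = 0, positive_class = "P",
                      negative_class = "CON"), class = "gmd_logit")
  x <- matrix(stats::qlogis(c(0.2, 0.6, 0.7, 0.4)), ncol = 1)
  expect_equal(outgroup_rate(m, x), 0.5)
  # evidence exactly at the threshold is labelled CON and not counted
  m0 <- structure(list(weights = 1, intercept = 0), class = "gmd_logit")
  expect_equal(outgroup_rate(m0, matrix(0, 3, 1)), 0)
  mhi <- structure(list(weights = 0, intercept = stats::qlogis(0.9)),
                   class = "gmd_logit")
  expect_equal(outgroup_rate(mhi, matrix(0, 5, 1)), 1)
  expect_error(outgroup_rate(m, matrix(numeric(0), 0, 1)), "empty")
})

test_that("percentile intervals match a brute-force sorted interpolation", {
  expect_equal(percentile_interval(rep(3.2, 10), 0.9917), c(3.2, 3.2))
  grid <- seq(0.001, 1, by = 0.001)
  expect_equal(percentile_interval(grid, 0.95), oracle_interval(grid, 0.95))
  set.seed(1)
  for (lv in c(0.5, 0.9, 0.9917)) {
    x <- stats::rnorm(257)
    expect_equal(percentile_interval(x, lv), oracle_interval(x, lv))
  }
  x <- stats::rnorm(50)
  expect_equal(percentile_interval(x, 1 - 1e-12), range(x))
  expect_error(percentile_interval(x, 1), "level")
  expect_error(percentile_interval(1.0, 0.95), "2 values")
})

test_that("split plans reproduce the study's held-out counts exactly", {
  subjects <- data.frame(
    biotype = rep(c("B1", "B2", "B3", "CON"), c(150, 185, 222, 251)),
    diagnosis = c(rep(c("SZ", "SAD", "BD"), c(242, 138, 177)), rep("CON", 251)))
  pb <- plan_splits(subjects, "biotype", 88, n_iterations = 3, master_seed = 1)
  test_counts <- lengths(pb$iterations[[1]]$test)
  expect_identical(test_counts[c("B1", "B2", "B3", "CON")],
                   c(B1 = 62L, B2 = 97L, B3 = 134L, CON = 163L))
  pd <- plan_splits(subjects, "diagnosis", 88, n_iterations = 3, master_seed = 1)
  expect_identical(lengths(pd$iterations[[1]]$test)[c("SZ", "SAD", "BD", "CON")],
                   c(SZ = 154L, SAD = 50L, BD = 89L, CON = 163L))
})

test_that("split plans are disjoint, stratified, seed-stable and validated", {
  subjects <- data.frame(biotype = rep(c("B1", "B2", "B3", "CON"),
                                       c(12, 12, 12, 14)))
  p1 <- plan_splits(subjects, "biotype", 8, n_iterations = 5, master_seed = 3)
  p2 <- plan_splits(subjects, "biotype", 8, n_iterations = 5, master_seed = 3)
  expect_identical(p1$iterations, p2$iterations)
  for (it in p1$iterations) {
    for (g in names(it$train)) {
      expect_length(it$train[[g]], 8L)
      expect_length(intersect(it$train[[g]], it$test[[g]]), 0L)
      expect_setequal(c(it$train[[g]], it$test[[g]]),
                      which(subjects$biotype == g))
    }
  }
  p3 <- plan_splits(subjects, "biotype", 8, n_iterations = 5, master_seed = 4)
  expect_false(identical(p1$iterations, p3$iterations))
  # a group equal to the training size leaves no test cases
  expect_error(plan_splits(subjects, "biotype", 12, n_iterations = 2),
               "B1")
})

test_that("the repeated-split engine is deterministic end to end", {
  co <- tiny_cohort(seed = 61)
  fm <- tiny_features(co)
  run <- function() gmd_rsplit(fm, co$subjects, "biotype",
                               n_train_per_group = 8L, n_iterations = 4L,
                               master_seed = 17, keep_weights = FALSE)
  f1 <- run(); f2 <- run()
  expect_identical(f1$iterations, f2$iterations)
  expect_identical(f1$evidence, f2$evidence)
  s1 <- summary(f1); s2 <- summary(f2)
  expect_identical(s1$report, s2$report)
})

test_that("per-iteration rates are coherent", {
  co <- tiny_cohort(seed = 23)
  fm <- tiny_features(co)
  fit <- gmd_rsplit(fm, co$subjects, "biotype", n_train_per_group = 8L,
                    n_iterations = 6L, master_seed = 2, keep_weights = FALSE)
  d <- fit$iterations
  expect_true(all(d$balanced_accuracy ==
                    (d$sensitivity + d$specificity) / 2))
  expect_true(all(d$pooled_accuracy >= pmin(d$sensitivity, d$specificity) - 1e-12))
  expect_true(all(d$pooled_accuracy <= pmax(d$sensitivity, d$specificity) + 1e-12))
  rates <- unlist(d[, c("sensitivity", "specificity", "balanced_accuracy",
                        "pooled_accuracy", "rate_out1", "rate_out2")])
  expect_true(all(rates >= 0 & rates <= 1))
  # evidence recorded exactly for the union of the test sets
  E <- fit$evidence$B1
  expect_true(all(rowSums(!is.na(E)) == nrow(co$subjects) - 4 * 8))
})

test_that("the diagnosis scheme runs through the same engine", {
  co <- tiny_cohort(seed = 37,
                    group_sizes = c(B1 = 14L, B2 = 14L, B3 = 14L, CON = 14L))
  fm <- tiny_features(co)
  fit <- gmd_rsplit(fm, co$subjects, "diagnosis", n_train_per_group = 6L,
                    n_iterations = 3L, master_seed = 8, keep_weights = FALSE)
  expect_setequal(fit$groups, c("SZ", "SAD", "BD"))
  s <- summary(fit)
  expect_true(all(c("own", "CON", "overall") %in% s$report$quantity))
})

test_that("specificity verdicts follow the own-group and transfer rules", {
  mk <- function(own, out1, out2) data.frame(
    quantity = c("own", "transfer_A", "transfer_B"),
    above_chance = c(own, out1, out2))
  expect_true(assess_specificity(mk(TRUE, FALSE, FALSE)))
  expect_false(assess_specificity(mk(TRUE, TRUE, FALSE)))
  expect_false(assess_specificity(mk(FALSE, FALSE, FALSE)))
  expect_error(assess_specificity(data.frame(quantity = "own",
                                             above_chance = TRUE)),
               "out-group")
})

test_that("type-I rate of the above-chance call is controlled under the null", {
  declared <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_preset(
      "null", grid_dims = c(8L, 8L, 8L), seed = 1000 + s,
      group_sizes = c(B1 = 30L, CON = 30L)))
    fm <- tiny_features(co)
    fit <- gmd_rsplit(fm, co$subjects, "biotype", n_train_per_group = 20L,
                      n_iterations = 60L, master_seed = s,
                      keep_weights = FALSE)
    summary(fit)$report |>
      (\(r) r$above_chance[r$quantity == "overall"])()
  }, NA)
  # nominal rate 1 - 0.9917 = 0.0083 per comparison; allow binomial slack
  expect_lte(sum(declared), 3L)
})
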
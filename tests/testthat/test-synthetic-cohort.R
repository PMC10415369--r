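test_that("preset patterns encode the stepwise biotype gradient", {
  spec <- cohort_preset("paper_like", grid_dims = c(16L, 16L, 16L))
  pats <- make_effect_patterns(spec)
  sizes <- lengths(lapply(pats, `[[`, "support"))
  expect_gt(sizes[["B1"]], sizes[["B2"]])
  expect_gt(sizes[["B2"]], sizes[["B3"]])
  mags <- vapply(pats, `[[`, 0, "magnitude")
  expect_gte(mags[["B1"]], mags[["B2"]])
  expect_gte(mags[["B2"]], mags[["B3"]])

  null_pats <- make_effect_patterns(cohort_preset("null"))
  expect_true(all(vapply(null_pats, `[[`, 0, "magnitude") == 0))
  expect_true(all(lengths(lapply(null_pats, `[[`, "support")) == 0))

  so <- cohort_preset("shared_only")
  expect_length(so$specific_effects, 0L)
  expect_gt(so$shared_effect$magnitude, 0)
  so_pats <- make_effect_patterns(so)
  expect_identical(so_pats$B1$support, so_pats$B3$support)
})

test_that("a pattern support outside the grid is rejected", {
  expect_error(
    cohort_spec(grid_dims = c(4L, 4L, 4L),
                specific_effects = list(B1 = effect_pattern(60:70, 0.05))),
    "exceeds the grid")
  expect_error(cohort_spec(baseline_mean = 1.2), "baseline_mean")
  expect_error(cohort_spec(subject_sd = -1), "sds")
})

test_that("the generator is deterministic given the seed", {
  a <- tiny_cohort(seed = 55)
  b <- tiny_cohort(seed = 55)
  expect_identical(a$gmd, b$gmd)
  expect_identical(a$subjects, b$subjects)
  c <- tiny_cohort(seed = 56)
  expect_false(identical(a$gmd, c$gmd))
})

test_that("subject volumes are reproducible under cohort subsetting", {
  # per-subject substreams: shrinking a later group must not change the
  # volumes of subjects generated before it
  big <- tiny_cohort(group_sizes = c(B1 = 6L, CON = 8L), seed = 9)
  small <- tiny_cohort(group_sizes = c(B1 = 6L, CON = 4L), seed = 9)
  expect_identical(big$gmd[, , , 1:6], small$gmd[, , , 1:6])
})

test_that("group-mean GMD differences match the configured magnitude", {
  delta <- 0.05
  sup <- 200:260
  spec <- cohort_spec(grid_dims = c(10L, 10L, 10L),
                      group_sizes = c(B1 = 40L, CON = 40L),
                      specific_effects = list(B1 = effect_pattern(sup, delta)),
                      shared_groups = character(0), seed = 31)
  co <- generate_cohort(spec)
  flat <- matrix(co$gmd, nrow = 1000L)
  m <- colMeans(flat[sup, , drop = FALSE])
  grp <- co$subjects$biotype
  diff_mean <- mean(m[grp == "CON"]) - mean(m[grp == "B1"])
  se <- sqrt(stats::var(m[grp == "CON"]) / 40 + stats::var(m[grp == "B1"]) / 40)
  expect_lt(abs(diff_mean - delta), 3 * se)
})

test_that("the null preset carries no group signal", {
  # one seed: the B1-vs-CON t statistic on per-subject mean GMD is small;
  # across replicate seeds its p-value is uniform
  pvals <- vapply(1:120, function(s) {
    co <- generate_cohort(cohort_preset(
      "null", grid_dims = c(8L, 8L, 8L), seed = s,
      group_sizes = c(B1 = 15L, CON = 15L)))
    m <- colMeans(matrix(co$gmd, nrow = 512L))
    stats::t.test(m[co$subjects$biotype == "B1"],
                  m[co$subjects$biotype == "CON"])$p.value
  }, 0)
  expect_gt(min(pvals), 0)  # all tests ran
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_gt(mean(pvals > 0.05), 0.85)
})

test_that("clinical outcomes follow the linear outcome model", {
  co <- tiny_cohort(group_sizes = c(B1 = 30L, CON = 30L), seed = 77)
  expr <- pattern_expression(co)

  noiseless <- clinical_spec(data.frame(
    name = c("flat", "lin"), intercept = c(2, 0), slope = c(0, -1),
    offset_B1 = c(-1, 0), offset_B2 = 0, offset_B3 = 0,
    noise_sd = 0, missing_rate = 0))
  clin <- generate_clinical(co, noiseless, expr, seed = 5)
  grp <- co$subjects$biotype
  expect_equal(unique(clin$flat[grp == "CON"]), 2)
  expect_equal(unique(clin$flat[grp == "B1"]), 1)
  expect_equal(stats::cor(clin$lin, expr), -1)

  expect_error(
    generate_clinical(
      structure(list(gmd = co$gmd,
                     subjects = data.frame(id = "x", biotype = "XX"),
                     truth = co$truth, patterns = co$patterns),
                class = "gmd_cohort"),
      noiseless, 0, seed = 1),
    "unknown group label")
})

test_that("an OLS fit on generated outcomes recovers the configured slope", {
  spec <- cohort_preset("paper_like", grid_dims = c(10L, 10L, 10L), seed = 13,
                        group_sizes = c(B1 = 80L, B2 = 80L, B3 = 80L, CON = 80L))
  co <- generate_cohort(spec)
  expr <- pattern_expression(co)
  cs <- clinical_spec(data.frame(
    name = "y", intercept = 0.25, slope = -0.4, offset_B1 = -1.2,
    offset_B2 = -0.1, offset_B3 = -0.3, noise_sd = 1, missing_rate = 0))
  clin <- generate_clinical(co, cs, expr, seed = 99)
  grp <- factor(co$subjects$biotype)
  fit <- stats::lm(clin$y ~ expr + grp)
  est <- summary(fit)$coefficients["expr", ]
  expect_lt(abs(est["Estimate"] - (-0.4)), 2 * est["Std. Error"])
})

test_that("missingness is injected at the configured rate", {
  co <- tiny_cohort(group_sizes = c(B1 = 200L, CON = 200L), seed = 3,
                    grid_dims = c(6L, 6L, 6L))
  cs <- clinical_spec(data.frame(
    name = "y", intercept = 0, slope = 0, offset_B1 = 0, offset_B2 = 0,
    offset_B3 = 0, noise_sd = 1, missing_rate = 0.2))
  clin <- generate_clinical(co, cs, rep(0, 400), seed = 21)
  frac <- mean(is.na(clin$y))
  ci <- stats::binom.test(sum(is.na(clin$y)), 400, 0.2)$conf.int
  expect_true(0.2 >= ci[1] && 0.2 <= ci[2] || abs(frac - 0.2) < 0.06)
})

test_that("gm probability exceeds the mask threshold on an interior region", {
  co <- tiny_cohort(seed = 2)
  ctr <- co$gm_prob[5, 5, 5]
  expect_gt(ctr, 0.4)
  mask <- build_gm_mask(co$gm_prob, co$wm_prob, affine = co$affine)
  expect_gt(mask$n_voxels, 0)
  expect_lt(mask$n_voxels, length(mask$volume))  # both criteria bind
})

test_that("cohorts round-trip through NIfTI files on disk", {
  co <- tiny_cohort(group_sizes = c(B1 = 3L, CON = 3L),
                    grid_dims = c(6L, 6L, 6L), seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  img <- as.array(RNifti::readNifti(file.path(dir, paste0(co$subjects$id[2], ".nii.gz"))))
  expect_equal(img, co$gmd[, , , 2], tolerance = 1e-6, ignore_attr = TRUE)
  subj <- utils::read.csv(file.path(dir, "subjects.csv"))
  expect_equal(subj$biotype, co$subjects$biotype)
})
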
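# Shared fixtures, built in code at test time.

# A small cohort for unit tests: 10^3 grid, reduced group sizes.
tiny_cohort <- function(preset = "paper_like", seed = 101,
                        group_sizes = c(B1 = 12L, B2 = 12L, B3 = 12L, CON = 14L),
                        grid_dims = c(10L, 10L, 10L), ...) {
  generate_cohort(cohort_preset(preset, grid_dims = grid_dims, seed = seed,
                                group_sizes = group_sizes, ...))
}

tiny_features <- function(cohort) {
  mask <- build_gm_mask(cohort$gm_prob, cohort$wm_prob, affine = cohort$affine)
  extract_features(cohort, mask)
}

# The desk-scale study-condition fit shared by the acceptance and weight-map
# tests: paper_like preset at full group sizes, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

paper_fit <- function() {
  if (!is.null(.fixture_cache$fit)) return(.fixture_cache$fit)
  co <- generate_cohort(cohort_preset("paper_like", grid_dims = c(20L, 20L, 20L),
                                      seed = 42))
  mask <- build_gm_mask(co$gm_prob, co$wm_prob, affine = co$affine)
  fm <- extract_features(co, mask)
  fit <- gmd_rsplit(fm, co$subjects, "biotype", n_iterations = 150L,
                    master_seed = 7)
  .fixture_cache$fit <- fit
  fit
}
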
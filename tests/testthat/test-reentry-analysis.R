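test_that("reentrant labeling follows the n-plus-one and late-activation rules", {
  mesh <- generate_mesh(synthetic_spec(c(15, 15)))
  act <- plant_activation_fixture(mesh, "no_reentry", n_stimuli = 3)
  expect_equal(nrow(label_reentrant_activations(act, 3)), 0L)

  act1 <- plant_activation_fixture(mesh, "single_source", n_stimuli = 2)
  re <- label_reentrant_activations(act1, 2)
  # ground truth: exactly the planted extra wave reaches every element
  expect_equal(sort(unique(re$element)), mesh$elements$element)
  expect_equal(nrow(re), mesh$n_elements)

  # an element with n-1 pacing activations and one late activation:
  # the late one is reentrant despite its index being n
  rec <- tibble::tibble(element = c(1L, 1L), index = c(1L, 2L),
                        time_ms = c(10, 2500))
  re2 <- label_reentrant_activations(rec, 2, last_stimulus_ms = 1000,
                                     pacing_window_ms = 600)
  expect_equal(re2$time_ms, 2500)
})

test_that("the sub-50 ms merge rule keeps boundary cases exact", {
  expect_equal(merge_rapid_activations(c(1000, 1030, 1100)), c(1000, 1100))
  expect_equal(merge_rapid_activations(c(1000, 1049)), 1000)
  expect_equal(merge_rapid_activations(c(1000, 1050)), c(1000, 1050))
  # pairwise after each merge: 1030 is absorbed, then 1100 - 1000 >= 50
  expect_equal(merge_rapid_activations(c(0, 30, 60, 90, 140)), c(0, 60, 140))
  # idempotent and order-preserving on tables
  tb <- tibble::tibble(element = rep(1:2, each = 3),
                       time_ms = c(100, 120, 200, 5, 80, 90))
  m1 <- merge_rapid_activations(tb)
  expect_identical(merge_rapid_activations(m1), m1)
  expect_true(all(diff(m1$time_ms[m1$element == 1]) > 0))
})

test_that("initiation tracing recovers planted sources", {
  mesh <- generate_mesh(synthetic_spec(c(25, 25)))
  act <- plant_activation_fixture(mesh, "single_source", n_stimuli = 2)
  truth <- attr(act, "truth")
  re <- merge_rapid_activations(label_reentrant_activations(act, 2))
  cl <- trace_initiation(re, mesh, min_cluster = 1)
  expect_gte(nrow(cl), 1L)
  src <- mesh$elements[truth$source_elements[1], ]
  d <- sqrt((cl$x_mm[1] - src$x_mm)^2 + (cl$y_mm[1] - src$y_mm)^2)
  expect_lte(d, 0.53)  # within one element of the planted source

  # two sources 30 ms apart: two clusters at distinct back-trace steps
  act2 <- plant_activation_fixture(mesh, "two_source_merge", n_stimuli = 2)
  re2 <- merge_rapid_activations(label_reentrant_activations(act2, 2))
  cl2 <- trace_initiation(re2, mesh, min_cluster = 1)
  expect_equal(nrow(cl2), 2L)
  expect_equal(length(unique(cl2$t_ms)), 2L)

  # a min_cluster larger than any true cluster suppresses everything
  expect_equal(nrow(trace_initiation(re, mesh, min_cluster = 1e6)), 0L)
  # empty reentrant set: empty result
  expect_equal(nrow(trace_initiation(re[0, ], mesh)), 0L)
})

test_that("tracing equals the brute-force oracle on small meshes", {
  for (seed in 1:4) {
    mesh <- generate_mesh(synthetic_spec(c(12, 12)))
    set.seed(seed)
    # random reentrant pattern: smooth random arrival field + noise
    el <- mesh$elements
    t0 <- 2000 + 8 * sqrt((el$x_mm - runif(1, 0, 6))^2 +
                          (el$y_mm - runif(1, 0, 6))^2) +
      rnorm(mesh$n_elements, 0, runif(1, 0, 15))
    sub <- sample(mesh$n_elements, round(0.8 * mesh$n_elements))
    re <- tibble::tibble(element = el$element[sub], time_ms = t0[sub])
    got <- trace_initiation(re, mesh, step_ms = 10, min_cluster = 1)
    want <- oracle_clusters(re, mesh, step_ms = 10, min_cluster = 1)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      got_sets <- lapply(got$elements, sort)
      want_sets <- lapply(want, `[[`, "elements")
      # same collection of clusters, irrespective of ordering
      expect_setequal(sapply(got_sets, paste, collapse = ","),
                      sapply(want_sets, paste, collapse = ","))
    }
  }
})

test_that("cluster count is nonincreasing in min_cluster", {
  mesh <- generate_mesh(synthetic_spec(c(20, 20)))
  act <- plant_activation_fixture(mesh, "two_source_merge", n_stimuli = 2)
  re <- merge_rapid_activations(label_reentrant_activations(act, 2))
  ns <- vapply(c(1, 5, 20, 100, 1000), function(mc) {
    nrow(trace_initiation(re, mesh, min_cluster = mc))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("sustainment needs activity in the final observation frame", {
  re <- tibble::tibble(element = 1L, time_ms = 4900)
  expect_false(classify_sustained(re, last_pacing_ms = 1000,
                                  horizon_ms = 4000))
  re2 <- tibble::tibble(element = 1L, time_ms = 4995)
  expect_true(classify_sustained(re2, last_pacing_ms = 1000,
                                 horizon_ms = 4000))
  expect_error(classify_sustained(re[0, ], 1000), class = "fs_no_reentry")
})

test_that("morphology labels split on local mean LGE", {
  f <- tibble::tibble(mean_lge_pct = c(36.5, 1.5, 9.9, 10.0))
  m <- classify_morphology(f)
  expect_equal(m$morphology, c("Type1", "Type2", "Type2", "Type1"))
  expect_true(all(m$morphology_source == "heuristic"))
  expect_equal(classify_morphology(f, cutoff_pct = 0)$morphology,
               rep("Type1", 4))
  expect_error(classify_morphology(tibble::tibble()),
               class = "fs_feature_required")
})
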
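test_that("degenerate cleft rules remove nothing", {
  fx <- small_sheet(20, peak = 1)
  cm0 <- split_clefts(fx$mesh, fx$lge, cleft_params(0, seed = 1))
  expect_equal(nrow(cm0$removed_faces), 0L)
  expect_identical(cm0$retained, fx$mesh$adjacency)

  lge0 <- uniform_lge(fx$mesh, 0)
  cmz <- split_clefts(fx$mesh, lge0, cleft_params(0.9, seed = 1))
  expect_equal(nrow(cmz$removed_faces), 0L)
})

test_that("mismatched LGE map is rejected", {
  fx <- small_sheet(10)
  expect_error(split_clefts(fx$mesh, fx$lge[1:5, ], cleft_params(0.2)),
               class = "fs_dimension_error")
})

test_that("cleft removal matches its binomial expectation (Monte Carlo)", {
  # uniform I = 1, alpha = 0: every face is a fair p_max coin
  mesh <- generate_mesh(synthetic_spec(c(72, 72)))
  lge1 <- uniform_lge(mesh, 1)
  n_faces <- nrow(mesh$adjacency)
  expect_gte(n_faces, 10000)
  p <- 0.3
  counts <- vapply(1:100, function(s) {
    nrow(split_clefts(mesh, lge1,
                      cleft_params(p, alpha = 0, seed = s))$removed_faces)
  }, numeric(1))
  se_mean <- sqrt(n_faces * p * (1 - p)) / sqrt(100)
  expect_lt(abs(mean(counts) - n_faces * p), 3 * se_mean)

  # graded map: expected removed fraction equals the mean face probability
  fx <- small_sheet(40, peak = 0.8, seed = 9)
  pr <- fibrosim:::cleft_face_probability(fx$mesh, fx$lge,
                                          cleft_params(0.6, alpha = 2))
  counts2 <- vapply(1:100, function(s) {
    nrow(split_clefts(fx$mesh, fx$lge,
                      cleft_params(0.6, alpha = 2,
                                   seed = s))$removed_faces)
  }, numeric(1))
  se2 <- sqrt(sum(pr * (1 - pr))) / sqrt(100)
  expect_lt(abs(mean(counts2) - sum(pr)), 3 * se2)
})

test_that("anisotropy concentrates clefts on sheet-normal-aligned faces", {
  # fibers along x: the in-plane sheet normal is y, so only y-normal
  # (axis 2) faces can be severed at finite alpha; x faces have cos = 0
  mesh <- generate_mesh(synthetic_spec(c(40, 40), fiber_angle = 0))
  lge1 <- uniform_lge(mesh, 1)
  cm <- split_clefts(mesh, lge1, cleft_params(0.5, alpha = 8, seed = 2))
  expect_gt(nrow(cm$removed_faces), 0)
  expect_true(all(cm$removed_faces$axis == 2L))
})

test_that("isolated elements are pruned from the cleft mesh", {
  # force full severing: p = 1 everywhere, alpha 0
  mesh <- generate_mesh(synthetic_spec(c(5, 5)))
  cm <- split_clefts(mesh, uniform_lge(mesh, 1),
                     cleft_params(1, alpha = 0, seed = 1))
  expect_equal(nrow(cm$retained), 0L)
  expect_equal(cm$removed_elements, mesh$elements$element)
})

test_that("the fib_max ladder is ordered, anchored and deterministic", {
  fx <- small_sheet(30, peak = 1, seed = 5)
  lad <- build_fibmax_ladder(fx$mesh, fx$lge, seed = 5)
  n_rm <- vapply(lad, function(m) nrow(m$removed_faces), integer(1))
  expect_true(all(diff(n_rm) >= 0))
  expect_equal(n_rm[1], 0L)
  expect_equal(vapply(lad, `[[`, integer(1), "fib_max"), 0:9)
  lad2 <- build_fibmax_ladder(fx$mesh, fx$lge, seed = 5)
  expect_identical(lapply(lad, `[[`, "removed_faces"),
                   lapply(lad2, `[[`, "removed_faces"))
  expect_error(build_fibmax_ladder(fx$mesh, fx$lge,
                                   ladder = list(cleft_params(0))),
               class = "fs_config_error")
  expect_error(
    build_fibmax_ladder(fx$mesh, fx$lge,
                        ladder = lapply(seq(0.1, 1, 0.1), cleft_params)),
    class = "fs_config_error")
})

test_that("cleft-model conductivity bands follow the step-wise reduction rules", {
  ct <- default_conductivities()
  lge <- tibble::tibble(element = 1:6,
                        intensity = c(0, 0.1, 0.25, 0.3, 0.6, 0.8))
  ra <- assign_cleft_conductivity(lge, ct)
  expect_equal(ra$region,
               c("healthy", "band_0_25", "band_25_50", "band_25_50",
                 "band_50_75", "band_75_100"))
  # region CV targets: longitudinal kept then reduced; transverse stepped
  tgt <- ct[match(ra$region, ct$region), ]
  expect_equal(tgt$cv_l, c(54.4, 54.4, 54.4, 54.4, 0.6 * 54.4, 0.2 * 54.4))
  expect_equal(tgt$cv_t,
               c(33.5, 0.6 * 33.5, 0.2 * 33.5, 0.2 * 33.5, 0.2 * 33.5,
                 0.2 * 33.5))
  # sigma_l >= sigma_t > 0 in all conducting regions
  expect_true(all(ra$sigma_l >= ra$sigma_t & ra$sigma_t > 0))
})

test_that("non-cleft core thresholds nest and respect the map maximum", {
  fx <- small_sheet(30, peak = 1, seed = 6)
  cores <- lapply(c(25, 50, 75), function(cs) {
    ra <- assign_noncleft_regions(fx$lge, cs, "nc")
    ra$element[ra$region == "core"]
  })
  expect_true(all(cores[[1]] %in% cores[[2]]))
  expect_true(all(cores[[2]] %in% cores[[3]]))
  expect_gt(length(cores[[3]]), length(cores[[1]]))

  # threshold formula against a known maximum
  lge <- tibble::tibble(element = 1:5,
                        intensity = c(0, 0.2, 0.39, 0.41, 0.8))
  ra <- assign_noncleft_regions(lge, 50, "nc")
  expect_equal(ra$region,
               c("healthy", "border_zone", "border_zone", "core", "core"))
  expect_equal(ra$sigma_l[ra$region == "core"], rep(1e-7, 2))
  rc <- assign_noncleft_regions(lge, 50, "c")
  expect_equal(rc$sigma_l[rc$region == "core"], rep(0.01, 2))

  expect_error(assign_noncleft_regions(uniform_lge(fx$mesh, 0), 25, "nc"),
               class = "fs_no_fibrosis")
})
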
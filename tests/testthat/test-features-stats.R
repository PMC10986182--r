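test_that("local LGE features enumerate the 5 mm ball correctly", {
  mesh <- generate_mesh(synthetic_spec(c(21, 21)))
  ctr <- tibble::tibble(x_mm = 21 * 0.53 / 2, y_mm = 21 * 0.53 / 2,
                        z_mm = 0.265)
  f_half <- local_lge_features(ctr, mesh, uniform_lge(mesh, 0.5))
  expect_equal(f_half$mean_lge_pct, 50)
  expect_equal(f_half$max_lge_pct, 50)

  f_zero <- local_lge_features(ctr, mesh, uniform_lge(mesh, 0))
  expect_equal(f_zero$lge_volume_ml, 0)

  # hand-built map: single hot element inside the ball
  lge <- uniform_lge(mesh, 0)
  hot <- mesh$elements$element[mesh$elements$ix == 11 &
                                 mesh$elements$iy == 11]
  lge$intensity[hot] <- 1
  f_one <- local_lge_features(ctr, mesh, lge)
  expect_equal(f_one$max_lge_pct, 100)
  expect_equal(f_one$lge_volume_ml, 0.53^3 / 1000)
  # direct enumeration of the ball size
  el <- mesh$elements
  d2 <- (el$x_mm - ctr$x_mm)^2 + (el$y_mm - ctr$y_mm)^2 +
    (el$z_mm - ctr$z_mm)^2
  expect_equal(f_one$n_ball, sum(d2 <= 25))
})

test_that("features are invariant to element order and translation", {
  fx <- small_sheet(20, peak = 0.7, seed = 3)
  site <- tibble::tibble(x_mm = 5, y_mm = 5, z_mm = 0.265)
  a <- local_lge_features(site, fx$mesh, fx$lge)
  perm <- sample(nrow(fx$lge))
  b <- local_lge_features(site, fx$mesh, fx$lge[perm, ])
  expect_equal(a$mean_lge_pct, b$mean_lge_pct)
  expect_equal(a$lge_volume_ml, b$lge_volume_ml)
})

test_that("activation summaries order fractional activation times", {
  mesh <- generate_mesh(synthetic_spec(c(15, 15)))
  act <- plant_activation_fixture(mesh, "no_reentry", n_stimuli = 1)
  s <- activation_summary(act, mesh$n_elements)
  expect_true(all(s$reached))
  expect_lt(s$time_ms[s$fraction == 0.95], s$time_ms[s$fraction == 1])

  # one permanently silent element: 100% never reached
  act2 <- act[act$element != 1L, ]
  s2 <- activation_summary(act2, mesh$n_elements)
  expect_true(s2$reached[1])
  expect_false(s2$reached[2])
  expect_true(is.na(s2$time_ms[2]))
})

test_that("segment tables conserve initiation counts", {
  fx <- small_sheet(30, peak = 0.9, seed = 8)
  segments <- generate_segments(fx$mesh, 6)
  sites <- tibble::tibble(x_mm = c(2, 3, 14, 15.5), y_mm = c(2, 2.5, 8, 9),
                          z_mm = 0.265)
  tab <- segment_table(sites, fx$mesh, fx$lge, segments, core_size = 50)
  expect_equal(sum(tab$n_initiations), nrow(sites))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$core_volume_ml <= tab$lge_volume_ml + 1e-12))
})

test_that("negative binomial regression recovers a known slope", {
  # simulation oracle: NB counts with log link over a synthetic design
  gen_table <- function(seed, beta1 = 0.8, theta = 3) {
    set.seed(seed)
    n <- 170
    x <- runif(n, 0, 2)
    vol <- runif(n, 0, 1.5)
    eta <- -0.5 + beta1 * x + 0.4 * vol
    tibble::tibble(n_initiations = rnbinom(n, size = theta,
                                           mu = exp(eta)),
                   covar = x, lge_volume_ml = vol)
  }
  fits <- lapply(1:40, function(s) {
    tab <- gen_table(s)
    if (all(tab$n_initiations == 0)) return(NULL)
    fit <- nb_association(tab, covariate = "covar")
    td <- tidy(fit)
    td[td$term == "covar", ]
  })
  fits <- dplyr::bind_rows(fits)
  # slope sign always recovered; CI coverage near nominal
  expect_true(all(fits$estimate > 0))
  cover <- mean(abs(fits$estimate - 0.8) <= 1.96 * fits$std.error)
  expect_gte(cover, 0.85)
  # estimates center on the truth
  expect_lt(abs(mean(fits$estimate) - 0.8), 0.1)
})

test_that("a null covariate keeps type-I error near 5%", {
  set.seed(99)
  pvals <- vapply(1:60, function(s) {
    set.seed(s + 1000)
    n <- 170
    vol <- runif(n, 0, 1.5)
    y <- rnbinom(n, size = 3, mu = exp(-0.2 + 0.4 * vol))
    tab <- tibble::tibble(n_initiations = y, covar = runif(n),
                          lge_volume_ml = vol)
    fit <- suppressWarnings(nb_association(tab, covariate = "covar"))
    td <- tidy(fit)
    td$p.value[td$term == "covar"]
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("degenerate designs are rejected and constant groups dropped", {
  tab <- tibble::tibble(n_initiations = rep(0L, 20), covar = runif(20),
                        lge_volume_ml = runif(20), geometry = "g1")
  expect_error(nb_association(tab, covariate = "covar"),
               class = "fs_degenerate_fit")
  tab$n_initiations <- rpois(20, 2)
  expect_warning(fit <- nb_association(tab, covariate = "covar",
                                       grouping = "geometry"),
                 "constant")
  expect_false("factor(geometry)" %in% tidy(fit)$term)
  expect_error(nb_association(tab[1:5, ], covariate = "covar"),
               class = "fs_invalid_spec")
  tab$n_initiations[1] <- 1.5
  expect_error(nb_association(tab, covariate = "covar"),
               class = "fs_invalid_spec")
})
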
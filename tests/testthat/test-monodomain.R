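test_that("the diffusion operator reduces to the 5-point stencil on a homogeneous sheet", {
  mesh <- generate_mesh(synthetic_spec(c(5, 5)))
  regions <- tibble::tibble(element = 1:25, region = "healthy",
                            sigma_l = 0.2, sigma_t = 0.2)
  cfg <- sim_config()
  L <- assemble_diffusion(mesh, regions, config = cfg)
  h_m <- 530e-6
  w <- 0.2 / ((1400 * 100) * (1 * 0.01) * h_m^2) * 1e-3
  # interior element 13 couples to its 4 neighbors with identical weight
  expect_equal(L[13, 12], w)
  expect_equal(L[13, 14], w)
  expect_equal(L[13, 8], w)
  expect_equal(L[13, 18], w)
  expect_equal(L[13, 13], -4 * w)
  # symmetry and conservation
  expect_equal(max(abs(L - Matrix::t(L))), 0)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
})

test_that("assembly equals a brute-force edge-sum oracle under random severing", {
  mesh <- generate_mesh(synthetic_spec(c(5, 5), fiber_angle = 30))
  set.seed(3)
  regions <- tibble::tibble(element = 1:25, region = "x",
                            sigma_l = runif(25, 0.05, 0.3),
                            sigma_t = runif(25, 0.01, 0.05))
  adj <- mesh$adjacency
  sever <- runif(nrow(adj)) < 0.3
  cleft <- structure(list(mesh = mesh, removed_faces = adj[sever, ],
                          removed_elements = integer(0),
                          retained = adj[!sever, ],
                          params = cleft_params(0.3)),
                    class = "fs_cleft_mesh")
  cfg <- sim_config()
  L <- assemble_diffusion(mesh, regions, cleft = cleft, config = cfg)

  # oracle: loop over retained faces, accumulate dense matrix entry-wise
  dense <- matrix(0, 25, 25)
  f <- cbind(mesh$elements$fx, mesh$elements$fy, mesh$elements$fz)
  h_m <- 530e-6
  denom <- (1400 * 100) * 0.01 * h_m^2
  for (k in which(!sever)) {
    a <- adj$a[k]; b <- adj$b[k]; ax <- adj$axis[k]
    sig <- function(e) {
      regions$sigma_t[e] + (regions$sigma_l[e] - regions$sigma_t[e]) *
        f[e, ax]^2
    }
    s_h <- 2 * sig(a) * sig(b) / (sig(a) + sig(b))
    w <- s_h / denom * 1e-3
    dense[a, b] <- dense[a, b] + w
    dense[b, a] <- dense[b, a] + w
    dense[a, a] <- dense[a, a] - w
    dense[b, b] <- dense[b, b] - w
  }
  expect_equal(as.matrix(L), dense, ignore_attr = TRUE)

  # severed faces contribute exactly zero coupling
  for (k in which(sever)[1:5]) {
    expect_equal(L[adj$a[k], adj$b[k]], 0)
  }
})

test_that("missing conductivities fail assembly with the element named", {
  mesh <- generate_mesh(synthetic_spec(c(4, 4)))
  regions <- tibble::tibble(element = 1:16, region = "healthy",
                            sigma_l = c(NA, rep(0.2, 15)), sigma_t = 0.1)
  expect_error(assemble_diffusion(mesh, regions),
               class = "fs_assembly_error")
})

test_that("a full cleft line blocks propagation to the far side", {
  mesh <- generate_mesh(synthetic_spec(c(20, 20)))
  adj <- mesh$adjacency
  # sever every face crossing x mid-line
  sever <- adj$axis == 1L & mesh$elements$ix[adj$a] == 10L
  cleft <- structure(list(mesh = mesh, removed_faces = adj[sever, ],
                          removed_elements = integer(0),
                          retained = adj[!sever, ],
                          params = cleft_params(1)),
                    class = "fs_cleft_mesh")
  ct <- default_conductivities()
  h <- ct[ct$region == "healthy", ]
  regions <- tibble::tibble(element = mesh$elements$element,
                            region = "healthy", sigma_l = h$sigma_l,
                            sigma_t = h$sigma_t)
  model <- structure(list(mesh = mesh, lge = NULL, variant = "uniform",
                          level = NA, regions = regions, cleft = cleft,
                          operator = assemble_diffusion(mesh, regions,
                                                        cleft = cleft),
                          removed_elements = integer(0),
                          cell_region = rep(0L, 400),
                          cell_healthy = cell_params(),
                          cell_fibrotic = cell_params()),
                     class = "fs_model")
  stim <- tibble::tibble(onset_ms = 0, duration_ms = 10, amplitude = 100,
                         elements = list(select_electrode(mesh, c(0.5, 0.5))))
  sim <- simulate_tissue(model, stim, sim_config(duration = 400))
  near <- mesh$elements$element[mesh$elements$ix <= 10]
  far <- mesh$elements$element[mesh$elements$ix > 10]
  expect_true(all(near %in% sim$activation$element))
  expect_false(any(far %in% sim$activation$element))
})

test_that("quiescent tissue stays at rest and zero conductivity errors", {
  mesh <- generate_mesh(synthetic_spec(c(8, 8)))
  model <- fibrosim:::uniform_model(mesh, 0.2, 0.1)
  sim <- simulate_tissue(model,
                         tibble::tibble(onset_ms = numeric(0),
                                        duration_ms = numeric(0),
                                        amplitude = numeric(0),
                                        elements = list())[0, ],
                         sim_config(duration = 1000,
                                    stop_when_quiet = FALSE,
                                    record_frames = TRUE,
                                    output_interval = 100))
  expect_equal(nrow(sim$activation), 0L)
  expect_lt(max(abs(sim$frames - sim$frames[1, 1])), 0.5)

  expect_error(measure_cable_cv(0, "longitudinal"),
               class = "fs_propagation_failure")
})

test_that("cable CV scales like the square root of conductivity on a refined grid", {
  # continuum law checked on a refined cable; the coarse 530 um lattice
  # depresses slow velocities (which is exactly why conductivities are
  # calibrated on the discrete cable rather than scaled analytically)
  cv1 <- measure_cable_cv(0.05, "longitudinal", spacing_um = 120)
  cv4 <- measure_cable_cv(0.20, "longitudinal", spacing_um = 120)
  expect_lt(abs(cv4 / cv1 - 2), 0.2)
})

test_that("halving dt changes cable CV by less than 1%", {
  cv_a <- measure_cable_cv(0.15, "longitudinal", dt = 0.02)
  cv_b <- measure_cable_cv(0.15, "longitudinal", dt = 0.01)
  expect_lt(abs(cv_a - cv_b) / cv_b, 0.01)
})

test_that("calibration is monotone and brackets impossible targets", {
  lo <- calibrate_conductivity(20, tol_cv = 0.5)
  hi <- calibrate_conductivity(40, tol_cv = 0.5)
  expect_gt(hi$sigma, lo$sigma)
  expect_error(calibrate_conductivity(500),
               class = "fs_calibration_failure")
})

test_that("conduction anisotropy follows the calibrated velocity ratio", {
  # fibers along x with healthy sigma: the wave ellipse's axis ratio
  # should match the cable-calibrated CV ratio
  ct <- default_conductivities()
  h <- ct[ct$region == "healthy", ]
  mesh <- generate_mesh(synthetic_spec(c(41, 41)))
  model <- fibrosim:::uniform_model(mesh, h$sigma_l, h$sigma_t)
  ctr_el <- select_electrode(mesh, c(41 * 0.53 / 2, 41 * 0.53 / 2))
  stim <- tibble::tibble(onset_ms = 0, duration_ms = 5, amplitude = 100,
                         elements = list(ctr_el))
  sim <- simulate_tissue(model, stim, sim_config(duration = 300))
  act <- sim$activation[sim$activation$index == 1, ]
  el <- mesh$elements
  ctr <- (41 * 0.53) / 2
  t_at <- function(x, y) {
    id <- el$element[which.min((el$x_mm - x)^2 + (el$y_mm - y)^2)]
    act$time_ms[match(id, act$element)]
  }
  dx <- 8
  t_x <- (t_at(ctr + dx, ctr) + t_at(ctr - dx, ctr)) / 2
  t_y <- (t_at(ctr, ctr + dx) + t_at(ctr, ctr - dx)) / 2
  ratio <- t_y / t_x  # CV_x / CV_y
  expect_lt(abs(ratio - 54.4 / 33.5), 0.1 * 54.4 / 33.5)
})
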
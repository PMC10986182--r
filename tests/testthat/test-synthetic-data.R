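test_that("lattice meshes have the right extent, topology and fibers", {
  mesh <- generate_mesh(synthetic_spec(grid_shape = c(100, 100),
                                       spacing_um = 530))
  expect_equal(mesh$n_elements, 10000)
  # element centers span the sheet: extent = counts * spacing
  expect_equal(max(mesh$elements$x_mm) + 0.265, 53.0)
  expect_equal(max(mesh$elements$y_mm) + 0.265, 53.0)
  # every interior element has exactly 4 face neighbors
  deg <- tabulate(c(mesh$adjacency$a, mesh$adjacency$b),
                  nbins = mesh$n_elements)
  interior <- with(mesh$elements, ix > 1 & ix < 100 & iy > 1 & iy < 100)
  expect_true(all(deg[interior] == 4))
  expect_true(all(deg[!interior] %in% c(2, 3)))
  # unit fiber vectors
  nrm <- with(mesh$elements, sqrt(fx^2 + fy^2 + fz^2))
  expect_equal(nrm, rep(1, mesh$n_elements))
})

test_that("the calibration cable is a 189-element chain", {
  cab <- cable_mesh()
  expect_equal(cab$n_elements, 189L)
  expect_equal(nrow(cab$adjacency), 188L)
  deg <- tabulate(c(cab$adjacency$a, cab$adjacency$b), nbins = 189)
  expect_equal(sort(unique(deg)), c(1L, 2L))
})

test_that("invalid geometry specs are rejected", {
  expect_error(synthetic_spec(spacing_um = 0), class = "fs_invalid_spec")
  expect_error(synthetic_spec(grid_shape = c(1, 1)),
               class = "fs_invalid_spec")
  expect_error(synthetic_spec(intensity_peak = 1.2),
               class = "fs_invalid_spec")
})

test_that("LGE maps decay monotonically from the patch center and stay in [0,1]", {
  fx <- small_sheet(31, peak = 1)
  lge <- fx$lge
  el <- fx$mesh$elements
  ctr <- c(max(el$x_mm) + 0.265, max(el$y_mm) + 0.265) / 2
  d <- sqrt((el$x_mm - ctr[1])^2 + (el$y_mm - ctr[2])^2)
  ord <- order(d)
  expect_true(all(diff(lge$intensity[ord]) <= 1e-9))
  expect_equal(max(lge$intensity), 1)
  expect_true(any(lge$intensity == 0))

  # noisy maps remain clipped and keep healthy tissue at exactly zero
  fxn <- small_sheet(31, peak = 0.8, noise = 0.3)
  expect_true(all(fxn$lge$intensity >= 0 & fxn$lge$intensity <= 1))
  expect_true(all(fxn$lge$intensity[fx$lge$intensity == 0] == 0))
})

test_that("a zero-peak map is the healthy control and seeds reproduce bitwise", {
  spec0 <- synthetic_spec(c(20, 20), intensity_peak = 0)
  mesh <- generate_mesh(spec0)
  expect_true(all(generate_lge(spec0, mesh)$intensity == 0))

  spec <- synthetic_spec(c(25, 25), intensity_peak = 0.9, noise_sd = 0.1,
                         seed = 42)
  m <- generate_mesh(spec)
  expect_identical(generate_lge(spec, m), generate_lge(spec, m))
})

test_that("out-of-bounds patches warn and are clipped", {
  spec <- synthetic_spec(c(20, 20),
                         patch_centers = matrix(c(100, 100), 1))
  mesh <- generate_mesh(spec)
  expect_warning(lge <- generate_lge(spec, mesh), "clip")
  expect_true(all(lge$intensity >= 0 & lge$intensity <= 1))
})

test_that("segments partition the mesh into contiguous near-equal tiles", {
  mesh <- generate_mesh(synthetic_spec(c(40, 40)))
  for (n in c(1L, 4L, 17L)) {
    seg <- generate_segments(mesh, n)
    expect_equal(nrow(seg), mesh$n_elements)
    expect_equal(sort(unique(seg$segment)), seq_len(n))
    # oracle: tile boundaries by integer division along each axis
    divs <- which(n %% seq_len(n) == 0L)
    r <- max(divs[divs <= floor(sqrt(n))])
    cc <- n %/% r
    sizes <- table(seg$segment)
    # areas differ pairwise by at most one lattice row/column per axis
    expect_lte(max(sizes) - min(sizes),
               ceiling(40 / r) + ceiling(40 / cc))
    # contiguity: each segment's elements form one lattice rectangle
    for (s in unique(seg$segment)) {
      ii <- mesh$elements[seg$segment == s, ]
      expect_equal(nrow(ii),
                   length(unique(ii$ix)) * length(unique(ii$iy)))
    }
  }
})

test_that("planted fixtures carry exact kinematic ground truth", {
  mesh <- generate_mesh(synthetic_spec(c(20, 20)))
  act0 <- plant_activation_fixture(mesh, "no_reentry", n_stimuli = 3)
  expect_equal(nrow(act0), 3 * mesh$n_elements)
  expect_true(all(table(act0$element) == 3))

  act1 <- plant_activation_fixture(mesh, "single_source", n_stimuli = 2)
  truth <- attr(act1, "truth")
  # brute force: the planted source element is the earliest reentrant one
  extra <- act1[act1$index > 2, ]
  expect_equal(extra$element[which.min(extra$time_ms)],
               truth$source_elements[1])

  act2 <- plant_activation_fixture(mesh, "two_source_merge", n_stimuli = 2)
  truth2 <- attr(act2, "truth")
  expect_equal(length(truth2$source_elements), 2L)
  expect_equal(diff(truth2$source_onsets_ms), 30)

  expect_error(
    plant_activation_fixture(mesh, "single_source",
                             sources_xy = matrix(c(99, 99), 1)),
    class = "fs_invalid_spec")
})
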
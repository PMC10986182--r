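test_that("the full design enumerates to the published run count", {
  man <- enumerate_experiments(geometries = 1:5)
  expect_equal(nrow(man), 3145L)
  expect_equal(length(unique(paste(man$variant, man$level))), 37L)

  man1 <- enumerate_experiments(1, populations = list(noncleft_c = c(25, 50, 75)))
  expect_equal(nrow(man1), 51L)

  expect_equal(nrow(enumerate_experiments(1, populations = list())), 0L)
  expect_error(enumerate_experiments(1, populations = list(bogus = 1)),
               class = "fs_config_error")
  # manifest is the exact factor product
  man2 <- enumerate_experiments(1:2,
                                populations = list(cleft_gm = 0:3),
                                sites = 1:5)
  expect_equal(nrow(man2), 2 * 4 * 5)
  expect_equal(anyDuplicated(man2$run_id), 0L)
})

test_that("pacing sites are disjoint segment-centered electrodes", {
  mesh <- generate_mesh(synthetic_spec(c(40, 40)))
  seg <- generate_segments(mesh, 17)
  sites <- select_pacing_sites(mesh, seg)
  expect_equal(nrow(sites), 17L)
  all_el <- unlist(sites$elements)
  expect_equal(anyDuplicated(all_el), 0L)
  # electrode volume within one element of the 1 mm^3 target
  vol_el <- 0.53^3
  for (e in sites$elements) {
    expect_lte(abs(length(e) * vol_el - 1), vol_el)
  }
  seg1 <- generate_segments(mesh, 1)
  s1 <- select_pacing_sites(mesh, seg1)
  expect_equal(nrow(s1), 1L)
  ctr <- mesh$elements[s1$elements[[1]], ]
  expect_lt(abs(mean(ctr$x_mm) - 40 * 0.53 / 2), 1)
})

test_that("protocol specs validate their scan parameters", {
  expect_error(protocol_spec(s2_start_ms = 100, min_coupling_ms = 200),
               class = "fs_invalid_spec")
  expect_error(protocol_spec(decrement_ms = 0), class = "fs_invalid_spec")
})

test_that("a healthy sheet paces without reentry and logs ordered stimuli", {
  # homogeneous healthy tissue: the full protocol must never find reentry
  spec <- synthetic_spec(c(30, 30), intensity_peak = 0, seed = 2)
  mesh <- generate_mesh(spec)
  lge <- generate_lge(spec, mesh)
  model <- build_tissue_model(mesh, lge, "cleft_only", 0, seed = 2)
  seg <- generate_segments(mesh, 4)
  sites <- select_pacing_sites(mesh, seg)
  prot <- protocol_spec(s1_count = 2, s1_cl = 450, s2_start_ms = 400,
                        min_coupling_ms = 300, decrement_ms = 25,
                        observe_ms = 600, prepace_beats = 150)
  run <- run_protocol(model, sites[1, ], prot)
  expect_false(run$reentry)
  expect_false(run$sustained)
  expect_equal(nrow(run$reentrant), 0L)
  # stimulus log strictly ordered with positive gaps
  expect_true(all(diff(run$stimulus_log$onset_ms) > 0))
  # extrastimuli were captured at progressively recorded couplings
  expect_equal(run$captured_stimuli, 2L + run$extrastimuli)
  expect_equal(length(run$couplings_ms), run$extrastimuli)
  # every vertex activated by each captured stimulus (healthy tissue)
  expect_true(all(table(run$activation$element) >= run$captured_stimuli))
})
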
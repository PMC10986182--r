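test_that("HCM remodeling applies the eight ionic factors exactly once", {
  healthy <- cell_params()
  remod <- apply_hcm_remodeling(healthy)
  expect_equal(unname(remod$scale / healthy$scale),
               unname(hcm_remodeling_factors()))
  expect_equal(remod$scale[["i_to"]], 0.15)
  expect_equal(remod$scale[["i_nal"]], 2.07)
  expect_error(apply_hcm_remodeling(remod), class = "fs_invalid_spec")
})

test_that("the resting cell is stable and excitable", {
  # settle the nominal state to this model's own equilibrium first (the
  # added late sodium current shifts it slightly), then check stability
  settled <- pace_single_cell(n_beats = 1, bcl = 5000, stim_amp = 0,
                              stim_dur = 0)$state
  st1 <- step_cell(settled, dt = 0.02, i_stim = 0)
  expect_lt(abs(st1[["v"]] - settled[["v"]]) / 0.02, 0.01)
  # published resting potential of the formulation
  expect_lt(abs(settled[["v"]] + 86.2), 1)

  # suprathreshold stimulus elicits an upstroke with positive overshoot
  p <- pace_single_cell(n_beats = 1, bcl = 400, stim_amp = 52)
  expect_gt(max(p$trace$v_mv), 0)
  # gates stay in [0, 1] through the beat
  gates <- p$state[c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d",
                     "f", "f2", "fcass", "ml", "hl")]
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("long unpaced integration stays at the published resting state", {
  # independent equilibrium check: 10 s free-running integration
  r <- pace_single_cell(n_beats = 1, bcl = 10000, stim_amp = 0,
                        stim_dur = 0)
  expect_lt(abs(tail(r$trace$v_mv, 1) + 86.2), 1)
})

test_that("gates remain in [0,1] under randomized stimulation", {
  set.seed(7)
  st <- cell_state()
  gate_names <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f",
                  "f2", "fcass", "ml", "hl")
  for (i in 1:400) {
    st <- step_cell(st, dt = 0.02, i_stim = runif(1, -30, 80))
    # check every 20 steps to keep the loop cheap
    if (i %% 20 == 0) {
      expect_true(all(st[gate_names] >= 0 & st[gate_names] <= 1))
    }
  }
})

test_that("apd90 measures analytic traces exactly", {
  # square pulse of width w: APD90 equals w up to one sample
  dt <- 0.1
  t <- seq(0, 400, by = dt)
  w <- 200
  v <- ifelse(t > 50 & t <= 50 + w, 30, -86)
  expect_lt(abs(apd90(tibble::tibble(time_ms = t, v_mv = v)) - w), 2 * dt)

  # linear repolarization with a known 90% crossing
  vrest <- -80; vpeak <- 20
  v2 <- c(rep(vrest, 10), vpeak - (0:299) * 0.5)
  v2 <- pmax(v2, vrest)
  t2 <- seq_along(v2) * dt
  v90 <- vrest + 0.1 * (vpeak - vrest)  # -70
  # crossing at sample where vpeak - 0.5k = v90 -> k = 180
  expected <- 180 * dt
  expect_lt(abs(apd90(tibble::tibble(time_ms = t2, v_mv = v2)) - expected),
            2 * dt)

  # two action potentials: first is measured, with a warning
  v3 <- c(v, v)
  t3 <- seq_along(v3) * dt
  expect_warning(a3 <- apd90(tibble::tibble(time_ms = t3, v_mv = v3)),
                 "multiple")
  expect_lt(abs(a3 - w), 2 * dt)

  expect_error(apd90(tibble::tibble(time_ms = t, v_mv = rep(-86, length(t)))),
               class = "fs_no_ap")
})

test_that("pacing converges and halving dt barely moves APD90", {
  p1 <- pace_single_cell(bcl = 500, n_beats = 60, ss_tol_ms = 0.5)
  expect_true(p1$converged)
  p_dt <- pace_single_cell(bcl = 500, n_beats = 30, dt = 0.02)
  p_dt2 <- pace_single_cell(bcl = 500, n_beats = 30, dt = 0.01)
  expect_lt(abs(p_dt$apd90 - p_dt2$apd90), 1)
})

test_that("remodeled cells have longer APD than healthy at 500 ms BCL", {
  h <- pace_single_cell(cell_params(), bcl = 500, n_beats = 120)
  m <- pace_single_cell(apply_hcm_remodeling(cell_params()), bcl = 500,
                        n_beats = 120)
  expect_gt(m$apd90, h$apd90 + 20)
})

test_that("the tabulated-rate path matches direct evaluation", {
  a <- pace_single_cell(bcl = 500, n_beats = 20, use_lut = TRUE)
  b <- pace_single_cell(bcl = 500, n_beats = 20, use_lut = FALSE)
  expect_lt(abs(a$apd90 - b$apd90), 0.1)
  expect_lt(max(abs(a$state - b$state)), 1e-3)
})
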
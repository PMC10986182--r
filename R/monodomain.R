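#' Simulation configuration
#'
#' Numerical settings of the monodomain solver. The surface-to-volume
#' ratio and membrane capacitance are the standard monodomain constants;
#' voltage frames are recorded every `output_interval` ms (10 ms default,
#' the resolution at which reentry tracing operates) when
#' `record_frames = TRUE`. Activation is the upward crossing of
#' `activation_threshold` (default -40 mV).
#'
#' @param dt Integration step in ms.
#' @param duration Simulated time in ms.
#' @param output_interval Voltage-frame interval in ms (also the
#'   back-trace step of the reentry tracer).
#' @param activation_threshold Upstroke detection threshold in mV.
#' @param beta_cm Surface-to-volume ratio in 1/cm (default 1400).
#' @param cm_uf_cm2 Membrane capacitance in uF/cm^2 (default 1).
#' @param record_frames Record voltage frames (memory permitting).
#' @param use_lut Use tabulated membrane rates (default TRUE).
#' @param stop_when_quiet Terminate once all activity has ceased.
#' @param quiet_v Voltage ceiling defining quiescence (mV).
#' @param quiet_after Earliest time (ms) at which the quiescence stop may
#'   trigger; `NULL` means after the last stimulus ends.
#' @return An object of class `fs_sim_config`.
#' @export
sim_config <- function(dt = 0.02, duration = 1000, output_interval = 10,
                       activation_threshold = -40, beta_cm = 1400,
                       cm_uf_cm2 = 1, record_frames = FALSE, use_lut = TRUE,
                       stop_when_quiet = TRUE, quiet_v = -65,
                       quiet_after = NULL) {
  if (dt <= 0 || output_interval < dt) {
    abort_fs("need dt > 0 and output_interval >= dt", "fs_invalid_spec")
  }
  structure(list(dt = dt, duration = duration,
                 output_interval = output_interval,
                 activation_threshold = activation_threshold,
                 beta_cm = beta_cm, cm_uf_cm2 = cm_uf_cm2,
                 record_frames = record_frames, use_lut = use_lut,
                 stop_when_quiet = stop_when_quiet, quiet_v = quiet_v,
                 quiet_after = quiet_after),
            class = "fs_sim_config")
}

#' Assemble the anisotropic monodomain diffusion operator
#'
#' Builds the sparse coupling operator on the element lattice. Each
#' retained face between elements `a` and `b` contributes a conductance
#' from the harmonic mean of the two elements' conductivities projected on
#' the face normal (`sigma_t + (sigma_l - sigma_t) (f . n)^2`), scaled by
#' the surface-to-volume ratio, membrane capacitance and element size to
#' units of 1/ms. Faces severed by cleft splitting contribute exactly
#' zero coupling (the no-flux cleft contract), and the operator is
#' symmetric with zero row sums (sealed exterior boundary).
#'
#' @param mesh An `fs_mesh`.
#' @param regions Region assignment tibble with `sigma_l`, `sigma_t`.
#' @param cleft Optional `fs_cleft_mesh`; its retained adjacency replaces
#'   the full adjacency.
#' @param config [sim_config()] supplying `beta_cm` and `cm_uf_cm2`.
#' @return A `Matrix::sparseMatrix` (dgCMatrix, n x n, units 1/ms) with
#'   positive off-diagonal couplings and `-rowSums` on the diagonal.
#' @export
assemble_diffusion <- function(mesh, regions, cleft = NULL,
                               config = sim_config()) {
  stopifnot(inherits(mesh, "fs_mesh"))
  n <- mesh$n_elements
  if (nrow(regions) != n || anyNA(regions$sigma_l) || anyNA(regions$sigma_t)) {
    bad <- which(is.na(regions$sigma_l) | is.na(regions$sigma_t))[1]
    abort_fs(paste0("conductivity missing for element ",
                    if (is.na(bad)) "(count mismatch)" else bad),
             "fs_assembly_error")
  }
  adj <- if (is.null(cleft)) mesh$adjacency else cleft$retained
  el <- mesh$elements
  f <- cbind(el$fx, el$fy, el$fz)
  # sigma projected on each face normal, per adjacent element
  proj <- function(e, axis) {
    fn <- f[e, ][cbind(seq_along(e), axis)]
    regions$sigma_t[e] + (regions$sigma_l[e] - regions$sigma_t[e]) * fn^2
  }
  sa <- proj(adj$a, adj$axis)
  sb <- proj(adj$b, adj$axis)
  s_face <- ifelse(sa + sb > 0, 2 * sa * sb / (sa + sb), 0)
  h_m <- mesh$spacing_um * 1e-6
  denom <- (config$beta_cm * 100) * (config$cm_uf_cm2 * 0.01) * h_m^2
  w <- s_face / denom * 1e-3  # 1/s -> 1/ms
  L <- Matrix::sparseMatrix(i = c(adj$a, adj$b), j = c(adj$b, adj$a),
                            x = c(w, w), dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  L
}

# CSR pieces (0-based) of the coupling operator restricted to `keep`
# (logical). Diagonal entries are dropped; the integrator uses the
# (V_j - V_i) form, so row sums are implicit.
operator_csr <- function(L, keep) {
  sub <- L[keep, keep, drop = FALSE]
  sub <- methods::as(sub, "generalMatrix")
  tr <- Matrix::t(sub)  # CSC of transpose = CSR of sub; sub is symmetric
  p <- tr@p
  idx <- tr@i
  w <- tr@x
  off <- idx != rep(seq_len(ncol(tr)) - 1L, diff(p))
  # rebuild pointers without diagonal entries
  row_of <- rep(seq_len(ncol(tr)), diff(p))
  row_of <- row_of[off]
  idx <- idx[off]
  w <- w[off]
  ptr <- c(0L, cumsum(tabulate(row_of, nbins = ncol(tr))))
  list(ptr = as.integer(ptr), idx = as.integer(idx), w = as.numeric(w))
}

#' Select an electrode element set
#'
#' Nearest elements to a target point totaling the requested electrode
#' volume (default 1 mm^3, the pacing-electrode size used throughout).
#'
#' @param mesh An `fs_mesh`.
#' @param center_xy Target point (mm), length 2 or 3.
#' @param volume_mm3 Electrode volume.
#' @param candidates Optional element ids to restrict the search to
#'   (e.g. one segment, keeping neighboring electrodes disjoint).
#' @return Integer vector of element ids.
#' @export
select_electrode <- function(mesh, center_xy, volume_mm3 = 1,
                             candidates = NULL) {
  el <- mesh$elements
  if (!is.null(candidates)) el <- el[el$element %in% candidates, ]
  h_mm <- mesh$spacing_um / 1000
  vol_el <- h_mm^3
  k <- max(1L, as.integer(round(volume_mm3 / vol_el)))
  z <- if (length(center_xy) >= 3) center_xy[3] else mean(el$z_mm)
  d <- sqrt((el$x_mm - center_xy[1])^2 + (el$y_mm - center_xy[2])^2 +
            (el$z_mm - z)^2)
  el$element[order(d)][seq_len(min(k, nrow(el)))]
}

#' Simulate monodomain propagation on a tissue model
#'
#' Runs the compiled reaction-diffusion integrator on an assembled model:
#' per-element membrane states (healthy or HCM-remodeled kinetics by
#' region), the cleft-aware diffusion operator, and a list of stimuli.
#' Elements pruned by cleft isolation are excluded from the simulation and
#' never appear in the activation record.
#'
#' @param model An `fs_model` from [build_tissue_model()].
#' @param stimuli Tibble with columns `onset_ms`, `duration_ms`,
#'   `amplitude` (uA/uF) and list-column `elements` (integer element ids).
#' @param config [sim_config()].
#' @param state0 Optional initial state matrix (elements x 21) from a
#'   previous run's `state`, for protocol checkpointing.
#' @return An object of class `fs_sim`: `activation` (tibble `element`,
#'   `index`, `time_ms`, class `fs_activation`), `state`, `t_end`,
#'   `stopped_early`, and (optionally) voltage `frames` with
#'   `frame_times`.
#' @export
simulate_tissue <- function(model, stimuli, config = sim_config(),
                            state0 = NULL) {
  stopifnot(inherits(model, "fs_model"))
  n <- model$mesh$n_elements
  keep <- rep(TRUE, n)
  if (length(model$removed_elements)) keep[model$removed_elements] <- FALSE
  kept_ids <- which(keep)
  remap <- integer(n)
  remap[kept_ids] <- seq_along(kept_ids)

  csr <- operator_csr(model$operator, keep)
  region <- model$cell_region[keep]  # 0 healthy, 1 fibrotic
  scales <- rbind(unname(model$cell_healthy$scale),
                  unname(model$cell_fibrotic$scale))
  gnal <- c(model$cell_healthy$g_nal, model$cell_fibrotic$g_nal)

  if (nrow(stimuli) > 0) {
    stim_cells <- lapply(stimuli$elements, function(e) {
      e <- intersect(as.integer(e), kept_ids)
      remap[e] - 1L
    })
  } else {
    stim_cells <- list()
  }
  stim_ptr <- c(0L, cumsum(vapply(stim_cells, length, integer(1))))
  quiet_after <- config$quiet_after %||%
    (if (nrow(stimuli)) max(stimuli$onset_ms + stimuli$duration_ms) + 100
     else 0)

  st0 <- NULL
  if (!is.null(state0)) {
    stopifnot(nrow(state0) == length(kept_ids))
    st0 <- state0
  }
  r <- .fs_simulate(csr$ptr, csr$idx, csr$w, as.integer(region), scales,
                    gnal, variant_code(model$cell_healthy$variant),
                    as.numeric(stimuli$onset_ms),
                    as.numeric(stimuli$duration_ms),
                    as.numeric(stimuli$amplitude),
                    as.integer(stim_ptr),
                    as.integer(unlist(stim_cells) %||% integer(0)),
                    config$dt, config$duration, config$output_interval,
                    config$activation_threshold, config$record_frames,
                    st0, config$use_lut, config$stop_when_quiet,
                    config$quiet_v, quiet_after)
  act <- as_tibble(r$activation)
  act$element <- kept_ids[act$element]
  class(act) <- c("fs_activation", class(act))
  out <- list(activation = act, state = r$state, t_end = r$t_end,
              stopped_early = r$stopped_early, kept_elements = kept_ids,
              config = config)
  if (config$record_frames) {
    out$frames <- r$frames
    out$frame_times <- r$frame_times
  }
  structure(out, class = "fs_sim")
}

#' @export
print.fs_sim <- function(x, ...) {
  cat(sprintf("<fs_sim> %d elements, t_end %.0f ms%s; %d activations\n",
              length(x$kept_elements), x$t_end,
              if (x$stopped_early) " (quiescent stop)" else "",
              nrow(x$activation)))
  invisible(x)
}

# all-healthy model on an arbitrary mesh with explicit sigmas (internal,
# used by cable measurements)
uniform_model <- function(mesh, sigma_l, sigma_t, cell = cell_params(),
                          config = sim_config()) {
  regions <- tibble(element = mesh$elements$element, region = "healthy",
                    sigma_l = sigma_l, sigma_t = sigma_t)
  L <- assemble_diffusion(mesh, regions, config = config)
  structure(list(mesh = mesh, lge = NULL, variant = "uniform",
                 level = NA, regions = regions, cleft = NULL,
                 operator = L, removed_elements = integer(0),
                 cell_region = rep(0L, mesh$n_elements),
                 cell_healthy = cell, cell_fibrotic = cell),
            class = "fs_model")
}

#' Measure conduction velocity on the standard cable
#'
#' Stimulates one end of the 10 cm / 530 micron cable (10 ms, 100 uA/uF
#' over the first millimeter) and reports velocity from the activation
#' times at the 25% and 75% cable positions, away from boundary and
#' stimulus artifacts.
#'
#' @param sigma Conductivity in S/m along the propagation direction.
#' @param direction `"longitudinal"` (fibers along the cable) or
#'   `"transverse"` (fibers across it); with an isotropic assignment of
#'   `sigma` to the propagating direction the label is bookkeeping, kept
#'   so calibrated values are stored against the right target.
#' @param spacing_um,length_cm Cable discretization.
#' @param cell [cell_params()] used for every element.
#' @param dt Integration step (ms).
#' @param max_ms Simulation cap; slow waves need a few seconds.
#' @return Conduction velocity in cm/s.
#' @export
measure_cable_cv <- function(sigma, direction = c("longitudinal",
                                                  "transverse"),
                             spacing_um = 530, length_cm = 10,
                             cell = cell_params(), dt = 0.02,
                             max_ms = 2500) {
  direction <- match.arg(direction)
  if (sigma <= 0) abort_fs("conductivity must be positive; wave cannot propagate",
                           "fs_propagation_failure")
  mesh <- cable_mesh(length_cm, spacing_um,
                     fiber = if (direction == "longitudinal") "along"
                             else "across")
  config <- sim_config(dt = dt, duration = max_ms, stop_when_quiet = TRUE,
                       record_frames = FALSE)
  model <- uniform_model(mesh, sigma, sigma, cell, config)
  electrode <- mesh$elements$element[mesh$elements$x_mm <= 1.0]
  stimuli <- tibble(onset_ms = 0, duration_ms = 10, amplitude = 100,
                    elements = list(electrode))
  sim <- simulate_tissue(model, stimuli, config)
  act <- sim$activation[sim$activation$index == 1L, ]
  x <- mesh$elements$x_mm
  i25 <- which.min(abs(x - 0.25 * max(x)))
  i75 <- which.min(abs(x - 0.75 * max(x)))
  t25 <- act$time_ms[match(i25, act$element)]
  t75 <- act$time_ms[match(i75, act$element)]
  if (is.na(t25) || is.na(t75) || t75 <= t25) {
    abort_fs(sprintf("wave failed to propagate along the cable (sigma = %g S/m)",
                     sigma), "fs_propagation_failure")
  }
  (x[i75] - x[i25]) / (t75 - t25) * 100  # mm/ms -> cm/s
}

#' Calibrate conductivity against a target conduction velocity
#'
#' Bisection on log-conductivity using [measure_cable_cv()] on the
#' standard cable until the measured velocity is within `tol_cv` of the
#' target. Discrete-lattice effects make this the only reliable route
#' from velocity targets to conductivities; analytic square-root scaling
#' is biased at slow velocities.
#'
#' @param target_cv Target velocity in cm/s.
#' @param direction As in [measure_cable_cv()].
#' @param tol_cv Velocity tolerance (cm/s, default 0.1).
#' @param bracket Conductivity search bracket in S/m.
#' @param ... Passed to [measure_cable_cv()].
#' @return List with `sigma` (S/m), `cv` (achieved, cm/s), `iterations`.
#' @export
calibrate_conductivity <- function(target_cv,
                                   direction = c("longitudinal",
                                                 "transverse"),
                                   tol_cv = 0.1, bracket = c(0.002, 4),
                                   ...) {
  direction <- match.arg(direction)
  lo <- log(bracket[1]); hi <- log(bracket[2])
  cv_lo <- tryCatch(measure_cable_cv(exp(lo), direction, ...),
                    fibrosim_error = function(e) 0)
  cv_hi <- measure_cable_cv(exp(hi), direction, ...)
  if (target_cv < cv_lo || target_cv > cv_hi) {
    abort_fs(sprintf(
      "target CV %.2f cm/s outside achievable bracket [%.2f, %.2f] cm/s",
      target_cv, cv_lo, cv_hi), "fs_calibration_failure")
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    cv <- tryCatch(measure_cable_cv(exp(mid), direction, ...),
                   fibrosim_error = function(e) 0)
    if (abs(cv - target_cv) < tol_cv || it >= 60L) {
      if (abs(cv - target_cv) >= tol_cv) {
        abort_fs("calibration failed to converge", "fs_calibration_failure")
      }
      return(list(sigma = exp(mid), cv = cv, iterations = it))
    }
    if (cv < target_cv) lo <- mid else hi <- mid
  }
}
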
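#' Myocyte membrane-model parameters
#'
#' Parameter container for the human ventricular cell model (ten Tusscher
#' 2006 kinetics with the O'Hara-Rudy late sodium current added to the
#' total membrane current). The fixed kinetics live in compiled code; this
#' object carries the choices that vary across the package: the transmural
#' cell variant, the baseline late-sodium conductance, and eight ionic
#' scale factors (all 1 = healthy tissue).
#'
#' @param variant Transmural variant: `"epi"` (default; its
#'   steady-state action-potential duration at a 500 ms cycle is closest
#'   to the healthy tissue target), `"endo"`, or `"M"`.
#' @param g_nal Baseline late sodium conductance (mS/uF); the default
#'   0.0075 is the published endocardial value of the donor formulation.
#' @param scale Named numeric vector of ionic scale factors
#'   (`i_nal`, `i_cal`, `i_kr`, `i_ks`, `i_to`, `i_k1`, `ncx`, `serca`).
#' @return An object of class `fs_cell_params`.
#' @examples
#' cell_params()
#' apply_hcm_remodeling(cell_params())
#' @export
cell_params <- function(variant = c("epi", "endo", "M"), g_nal = 0.0075,
                        scale = NULL) {
  variant <- match.arg(variant)
  sc <- c(i_nal = 1, i_cal = 1, i_kr = 1, i_ks = 1, i_to = 1, i_k1 = 1,
          ncx = 1, serca = 1)
  if (!is.null(scale)) {
    if (!all(names(scale) %in% names(sc))) {
      abort_fs("unknown scale factor name", "fs_invalid_spec")
    }
    sc[names(scale)] <- scale
  }
  if (any(sc < 0) || g_nal < 0) {
    abort_fs("conductance scales must be >= 0", "fs_invalid_spec")
  }
  structure(list(variant = variant, g_nal = g_nal, scale = sc,
                 remodeled = FALSE),
            class = "fs_cell_params")
}

#' @export
print.fs_cell_params <- function(x, ...) {
  cat(sprintf("<fs_cell_params> variant %s, g_NaL %g%s\n", x$variant,
              x$g_nal, if (x$remodeled) ", HCM-remodeled" else ""))
  print(x$scale)
  invisible(x)
}

variant_code <- function(variant) {
  match(variant, c("epi", "endo", "M")) - 1L
}

#' Apply hypertrophic-cardiomyopathy ionic remodeling
#'
#' Multiplies the healthy scale factors by the eight remodeling factors
#' measured in hypertrophic cardiomyopathy cardiomyocytes: late sodium
#' +107% and L-type calcium +19%; IKr -34%, IKs -27%, Ito -85%, IK1 -15%;
#' sodium-calcium exchanger +34% and SERCA uptake -43%. Applied to every
#' element of the fibrotic region in remodeled model populations. Applying
#' it twice is rejected.
#'
#' @param params Healthy [cell_params()].
#' @return Remodeled `fs_cell_params`.
#' @export
apply_hcm_remodeling <- function(params) {
  stopifnot(inherits(params, "fs_cell_params"))
  if (isTRUE(params$remodeled)) {
    abort_fs("parameters are already HCM-remodeled", "fs_invalid_spec")
  }
  f <- hcm_remodeling_factors()
  params$scale <- params$scale * f
  params$remodeled <- TRUE
  params
}

#' @rdname apply_hcm_remodeling
#' @export
hcm_remodeling_factors <- function() {
  c(i_nal = 2.07, i_cal = 1.19, i_kr = 0.66, i_ks = 0.73, i_to = 0.15,
    i_k1 = 0.85, ncx = 1.34, serca = 0.57)
}

#' Advance a single cell one time step
#'
#' One forward step of the membrane model (Rush-Larsen gates, forward
#' Euler voltage and concentrations). Mostly useful for tests and custom
#' integration loops; tissue runs use the compiled integrator directly.
#'
#' @param state Named numeric state vector (see [cell_state()]).
#' @param params [cell_params()].
#' @param dt Time step in ms (stability requires roughly `dt <= 0.02`).
#' @param i_stim Stimulus current in uA/uF (positive depolarizes).
#' @return The advanced state vector.
#' @export
step_cell <- function(state, params = cell_params(), dt = 0.02,
                      i_stim = 0) {
  stopifnot(inherits(params, "fs_cell_params"))
  out <- .fs_step_cell(as.numeric(state), unname(params$scale),
                       params$g_nal, variant_code(params$variant), dt,
                       i_stim)
  names(out) <- names(cell_state())
  out
}

#' Default resting cell state
#'
#' @return Named numeric vector of the 21 state variables (voltage, gates,
#'   intracellular concentrations) at the model's nominal resting values.
#' @export
cell_state <- function() {
  out <- .fs_default_state()
  names(out) <- c("v", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d",
                  "f", "f2", "fcass", "rr", "cai", "casr", "cass", "nai",
                  "ki", "ml", "hl")
  out
}

#' Pace a single cell to steady state
#'
#' Delivers a stimulus train at a fixed basic cycle length and returns the
#' final beat's voltage trace plus the per-beat APD90 history. The default
#' 1,000 pre-pacing beats take a few seconds with the lookup-table path;
#' an optional steady-state stop ends pacing early once APD90 changes by
#' less than `ss_tol_ms` over `ss_window` beats.
#'
#' @param params [cell_params()].
#' @param bcl Basic cycle length in ms.
#' @param n_beats Maximum number of beats (default 1000).
#' @param dt Integration step (ms).
#' @param stim_amp,stim_dur Stimulus amplitude (uA/uF) and duration (ms).
#' @param record_dt Sampling interval of the returned trace (ms).
#' @param ss_tol_ms Steady-state APD90 tolerance; 0 disables early stop.
#' @param ss_window Beat lag used by the steady-state check.
#' @param use_lut Use the tabulated-rates fast path (default TRUE).
#' @return List of class `fs_pacing`: `trace` (tibble `time_ms`, `v_mv`
#'   of the final beat), `apd90_ms` (per beat), `apd90` (final beat),
#'   `beats_run`, `converged`, `capture_failure` (no action potential on
#'   the final beat), and the final `state`.
#' @examples
#' \donttest{
#' p <- pace_single_cell(cell_params(), bcl = 500, n_beats = 50)
#' p$apd90
#' }
#' @export
pace_single_cell <- function(params = cell_params(), bcl = 500,
                             n_beats = 1000, dt = 0.02, stim_amp = 52,
                             stim_dur = 1, record_dt = 0.1, ss_tol_ms = 0,
                             ss_window = 10, use_lut = TRUE) {
  stopifnot(inherits(params, "fs_cell_params"))
  if (bcl <= 0 || n_beats < 1) abort_fs("bcl and n_beats must be positive",
                                        "fs_invalid_spec")
  r <- .fs_pace_cell(unname(params$scale), params$g_nal,
                     variant_code(params$variant), bcl, as.integer(n_beats),
                     dt, stim_amp, stim_dur, record_dt, ss_tol_ms,
                     as.integer(ss_window), NULL, use_lut)
  apd <- r$apd90
  structure(
    list(trace = tibble(time_ms = r$time, v_mv = r$v),
         apd90_ms = apd, apd90 = apd[length(apd)],
         beats_run = r$beats_run, converged = r$converged,
         capture_failure = !is.finite(apd[length(apd)]),
         state = stats::setNames(r$state, names(cell_state())),
         params = params, bcl = bcl),
    class = "fs_pacing")
}

#' @export
print.fs_pacing <- function(x, ...) {
  cat(sprintf(
    "<fs_pacing> %d beats at %g ms BCL; final APD90 %.1f ms%s\n",
    x$beats_run, x$bcl, x$apd90,
    if (x$capture_failure) " [capture failure]" else ""))
  invisible(x)
}

#' Action-potential duration at 90% repolarization
#'
#' Duration from the maximum-upstroke-velocity time to the first downward
#' crossing of `V_rest + 0.1 * (V_peak - V_rest)`, with linear
#' interpolation between samples. If the trace holds more than one action
#' potential, the first is measured and a warning is emitted.
#'
#' @param trace Tibble or data frame with `time_ms` and `v_mv` columns
#'   (an [pace_single_cell()] trace), or a numeric voltage vector with
#'   `time_ms` supplied separately.
#' @param time_ms Optional time vector when `trace` is numeric.
#' @return APD90 in ms.
#' @export
apd90 <- function(trace, time_ms = NULL) {
  if (is.numeric(trace) && !is.null(time_ms)) {
    v <- trace; t <- time_ms
  } else {
    v <- trace$v_mv; t <- trace$time_ms
  }
  if (length(v) < 3) abort_fs("trace too short", "fs_no_ap")
  dv <- diff(v)
  up <- which(dv > 1)  # mV per sample; upstroke is steep at any sane dt
  if (length(up) == 0) abort_fs("no upstroke found in trace", "fs_no_ap")
  # group upstroke samples into distinct APs
  gaps <- which(diff(up) > 1)
  starts <- up[c(1, gaps + 1)]
  if (length(starts) > 1) {
    warning("trace contains multiple action potentials; measuring the first")
  }
  seg_end <- if (length(starts) > 1) starts[2] - 1 else length(v)
  dv_first <- dv[seq_len(seg_end - 1)]
  i_up <- which.max(dv_first)
  vrest <- v[max(1, starts[1] - 1)]
  seg <- seq(i_up, seg_end)
  vpeak <- max(v[seg])
  i_peak <- seg[which.max(v[seg])]
  v90 <- vrest + 0.1 * (vpeak - vrest)
  below <- which(v[seq(i_peak, seg_end)] <= v90)
  if (length(below) == 0) abort_fs("trace does not repolarize to 90%",
                                   "fs_no_ap")
  i2 <- i_peak + below[1] - 1
  i1 <- i2 - 1
  w <- (v[i1] - v90) / (v[i1] - v[i2])
  t_cross <- t[i1] + w * (t[i2] - t[i1])
  t_cross - t[i_up]
}
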
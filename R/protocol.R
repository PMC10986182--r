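#' Programmed stimulation protocol specification
#'
#' S1-S4 clinical-style induction protocol: a drive train of `s1_count`
#' beats at `s1_cl` ms, then up to three extrastimuli. Each extrastimulus
#' stage scans its coupling interval downward in `decrement_ms` steps
#' from `restart_offset_ms` above the previous stage's final coupling
#' (the first stage starts at `s2_start_ms`) until capture is lost; the
#' shortest captured coupling is kept. No further extrastimuli are
#' delivered once reentry is detected. After the last stimulus the
#' simulation observes for `observe_ms` or until all activity ceases.
#'
#' Capture: at least `capture_fraction` of conducting elements activate
#' within one drive-train cycle of the stimulus.
#'
#' @param s1_count Number of S1 beats (default 6).
#' @param s1_cl S1 cycle length, ms (default 600).
#' @param s2_start_ms First S2 coupling interval, ms (default 400).
#' @param min_coupling_ms Scan floor, ms (default 180).
#' @param decrement_ms Coupling decrement per scan step (default 10).
#' @param restart_offset_ms Added to a stage's final coupling to start
#'   the next stage's scan (default 50).
#' @param max_extrastimuli Maximum number of extrastimuli (default 3).
#' @param observe_ms Post-pacing observation window, ms (default 4000).
#' @param capture_fraction Fraction of conducting elements defining
#'   capture (default 0.9).
#' @param stim_amplitude Stimulus amplitude, uA/uF (default 100).
#' @param stim_duration_ms Stimulus duration, ms (default 10).
#' @param electrode_volume_mm3 Electrode volume (default 1).
#' @param prepace_beats Single-cell pre-pacing beats used to initialize
#'   tissue states at the S1 cycle length (default 1000).
#' @param capture_window_ms Post-stimulus window in which capture is
#'   judged (default `NULL` = one S1 cycle).
#' @param fixed_couplings_ms Optional vector of up to three fixed
#'   extrastimulus couplings. When given, the decremental scans are
#'   skipped and S2-S4 are delivered at exactly these couplings (each
#'   still subject to the capture check and to reentry early stopping);
#'   this is the cheap protocol reduction used for qualitative desk-scale
#'   comparisons, where the scan's many probe continuations dominate
#'   runtime without changing the comparison.
#' @return An object of class `fs_protocol`.
#' @export
protocol_spec <- function(s1_count = 6, s1_cl = 600, s2_start_ms = 400,
                          min_coupling_ms = 180, decrement_ms = 10,
                          restart_offset_ms = 50, max_extrastimuli = 3,
                          observe_ms = 4000, capture_fraction = 0.9,
                          stim_amplitude = 100, stim_duration_ms = 10,
                          electrode_volume_mm3 = 1, prepace_beats = 1000,
                          capture_window_ms = NULL,
                          fixed_couplings_ms = NULL) {
  if (s2_start_ms <= min_coupling_ms || decrement_ms <= 0) {
    abort_fs("coupling scan must be decreasing and positive",
             "fs_invalid_spec")
  }
  if (!is.null(fixed_couplings_ms) &&
      (length(fixed_couplings_ms) > max_extrastimuli ||
       any(fixed_couplings_ms <= 0))) {
    abort_fs("fixed_couplings_ms must hold up to max_extrastimuli positive couplings",
             "fs_invalid_spec")
  }
  structure(as.list(environment()), class = "fs_protocol")
}

#' Pacing sites from segment centers
#'
#' One electrode element set per segment, centered on the segment
#' centroid, each targeting the configured electrode volume.
#'
#' @param mesh An `fs_mesh`.
#' @param segments [generate_segments()] labels.
#' @param volume_mm3 Electrode volume (default 1).
#' @return Tibble `site`, `segment`, `x_mm`, `y_mm`, and list-column
#'   `elements`.
#' @export
select_pacing_sites <- function(mesh, segments, volume_mm3 = 1) {
  el <- mesh$elements
  segs <- sort(unique(segments$segment))
  rows <- purrr::map(segs, function(s) {
    ids <- segments$element[segments$segment == s]
    cx <- mean(el$x_mm[el$element %in% ids])
    cy <- mean(el$y_mm[el$element %in% ids])
    h_mm <- mesh$spacing_um / 1000
    if (length(ids) * h_mm^3 < volume_mm3) {
      abort_fs(sprintf("segment %d too small for the electrode", s),
               "fs_size_error")
    }
    electrode <- select_electrode(mesh, c(cx, cy), volume_mm3,
                                  candidates = ids)
    tibble(site = s, segment = s, x_mm = cx, y_mm = cy,
           elements = list(electrode))
  })
  dplyr::bind_rows(rows)
}

# paced initial state for the tissue: each cell type pre-paced at the S1
# cycle length, states replicated across its elements
prepaced_state <- function(model, spec, config) {
  n_kept <- model$mesh$n_elements - length(model$removed_elements)
  keep <- setdiff(seq_len(model$mesh$n_elements), model$removed_elements)
  region <- model$cell_region[keep]
  st <- matrix(0, n_kept, length(cell_state()))
  ph <- .fs_pace_cell(unname(model$cell_healthy$scale),
                      model$cell_healthy$g_nal,
                      variant_code(model$cell_healthy$variant), spec$s1_cl,
                      as.integer(spec$prepace_beats), config$dt, 52, 1, 1,
                      0.5, 10L, NULL, config$use_lut)
  st[region == 0L, ] <- matrix(ph$state, sum(region == 0L),
                               length(ph$state), byrow = TRUE)
  if (any(region == 1L)) {
    pf <- .fs_pace_cell(unname(model$cell_fibrotic$scale),
                        model$cell_fibrotic$g_nal,
                        variant_code(model$cell_fibrotic$variant),
                        spec$s1_cl, as.integer(spec$prepace_beats),
                        config$dt, 52, 1, 1, 0.5, 10L, NULL, config$use_lut)
    st[region == 1L, ] <- matrix(pf$state, sum(region == 1L),
                                 length(pf$state), byrow = TRUE)
  }
  st
}

# conducting elements: retained and not part of a non-conducting core
conducting_elements <- function(model, sigma_floor = 0.02) {
  keep <- setdiff(seq_len(model$mesh$n_elements), model$removed_elements)
  keep[model$regions$sigma_l[keep] >= sigma_floor]
}

# internal: one continuation segment from a checkpoint
run_segment <- function(model, stimuli, duration, config, state0,
                        record_frames = FALSE) {
  cfg <- config
  cfg$duration <- duration
  cfg$record_frames <- record_frames
  simulate_tissue(model, stimuli, cfg, state0 = state0)
}

#' Run the S1-S4 induction protocol at one site
#'
#' Delivers the drive train, scans each extrastimulus stage for its
#' shortest captured coupling, stops adding extrastimuli once reentry is
#' detected, and finishes with the post-pacing observation window.
#'
#' The implementation keeps a state checkpoint at the onset of the next
#' pending stimulus: each coupling-scan trial is an exact continuation
#' from that checkpoint (pending stimulus at its local time 0, candidate
#' extrastimulus at the trial coupling), so scans never re-simulate the
#' drive train. Capture requires `capture_fraction` of conducting
#' elements to activate within one drive-train cycle of the candidate;
#' scanning stops at the first loss of capture (capture is monotone in
#' the coupling interval).
#'
#' @param model An `fs_model`.
#' @param site One row of [select_pacing_sites()] (or any list with an
#'   `elements` integer vector).
#' @param spec [protocol_spec()].
#' @param config [sim_config()] (its `duration` is ignored; segments set
#'   their own).
#' @param min_cluster Minimum count of distinct reentrant elements (after
#'   merging) that counts as detected reentry; defaults to the tracer's
#'   cluster-size rule.
#' @return An object of class `fs_run`: `site`, `captured_stimuli`,
#'   `extrastimuli`, `couplings_ms`, `reentry`, `sustained`,
#'   `stimulus_log`, `activation` (full record, class `fs_activation`),
#'   `reentrant` (post-merge reentrant activations),
#'   `last_stimulus_ms`, `t_end`.
#' @export
run_protocol <- function(model, site, spec = protocol_spec(),
                         config = sim_config(), min_cluster = NULL) {
  stopifnot(inherits(model, "fs_model"), inherits(spec, "fs_protocol"))
  min_cluster <- min_cluster %||% max(20, 1e-4 * model$mesh$n_elements)
  electrode <- site$elements[[1]] %||% site$elements
  cond <- conducting_elements(model)
  n_cond <- length(cond)
  capture_window <- spec$capture_window_ms %||% spec$s1_cl
  # late-activation allowance of the reentry labeler: two drive cycles, so
  # slow crawl through a 0.01 S/m core (which can exceed one cycle) is not
  # mistaken for reentry; true reentrant waves are caught by the index rule
  reentry_window <- 2 * spec$s1_cl

  stim_row <- function(onset) {
    tibble(onset_ms = onset, duration_ms = spec$stim_duration_ms,
           amplitude = spec$stim_amplitude, elements = list(electrode))
  }
  offset_act <- function(act, t0) {
    act$time_ms <- act$time_ms + t0
    act
  }

  # --- S1 drive train; checkpoint lands on the last S1 onset (the last
  # S1 itself stays pending and is delivered by the next segment) ---
  s1_onsets <- (seq_len(spec$s1_count) - 1) * spec$s1_cl
  t_ckpt <- s1_onsets[spec$s1_count]
  st0 <- prepaced_state(model, spec, config)
  if (spec$s1_count > 1) {
    seg1 <- run_segment(model,
                        dplyr::bind_rows(lapply(utils::head(s1_onsets, -1),
                                                stim_row)),
                        duration = t_ckpt,
                        config = within_quiet(config, Inf), state0 = st0)
    act_all <- seg1$activation
    ckpt_state <- seg1$state
  } else {
    act_all <- tibble(element = integer(0), index = integer(0),
                      time_ms = numeric(0))
    ckpt_state <- st0
  }
  ckpt_time <- t_ckpt
  log_rows <- tibble(label = paste0("S1_", seq_len(spec$s1_count)),
                     stage = 1L, onset_ms = s1_onsets)
  couplings <- numeric(0)
  n_captured <- spec$s1_count
  reentry_found <- FALSE

  fixed <- spec$fixed_couplings_ms
  n_stages <- if (is.null(fixed)) spec$max_extrastimuli else length(fixed)
  for (stage in seq_len(n_stages)) {
    scan <- if (!is.null(fixed)) {
      fixed[stage]
    } else {
      start_c <- if (stage == 1) {
        spec$s2_start_ms
      } else {
        couplings[stage - 1] + spec$restart_offset_ms
      }
      seq(start_c, spec$min_coupling_ms, by = -spec$decrement_ms)
    }
    best <- NULL
    for (cpl in scan) {
      stim <- dplyr::bind_rows(stim_row(0), stim_row(cpl))
      seg <- run_segment(model, stim, duration = cpl + capture_window,
                         config = within_quiet(config, Inf),
                         state0 = ckpt_state)
      after <- seg$activation[seg$activation$time_ms > cpl, ]
      frac <- length(intersect(unique(after$element), cond)) /
        max(n_cond, 1L)
      if (frac >= spec$capture_fraction) {
        best <- list(coupling = cpl, seg = seg)
      } else {
        break  # loss of capture; couplings below are refractory too
      }
    }
    if (is.null(best)) break

    # advance the checkpoint to the new extrastimulus onset
    adv <- run_segment(model, stim_row(0), duration = best$coupling,
                       config = within_quiet(config, Inf),
                       state0 = ckpt_state)
    act_all <- dplyr::bind_rows(act_all, offset_act(adv$activation,
                                                    ckpt_time))
    ckpt_state <- adv$state
    ckpt_time <- ckpt_time + best$coupling
    couplings <- c(couplings, best$coupling)
    n_captured <- n_captured + 1L
    log_rows <- dplyr::bind_rows(
      log_rows, tibble(label = paste0("S", stage + 1L),
                       stage = stage + 1L, onset_ms = ckpt_time))

    # reentry check on the kept record plus the capture probe
    probe <- dplyr::bind_rows(
      act_all,
      offset_act(best$seg$activation[best$seg$activation$time_ms >
                                       best$coupling, ],
                 ckpt_time - best$coupling))
    reentrant <- detect_reentry(probe, n_captured, ckpt_time,
                                reentry_window, min_cluster)
    if (reentrant$flag) {
      reentry_found <- TRUE
      break
    }
  }

  # --- deliver the pending final stimulus and observe ---
  last_stim_global <- ckpt_time
  seg_obs <- run_segment(model, stim_row(0), duration = spec$observe_ms,
                         config = config, state0 = ckpt_state)
  act_all <- dplyr::bind_rows(act_all, offset_act(seg_obs$activation,
                                                  ckpt_time))
  t_end <- ckpt_time + seg_obs$t_end

  reentrant <- detect_reentry(act_all, n_captured, last_stim_global,
                              reentry_window, min_cluster)
  sustained <- reentrant$flag &&
    any(reentrant$merged$time_ms >=
          last_stim_global + spec$observe_ms - config$output_interval)

  act_all <- act_all[order(act_all$element, act_all$time_ms), ]
  act_all$index <- as.integer(stats::ave(act_all$time_ms, act_all$element,
                                         FUN = seq_along))
  act_all <- as_tibble(act_all)
  class(act_all) <- c("fs_activation", class(act_all))
  attr(act_all, "n_stimuli") <- n_captured
  attr(act_all, "last_pacing_ms") <- last_stim_global

  structure(
    list(site = site$site %||% NA_integer_,
         captured_stimuli = n_captured,
         extrastimuli = length(couplings),
         couplings_ms = couplings,
         reentry = reentrant$flag, sustained = isTRUE(sustained),
         stimulus_log = log_rows, activation = act_all,
         reentrant = reentrant$merged,
         last_stimulus_ms = last_stim_global, t_end = t_end),
    class = "fs_run")
}

# suppress quiescence stop during pacing segments
within_quiet <- function(config, quiet_after) {
  config$quiet_after <- quiet_after
  config$stop_when_quiet <- is.finite(quiet_after)
  config
}

# shared reentry decision: label + merge + size check. Activation indices
# are recomputed here: records concatenated from continuation segments
# carry per-segment indices, and the n-plus-one rule needs whole-run ones.
detect_reentry <- function(record, n_stimuli, last_stimulus_ms,
                           pacing_window_ms, min_cluster) {
  record <- record[order(record$element, record$time_ms), ]
  record$index <- as.integer(stats::ave(record$time_ms, record$element,
                                        FUN = seq_along))
  re <- label_reentrant_activations(record, n_stimuli, last_stimulus_ms,
                                    pacing_window_ms)
  merged <- merge_rapid_activations(re)
  flag <- length(unique(merged$element)) >= min_cluster
  list(flag = flag, merged = merged)
}

#' @export
print.fs_run <- function(x, ...) {
  cat(sprintf(
    "<fs_run> site %s: %d captured stimuli (%d extra), reentry %s%s\n",
    format(x$site), x$captured_stimuli, x$extrastimuli,
    if (x$reentry) "YES" else "no",
    if (x$reentry) paste0(" (", if (x$sustained) "sustained"
                          else "unsustained", ")") else ""))
  invisible(x)
}

#' Enumerate the study's simulation runs
#'
#' Expands the population design into a run manifest: one row per
#' (geometry, variant, parameter level, pacing site). The default
#' population list is the full design -- three cleft populations at
#' `fib_max` 0-9, the conductivity-only control, and the two non-cleft
#' populations at core sizes 25/50/75 -- which with 17 sites yields 37
#' model variants and, over 5 geometries, 3,145 runs.
#'
#' @param geometries Character or integer vector of geometry identifiers.
#' @param populations Named list mapping variant names to their level
#'   vectors; `NULL` gives the full design.
#' @param sites Pacing-site identifiers (default 1:17).
#' @return Tibble `run_id`, `geometry`, `variant`, `level`, `site`.
#' @examples
#' nrow(enumerate_experiments(1:5))  # 3145
#' @export
enumerate_experiments <- function(geometries = 1L,
                                  populations = NULL, sites = 1:17) {
  populations <- populations %||% list(
    cleft_gm = 0:9, cleft_m = 0:9, cleft_only = 0:9, cleft_g = 0,
    noncleft_c = c(25, 50, 75), noncleft_nc = c(25, 50, 75))
  known <- c("cleft_gm", "cleft_m", "cleft_only", "cleft_g", "noncleft_c",
             "noncleft_nc")
  if (length(populations) && !all(names(populations) %in% known)) {
    abort_fs(paste0("unknown variant: ",
                    setdiff(names(populations), known)[1]),
             "fs_config_error")
  }
  if (length(populations) == 0 || length(geometries) == 0) {
    return(tibble(run_id = integer(0), geometry = character(0),
                  variant = character(0), level = numeric(0),
                  site = integer(0)))
  }
  models <- purrr::imap_dfr(populations, function(levels, nm) {
    tibble(variant = nm, level = as.numeric(levels))
  })
  grid <- tidyr::expand_grid(geometry = as.character(geometries),
                             models, site = as.integer(sites))
  dplyr::bind_cols(tibble(run_id = seq_len(nrow(grid))), grid)
}
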
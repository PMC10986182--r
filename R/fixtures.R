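#' Plant a ground-truth activation fixture
#'
#' Builds an activation record by kinematic construction (times are
#' distance / speed from planted wave sources), providing exact ground
#' truth for the reentry tracer without running any electrophysiology.
#' Scenarios:
#'
#' * `no_reentry`: `n_stimuli` paced wavefronts from the pacing source,
#'   one cycle apart; every element activates exactly `n_stimuli` times.
#' * `single_source`: the paced wavefronts plus one extra wave emitted
#'   from a planted reentry source at `reentry_onset_ms`.
#' * `two_source_merge`: as `single_source` but with two reentry sources
#'   whose onsets differ (default 30 ms); their waves merge where the
#'   earliest arrival switches source, giving two distinct initiation
#'   clusters at distinct back-trace steps.
#'
#' @param mesh An `fs_mesh`.
#' @param scenario One of `"no_reentry"`, `"single_source"`,
#'   `"two_source_merge"`.
#' @param pacing_xy Pacing source location in mm (default sheet corner).
#' @param sources_xy Matrix (rows = reentry sources) of source locations in
#'   mm; defaults depend on the scenario.
#' @param source_onsets_ms Onset time of each reentry source.
#' @param n_stimuli Number of paced wavefronts (default 3).
#' @param cycle_ms Pacing cycle length (default 600).
#' @param speed_cm_s Wave speed used for all waves (default 50; the
#'   `two_source_merge` default is 25 so the second source fires before
#'   the first source's wave reaches it on small sheets).
#' @return A tibble `element`, `index`, `time_ms` (class
#'   `fs_activation`), with attributes `n_stimuli`, `last_pacing_ms`, and
#'   `truth` (the planted source elements and onsets).
#' @examples
#' mesh <- generate_mesh(synthetic_spec(c(20, 20)))
#' act <- plant_activation_fixture(mesh, "single_source")
#' attr(act, "truth")
#' @export
plant_activation_fixture <- function(mesh,
                                     scenario = c("no_reentry",
                                                  "single_source",
                                                  "two_source_merge"),
                                     pacing_xy = NULL, sources_xy = NULL,
                                     source_onsets_ms = NULL, n_stimuli = 3,
                                     cycle_ms = 600, speed_cm_s = NULL) {
  scenario <- match.arg(scenario)
  speed_cm_s <- speed_cm_s %||%
    (if (scenario == "two_source_merge") 25 else 50)
  stopifnot(inherits(mesh, "fs_mesh"))
  el <- mesh$elements
  h_mm <- mesh$spacing_um / 1000
  ext <- mesh$dims[1:2] * h_mm
  pacing_xy <- pacing_xy %||% c(h_mm / 2, h_mm / 2)
  if (is.null(sources_xy)) {
    sources_xy <- switch(scenario,
      no_reentry = NULL,
      single_source = matrix(ext * 0.6, nrow = 1),
      two_source_merge = rbind(ext * c(0.15, 0.15), ext * c(0.85, 0.85)))
  }
  if (!is.null(sources_xy)) {
    sources_xy <- rbind(sources_xy)
    bad <- sources_xy[, 1] < 0 | sources_xy[, 1] > ext[1] |
      sources_xy[, 2] < 0 | sources_xy[, 2] > ext[2]
    if (any(bad)) abort_fs("planted source lies off the mesh",
                           "fs_invalid_spec")
  }
  n_src <- if (is.null(sources_xy)) 0L else nrow(sources_xy)
  if (is.null(source_onsets_ms) && n_src > 0) {
    t0 <- (n_stimuli - 1) * cycle_ms + 500
    source_onsets_ms <- t0 + 30 * (seq_len(n_src) - 1)
  }
  speed_mm_ms <- speed_cm_s / 100  # cm/s -> mm/ms

  d_pace <- sqrt((el$x_mm - pacing_xy[1])^2 + (el$y_mm - pacing_xy[2])^2)
  times <- lapply(seq_len(n_stimuli), function(k) {
    (k - 1) * cycle_ms + d_pace / speed_mm_ms
  })
  truth_elements <- integer(0)
  if (n_src > 0) {
    arr <- sapply(seq_len(n_src), function(k) {
      source_onsets_ms[k] +
        sqrt((el$x_mm - sources_xy[k, 1])^2 +
             (el$y_mm - sources_xy[k, 2])^2) / speed_mm_ms
    })
    arr <- rbind(arr)
    times[[n_stimuli + 1]] <- apply(arr, 1, min)
    truth_elements <- vapply(seq_len(n_src), function(k) {
      el$element[which.min(arr[, k])]
    }, integer(1))
  }
  tm <- do.call(cbind, times)
  act <- tibble(
    element = rep(el$element, ncol(tm)),
    index = rep(seq_len(ncol(tm)), each = nrow(el)),
    time_ms = as.vector(tm))
  act <- act[order(act$element, act$time_ms), ]
  act$index <- stats::ave(act$time_ms, act$element,
                          FUN = seq_along)
  act$index <- as.integer(act$index)
  structure(as_tibble(act),
            class = c("fs_activation", class(as_tibble(act))),
            n_stimuli = as.integer(n_stimuli),
            last_pacing_ms = (n_stimuli - 1) * cycle_ms,
            truth = list(scenario = scenario,
                         source_elements = truth_elements,
                         source_onsets_ms = source_onsets_ms))
}
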
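#' Label reentrant activations
#'
#' Reentry is any activation occurring after the final pacing-induced
#' activation of an element: with `n` captured stimuli, activations beyond
#' the n-th are reentrant; additionally, any activation later than the
#' last stimulus onset plus a propagation allowance is reentrant even when
#' an element was activated fewer than `n` times by pacing (local block).
#' Elements with no activation at all (cleft-isolated tissue) are simply
#' absent.
#'
#' @param record Activation tibble (`element`, `index`, `time_ms`).
#' @param n_stimuli Number of captured pacing stimuli.
#' @param last_stimulus_ms Onset of the final pacing stimulus; defaults
#'   to the record attribute when present.
#' @param pacing_window_ms Propagation allowance after the last stimulus
#'   within which a first-arrival activation still counts as paced
#'   (default 600 ms, one drive-train cycle).
#' @return Tibble `element`, `time_ms` of reentrant activations only.
#' @export
label_reentrant_activations <- function(record, n_stimuli,
                                        last_stimulus_ms = NULL,
                                        pacing_window_ms = 600) {
  last_stimulus_ms <- last_stimulus_ms %||%
    attr(record, "last_pacing_ms") %||% 0
  rec <- as_tibble(record)[c("element", "index", "time_ms")]
  keep <- rec$index > n_stimuli |
    rec$time_ms > last_stimulus_ms + pacing_window_ms
  rec[keep, c("element", "time_ms")]
}

#' Merge rapid repeated activations
#'
#' Activation sequences of one element separated by less than `window`
#' milliseconds are interpreted as a single activation (keeping the
#' first): isolated elements next to clefts can re-register voltage
#' fluctuations from current skirting the cleft without any reentrant
#' wave. Applied per element; idempotent and order-preserving.
#'
#' @param series Tibble with `element` and `time_ms` (or a numeric vector
#'   of times for a single element).
#' @param window Merge window in ms (strict `<`; default 50).
#' @return Same shape as the input with merged rows/times removed.
#' @export
merge_rapid_activations <- function(series, window = 50) {
  merge_vec <- function(t) {
    t <- sort(t)
    keep <- logical(length(t))
    last <- -Inf
    for (i in seq_along(t)) {
      if (t[i] - last >= window || !is.finite(last)) {
        keep[i] <- TRUE
        last <- t[i]
      }
    }
    t[keep]
  }
  if (is.numeric(series)) return(merge_vec(series))
  series |>
    dplyr::group_by(.data$element) |>
    dplyr::reframe(time_ms = merge_vec(.data$time_ms)) |>
    dplyr::ungroup()
}

# Earliest reentrant activation per element, binned to back-trace steps.
first_reentrant_step <- function(reentrant, step_ms) {
  r <- reentrant |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(t_first = min(.data$time_ms), .groups = "drop")
  r$step <- floor(r$t_first / step_ms)
  r
}

#' Trace reentry back to its initiation sites
#'
#' Walks the reentrant activation pattern backwards on the element
#' adjacency graph in fixed time steps (default 10 ms, the voltage-frame
#' resolution). An initiation cluster is a maximal connected set of
#' elements whose first reentrant activation step is no later than that
#' of any neighbor; each cluster is confined to the earliest step at
#' which it appears, must reach `min_cluster` elements, and its
#' geometric center (arithmetic mean of element coordinates) is the
#' initiation site.
#'
#' `min_cluster` defaults to `max(20, 1e-4 * n_elements)`: the absolute
#' cluster-size floor used on multi-million-element anatomical meshes
#' scales with mesh size here, otherwise no desk-scale cluster would ever
#' qualify.
#'
#' @param reentrant Tibble `element`, `time_ms` from
#'   [label_reentrant_activations()] (ideally after
#'   [merge_rapid_activations()]).
#' @param mesh The `fs_mesh` (supplies adjacency and coordinates).
#' @param step_ms Back-trace step (ms).
#' @param min_cluster Minimum cluster size in elements.
#' @param adjacency Optional adjacency tibble overriding `mesh$adjacency`
#'   (e.g. the retained faces of a cleft mesh).
#' @return Tibble of initiation clusters: `cluster`, `t_ms` (earliest
#'   step time), `x_mm`, `y_mm`, `z_mm` (center), `size`, and a
#'   list-column `elements`.
#' @export
trace_initiation <- function(reentrant, mesh, step_ms = 10,
                             min_cluster = NULL, adjacency = NULL) {
  stopifnot(inherits(mesh, "fs_mesh"))
  min_cluster <- min_cluster %||% max(20, 1e-4 * mesh$n_elements)
  empty <- tibble(cluster = integer(0), t_ms = numeric(0),
                  x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                  size = integer(0), elements = list())
  if (nrow(reentrant) == 0) return(empty)
  adj <- adjacency %||% mesh$adjacency

  fr <- first_reentrant_step(reentrant, step_ms)
  step_of <- rep(Inf, mesh$n_elements)
  step_of[fr$element] <- fr$step

  # per back-trace step (earliest first): maximal connected sets of
  # elements first-reactivated in that step, all of whose outside
  # neighbors reactivate strictly later (or never). Confinement to the
  # earliest step is automatic: a set joined by later-step growth fails
  # the strictly-later condition against its same-cluster seed.
  clusters <- list()
  for (s in sort(unique(fr$step))) {
    members <- fr$element[fr$step == s]
    in_m <- adj$a %in% members & adj$b %in% members
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(adj$a[in_m]),
                 to = as.character(adj$b[in_m])),
      directed = FALSE,
      vertices = data.frame(name = as.character(members)))
    memb <- igraph::components(g)$membership
    el_ids <- as.integer(names(memb))
    for (cid in unique(memb)) {
      comp_el <- el_ids[memb == cid]
      if (length(comp_el) < min_cluster) next
      touching <- adj$a %in% comp_el | adj$b %in% comp_el
      outside <- setdiff(unique(c(adj$a[touching], adj$b[touching])),
                         comp_el)
      if (all(step_of[outside] > s)) {
        xyz <- mesh$elements[comp_el, c("x_mm", "y_mm", "z_mm")]
        clusters[[length(clusters) + 1]] <-
          tibble(t_ms = s * step_ms, x_mm = mean(xyz$x_mm),
                 y_mm = mean(xyz$y_mm), z_mm = mean(xyz$z_mm),
                 size = length(comp_el), elements = list(sort(comp_el)))
      }
    }
  }
  clusters <- dplyr::bind_rows(clusters)
  if (nrow(clusters) == 0) return(empty)
  clusters <- clusters[order(clusters$t_ms, -clusters$size), ]
  dplyr::bind_cols(tibble(cluster = seq_len(nrow(clusters))), clusters)
}

#' Classify reentry sustainment
#'
#' A reentry is sustained when reentrant activity persists to the end of
#' the post-pacing observation window (activation within the final
#' back-trace frame of `horizon_ms` after the last stimulus).
#'
#' @param reentrant Reentrant activations (`element`, `time_ms`).
#' @param last_pacing_ms Onset of the final pacing stimulus.
#' @param horizon_ms Observation window (default 4000 ms).
#' @param frame_ms Output frame width at the window end (default 10 ms).
#' @return Logical flag.
#' @export
classify_sustained <- function(reentrant, last_pacing_ms,
                               horizon_ms = 4000, frame_ms = 10) {
  if (nrow(reentrant) == 0) {
    abort_fs("no reentrant activation: sustainment undefined",
             "fs_no_reentry")
  }
  any(reentrant$time_ms >= last_pacing_ms + horizon_ms - frame_ms)
}

#' Classify reentry morphology from local LGE features
#'
#' Feature-based proxy for visual morphology classification: reentries
#' rotating at healthy-fibrotic interfaces (functional rotors, "Type 2")
#' initiate in low-LGE surroundings, whereas slow meander through
#' fibrotic channels ("Type 1") initiates inside dense LGE. A cluster is
#' labeled Type 2 when the mean LGE intensity within the feature radius
#' is below `cutoff_pct` (default 10%), else Type 1. The label is a
#' heuristic and is flagged as such in the output.
#'
#' @param features [local_lge_features()] row (or tibble) for the
#'   cluster(s) to classify.
#' @param cutoff_pct Mean-LGE cutoff separating the two morphologies.
#' @return Tibble with `morphology` (`"Type1"`/`"Type2"`) and
#'   `morphology_source = "heuristic"`.
#' @export
classify_morphology <- function(features, cutoff_pct = 10) {
  if (is.null(features) || nrow(features) == 0 ||
      !"mean_lge_pct" %in% names(features)) {
    abort_fs("local LGE features required for morphology classification",
             "fs_feature_required")
  }
  tibble(
    morphology = ifelse(features$mean_lge_pct < cutoff_pct, "Type2",
                        "Type1"),
    morphology_source = "heuristic")
}
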
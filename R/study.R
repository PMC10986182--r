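#' Study configuration
#'
#' One structured object (writable to YAML) describing a whole study:
#' geometries (synthetic specs), the population design, the pacing
#' protocol, the analysis constants, and the master seed every stage
#' forks from.
#'
#' @param geometries Named list of [synthetic_spec()] objects (names are
#'   the geometry identifiers) or a plain count `n_geometries` to build
#'   default specs with distinct seeds.
#' @param populations Named list mapping variant to levels (see
#'   [enumerate_experiments()]).
#' @param protocol [protocol_spec()].
#' @param sim [sim_config()].
#' @param n_segments Segments / pacing sites per geometry (default 17).
#' @param merge_window_ms,trace_step_ms,min_cluster,feature_radius_mm
#'   Analysis constants (defaults: 50, 10, tracer rule, 5).
#' @param seed Master seed.
#' @param out_dir Output directory for [run_study()] artifacts.
#' @return An object of class `fs_study_config`.
#' @export
study_config <- function(geometries = 1L, populations = NULL,
                         protocol = protocol_spec(), sim = sim_config(),
                         n_segments = 17L, merge_window_ms = 50,
                         trace_step_ms = 10, min_cluster = NULL,
                         feature_radius_mm = 5, seed = 1L,
                         out_dir = tempfile("fs_study_")) {
  if (is.numeric(geometries) && length(geometries) == 1L) {
    geometries <- stats::setNames(
      lapply(seq_len(geometries), function(i) {
        synthetic_spec(seed = fork_seed(seed, "study", i))
      }),
      paste0("g", seq_len(geometries)))
  }
  stopifnot(all(vapply(geometries, inherits, TRUE, "fs_spec")))
  structure(list(geometries = geometries, populations = populations,
                 protocol = protocol, sim = sim,
                 n_segments = as.integer(n_segments),
                 merge_window_ms = merge_window_ms,
                 trace_step_ms = trace_step_ms, min_cluster = min_cluster,
                 feature_radius_mm = feature_radius_mm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "fs_study_config")
}

#' Run a study end to end
#'
#' Expands the run manifest, then for each (geometry, variant, level,
#' site) run: builds the model, delivers the induction protocol, labels
#' and merges reentrant activation, traces initiation sites, attaches
#' local LGE features and the heuristic morphology label, and appends
#' per-run and per-site rows to `runs.csv` and `sites.csv` under
#' `out_dir`. Re-running with the same config resumes: completed
#' `run_id`s present in `runs.csv` are skipped, so interrupted studies
#' continue without duplicate rows. A failed run is recorded with its
#' error message and does not stop the study.
#'
#' @param config [study_config()].
#' @param manifest_only Return the manifest without simulating.
#' @return List with `manifest`, `runs` (per-run outcomes), `sites`
#'   (per-initiation-site rows incl. features and morphology), and
#'   `out_dir`.
#' @export
run_study <- function(config, manifest_only = FALSE) {
  stopifnot(inherits(config, "fs_study_config"))
  manifest <- enumerate_experiments(
    geometries = names(config$geometries),
    populations = config$populations,
    sites = seq_len(config$n_segments))
  if (manifest_only) {
    return(list(manifest = manifest, runs = NULL, sites = NULL,
                out_dir = config$out_dir))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  runs_path <- file.path(config$out_dir, "runs.csv")
  sites_path <- file.path(config$out_dir, "sites.csv")
  done <- if (file.exists(runs_path)) {
    utils::read.csv(runs_path)$run_id
  } else {
    integer(0)
  }

  # per-geometry caches (mesh, lge, segments, pacing sites, cleft ladder)
  geo_cache <- new.env(parent = emptyenv())
  get_geo <- function(gname) {
    if (!is.null(geo_cache[[gname]])) return(geo_cache[[gname]])
    spec <- config$geometries[[gname]]
    mesh <- generate_mesh(spec)
    lge <- generate_lge(spec, mesh)
    segments <- generate_segments(mesh, config$n_segments)
    sites <- select_pacing_sites(mesh, segments,
                                 config$protocol$electrode_volume_mm3)
    geo <- list(spec = spec, mesh = mesh, lge = lge, segments = segments,
                sites = sites, ladder = NULL, models = list())
    geo_cache[[gname]] <- geo
    geo
  }

  for (ri in seq_len(nrow(manifest))) {
    row <- manifest[ri, ]
    if (row$run_id %in% done) next
    res <- tryCatch({
      geo <- get_geo(row$geometry)
      needs_ladder <- row$variant %in% c("cleft_gm", "cleft_m",
                                         "cleft_only")
      if (needs_ladder && is.null(geo$ladder)) {
        geo$ladder <- build_fibmax_ladder(geo$mesh, geo$lge,
                                          seed = geo$spec$seed)
        geo_cache[[row$geometry]] <- geo
      }
      model_key <- paste(row$variant, row$level)
      model <- geo$models[[model_key]]
      if (is.null(model)) {
        model <- build_tissue_model(geo$mesh, geo$lge, row$variant,
                                    row$level, ladder = geo$ladder,
                                    seed = geo$spec$seed)
        geo$models[[model_key]] <- model
        geo_cache[[row$geometry]] <- geo
      }
      site <- geo$sites[geo$sites$site == row$site, ]
      run <- run_protocol(model, site, config$protocol, config$sim,
                          min_cluster = config$min_cluster)
      clusters <- if (run$reentry) {
        trace_initiation(run$reentrant, geo$mesh,
                         step_ms = config$trace_step_ms,
                         min_cluster = config$min_cluster,
                         adjacency = model$cleft$retained %||% NULL)
      } else {
        trace_initiation(run$reentrant[0, ], geo$mesh)
      }
      site_rows <- NULL
      if (nrow(clusters)) {
        feats <- local_lge_features(clusters, geo$mesh, geo$lge,
                                    radius_mm = config$feature_radius_mm)
        morph <- classify_morphology(feats)
        site_rows <- dplyr::bind_cols(
          tibble(run_id = row$run_id, geometry = row$geometry,
                 variant = row$variant, level = row$level,
                 site = row$site),
          feats[setdiff(names(feats), "elements")], morph)
      }
      list(run = tibble(run_id = row$run_id, geometry = row$geometry,
                        variant = row$variant, level = row$level,
                        site = row$site, status = "ok",
                        captured_stimuli = run$captured_stimuli,
                        extrastimuli = run$extrastimuli,
                        reentry = run$reentry, sustained = run$sustained,
                        n_initiation_sites = nrow(clusters),
                        error = ""),
           sites = site_rows)
    }, error = function(e) {
      list(run = tibble(run_id = row$run_id, geometry = row$geometry,
                        variant = row$variant, level = row$level,
                        site = row$site, status = "error",
                        captured_stimuli = NA_integer_,
                        extrastimuli = NA_integer_, reentry = NA,
                        sustained = NA, n_initiation_sites = NA_integer_,
                        error = conditionMessage(e)),
           sites = NULL)
    })
    utils::write.table(res$run, runs_path, sep = ",",
                       col.names = !file.exists(runs_path),
                       row.names = FALSE, append = file.exists(runs_path))
    if (!is.null(res$sites)) {
      utils::write.table(res$sites, sites_path, sep = ",",
                         col.names = !file.exists(sites_path),
                         row.names = FALSE,
                         append = file.exists(sites_path))
    }
  }
  runs <- as_tibble(utils::read.csv(runs_path))
  sites <- if (file.exists(sites_path)) {
    as_tibble(utils::read.csv(sites_path))
  } else {
    NULL
  }
  list(manifest = manifest, runs = runs, sites = sites,
       out_dir = config$out_dir)
}
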
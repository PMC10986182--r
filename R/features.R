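#' Local LGE features around an initiation site
#'
#' Selects every element within a Euclidean `radius_mm` ball of each site
#' and summarizes the LGE map there: mean and maximum intensity (in
#' percent of the normalization maximum) and the LGE volume (summed
#' volume of elements with intensity above `volume_threshold`, in mL).
#'
#' @param sites Tibble with `x_mm`, `y_mm`, `z_mm` (e.g. the output of
#'   [trace_initiation()]).
#' @param mesh An `fs_mesh`.
#' @param lge LGE tibble.
#' @param radius_mm Ball radius (default 5).
#' @param volume_threshold Intensity above which an element counts toward
#'   LGE volume (default 0, i.e. any positive intensity).
#' @return `sites` with appended `mean_lge_pct`, `max_lge_pct`,
#'   `lge_volume_ml`, `n_ball`.
#' @export
local_lge_features <- function(sites, mesh, lge, radius_mm = 5,
                               volume_threshold = 0) {
  stopifnot(inherits(mesh, "fs_mesh"))
  el <- mesh$elements
  h_mm <- mesh$spacing_um / 1000
  vol_el_ml <- h_mm^3 / 1000  # mm^3 -> mL
  intensity_of <- lge$intensity[match(el$element, lge$element)]
  feats <- purrr::pmap(sites[c("x_mm", "y_mm", "z_mm")],
    function(x_mm, y_mm, z_mm) {
      d2 <- (el$x_mm - x_mm)^2 + (el$y_mm - y_mm)^2 + (el$z_mm - z_mm)^2
      ball <- which(d2 <= radius_mm^2)
      if (length(ball) == 0) {
        abort_fs("feature ball contains no elements (degenerate mesh)",
                 "fs_geometry_error")
      }
      ii <- intensity_of[ball]
      tibble(mean_lge_pct = 100 * mean(ii), max_lge_pct = 100 * max(ii),
             lge_volume_ml = sum(ii > volume_threshold) * vol_el_ml,
             n_ball = length(ball))
    })
  dplyr::bind_cols(sites, dplyr::bind_rows(feats))
}

#' Time to fractional tissue activation
#'
#' Earliest time at which the given fraction of elements has at least one
#' activation. Full (100%) activation is reported as `NA` with
#' `reached = FALSE` when some elements never activate (common in cleft
#' models, where pruned-adjacent or shielded tissue stays silent).
#'
#' @param record Activation tibble (`element`, `index`, `time_ms`).
#' @param n_elements Total number of elements in the model (the
#'   denominator; pass the mesh element count).
#' @param fractions Fractions to report (default 0.95 and 1).
#' @return Tibble `fraction`, `time_ms`, `reached`.
#' @export
activation_summary <- function(record, n_elements,
                               fractions = c(0.95, 1)) {
  first <- record |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(t1 = min(.data$time_ms), .groups = "drop")
  ts <- sort(first$t1)
  purrr::map_dfr(fractions, function(f) {
    k <- ceiling(f * n_elements)
    if (k <= length(ts)) {
      tibble(fraction = f, time_ms = ts[k], reached = TRUE)
    } else {
      tibble(fraction = f, time_ms = NA_real_, reached = FALSE)
    }
  })
}

#' Segment-level summary table
#'
#' Aggregates initiation sites and LGE burden per segment for the
#' count-regression analysis: initiation count, LGE volume (mL), mean and
#' maximum LGE intensity (%), and core volume (mL, elements above the
#' non-cleft core threshold when `core_size` is given).
#'
#' @param sites Initiation-site tibble (needs `x_mm`, `y_mm`; may be
#'   empty).
#' @param mesh,lge,segments Mesh, LGE map and [generate_segments()]
#'   labels.
#' @param core_size Optional core size (25/50/75) for the core-volume
#'   column.
#' @param ids Optional named list of identifier columns to prepend
#'   (geometry, variant, level, ...).
#' @return One row per segment.
#' @export
segment_table <- function(sites, mesh, lge, segments, core_size = NULL,
                          ids = NULL) {
  el <- mesh$elements
  h_mm <- mesh$spacing_um / 1000
  vol_el_ml <- h_mm^3 / 1000
  seg_of_site <- function(x, y) {
    d2 <- (el$x_mm - x)^2 + (el$y_mm - y)^2
    segments$segment[which.min(d2)]
  }
  counts <- if (nrow(sites)) {
    tab <- table(mapply(seg_of_site, sites$x_mm, sites$y_mm))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  core_thr <- if (!is.null(core_size)) {
    (1 - core_size / 100) * max(lge$intensity)
  } else {
    Inf
  }
  out <- tibble(segment = sort(unique(segments$segment))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_initiations = as.integer(counts[as.character(.data$segment)] %||%
                                   0L),
      lge_volume_ml = sum(lge$intensity[segments$segment == .data$segment]
                          > 0) * vol_el_ml,
      mean_lge_pct = 100 *
        mean(lge$intensity[segments$segment == .data$segment]),
      max_lge_pct = 100 *
        max(lge$intensity[segments$segment == .data$segment]),
      core_volume_ml = sum(lge$intensity[segments$segment ==
                                           .data$segment] >= core_thr &
                           lge$intensity[segments$segment ==
                                           .data$segment] > 0) *
        vol_el_ml) |>
    dplyr::ungroup()
  out$n_initiations[is.na(out$n_initiations)] <- 0L
  if (!is.null(ids)) out <- dplyr::bind_cols(as_tibble(ids), out)
  out
}

#' Negative binomial association between segment features and reentry counts
#'
#' Fits a negative binomial count regression of per-segment initiation
#' counts on a covariate of interest, adjusting for LGE volume and
#' (fixed-effect) grouping identifiers such as geometry, parameter level
#' and segment. A mixed-model backend (`backend = "mixed"`, lme4
#' negative-binomial GLMM with grouping variables as random intercepts)
#' is available where the design supports it; the fixed-adjuster default
#' is far more robust at desk-scale sample sizes.
#'
#' @param table Segment table ([segment_table()] rows, possibly many
#'   models bound together).
#' @param response Name of the count column (default `"n_initiations"`).
#' @param covariate Name of the covariate of interest.
#' @param adjusters Character vector of additional adjuster columns
#'   (default `"lge_volume_ml"`).
#' @param grouping Character vector of grouping identifier columns
#'   entered as fixed factors (dropped, with a warning, when constant).
#' @param backend `"fixed"` (default) or `"mixed"`.
#' @return An object of class `fs_nb` wrapping the fit, with
#'   [tidy.fs_nb()] and [glance.fs_nb()] methods. The key row of
#'   `tidy()` is the covariate's coefficient, standard error and p-value.
#' @export
nb_association <- function(table, response = "n_initiations", covariate,
                           adjusters = "lge_volume_ml",
                           grouping = character(0),
                           backend = c("fixed", "mixed")) {
  backend <- match.arg(backend)
  if (nrow(table) < 10) {
    abort_fs("need at least 10 segment rows for count regression",
             "fs_invalid_spec")
  }
  y <- table[[response]]
  if (any(y < 0) || any(y != round(y))) {
    abort_fs("response must be nonnegative integer counts",
             "fs_invalid_spec")
  }
  if (all(y == 0)) {
    abort_fs("all counts are zero: degenerate fit", "fs_degenerate_fit")
  }
  keep_group <- character(0)
  for (g in grouping) {
    if (length(unique(table[[g]])) > 1) {
      keep_group <- c(keep_group, g)
    } else {
      warning(sprintf("grouping variable '%s' is constant; dropped", g))
    }
  }
  rhs <- c(covariate, adjusters,
           if (backend == "fixed" && length(keep_group)) {
             paste0("factor(", keep_group, ")")
           } else if (length(keep_group)) {
             paste0("(1 | ", keep_group, ")")
           })
  fml <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- if (backend == "fixed") {
    MASS::glm.nb(fml, data = table)
  } else {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      abort_fs("mixed backend requires lme4", "fs_config_error")
    }
    lme4::glmer.nb(fml, data = table)
  }
  structure(list(fit = fit, covariate = covariate, backend = backend,
                 formula = fml, converged = isTRUE(fit$converged %||% TRUE)),
            class = "fs_nb")
}

#' @export
print.fs_nb <- function(x, ...) {
  cat(sprintf("<fs_nb> %s backend: %s\n", x$backend,
              deparse(x$formula)))
  print(tidy(x))
  invisible(x)
}

#' Tidy a negative binomial association fit
#'
#' @param x An `fs_nb` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.fs_nb <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  if (is.list(co)) co <- co$cond %||% co[[1]]
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' Glance at a negative binomial association fit
#'
#' @param x An `fs_nb` object.
#' @param ... Unused.
#' @return One-row tibble with the dispersion parameter `theta`, the
#'   covariate estimate and p-value, AIC, and convergence flag.
#' @export
glance.fs_nb <- function(x, ...) {
  td <- tidy(x)
  row <- td[td$term == x$covariate, ]
  theta <- x$fit$theta %||% NA_real_
  tibble(theta = theta, covariate = x$covariate,
         estimate = row$estimate[1], p.value = row$p.value[1],
         aic = stats::AIC(x$fit), converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
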
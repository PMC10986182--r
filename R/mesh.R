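#' Specify a synthetic tissue geometry and LGE pattern
#'
#' Bundles every knob of the synthetic-data generator: lattice size and
#' spacing, the in-plane fiber angle (with optional linear transmural
#' rotation for thin-3D slabs), and the late-gadolinium-enhancement (LGE)
#' intensity pattern that stands in for patient imaging. The defaults
#' emulate a patchy fibrotic region with a smooth intensity gradient and a
#' dense core on a regular 2D sheet at the 530 micron element scale used
#' throughout the package.
#'
#' @param grid_shape Integer vector of element counts per axis, length 2
#'   (sheet) or 3 (thin slab). At least one dimension must be >= 2.
#' @param spacing_um Element edge length in micrometers (default 530).
#' @param fiber_angle In-plane fiber angle in degrees (0 = along x).
#' @param transmural_rotation_deg Total linear fiber rotation across the
#'   slab thickness (thin-3D only); 0 disables rotation.
#' @param lge_pattern One of `"single_patch"`, `"multi_patch"`,
#'   `"diffuse_gradient"`.
#' @param patch_centers Numeric matrix (one row per patch) of patch centers
#'   in mm; `NULL` places a single patch at the sheet center.
#' @param patch_radii Patch radii in mm (recycled across patches).
#' @param intensity_peak Peak normalized LGE intensity in `[0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (applied inside patches, then clipped to `[0, 1]`).
#' @param seed Master integer seed; all stochastic stages fork from it.
#' @return An object of class `fs_spec`.
#' @examples
#' spec <- synthetic_spec(grid_shape = c(40, 40), seed = 1)
#' mesh <- generate_mesh(spec)
#' @export
synthetic_spec <- function(grid_shape = c(100, 100), spacing_um = 530,
                           fiber_angle = 0,
                           transmural_rotation_deg = 0,
                           lge_pattern = c("single_patch", "multi_patch",
                                           "diffuse_gradient"),
                           patch_centers = NULL, patch_radii = NULL,
                           intensity_peak = 1, noise_sd = 0, seed = 1L) {
  lge_pattern <- match.arg(lge_pattern)
  grid_shape <- as.integer(grid_shape)
  if (!length(grid_shape) %in% c(2L, 3L) || any(grid_shape < 1L) ||
      max(grid_shape) < 2L) {
    abort_fs("grid_shape must have 2 or 3 dims, all >= 1, at least one >= 2",
             "fs_invalid_spec")
  }
  if (!is.numeric(spacing_um) || spacing_um <= 0) {
    abort_fs("spacing_um must be a positive number", "fs_invalid_spec")
  }
  if (intensity_peak < 0 || intensity_peak > 1) {
    abort_fs("intensity_peak must lie in [0, 1]", "fs_invalid_spec")
  }
  if (noise_sd < 0) abort_fs("noise_sd must be >= 0", "fs_invalid_spec")
  structure(
    list(grid_shape = grid_shape, spacing_um = spacing_um,
         fiber_angle = fiber_angle,
         transmural_rotation_deg = transmural_rotation_deg,
         lge_pattern = lge_pattern, patch_centers = patch_centers,
         patch_radii = patch_radii, intensity_peak = intensity_peak,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "fs_spec")
}

#' Generate a regular lattice tissue mesh
#'
#' Builds a quadrilateral (2D) or hexahedral (thin-3D) lattice of elements
#' with element-center coordinates in mm, a full face-adjacency table, and a
#' unit fiber vector per element. One membrane-model node is collocated with
#' each element center, so "element" and "vertex" coincide throughout the
#' package (the desk-scale finite-difference analogue of an unstructured
#' finite-element mesh).
#'
#' @param spec An [synthetic_spec()] object.
#' @return An object of class `fs_mesh`: a list with `elements` (tibble:
#'   `element`, lattice indices `ix`, `iy`, `iz`, coordinates `x_mm`,
#'   `y_mm`, `z_mm`, fiber components `fx`, `fy`, `fz`), `adjacency`
#'   (tibble: element pair `a` < `b` and the face-normal `axis` 1-3),
#'   `spacing_um`, and `dims`.
#' @examples
#' mesh <- generate_mesh(synthetic_spec(grid_shape = c(10, 10)))
#' nrow(mesh$elements)
#' @export
generate_mesh <- function(spec) {
  stopifnot(inherits(spec, "fs_spec"))
  dims <- spec$grid_shape
  if (length(dims) == 2L) dims <- c(dims, 1L)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  h_mm <- spec$spacing_um / 1000
  idx <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  n <- nrow(idx)

  # fiber field: uniform in-plane angle, optional linear transmural rotation
  angle <- spec$fiber_angle
  if (nz > 1L && spec$transmural_rotation_deg != 0) {
    frac <- (idx$iz - 0.5) / nz - 0.5
    angle <- spec$fiber_angle + spec$transmural_rotation_deg * frac
  }
  ar <- angle * pi / 180
  elements <- tibble(
    element = seq_len(n),
    ix = idx$ix, iy = idx$iy, iz = idx$iz,
    x_mm = (idx$ix - 0.5) * h_mm,
    y_mm = (idx$iy - 0.5) * h_mm,
    z_mm = (idx$iz - 0.5) * h_mm,
    fx = cos(ar) + 0 * idx$ix, fy = sin(ar) + 0 * idx$ix, fz = 0)

  lin <- function(ix, iy, iz) ix + nx * (iy - 1L) + nx * ny * (iz - 1L)
  adj <- list()
  if (nx > 1L) {
    g <- idx[idx$ix < nx, ]
    adj[[1]] <- tibble(a = lin(g$ix, g$iy, g$iz),
                       b = lin(g$ix + 1L, g$iy, g$iz), axis = 1L)
  }
  if (ny > 1L) {
    g <- idx[idx$iy < ny, ]
    adj[[2]] <- tibble(a = lin(g$ix, g$iy, g$iz),
                       b = lin(g$ix, g$iy + 1L, g$iz), axis = 2L)
  }
  if (nz > 1L) {
    g <- idx[idx$iz < nz, ]
    adj[[3]] <- tibble(a = lin(g$ix, g$iy, g$iz),
                       b = lin(g$ix, g$iy, g$iz + 1L), axis = 3L)
  }
  adjacency <- dplyr::bind_rows(adj)
  adjacency <- adjacency[order(adjacency$a, adjacency$b), ]

  structure(
    list(elements = elements, adjacency = adjacency,
         spacing_um = spec$spacing_um, dims = dims, n_elements = n),
    class = "fs_mesh")
}

#' @export
print.fs_mesh <- function(x, ...) {
  cat(sprintf("<fs_mesh> %s lattice, %d elements, %.1f um spacing, %d faces\n",
              paste(x$dims, collapse = " x "), x$n_elements, x$spacing_um,
              nrow(x$adjacency)))
  invisible(x)
}

#' Standard calibration cable mesh
#'
#' The 10 cm, 530 micron resolution 1D strand used to translate conduction
#' velocities into lattice conductivities.
#'
#' @param length_cm Cable length in cm (default 10).
#' @param spacing_um Element size in micrometers (default 530).
#' @param fiber Direction of the per-element fiber vector: `"along"` the
#'   cable (propagation uses the longitudinal conductivity) or `"across"`
#'   (propagation uses the transverse conductivity).
#' @return An `fs_mesh` with `n = round(length_cm * 1e4 / spacing_um)`
#'   elements in a single chain.
#' @examples
#' cable_mesh()$n_elements
#' @export
cable_mesh <- function(length_cm = 10, spacing_um = 530,
                       fiber = c("along", "across")) {
  fiber <- match.arg(fiber)
  n <- as.integer(round(length_cm * 1e4 / spacing_um))
  angle <- if (fiber == "along") 0 else 90
  generate_mesh(synthetic_spec(grid_shape = c(n, 1L),
                               spacing_um = spacing_um, fiber_angle = angle,
                               lge_pattern = "single_patch",
                               intensity_peak = 0))
}

#' Partition a mesh into contiguous equal-area segments
#'
#' Desk-scale analogue of the 17-segment left-ventricular parcellation used
#' for segment-based pacing and statistics: the sheet is tiled into
#' `n_segments` contiguous rectangular regions by integer division of the
#' lattice indices (a grid of tiles whose row count is the largest divisor
#' of `n_segments` not exceeding its square root; prime counts give strip
#' tilings).
#'
#' @param mesh An `fs_mesh`.
#' @param n_segments Number of segments (default 17, one pacing site each).
#' @return A tibble with `element` and integer `segment` (1-based); every
#'   element receives exactly one label.
#' @examples
#' seg <- generate_segments(generate_mesh(synthetic_spec(c(20, 20))), 4)
#' table(seg$segment)
#' @export
generate_segments <- function(mesh, n_segments = 17L) {
  stopifnot(inherits(mesh, "fs_mesh"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) abort_fs("n_segments must be >= 1", "fs_invalid_spec")
  nx <- mesh$dims[1]; ny <- mesh$dims[2]
  divs <- which(n_segments %% seq_len(n_segments) == 0L)
  r <- max(divs[divs <= floor(sqrt(n_segments))])
  cc <- n_segments %/% r
  # more tiles along the longer axis
  if ((nx >= ny) == (cc >= r)) { tx <- cc; ty <- r } else { tx <- r; ty <- cc }
  el <- mesh$elements
  bx <- pmin(((el$ix - 1L) * tx) %/% nx, tx - 1L)
  by <- pmin(((el$iy - 1L) * ty) %/% ny, ty - 1L)
  tibble(element = el$element, segment = as.integer(bx * ty + by + 1L))
}
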
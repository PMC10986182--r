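#' Generate a synthetic normalized LGE intensity map
#'
#' Produces a per-element late-gadolinium-enhancement intensity in
#' `[0, 1]` emulating the output of an imaging segmentation pipeline:
#' zero in healthy tissue, rising smoothly to `intensity_peak` at patch
#' centers (a dense core surrounded by a gradual border). Patterns:
#'
#' * `single_patch`: one radially decaying patch, by default centered on
#'   the sheet with radius a quarter of the shorter extent.
#' * `multi_patch`: several patches; overlaps take the maximum.
#' * `diffuse_gradient`: a broad low-grade field rising linearly along x,
#'   multiplied by a wide central patch envelope.
#'
#' The radial profile is `peak * (1 - (d/r)^2)^2` for `d < r` and exactly 0
#' outside, so patch boundaries are crisp while the interior is smooth and
#' monotone. Gaussian noise (`noise_sd`) is added inside patches only and
#' the result is clipped to `[0, 1]`, so healthy tissue stays at exactly 0.
#'
#' @param spec An [synthetic_spec()].
#' @param mesh The mesh generated from `spec` (or a compatible one).
#' @return A tibble with columns `element` and `intensity`.
#' @examples
#' spec <- synthetic_spec(c(30, 30), intensity_peak = 0.8, seed = 2)
#' mesh <- generate_mesh(spec)
#' lge <- generate_lge(spec, mesh)
#' range(lge$intensity)
#' @export
generate_lge <- function(spec, mesh) {
  stopifnot(inherits(spec, "fs_spec"), inherits(mesh, "fs_mesh"))
  el <- mesh$elements
  h_mm <- spec$spacing_um / 1000
  ext <- mesh$dims[1:2] * h_mm
  centers <- spec$patch_centers
  if (is.null(centers)) {
    centers <- switch(spec$lge_pattern,
      single_patch = matrix(ext / 2, nrow = 1),
      multi_patch = rbind(ext * 0.3, ext * 0.7),
      diffuse_gradient = matrix(ext / 2, nrow = 1))
  }
  centers <- rbind(centers)
  radii <- spec$patch_radii %||% (min(ext) * switch(spec$lge_pattern,
    single_patch = 0.25, multi_patch = 0.18, diffuse_gradient = 0.45))
  radii <- rep_len(radii, nrow(centers))

  oob <- centers[, 1] < 0 | centers[, 1] > ext[1] |
    centers[, 2] < 0 | centers[, 2] > ext[2]
  if (any(oob)) {
    warning("patch center(s) outside mesh bounds; clipping to the sheet")
    centers[, 1] <- pmin(pmax(centers[, 1], 0), ext[1])
    centers[, 2] <- pmin(pmax(centers[, 2], 0), ext[2])
  }

  base <- rep(0, nrow(el))
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((el$x_mm - centers[k, 1])^2 + (el$y_mm - centers[k, 2])^2)
    prof <- ifelse(d < radii[k], (1 - (d / radii[k])^2)^2, 0)
    base <- pmax(base, prof)
  }
  if (spec$lge_pattern == "diffuse_gradient") {
    base <- base * (0.25 + 0.75 * el$x_mm / ext[1])
  }
  # rescale so the map maximum equals intensity_peak exactly (patch centers
  # rarely coincide with an element center on an even lattice)
  if (max(base) > 0) base <- base / max(base)
  intensity <- spec$intensity_peak * base
  if (spec$noise_sd > 0 && spec$intensity_peak > 0) {
    inside <- intensity > 0
    noise <- with_local_seed(fork_seed(spec$seed, "lge"),
                             rnorm(sum(inside), 0, spec$noise_sd))
    intensity[inside] <- intensity[inside] + noise
    intensity <- pmin(pmax(intensity, 0), 1)
  }
  tibble(element = el$element, intensity = intensity)
}
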
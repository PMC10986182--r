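#' Parameters of the stochastic cleft-splitting rule
#'
#' Interstitial fibrosis is represented by severing element-to-element
#' connections ("clefts"), creating local no-flux boundaries. A face
#' between neighboring elements is removed with probability
#' \deqn{p = p_{max} \cdot I \cdot |\cos\theta|^{\alpha}}
#' where `I` is the face LGE intensity (mean of the two adjacent
#' elements), `theta` the angle between the face normal and the local
#' fiber-sheet-normal direction, `p_max` scales the overall cleft density
#' and `alpha` sharpens the anisotropy (large `alpha` concentrates clefts
#' on faces whose normals align with the sheet normal, i.e. clefts run
#' along fibers). The exponent rendering of the anisotropy term is the
#' package default; `alpha_mode = "cos_arg"` instead evaluates
#' `|cos(alpha * theta)|` for comparison.
#'
#' @param p_max Maximum cleft probability in `[0, 1]`.
#' @param alpha Anisotropy exponent, `>= 0`.
#' @param seed Integer seed for the face-wise Bernoulli draws.
#' @param alpha_mode `"exponent"` (default) or `"cos_arg"`.
#' @return An object of class `fs_cleft_params`.
#' @export
cleft_params <- function(p_max, alpha = 2, seed = 1L,
                         alpha_mode = c("exponent", "cos_arg")) {
  alpha_mode <- match.arg(alpha_mode)
  if (p_max < 0 || p_max > 1) abort_fs("p_max must lie in [0, 1]",
                                       "fs_invalid_spec")
  if (alpha < 0) abort_fs("alpha must be >= 0", "fs_invalid_spec")
  structure(list(p_max = p_max, alpha = alpha, seed = as.integer(seed),
                 alpha_mode = alpha_mode),
            class = "fs_cleft_params")
}

# |cos theta| between each face normal and the fiber-sheet-normal
# direction. In-plane fibers f = (fx, fy, 0): the sheet normal is the
# in-plane normal (-fy, fx, 0); z-faces (axis 3) are orthogonal to it.
face_cos_theta <- function(mesh) {
  el <- mesh$elements
  adj <- mesh$adjacency
  sn_x <- -(el$fy[adj$a] + el$fy[adj$b]) / 2
  sn_y <- (el$fx[adj$a] + el$fx[adj$b]) / 2
  nrm <- sqrt(sn_x^2 + sn_y^2)
  nrm[nrm == 0] <- 1
  ct <- numeric(nrow(adj))
  ct[adj$axis == 1L] <- abs(sn_x / nrm)[adj$axis == 1L]
  ct[adj$axis == 2L] <- abs(sn_y / nrm)[adj$axis == 2L]
  ct[adj$axis == 3L] <- 0
  ct
}

# per-face severing probability under the cleft rule
cleft_face_probability <- function(mesh, lge, params) {
  adj <- mesh$adjacency
  intensity <- lge$intensity[match(mesh$elements$element, lge$element)]
  i_face <- (intensity[adj$a] + intensity[adj$b]) / 2
  ct <- face_cos_theta(mesh)
  aniso <- if (params$alpha_mode == "exponent") {
    ct^params$alpha
  } else {
    abs(cos(params$alpha * acos(pmin(ct, 1))))
  }
  params$p_max * i_face * aniso
}

#' Split cleft faces in a mesh
#'
#' Applies the stochastic cleft rule of [cleft_params()] to every internal
#' face. Elements left with no remaining neighbors are pruned from the
#' model ("completely isolated" tissue). Deterministic given
#' `(mesh, lge, params)` including the seed.
#'
#' @param mesh An `fs_mesh`.
#' @param lge LGE tibble from [generate_lge()].
#' @param params An `fs_cleft_params`.
#' @return An object of class `fs_cleft_mesh`: list with the base `mesh`,
#'   `removed_faces` (tibble `a`, `b`, `axis`), `removed_elements`
#'   (integer), `retained` adjacency tibble, and `params`.
#' @examples
#' spec <- synthetic_spec(c(20, 20), intensity_peak = 1, seed = 3)
#' mesh <- generate_mesh(spec)
#' lge <- generate_lge(spec, mesh)
#' cm <- split_clefts(mesh, lge, cleft_params(0.4, seed = 3))
#' nrow(cm$removed_faces)
#' @export
split_clefts <- function(mesh, lge, params) {
  stopifnot(inherits(mesh, "fs_mesh"), inherits(params, "fs_cleft_params"))
  if (nrow(lge) != mesh$n_elements) {
    abort_fs("lge map and mesh have different element counts",
             "fs_dimension_error")
  }
  adj <- mesh$adjacency
  p <- cleft_face_probability(mesh, lge, params)
  sever <- if (params$p_max == 0) {
    rep(FALSE, nrow(adj))
  } else {
    with_local_seed(fork_seed(params$seed, "cleft"),
                    runif(nrow(adj)) < p)
  }
  removed_faces <- adj[sever, ]
  retained <- adj[!sever, ]
  deg <- tabulate(c(retained$a, retained$b), nbins = mesh$n_elements)
  removed_elements <- which(deg == 0L)
  structure(list(mesh = mesh, removed_faces = removed_faces,
                 removed_elements = as.integer(removed_elements),
                 retained = retained, params = params),
            class = "fs_cleft_mesh")
}

#' @export
print.fs_cleft_mesh <- function(x, ...) {
  cat(sprintf(
    "<fs_cleft_mesh> %d/%d faces severed, %d elements isolated (p_max = %g, alpha = %g)\n",
    nrow(x$removed_faces), nrow(x$mesh$adjacency),
    length(x$removed_elements), x$params$p_max, x$params$alpha))
  invisible(x)
}

#' Build the ordered cleft-density ladder
#'
#' Generates one cleft mesh per parameter combination and orders them by
#' ascending number of severed faces; the position in the sorted list is
#' the global cleft-density index `fib_max` (0-9). The default ladder
#' sweeps `p_max` over 0, 0.1, ..., 0.9 at fixed `alpha = 2`; entry 0 must
#' have `p_max = 0` so that `fib_max = 0` reproduces the unsplit mesh.
#'
#' @param mesh,lge As in [split_clefts()].
#' @param ladder List of 10 [cleft_params()] objects (default as above).
#' @param seed Base seed used for the default ladder entries.
#' @return A list of 10 `fs_cleft_mesh` objects; element `i` has
#'   `fib_max = i - 1` (also stored in each object).
#' @export
build_fibmax_ladder <- function(mesh, lge, ladder = NULL, seed = 1L) {
  if (is.null(ladder)) {
    ladder <- lapply(0:9, function(i) {
      cleft_params(p_max = i / 10, alpha = 2,
                   seed = fork_seed(seed, "cleft", i))
    })
  }
  if (length(ladder) != 10L) {
    abort_fs("ladder must have exactly 10 parameter sets", "fs_config_error")
  }
  if (ladder[[1]]$p_max != 0) {
    abort_fs("ladder entry 1 must have p_max = 0 (zero-cleft control)",
             "fs_config_error")
  }
  metes <- lapply(ladder, function(p) split_clefts(mesh, lge, p))
  n_rm <- vapply(metes, function(m) nrow(m$removed_faces), integer(1))
  ord <- order(n_rm)
  out <- metes[ord]
  for (i in seq_along(out)) out[[i]]$fib_max <- i - 1L
  out
}
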
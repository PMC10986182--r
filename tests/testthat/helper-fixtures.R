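# shared fixture builders (everything generated in code; no stored data)

small_sheet <- function(n = 20, seed = 1, peak = 1, noise = 0, radius = NULL) {
  spec <- synthetic_spec(grid_shape = c(n, n), intensity_peak = peak,
                         noise_sd = noise, patch_radii = radius, seed = seed)
  mesh <- generate_mesh(spec)
  list(spec = spec, mesh = mesh, lge = generate_lge(spec, mesh))
}

# uniform-intensity map on an existing mesh
uniform_lge <- function(mesh, value) {
  tibble::tibble(element = mesh$elements$element,
                 intensity = rep(value, mesh$n_elements))
}

# independent brute-force initiation-cluster oracle: for each back-trace
# step s, connected sets of elements first-reactivated in step s whose
# outside neighbors all reactivate strictly later (or never), restricted
# to clusters >= min_cluster. Mirrors the definition, not the implementation.
oracle_clusters <- function(reentrant, mesh, step_ms = 10, min_cluster = 1) {
  first <- stats::aggregate(time_ms ~ element, reentrant, min)
  step_of <- rep(Inf, mesh$n_elements)
  step_of[first$element] <- floor(first$time_ms / step_ms)
  adj <- mesh$adjacency
  nbrs <- lapply(seq_len(mesh$n_elements), function(i) integer(0))
  for (k in seq_len(nrow(adj))) {
    nbrs[[adj$a[k]]] <- c(nbrs[[adj$a[k]]], adj$b[k])
    nbrs[[adj$b[k]]] <- c(nbrs[[adj$b[k]]], adj$a[k])
  }
  out <- list()
  for (s in sort(unique(step_of[is.finite(step_of)]))) {
    members <- which(step_of == s)
    # connected components among members by repeated flood fill
    unvisited <- members
    while (length(unvisited)) {
      comp <- unvisited[1]
      frontier <- comp
      repeat {
        nxt <- setdiff(intersect(unique(unlist(nbrs[frontier])), unvisited),
                       comp)
        if (!length(nxt)) break
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      unvisited <- setdiff(unvisited, comp)
      outside <- setdiff(unique(unlist(nbrs[comp])), comp)
      if (all(step_of[outside] > s) && length(comp) >= min_cluster) {
        out[[length(out) + 1]] <- list(step = s, elements = sort(comp))
      }
    }
  }
  out
}
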
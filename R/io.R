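#' Write a mesh with element data to a legacy VTK file
#'
#' Serializes the lattice mesh as an ASCII legacy-VTK unstructured grid
#' (quads for sheets, hexahedra for slabs) with per-element (CELL_DATA)
#' arrays: fiber vectors and any extra element fields passed in
#' `element_data` (e.g. LGE intensity, segment labels, region codes).
#' The lattice dimensions and spacing are embedded in the title line so
#' the reader can reconstruct the adjacency exactly.
#'
#' @param mesh An `fs_mesh`.
#' @param path Output file path.
#' @param element_data Optional named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, element_data = list()) {
  stopifnot(inherits(mesh, "fs_mesh"))
  nx <- mesh$dims[1]; ny <- mesh$dims[2]; nz <- mesh$dims[3]
  h <- mesh$spacing_um / 1000
  is3d <- nz > 1L
  npx <- nx + 1L; npy <- ny + 1L; npz <- if (is3d) nz + 1L else 1L
  pts <- expand.grid(px = 0:(npx - 1L), py = 0:(npy - 1L),
                     pz = 0:(npz - 1L))
  pid <- function(px, py, pz) px + npx * (py + npy * pz)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("fibrosim lattice nx=%d ny=%d nz=%d spacing_um=%g",
                       nx, ny, nz, mesh$spacing_um),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(pts))), con)
  writeLines(sprintf("%g %g %g", pts$px * h, pts$py * h, pts$pz * h), con)

  el <- mesh$elements
  if (is3d) {
    corners <- cbind(pid(el$ix - 1L, el$iy - 1L, el$iz - 1L),
                     pid(el$ix, el$iy - 1L, el$iz - 1L),
                     pid(el$ix, el$iy, el$iz - 1L),
                     pid(el$ix - 1L, el$iy, el$iz - 1L),
                     pid(el$ix - 1L, el$iy - 1L, el$iz),
                     pid(el$ix, el$iy - 1L, el$iz),
                     pid(el$ix, el$iy, el$iz),
                     pid(el$ix - 1L, el$iy, el$iz))
    ctype <- 12L
  } else {
    corners <- cbind(pid(el$ix - 1L, el$iy - 1L, 0L),
                     pid(el$ix, el$iy - 1L, 0L),
                     pid(el$ix, el$iy, 0L),
                     pid(el$ix - 1L, el$iy, 0L))
    ctype <- 9L
  }
  k <- ncol(corners)
  writeLines(sprintf("CELLS %d %d", nrow(corners),
                     nrow(corners) * (k + 1L)), con)
  writeLines(paste(k, apply(corners, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(corners)), con)
  writeLines(as.character(rep(ctype, nrow(corners))), con)

  writeLines(sprintf("CELL_DATA %d", nrow(el)), con)
  writeLines("VECTORS fiber float", con)
  writeLines(sprintf("%.9g %.9g %.9g", el$fx, el$fy, el$fz), con)
  for (nm in names(element_data)) {
    v <- element_data[[nm]]
    stopifnot(length(v) == nrow(el))
    if (is.integer(v) || all(v == round(v))) {
      writeLines(c(sprintf("SCALARS %s int 1", nm),
                   "LOOKUP_TABLE default", as.character(as.integer(v))),
                 con)
    } else {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default", sprintf("%.9g", v)), con)
    }
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' Reconstructs the lattice (topology is regenerated from the embedded
#' dimensions, so adjacency is bit-identical), restores the stored fiber
#' field and returns any element-data arrays.
#'
#' @param path VTK file from [write_mesh()].
#' @return List with `mesh` (an `fs_mesh`) and `element_data` (named
#'   list of per-element vectors).
#' @export
read_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !grepl("^# vtk", lines[1])) {
    abort_fs(sprintf("%s: not a VTK legacy file (line 1)", path),
             "fs_parse_error")
  }
  m <- regmatches(lines[2], regexec(
    "nx=(\\d+) ny=(\\d+) nz=(\\d+) spacing_um=([0-9.eE+-]+)", lines[2]))[[1]]
  if (length(m) != 5) {
    abort_fs(sprintf("%s: missing lattice descriptor (line 2)", path),
             "fs_parse_error")
  }
  nx <- as.integer(m[2]); ny <- as.integer(m[3]); nz <- as.integer(m[4])
  spacing <- as.numeric(m[5])
  dims <- if (nz > 1L) c(nx, ny, nz) else c(nx, ny)
  mesh <- generate_mesh(synthetic_spec(grid_shape = dims,
                                       spacing_um = spacing,
                                       intensity_peak = 0))
  n <- mesh$n_elements

  i_cd <- grep("^CELL_DATA", lines)
  if (length(i_cd) != 1) {
    abort_fs(sprintf("%s: CELL_DATA section missing or truncated", path),
             "fs_parse_error")
  }
  i <- i_cd + 1L
  element_data <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^VECTORS fiber", ln)) {
      if (i + n > length(lines)) {
        abort_fs(sprintf("%s: truncated at line %d", path, i),
                 "fs_parse_error")
      }
      vv <- do.call(rbind, strsplit(lines[(i + 1L):(i + n)], " "))
      mesh$elements$fx <- as.numeric(vv[, 1])
      mesh$elements$fy <- as.numeric(vv[, 2])
      mesh$elements$fz <- as.numeric(vv[, 3])
      i <- i + n + 1L
    } else if (grepl("^SCALARS", ln)) {
      nm <- strsplit(ln, " ")[[1]][2]
      typ <- strsplit(ln, " ")[[1]][3]
      if (i + 1L + n > length(lines)) {
        abort_fs(sprintf("%s: truncated at line %d", path, i),
                 "fs_parse_error")
      }
      vals <- lines[(i + 2L):(i + 1L + n)]
      element_data[[nm]] <- if (typ == "int") as.integer(vals)
                            else as.numeric(vals)
      i <- i + n + 2L
    } else if (nzchar(trimws(ln))) {
      abort_fs(sprintf("%s: unexpected content at line %d: '%s'", path, i,
                       ln), "fs_parse_error")
    } else {
      i <- i + 1L
    }
  }
  list(mesh = mesh, element_data = element_data)
}

#' Write / read activation records
#'
#' Tab-separated text with columns `vertex_id`, `activation_index`,
#' `time_ms`. Reading sorts unsorted rows (with a warning) and fails on
#' truncated or malformed lines rather than silently dropping them.
#'
#' @param record Activation tibble (`element`, `index`, `time_ms`).
#' @param path File path.
#' @return `path` (write) / the activation tibble (read).
#' @export
write_activation <- function(record, path) {
  df <- data.frame(vertex_id = record$element,
                   activation_index = record$index,
                   time_ms = record$time_ms)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_activation
#' @export
read_activation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1 ||
      !identical(strsplit(lines[1], "\t")[[1]],
                 c("vertex_id", "activation_index", "time_ms"))) {
    abort_fs(sprintf("%s: bad or missing activation header (line 1)", path),
             "fs_parse_error")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    abort_fs(sprintf("%s: malformed row at line %d", path,
                     which(nf != 3)[1] + 1L), "fs_parse_error")
  }
  df <- tibble(
    element = as.integer(vapply(parts, `[[`, "", 1)),
    index = as.integer(vapply(parts, `[[`, "", 2)),
    time_ms = as.numeric(vapply(parts, `[[`, "", 3)))
  if (anyNA(df$element) || anyNA(df$time_ms)) {
    abort_fs(sprintf("%s: non-numeric field", path), "fs_parse_error")
  }
  if (is.unsorted(order(df$element, df$time_ms)) ||
      any(diff(order(df$element, df$time_ms)) < 0)) {
    # reorder canonically when rows arrive shuffled
  }
  ord <- order(df$element, df$time_ms)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("activation rows were unsorted; sorted on read")
    df <- df[ord, ]
  }
  class(df) <- c("fs_activation", class(df))
  df
}
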
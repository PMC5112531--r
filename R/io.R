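#' Write a TriSurface as ASCII PLY
#'
#' @param surface a \linkS4class{TriSurface}
#' @param file output path.
#' @export
writePly <- function(surface, file) {
  v <- surface@vertices; f <- surface@faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f))
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(file)
}

#' Read an ASCII PLY triangle mesh
#'
#' Minimal reader for the ASCII PLY files this package writes (x/y/z vertex
#' properties, triangular faces).
#'
#' @param file path to a PLY file.
#' @return a \linkS4class{TriSurface}
#' @export
readPly <- function(file) {
  lines <- readLines(file)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("not an ASCII PLY file")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  hdr <- which(lines == "end_header")[1]
  vm <- matrix(scan(text = lines[(hdr + 1):(hdr + nv)], quiet = TRUE),
               nv, byrow = TRUE)[, 1:3, drop = FALSE]
  faces <- if (nf > 0) {
    fm <- matrix(scan(text = lines[(hdr + nv + 1):(hdr + nv + nf)],
                      quiet = TRUE), nf, byrow = TRUE)
    fm[, 2:4, drop = FALSE] + 1L
  } else matrix(integer(0), 0, 3)
  storage.mode(faces) <- "integer"
  triSurface(vm, faces)
}

#' Write per-vertex longitudinal thickness as CSV
#'
#' Long-format table (vertex_id, week, thickness) of a surface series.
#'
#' @param series a \linkS4class{SurfaceSeries} with "thickness" scalars.
#' @param file output path.
#' @export
writeThicknessCsv <- function(series, file) {
  rows <- do.call(rbind, lapply(seq_along(series@timepoints), function(t)
    data.frame(vertex_id = seq_len(nVertices(series@white[[t]])),
               week = series@timepoints[t],
               thickness = scalar(series@white[[t]], "thickness"))))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Write the top-surface profile frames of a run as CSV
#'
#' Columns: frame, g, x, height.
#'
#' @param sim a \linkS4class{SimResult}.
#' @param file output path.
#' @export
writeProfilesCsv <- function(sim, file) {
  rows <- do.call(rbind, lapply(seq_along(sim@profiles), function(i)
    data.frame(frame = i, g = sim@frameGrowth[i],
               x = sim@profiles[[i]][, 1], height = sim@profiles[[i]][, 2])))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read a top-surface profile CSV
#'
#' Reads a file written by \code{\link{writeProfilesCsv}} and returns the
#' requested frame as a two-column (x, height) matrix.
#'
#' @param file path.
#' @param frame frame number; default the last.
#' @export
readProfileCsv <- function(file, frame = NULL) {
  d <- read.csv(file)
  if (is.null(frame)) frame <- max(d$frame)
  d <- d[d$frame == frame, ]
  cbind(x = d$x, height = d$height)
}

#' Write a deformed mesh frame as legacy ASCII VTK
#'
#' Unstructured-grid export of the plate mesh in its current configuration
#' with optional per-element cell data (growth multiplier, layer).
#'
#' @param mesh a \linkS4class{BilayerMesh} (reference configuration).
#' @param x current node positions (interleaved vector, as in
#'   \code{SimResult@final$x}); NULL writes the reference mesh.
#' @param file output path.
#' @param cellData named list of per-element numeric vectors.
#' @export
writeVtkFrame <- function(mesh, x = NULL, file, cellData = list()) {
  d <- ncol(mesh@nodes)
  pos <- if (is.null(x)) mesh@nodes else matrix(x, ncol = d, byrow = TRUE)
  if (d == 2L) pos <- cbind(pos, 0)
  el <- mesh@elements - 1L
  nv <- ncol(el)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "gyrogen frame", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(pos))), con)
  writeLines(paste(pos[, 1], pos[, 2], pos[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * (nv + 1)), con)
  writeLines(do.call(paste, c(list(nv), as.data.frame(el))), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(as.character(rep(if (nv == 4) 9L else 12L, nrow(el))), con)
  if (length(cellData)) {
    writeLines(sprintf("CELL_DATA %d", nrow(el)), con)
    for (nm in names(cellData)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(as.character(cellData[[nm]]), con)
    }
  }
  invisible(file)
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{simConfig}}.
#'
#' @param file path to a YAML file.
#' @return a \linkS4class{SimConfig}
#' @export
readSimConfigYaml <- function(file) {
  y <- yaml::read_yaml(file)
  known <- names(formals(simConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(simConfig, y)
}
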